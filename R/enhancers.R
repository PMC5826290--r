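#' Predict cell-type-specific enhancer candidates
#'
#' GATC fragments with at least a `diff_threshold` rpm difference in
#' all replicates between at least two cell types (same all-pairwise
#' consistent-sign rule as [find_differential_fragments()]) are merged
#' into regions. A region is designated an enhancer candidate when it
#' lies more than `tss_min_dist` bp from every transcriptional start
#' site and does not overlap any coding sequence interval. Candidates
#' are ranked by the magnitude of the accessibility change (the largest
#' minimum cross-replicate difference among member fragments).
#'
#' @param tracks Named list of replicate tracks per cell type.
#' @param map A `fragment_map`.
#' @param ann A `gene_annotation`; must carry CDS intervals (an empty
#'   CDS table is allowed, a missing one is an error since the coding
#'   filter could not be applied).
#' @param peaks Optional `peak_set`; when given, only regions sharing a
#'   fragment with a significant peak are considered.
#' @param diff_threshold rpm difference required in every replicate
#'   pair (default 10, the published enhancer rule; the differential
#'   region rule uses 20).
#' @param tss_min_dist Regions at a TSS distance less than or equal to
#'   this are rejected (default 2000; ties go toward rejection).
#' @param min_fragments Minimum merged run length (default 1).
#' @return An `enhancer_candidates` data frame sorted by decreasing
#'   `magnitude`, with `chrom`, `start`, `end`, `first_id`, `last_id`,
#'   `higher`, `lower`, `magnitude`, `tss_distance`, `overlaps_cds`
#'   (always `FALSE` for returned rows).
#' @export
predict_enhancers <- function(tracks, map, ann, peaks = NULL,
                              diff_threshold = 10, tss_min_dist = 2000,
                              min_fragments = 1L) {
  if (is.null(ann$cds)) {
    stop("annotation carries no CDS intervals; coding-overlap filter ",
         "cannot be applied")
  }
  diff <- find_differential_fragments(tracks, threshold = diff_threshold)
  regions <- merge_differential_fragments(diff, map,
                                          min_fragments = min_fragments)
  if (!is.null(peaks) && nrow(regions) > 0L) {
    keep <- vapply(seq_len(nrow(regions)), function(i) {
      any(peaks$chrom == regions$chrom[i] & peaks$start < regions$end[i] &
            peaks$end > regions$start[i])
    }, logical(1))
    regions <- regions[keep, , drop = FALSE]
  }
  empty <- structure(
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               first_id = integer(0), last_id = integer(0),
               higher = character(0), lower = character(0),
               magnitude = numeric(0), tss_distance = integer(0),
               overlaps_cds = logical(0), stringsAsFactors = FALSE),
    diff_threshold = diff_threshold, tss_min_dist = tss_min_dist,
    class = c("enhancer_candidates", "data.frame"))
  if (nrow(regions) == 0L) return(empty)

  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    # distance from the nearest region edge to the nearest TSS point
    t <- ann$tss[ann$tss$chrom == r$chrom, , drop = FALSE]
    tdist <- if (nrow(t) == 0L) Inf else
      min(pmax(0L, pmax(r$start - t$pos, t$pos - (r$end - 1L))))
    if (tdist <= tss_min_dist) return(NULL)
    cds <- ann$cds
    if (nrow(cds) > 0L &&
          any(cds$chrom == r$chrom & cds$start < r$end &
                cds$end > r$start)) {
      return(NULL)
    }
    hits <- diff[diff$fragment_id >= r$first_id &
                   diff$fragment_id <= r$last_id, , drop = FALSE]
    best <- hits[which.max(hits$magnitude), , drop = FALSE]
    data.frame(chrom = r$chrom, start = r$start, end = r$end,
               first_id = r$first_id, last_id = r$last_id,
               higher = best$higher, lower = best$lower,
               magnitude = best$magnitude,
               tss_distance = as.integer(tdist), overlaps_cds = FALSE,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$magnitude, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, diff_threshold = diff_threshold,
            tss_min_dist = tss_min_dist,
            class = c("enhancer_candidates", "data.frame"))
}

#' Write enhancer candidates as BED6 plus a TSV report
#'
#' @param enh An `enhancer_candidates` object.
#' @param bed_path,tsv_path Output files (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_enhancers <- function(enh, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    out <- data.frame(enh$chrom, enh$start, enh$end,
                      region_name(enh$chrom, enh$start, enh$end),
                      enh$magnitude, "+")
    utils::write.table(out, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(as.data.frame(enh), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(c(bed = bed_path, tsv = tsv_path))
}
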
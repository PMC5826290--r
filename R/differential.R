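#' Find fragments with cell-type differential accessibility
#'
#' A fragment is differential when there exist two cell types A, B such
#' that every replicate of A differs from every replicate of B by more
#' than `threshold` rpm with one consistent sign. Equivalently, per
#' fragment, `min(rpm over A replicates) - max(rpm over B replicates) >
#' threshold` (or the same with A and B swapped). The published rule
#' uses >20 rpm.
#'
#' @param tracks Named list (one element per cell type) of replicate
#'   tracks: each element a list of `signal_track`s / rpm vectors or a
#'   fragments-by-replicates matrix.
#' @param threshold rpm difference that every replicate pair must
#'   exceed.
#' @return A `differential_fragments` data frame with one row per
#'   (fragment, cell-type pair) hit: `fragment_id`, `higher`, `lower`,
#'   `magnitude` (the minimum cross-replicate difference). The attribute
#'   `threshold` records the rule used.
#' @export
find_differential_fragments <- function(tracks, threshold = 20) {
  if (length(tracks) < 2L) stop("need at least two cell types")
  if (is.null(names(tracks)) || any(names(tracks) == "")) {
    stop("tracks must be a named list keyed by cell type")
  }
  mats <- lapply(tracks, as_rpm_matrix)
  nf <- unique(vapply(mats, nrow, integer(1)))
  if (length(nf) != 1L) stop("cell types are over different fragment maps")
  mins <- matrix(vapply(mats, function(m) do.call(pmin, as.data.frame(m)),
                        numeric(nf)), nrow = nf)
  maxs <- matrix(vapply(mats, function(m) do.call(pmax, as.data.frame(m)),
                        numeric(nf)), nrow = nf)
  cts <- names(tracks)
  hits <- list()
  for (i in seq_along(cts)) {
    for (j in seq_along(cts)) {
      if (i == j) next
      mag <- mins[, i] - maxs[, j]
      sel <- which(mag > threshold)
      if (length(sel)) {
        hits[[length(hits) + 1L]] <- data.frame(
          fragment_id = sel, higher = cts[i], lower = cts[j],
          magnitude = mag[sel], stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(fragment_id = integer(0), higher = character(0),
               lower = character(0), magnitude = numeric(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$fragment_id, out$higher, out$lower), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, threshold = threshold,
            class = c("differential_fragments", "data.frame"))
}

#' Merge adjacent differential fragments into regions
#'
#' Fragments selected by [find_differential_fragments()] that are
#' adjacent in the map (consecutive ids on the same chromosome) are
#' merged; runs shorter than `min_fragments` are dropped.
#'
#' @param diff A `differential_fragments` object (or integer fragment
#'   ids).
#' @param map A `fragment_map`.
#' @param min_fragments Minimum run length to keep.
#' @return A `peak_set`-like data frame of merged regions.
#' @export
merge_differential_fragments <- function(diff, map, min_fragments = 1L) {
  ids <- sort(unique(if (is.data.frame(diff)) diff$fragment_id else diff))
  if (length(ids) == 0L) {
    return(peak_set(data.frame(chrom = character(0), start = integer(0),
                               end = integer(0), first_id = integer(0),
                               last_id = integer(0),
                               n_fragments = integer(0), score = numeric(0),
                               height = numeric(0), fdr = numeric(0)),
                    map = map))
  }
  chrom_id <- match(map$chrom, chrom_levels(map))[ids]
  brk <- c(TRUE, diff(ids) != 1L | diff(chrom_id) != 0L)
  grp <- cumsum(brk)
  first <- ids[!duplicated(grp)]
  last <- ids[!duplicated(grp, fromLast = TRUE)]
  keep <- (last - first + 1L) >= min_fragments
  first <- first[keep]; last <- last[keep]
  peak_set(data.frame(chrom = map$chrom[first], start = map$start[first],
                      end = map$end[last], first_id = first, last_id = last,
                      n_fragments = last - first + 1L, score = NA_real_,
                      height = NA_real_, fdr = NA_real_,
                      stringsAsFactors = FALSE),
           map = map)
}

#' Call differentially accessible regions between cell types
#'
#' For each ordered cell-type pair (A, B), replicate-mean tracks are
#' subtracted (negative values zeroed) and the peak caller is run on the
#' comparison track; regions below the FDR threshold are returned.
#'
#' @inheritParams find_differential_fragments
#' @param map A `fragment_map`.
#' @param fdr_threshold FDR cutoff (default 1%).
#' @param n_shuffles,seed,min_rpm Passed to [call_significant_peaks()];
#'   each comparison uses a seed derived deterministically from `seed`.
#' @return Named list of `peak_set`s, one per ordered pair
#'   (`"A_vs_B"`).
#' @export
call_differential_regions <- function(tracks, map, fdr_threshold = 0.01,
                                      n_shuffles = 100, seed = 1,
                                      min_rpm = 0) {
  if (length(tracks) < 2L) stop("need at least two cell types")
  means <- lapply(tracks, function(t) average_replicates(
    if (is.matrix(t)) lapply(seq_len(ncol(t)), function(j) t[, j]) else t))
  cts <- names(tracks)
  out <- list()
  k <- 0L
  for (a in cts) {
    for (b in cts) {
      if (a == b) next
      k <- k + 1L
      cmp <- subtract_tracks(means[[a]], means[[b]], zero_negatives = TRUE)
      out[[paste0(a, "_vs_", b)]] <- call_significant_peaks(
        cmp, map, fdr_threshold = fdr_threshold, n_shuffles = n_shuffles,
        seed = derive_seed(seed, k), min_rpm = min_rpm)
    }
  }
  out
}

#' Region-by-cell-type accessibility matrix
#'
#' Entry (r, c) is the mean rpm over the region's member fragments,
#' averaged across the cell type's replicates.
#'
#' @param regions Data frame of regions with `chrom`, `start`, `end`,
#'   `first_id`, `last_id` (e.g. union of [call_differential_regions()]
#'   output).
#' @param tracks Named list of replicate tracks per cell type.
#' @return Numeric matrix, rows named `chrom:start-end`, columns by cell
#'   type.
#' @export
build_region_matrix <- function(regions, tracks) {
  if (nrow(regions) == 0L) stop("no regions")
  means <- lapply(tracks, function(t) rowMeans(as_rpm_matrix(t)))
  mat <- vapply(means, function(v) {
    vapply(seq_len(nrow(regions)), function(i) {
      mean(v[regions$first_id[i]:regions$last_id[i]])
    }, numeric(1))
  }, numeric(nrow(regions)))
  mat <- matrix(mat, nrow = nrow(regions),
                dimnames = list(region_name(regions$chrom, regions$start,
                                            regions$end),
                                names(tracks)))
  mat
}

#' Merge region sets from several comparisons into one non-redundant set
#'
#' @param region_sets List of `peak_set`s over the same fragment map.
#' @param map A `fragment_map`.
#' @return A `peak_set` of merged (fragment-union) regions.
#' @export
union_regions <- function(region_sets, map) {
  pooled <- do.call(rbind, lapply(region_sets, function(p) {
    as.data.frame(p)[, c("first_id", "last_id"), drop = FALSE]
  }))
  if (is.null(pooled) || nrow(pooled) == 0L) {
    return(merge_differential_fragments(integer(0), map))
  }
  ir <- IRanges::reduce(IRanges::IRanges(pooled$first_id, pooled$last_id),
                        min.gapwidth = 0L)
  first <- IRanges::start(ir); last <- IRanges::end(ir)
  ord <- order(first)
  first <- first[ord]; last <- last[ord]
  peak_set(data.frame(chrom = map$chrom[first], start = map$start[first],
                      end = map$end[last], first_id = first, last_id = last,
                      n_fragments = last - first + 1L, score = NA_real_,
                      height = NA_real_, fdr = NA_real_,
                      stringsAsFactors = FALSE),
           map = map)
}

#' Hierarchically cluster a region accessibility matrix
#'
#' Rows are standardised (zero mean, unit variance; constant rows become
#' zeros with a warning), clustered agglomeratively on Euclidean
#' distance (average linkage by default) and the dendrogram is cut into
#' `k_major` clusters. Deterministic for fixed input; row order does not
#' affect memberships.
#'
#' @param mat Numeric region-by-cell-type matrix.
#' @param k_major Number of major clusters to report.
#' @param linkage `hclust` agglomeration method.
#' @return A `region_clustering`: list with `labels` (named cluster id
#'   per row), `order` (dendrogram row order), `hclust`, `k`.
#' @export
hierarchical_cluster <- function(mat, k_major = 2, linkage = "average") {
  if (nrow(mat) < 2L) stop("need at least two regions to cluster")
  sds <- apply(mat, 1L, stats::sd)
  if (all(sds == 0)) {
    warning("all rows are constant; returning a single cluster")
    return(structure(list(labels = stats::setNames(rep(1L, nrow(mat)),
                                                   rownames(mat)),
                          order = seq_len(nrow(mat)), hclust = NULL,
                          k = 1L),
                     class = "region_clustering"))
  }
  if (any(sds == 0)) warning("constant rows standardised to zero")
  z <- t(scale(t(mat)))
  z[!is.finite(z)] <- 0
  h <- stats::hclust(stats::dist(z), method = linkage)
  labels <- stats::cutree(h, k = min(k_major, nrow(mat)))
  structure(list(labels = labels, order = h$order, hclust = h,
                 k = min(k_major, nrow(mat))),
            class = "region_clustering")
}

#' @export
print.region_clustering <- function(x, ...) {
  cat(sprintf("region clustering: %d regions in %d cluster(s)\n",
              length(x$labels), length(unique(x$labels))))
  invisible(x)
}

#' Extract region sequences for motif analysis
#'
#' One record per region, named `chrom:start-end` (with `:cluster`
#' appended when cluster labels are given), suitable for export to
#' external motif-discovery tools.
#'
#' @param regions Data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param genome Named character vector or `DNAStringSet`.
#' @param clusters Optional cluster label per region.
#' @param path Optional FASTA output file.
#' @return A `DNAStringSet` (invisibly when `path` is given).
#' @export
export_region_sequences <- function(regions, genome, clusters = NULL,
                                    path = NULL) {
  g <- as_genome(genome)
  if (nrow(regions) > 0L) {
    if (!all(regions$chrom %in% names(g))) {
      stop("region on a chromosome absent from the genome")
    }
    lens <- nchar(g)[regions$chrom]
    if (any(regions$start < 0L | regions$end > lens |
              regions$start >= regions$end)) {
      stop("region outside genome bounds")
    }
  }
  seqs <- vapply(seq_len(nrow(regions)), function(i) {
    substr(g[[regions$chrom[i]]], regions$start[i] + 1L, regions$end[i])
  }, character(1))
  ids <- region_name(regions$chrom, regions$start, regions$end)
  if (!is.null(clusters)) ids <- paste0(ids, ":", clusters)
  out <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  if (!is.null(path)) {
    Biostrings::writeXStringSet(out, path)
    return(invisible(out))
  }
  out
}
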
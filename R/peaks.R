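#' Enumerate candidate accessibility peaks
#'
#' A candidate peak is a maximal run of two or more consecutive GATC
#' fragments whose rpm exceeds `min_rpm`. Runs never cross chromosome
#' boundaries. Each peak is scored by the mean rpm over its member
#' fragments; the maximum member rpm is kept as `height`.
#'
#' @param track `signal_track` or rpm vector.
#' @param map A `fragment_map`.
#' @param min_rpm Detection floor; a fragment seeds a run when
#'   `rpm > min_rpm`. Default 0 (any nonzero fragment).
#' @return A `peak_set` data frame with columns `chrom`, `start`, `end`,
#'   `first_id`, `last_id`, `n_fragments`, `score`, `height`, `fdr`
#'   (`NA` until assessed).
#' @export
enumerate_candidate_peaks <- function(track, map, min_rpm = 0) {
  rpm <- as_rpm(track)
  stopifnot(length(rpm) == nrow(map), min_rpm >= 0)
  n <- length(rpm)
  ok <- rpm > min_rpm
  chrom_id <- match(map$chrom, chrom_levels(map))
  change <- if (n > 1L) {
    (ok[-1L] != ok[-n]) | (chrom_id[-1L] != chrom_id[-n])
  } else logical(0)
  seg_first <- which(c(TRUE, change))
  seg_len <- diff(c(seg_first, n + 1L))
  keep <- ok[seg_first] & seg_len >= 2L
  first <- seg_first[keep]
  last <- first + seg_len[keep] - 1L
  cs <- c(0, cumsum(rpm))
  sums <- cs[last + 1L] - cs[first]
  heights <- vapply(seq_along(first),
                    function(i) max(rpm[first[i]:last[i]]), numeric(1))
  peaks <- data.frame(
    chrom = map$chrom[first],
    start = map$start[first],
    end = map$end[last],
    first_id = map$id[first],
    last_id = map$id[last],
    n_fragments = last - first + 1L,
    score = sums / (last - first + 1L),
    height = heights,
    fdr = rep(NA_real_, length(first)),
    stringsAsFactors = FALSE)
  peak_set(peaks, map = map)
}

#' Construct a peak set
#'
#' @param peaks Data frame of peaks (see [enumerate_candidate_peaks()]).
#' @param map Optional `fragment_map`; its signature is attached so
#'   later operations can detect map mismatches.
#' @param fdr_threshold Threshold recorded on the set, if any.
#' @param sample_id Optional sample / cell-type label.
#' @return A `peak_set`.
#' @export
peak_set <- function(peaks, map = NULL, fdr_threshold = NA_real_,
                     sample_id = NA_character_) {
  rownames(peaks) <- NULL
  structure(peaks,
            map_signature = if (!is.null(map)) map_signature(map)
                            else attr(peaks, "map_signature"),
            fdr_threshold = fdr_threshold,
            sample_id = sample_id,
            class = unique(c("peak_set", class(peaks))))
}

#' @export
print.peak_set <- function(x, ...) {
  thr <- attr(x, "fdr_threshold")
  cat(sprintf("peak set: %d peak(s)%s\n", nrow(x),
              if (!is.na(thr)) sprintf(" at FDR < %g", thr) else ""))
  NextMethod()
}

#' Estimate a permutation FDR for candidate peak scores
#'
#' The null model permutes per-fragment rpm values across fragment
#' positions (whole-fragment shuffling), preserving the marginal rpm
#' distribution while destroying spatial runs. For every observed
#' candidate-peak score `s`,
#' `FDR(s) = mean_shuffles #\{null peaks with score >= s\} / #\{observed
#' peaks with score >= s\}`, clipped to `[0, 1]`. The reported value is
#' the q-value `min over thresholds t <= s of FDR(t)` -- the best FDR
#' attainable at any threshold the peak passes -- which is monotone
#' non-increasing in score and immune to the small-denominator noise of
#' the raw ratio at the extreme top scores.
#'
#' @param track `signal_track` or rpm vector.
#' @param map A `fragment_map`.
#' @param n_shuffles Number of permutations (>= 10).
#' @param seed RNG seed; the same seed and inputs give an identical
#'   table.
#' @param min_rpm Candidate detection floor (see
#'   [enumerate_candidate_peaks()]).
#' @return A `peak_fdr` object: `table` (`score`, `fdr`, ascending in
#'   score), `n_shuffles`, `seed`, `n_observed`. Zero observed
#'   candidates yield an empty table.
#' @export
estimate_peak_fdr <- function(track, map, n_shuffles = 100, seed = 1,
                              min_rpm = 0) {
  if (n_shuffles < 10) stop("n_shuffles must be at least 10")
  rpm <- as_rpm(track)
  obs <- enumerate_candidate_peaks(rpm, map, min_rpm = min_rpm)
  if (nrow(obs) == 0L) {
    return(structure(list(table = data.frame(score = numeric(0),
                                             fdr = numeric(0)),
                          n_shuffles = n_shuffles, seed = seed,
                          n_observed = 0L),
                     class = "peak_fdr"))
  }
  null_scores <- with_seed(seed, {
    unlist(lapply(seq_len(n_shuffles), function(i) {
      enumerate_candidate_peaks(sample(rpm), map, min_rpm = min_rpm)$score
    }), use.names = FALSE)
  })
  u <- sort(unique(obs$score))
  cnt <- tabulate(match(obs$score, u), nbins = length(u))
  n_obs_ge <- rev(cumsum(rev(cnt)))
  ns <- sort(null_scores)
  n_null_ge <- length(ns) - findInterval(u, ns, left.open = TRUE)
  fdr <- pmin(1, (n_null_ge / n_shuffles) / n_obs_ge)
  # q-value: best FDR over all thresholds a peak of this score passes
  fdr <- cummin(fdr)
  structure(list(table = data.frame(score = u, fdr = fdr),
                 n_shuffles = n_shuffles, seed = seed,
                 n_observed = nrow(obs)),
            class = "peak_fdr")
}

#' @export
print.peak_fdr <- function(x, ...) {
  cat(sprintf("permutation FDR table: %d score level(s) from %d peak(s), %d shuffles (seed %s)\n",
              nrow(x$table), x$n_observed, x$n_shuffles,
              format(x$seed)))
  invisible(x)
}

#' Look up the FDR of peak scores
#'
#' @param fdr A `peak_fdr` object.
#' @param scores Numeric peak scores.
#' @return FDR per score (the FDR of the largest tabulated score not
#'   exceeding each query; scores below all tabulated scores get 1).
#' @export
fdr_lookup <- function(fdr, scores) {
  tab <- fdr$table
  if (nrow(tab) == 0L) return(rep(NA_real_, length(scores)))
  idx <- findInterval(scores, tab$score)
  out <- rep(1, length(scores))
  out[idx > 0L] <- tab$fdr[idx[idx > 0L]]
  out
}

#' Call significant accessibility peaks
#'
#' Candidate peaks (runs of >= 2 consecutive fragments) are assigned a
#' permutation FDR and those below `fdr_threshold` are returned. The
#' published threshold is a 1% FDR.
#'
#' @inheritParams estimate_peak_fdr
#' @param fdr_threshold Keep peaks with `fdr < fdr_threshold`
#'   (default 0.01).
#' @return A `peak_set` of significant peaks, sorted and non-overlapping.
#' @export
call_significant_peaks <- function(track, map, fdr_threshold = 0.01,
                                   n_shuffles = 100, seed = 1,
                                   min_rpm = 0) {
  rpm <- as_rpm(track)
  cand <- enumerate_candidate_peaks(rpm, map, min_rpm = min_rpm)
  ft <- estimate_peak_fdr(rpm, map, n_shuffles = n_shuffles, seed = seed,
                          min_rpm = min_rpm)
  cand$fdr <- fdr_lookup(ft, cand$score)
  sig <- cand[!is.na(cand$fdr) & cand$fdr < fdr_threshold, , drop = FALSE]
  peak_set(sig, fdr_threshold = fdr_threshold,
           sample_id = if (inherits(track, "signal_track")) track$sample_id
                       else NA_character_)
}

#' Intersect significant peaks across replicates
#'
#' A peak survives only when it shares at least one GATC fragment with a
#' significant peak in every other replicate; surviving overlapping
#' peaks are merged to the union of their fragments. With more than two
#' replicates, presence in all replicates is required.
#'
#' @param a,b `peak_set`s from two replicates over the same fragment
#'   map, or pass a list of sets as `a`.
#' @return A merged `peak_set`, sorted and non-overlapping. Merged peaks
#'   carry the mean member score, the max member height and the max
#'   member FDR.
#' @export
intersect_replicate_peaks <- function(a, b = NULL) {
  sets <- if (is.null(b)) a else list(a, b)
  if (length(sets) < 2L) stop("need at least two replicate peak sets")
  sigs <- lapply(sets, attr, "map_signature")
  sigs <- sigs[!vapply(sigs, is.null, logical(1))]
  if (length(sigs) > 1L) {
    for (s in sigs[-1L]) {
      if (!identical(s, sigs[[1L]])) {
        stop("peak sets were built on different fragment maps")
      }
    }
  }
  pooled <- do.call(rbind, lapply(sets, function(p) {
    as.data.frame(p)[, c("chrom", "start", "end", "first_id", "last_id",
                         "n_fragments", "score", "height", "fdr")]
  }))
  repl <- rep(seq_along(sets), vapply(sets, nrow, integer(1)))
  empty <- peak_set(pooled[0, , drop = FALSE])
  attr(empty, "map_signature") <- if (length(sigs)) sigs[[1L]] else NULL
  if (nrow(pooled) == 0L) return(empty)
  ir <- IRanges::IRanges(pooled$first_id, pooled$last_id)
  merged <- IRanges::reduce(ir, min.gapwidth = 0L)
  ov <- IRanges::findOverlaps(ir, merged)
  comp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  nreps <- vapply(split(repl, comp), function(r) length(unique(r)),
                  integer(1))
  keep_comp <- as.integer(names(nreps)[nreps == length(sets)])
  if (length(keep_comp) == 0L) return(empty)
  rows <- lapply(keep_comp, function(k) {
    members <- pooled[comp == k, , drop = FALSE]
    data.frame(chrom = members$chrom[1L],
               start = min(members$start),
               end = max(members$end),
               first_id = IRanges::start(merged)[k],
               last_id = IRanges::end(merged)[k],
               n_fragments = IRanges::width(merged)[k],
               score = mean(members$score),
               height = max(members$height),
               fdr = max(members$fdr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  sig <- if (length(sigs)) sigs[[1L]] else NULL
  lev <- if (!is.null(sig)) names(sig$chrom_lengths) else unique(out$chrom)
  out <- out[order(match(out$chrom, lev), out$start), , drop = FALSE]
  res <- peak_set(out, fdr_threshold = attr(sets[[1L]], "fdr_threshold"))
  attr(res, "map_signature") <- sig
  res
}

#' Map peaks to potentially regulated genes
#'
#' Genes overlapping a peak are assigned at distance 0. Otherwise the
#' nearest gene on each side within `max_dist` is assigned, unless
#' another gene body lies between the peak edge and that gene; at most
#' one non-overlapping gene is assigned per side. The published rule
#' uses 5 kb.
#'
#' @param peaks A `peak_set` (or data frame with `chrom`, `start`,
#'   `end`).
#' @param ann A `gene_annotation`.
#' @param max_dist Maximum peak-edge-to-gene distance in bp.
#' @return Data frame with `peak`, `gene_id`, `distance` (bp, 0 when
#'   overlapping).
#' @export
assign_peaks_to_genes <- function(peaks, ann, max_dist = 5000) {
  genes <- ann$genes
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    pname <- region_name(p$chrom, p$start, p$end)
    g <- genes[genes$chrom == p$chrom, , drop = FALSE]
    if (nrow(g) == 0L) next
    overl <- g$start < p$end & g$end > p$start
    if (any(overl)) {
      ov <- g[overl, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        peak = pname, gene_id = ov$gene_id, distance = 0L,
        stringsAsFactors = FALSE)
    }
    # left side: gene entirely upstream of the peak
    left <- g[!overl & g$end <= p$start, , drop = FALSE]
    if (nrow(left) > 0L) {
      d <- p$start - left$end
      j <- which(d == min(d))
      j <- j[order(left$gene_id[j])][1L]
      blocked <- any(left$start > left$end[j] & left$end <= p$start &
                       seq_len(nrow(left)) != j)
      if (d[j] <= max_dist && !blocked) {
        out[[length(out) + 1L]] <- data.frame(
          peak = pname, gene_id = left$gene_id[j], distance = d[j],
          stringsAsFactors = FALSE)
      }
    }
    # right side
    right <- g[!overl & g$start >= p$end, , drop = FALSE]
    if (nrow(right) > 0L) {
      d <- right$start - p$end
      j <- which(d == min(d))
      j <- j[order(right$gene_id[j])][1L]
      blocked <- any(right$end < right$start[j] & right$start >= p$end &
                       seq_len(nrow(right)) != j)
      if (d[j] <= max_dist && !blocked) {
        out[[length(out) + 1L]] <- data.frame(
          peak = pname, gene_id = right$gene_id[j], distance = d[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(peak = character(0), gene_id = character(0),
                      distance = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a peak set to BED5 or GFF3
#'
#' BED5 columns are chrom, start, end, name (`chrom:start-end`) and
#' score (peak height, max member rpm). GFF3 output additionally
#' carries the `fdr` attribute.
#'
#' @param peaks A `peak_set`.
#' @param path Output file.
#' @param format `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  if (format == "bed") {
    out <- data.frame(peaks$chrom, peaks$start, peaks$end,
                      region_name(peaks$chrom, peaks$start, peaks$end),
                      peaks$height)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    gr <- GenomicRanges::GRanges(
      peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end))
    S4Vectors::mcols(gr)$type <- "peak"
    S4Vectors::mcols(gr)$score <- peaks$height
    S4Vectors::mcols(gr)$ID <- region_name(peaks$chrom, peaks$start,
                                           peaks$end)
    S4Vectors::mcols(gr)$fdr <- peaks$fdr
    rtracklayer::export(gr, path, format = "gff3")
  }
  invisible(path)
}

#' Read a peak set from BED or GFF3
#'
#' Any BED-like file with at least 3 columns is accepted (e.g. external
#' ATAC or FAIRE peak files); column 5, when present, is taken as the
#' peak height.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return A `peak_set` (fragment columns are `NA` for external peaks).
#' @export
read_peaks <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  if (format == "bed") {
    df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    peaks <- data.frame(chrom = as.character(df[[1L]]),
                        start = as.integer(df[[2L]]),
                        end = as.integer(df[[3L]]),
                        first_id = NA_integer_, last_id = NA_integer_,
                        n_fragments = NA_integer_,
                        score = NA_real_,
                        height = if (ncol(df) >= 5L) as.numeric(df[[5L]])
                                 else NA_real_,
                        fdr = NA_real_, stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    d <- as.data.frame(gr)
    peaks <- data.frame(chrom = as.character(d$seqnames),
                        start = d$start - 1L, end = d$end,
                        first_id = NA_integer_, last_id = NA_integer_,
                        n_fragments = NA_integer_,
                        score = NA_real_,
                        height = if (!is.null(d$score)) d$score else NA_real_,
                        fdr = if (!is.null(d$fdr)) as.numeric(d$fdr)
                              else NA_real_,
                        stringsAsFactors = FALSE)
  }
  peak_set(peaks)
}
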
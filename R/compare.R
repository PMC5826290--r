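#' Fraction of reference peaks recovered by a query peak set
#'
#' A reference peak counts as recovered when at least 1 bp of any query
#' peak overlaps it. Optionally stratified into promoter-proximal
#' (within `promoter_dist` of a TSS) and distal reference peaks.
#'
#' @param query,reference `peak_set`s (or data frames with `chrom`,
#'   `start`, `end`) in the same coordinate system.
#' @param tss Optional TSS table (`chrom`, `pos`) for stratification.
#' @param promoter_dist Promoter window in bp (default 2000).
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return List with `fraction`, `overlapped`, `n_reference`, and, when
#'   `tss` is given, `promoter` and `distal` sublists.
#' @export
peak_overlap_fraction <- function(query, reference, tss = NULL,
                                  promoter_dist = 2000, min_overlap = 1L) {
  if (nrow(reference) == 0L) stop("empty reference peak set")
  hit <- overlaps_any(reference, query, min_overlap = min_overlap)
  out <- list(fraction = mean(hit), overlapped = sum(hit),
              n_reference = nrow(reference))
  if (!is.null(tss)) {
    prox <- vapply(seq_len(nrow(reference)), function(i) {
      t <- tss[tss$chrom == reference$chrom[i], , drop = FALSE]
      nrow(t) > 0L &&
        min(pmax(0L, pmax(reference$start[i] - t$pos,
                          t$pos - (reference$end[i] - 1L)))) <= promoter_dist
    }, logical(1))
    out$promoter <- list(fraction = if (any(prox)) mean(hit[prox]) else NA,
                         overlapped = sum(hit[prox]), n_reference = sum(prox))
    out$distal <- list(fraction = if (any(!prox)) mean(hit[!prox]) else NA,
                       overlapped = sum(hit[!prox]),
                       n_reference = sum(!prox))
  }
  out
}

# logical: does each interval of `a` overlap any interval of `b`?
overlaps_any <- function(a, b, min_overlap = 1L) {
  if (nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  gra <- GenomicRanges::GRanges(a$chrom,
                                IRanges::IRanges(a$start + 1L, a$end))
  grb <- GenomicRanges::GRanges(b$chrom,
                                IRanges::IRanges(b$start + 1L, b$end))
  GenomicRanges::countOverlaps(gra, grb, minoverlap = min_overlap) > 0L
}

#' Monte Carlo significance of peak-set overlap
#'
#' The observed statistic is the number of query peaks overlapping at
#' least one reference peak. In each simulation every query peak is
#' re-placed uniformly at random within its own chromosome (length
#' preserved; placed peaks may overlap each other) and the statistic is
#' recomputed. The empirical p-value is
#' `(1 + #\{null >= observed\}) / (n + 1)`.
#'
#' @param query,reference Peak sets (`chrom`, `start`, `end`).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param n Number of simulations (>= 100).
#' @param seed RNG seed (same seed, same null counts).
#' @return An `overlap_result`: list with `fraction` (of query peaks
#'   overlapped), `observed`, `null` (integer vector of length `n`),
#'   `p_value`, `n_simulations`, `seed`.
#' @export
monte_carlo_overlap <- function(query, reference, chrom_lengths, n = 1000,
                                seed = 1) {
  if (n < 100) stop("n must be at least 100")
  if (nrow(query) == 0L) stop("empty query peak set")
  if (nrow(reference) == 0L) stop("empty reference peak set")
  widths <- query$end - query$start
  lens <- chrom_lengths[query$chrom]
  if (anyNA(lens)) stop("query chromosome missing from chrom_lengths")
  if (any(widths > lens)) stop("peak longer than its chromosome")

  # merged reference intervals per chromosome for fast point queries
  ref <- lapply(split(reference, reference$chrom), function(r) {
    gr <- IRanges::reduce(IRanges::IRanges(r$start + 1L, r$end))
    list(starts = IRanges::start(gr) - 1L, ends = IRanges::end(gr))
  })
  hit_one <- function(chrom, s, w) {
    rr <- ref[[chrom]]
    if (is.null(rr)) return(rep(FALSE, length(s)))
    i <- findInterval(s, rr$starts)
    (i >= 1L & rr$ends[pmax(i, 1L)] > s) |
      (i < length(rr$starts) & rr$starts[i + 1L] < s + w)
  }
  observed <- sum(vapply(seq_len(nrow(query)), function(j) {
    hit_one(query$chrom[j], query$start[j], widths[j])
  }, logical(1)))

  null <- with_seed(seed, {
    counts <- integer(n)
    for (j in seq_len(nrow(query))) {
      smax <- lens[j] - widths[j]
      s <- sample.int(smax + 1L, n, replace = TRUE) - 1L
      counts <- counts + hit_one(query$chrom[j], s, widths[j])
    }
    counts
  })
  p <- (1 + sum(null >= observed)) / (n + 1)
  structure(list(fraction = observed / nrow(query), observed = observed,
                 null = null, p_value = p, n_simulations = n, seed = seed),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo overlap: %d/%s query peaks overlap reference (%.1f%%), p = %.3g (%d simulations)\n",
    x$observed, format(round(x$observed / x$fraction)), 100 * x$fraction,
    x$p_value, x$n_simulations))
  invisible(x)
}

#' Correlation of peak heights at shared peaks
#'
#' Reference peaks are paired with the query peak overlapping them most
#' (by bp); the squared Pearson correlation of the paired heights and
#' its p-value are returned.
#'
#' @param a Query `peak_set` with a `height` column.
#' @param b Reference `peak_set` with a `height` column.
#' @return List with `r2`, `p_value`, `n_pairs` and the `pairs` data
#'   frame. At least 3 shared peaks are required.
#' @export
shared_peak_height_correlation <- function(a, b) {
  gra <- GenomicRanges::GRanges(a$chrom,
                                IRanges::IRanges(a$start + 1L, a$end))
  grb <- GenomicRanges::GRanges(b$chrom,
                                IRanges::IRanges(b$start + 1L, b$end))
  ov <- GenomicRanges::findOverlaps(grb, gra)
  if (length(ov) == 0L) stop("fewer than 3 shared peaks")
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(grb)[qh], IRanges::ranges(gra)[sh]))
  best <- vapply(split(seq_along(qh), qh),
                 function(ii) ii[which.max(w[ii])], integer(1))
  pairs <- data.frame(ref = qh[best], query = sh[best],
                      height_ref = b$height[qh[best]],
                      height_query = a$height[sh[best]])
  if (nrow(pairs) < 3L) stop("fewer than 3 shared peaks")
  ct <- stats::cor.test(pairs$height_query, pairs$height_ref,
                        method = "pearson")
  list(r2 = unname(ct$estimate)^2, p_value = ct$p.value,
       n_pairs = nrow(pairs), pairs = pairs)
}

#' Rank correlation matrix of cell-type tracks
#'
#' Spearman rank correlation between replicate-mean rpm tracks, one per
#' cell type. The matrix is exactly symmetric with unit diagonal;
#' entries involving a constant track are `NA` with a warning.
#'
#' @param tracks Named list of rpm vectors (one per cell type) or a
#'   fragments-by-cell-types matrix.
#' @param method Correlation method (default `"spearman"`).
#' @return Symmetric correlation matrix.
#' @export
correlation_matrix <- function(tracks, method = "spearman") {
  m <- as_rpm_matrix(tracks)
  if (is.list(tracks) && !is.null(names(tracks))) colnames(m) <- names(tracks)
  if (ncol(m) < 2L) stop("need at least two tracks")
  const <- apply(m, 2L, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning("constant track(s): ",
            paste(colnames(m)[const], collapse = ", "),
            "; correlations undefined (NA)")
  }
  cc <- suppressWarnings(stats::cor(m, method = method))
  cc[const, ] <- NA_real_
  cc[, const] <- NA_real_
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  cc
}

#' Principal component analysis of cell-type tracks
#'
#' PCA of the cell-type-by-fragment matrix of replicate-mean rpm
#' (fragments as features, centred, unscaled).
#'
#' @param tracks Named list of rpm vectors, one per cell type (>= 3).
#' @param n_components Number of components to return (default all).
#' @return List with `coordinates` (cell types x components),
#'   `variance_explained` (non-increasing fractions summing to <= 1)
#'   and the `prcomp` fit.
#' @export
pca_cell_types <- function(tracks, n_components = NULL) {
  m <- t(as_rpm_matrix(tracks))
  rownames(m) <- names(tracks)
  if (nrow(m) < 3L) stop("need at least three cell types")
  if (!is.null(n_components) && n_components > nrow(m)) {
    stop("fewer cell types than requested components")
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  k <- n_components %||% ncol(fit$x)
  list(coordinates = fit$x[, seq_len(min(k, ncol(fit$x))), drop = FALSE],
       variance_explained = ve[seq_len(min(k, length(ve)))],
       fit = fit)
}
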
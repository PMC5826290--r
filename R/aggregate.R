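#' Average signal profile around anchor points
#'
#' Signal is piecewise-constant per GATC fragment: each base pair takes
#' the rpm of its fragment, windows of `2 * flank` bp are centred on the
#' anchors (strand-flipped for minus-strand anchors), binned at `bin`
#' bp, and averaged over anchors. Windows truncated by a chromosome end
#' contribute only their covered base pairs.
#'
#' @param track `signal_track` or rpm vector.
#' @param map A `fragment_map`.
#' @param anchors Data frame with `chrom`, `pos` (0-based bp) and
#'   optionally `strand` (`+` assumed).
#' @param flank Half-window in bp (default 2000).
#' @param bin Bin width in bp (default 10; `flank` must be a multiple).
#' @return An `aggregation_profile` data frame with `offset` (bin
#'   midpoint relative to the anchor), `mean` and `n` (bp contributions
#'   per bin); attributes `n_anchors`, `bin`, `flank`.
#' @export
aggregate_at_points <- function(track, map, anchors, flank = 2000,
                                bin = 10) {
  rpm <- as_rpm(track)
  stopifnot(length(rpm) == nrow(map), flank >= bin, flank %% bin == 0)
  if (nrow(anchors) == 0L) stop("no anchors")
  if (is.null(anchors$strand)) anchors$strand <- "+"
  cl <- attr(map, "chrom_lengths")
  idx <- split(seq_len(nrow(map)), map$chrom)
  nbins <- 2L * flank %/% bin
  sums <- numeric(nbins)
  counts <- numeric(nbins)
  rel <- seq_len(2L * flank) - 1L - flank       # -flank .. flank-1
  bin_id <- rel %/% bin + flank %/% bin + 1L    # 1 .. nbins
  for (i in seq_len(nrow(anchors))) {
    ch <- anchors$chrom[i]
    rows <- idx[[ch]]
    if (is.null(rows)) stop("anchor on chromosome absent from the map")
    gpos <- if (anchors$strand[i] == "-") anchors$pos[i] - rel
            else anchors$pos[i] + rel
    ok <- gpos >= 0L & gpos < cl[[ch]]
    if (!any(ok)) next
    vals <- rpm[rows[findInterval(gpos[ok], map$start[rows])]]
    b <- bin_id[ok]
    sums <- sums + rowsum_fixed(vals, b, nbins)
    counts <- counts + tabulate(b, nbins)
  }
  prof <- data.frame(offset = (seq_len(nbins) - 1L) * bin - flank + bin / 2,
                     mean = ifelse(counts > 0, sums / counts, NA_real_),
                     n = counts)
  structure(prof, n_anchors = nrow(anchors), bin = bin, flank = flank,
            class = c("aggregation_profile", "data.frame"))
}

# sum `x` into `nbins` groups given integer group ids
rowsum_fixed <- function(x, g, nbins) {
  out <- numeric(nbins)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Average signal profile over scaled intervals
#'
#' Interval bodies are rescaled to a common internal length (sampled at
#' `body_bins` relative positions); flanks are kept in real bp and
#' binned at `bin` bp. Zero-length intervals are skipped with a
#' warning.
#'
#' @param track `signal_track` or rpm vector.
#' @param map A `fragment_map`.
#' @param intervals Data frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. an external peak or enhancer set.
#' @param flank Flank length in bp (default 2000).
#' @param bin Flank bin width in bp (default 10).
#' @param body_bins Number of internal body bins (default 100; the body
#'   spans 1000 internal units regardless of true length).
#' @return An `aggregation_profile` data frame with `position`
#'   (upstream bp < 0, body 0..1000 units, downstream > 1000), `mean`
#'   and `n` (intervals contributing).
#' @export
aggregate_at_intervals <- function(track, map, intervals, flank = 2000,
                                   bin = 10, body_bins = 100) {
  rpm <- as_rpm(track)
  stopifnot(length(rpm) == nrow(map), flank >= bin, flank %% bin == 0)
  if (nrow(intervals) == 0L) stop("no intervals")
  zero <- intervals$end <= intervals$start
  if (any(zero)) {
    warning(sum(zero), " zero-length interval(s) skipped")
    intervals <- intervals[!zero, , drop = FALSE]
    if (nrow(intervals) == 0L) stop("no usable intervals")
  }
  cl <- attr(map, "chrom_lengths")
  idx <- split(seq_len(nrow(map)), map$chrom)
  nfl <- flank %/% bin
  npos <- nfl + body_bins + nfl
  sums <- numeric(npos)
  counts <- numeric(npos)
  value_at <- function(ch, pos) {
    rows <- idx[[ch]]
    ok <- pos >= 0L & pos < cl[[ch]]
    v <- rep(NA_real_, length(pos))
    if (any(ok)) v[ok] <- rpm[rows[findInterval(pos[ok], map$start[rows])]]
    v
  }
  up_rel <- seq_len(flank) - 1L - flank     # -flank .. -1
  up_bin <- up_rel %/% bin + nfl + 1L       # 1 .. nfl
  dn_rel <- seq_len(flank) - 1L             # 0 .. flank-1
  dn_bin <- dn_rel %/% bin + nfl + body_bins + 1L
  for (i in seq_len(nrow(intervals))) {
    ch <- intervals$chrom[i]
    if (is.null(idx[[ch]])) stop("interval on chromosome absent from map")
    s <- intervals$start[i]; e <- intervals$end[i]
    w <- e - s
    # flank bins: mean of covered bp per bin
    for (side in 1:2) {
      pos <- if (side == 1L) s + up_rel else e + dn_rel
      bid <- if (side == 1L) up_bin else dn_bin
      v <- value_at(ch, pos)
      ok <- !is.na(v)
      if (any(ok)) {
        bs <- rowsum_fixed(v[ok], bid[ok], npos)
        bc <- tabulate(bid[ok], npos)
        contrib <- bc > 0
        sums[contrib] <- sums[contrib] + bs[contrib] / bc[contrib]
        counts[contrib] <- counts[contrib] + 1
      }
    }
    # body: one sample per internal bin at the bin-centre quantile
    f <- (seq_len(body_bins) - 0.5) / body_bins
    pos <- s + pmin(w - 1L, floor(f * w))
    v <- value_at(ch, pos)
    bid <- nfl + seq_len(body_bins)
    sums[bid] <- sums[bid] + v
    counts[bid] <- counts[bid] + 1
  }
  body_units <- 1000
  position <- c(up_rel[!duplicated(up_bin)] + bin / 2,
                (seq_len(body_bins) - 0.5) / body_bins * body_units,
                body_units + dn_rel[!duplicated(dn_bin)] + bin / 2)
  prof <- data.frame(position = position,
                     mean = ifelse(counts > 0, sums / counts, NA_real_),
                     n = counts)
  structure(prof, n_intervals = nrow(intervals), bin = bin, flank = flank,
            body_bins = body_bins,
            class = c("aggregation_profile", "data.frame"))
}

#' Write an aggregation profile as TSV
#'
#' @param profile An `aggregation_profile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
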
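#' Read mapped read placements
#'
#' A read placement is the 5' position of one mapped read. Accepted
#' formats: BED (3+ columns; for minus-strand reads the 5' end is the
#' interval end minus one) and a minimal 3-column TSV
#' (`chrom`, `pos`, `strand`) with 0-based positions.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"bed"` or `"tsv"`.
#' @return Data frame with columns `chrom`, `pos` (0-based), `strand`.
#' @export
read_read_placements <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    d <- as.data.frame(gr)
    strand <- as.character(d$strand)
    strand[strand == "*"] <- "+"
    pos <- ifelse(strand == "-", d$end - 1L, d$start - 1L)
    return(data.frame(chrom = as.character(d$seqnames), pos = as.integer(pos),
                      strand = strand, stringsAsFactors = FALSE))
  }
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = as.character(df[[1L]]), pos = as.integer(df[[2L]]),
             strand = if (ncol(df) >= 3L) as.character(df[[3L]]) else "+",
             stringsAsFactors = FALSE)
}

#' Write read placements as BED6
#'
#' Each read becomes a 1-bp interval at its 5' position.
#'
#' @param reads Data frame with `chrom`, `pos`, `strand`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_read_placements <- function(reads, path) {
  out <- data.frame(reads$chrom, reads$pos, reads$pos + 1L,
                    paste0("read_", seq_len(nrow(reads))), 0L, reads$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Count reads per GATC fragment
#'
#' Each read is assigned to the unique fragment containing its 5'
#' position (fragments are half-open, so a read placed exactly on a
#' GATC boundary belongs to the downstream fragment). Reads on
#' chromosomes absent from the map, or with positions outside the
#' chromosome, are skipped and counted.
#'
#' @param reads Data frame with `chrom`, `pos` (0-based).
#' @param map A `fragment_map`.
#' @return Integer vector of counts, one per fragment, with attributes
#'   `assigned` and `skipped`. A warning is raised when reads are skipped.
#' @export
count_reads_per_fragment <- function(reads, map) {
  counts <- integer(nrow(map))
  skipped <- 0L
  cl <- attr(map, "chrom_lengths")
  for (ch in unique(reads$chrom)) {
    pos <- reads$pos[reads$chrom == ch]
    if (!ch %in% names(cl)) {
      skipped <- skipped + length(pos)
      next
    }
    ok <- pos >= 0L & pos < cl[[ch]]
    skipped <- skipped + sum(!ok)
    pos <- pos[ok]
    if (length(pos) == 0L) next
    rows <- which(map$chrom == ch)
    idx <- findInterval(pos, map$start[rows])
    tab <- tabulate(idx, nbins = length(rows))
    counts[rows] <- counts[rows] + tab
  }
  if (skipped > 0L) {
    warning(sprintf("%d read(s) outside the fragment map were skipped",
                    skipped))
  }
  attr(counts, "assigned") <- sum(counts)
  attr(counts, "skipped") <- skipped
  counts
}

#' Normalize raw fragment counts to reads per million
#'
#' `rpm[i] = raw[i] * 1e6 / sum(raw)`; the denominator is the number of
#' assigned reads, so `sum(rpm) == 1e6` up to floating point.
#'
#' @param raw Non-negative count vector with at least one nonzero entry.
#' @return Numeric rpm vector.
#' @export
normalize_rpm <- function(raw) {
  raw <- as.numeric(raw)
  if (any(raw < 0)) stop("negative counts")
  total <- sum(raw)
  if (total == 0) stop("no assigned reads")
  raw * 1e6 / total
}

#' Subtract one rpm track from another
#'
#' Comparison tracks between cell types are formed by subtraction with
#' negative values zeroed, so that each direction of change gets its own
#' track.
#'
#' @param a,b rpm vectors over the same fragment map.
#' @param zero_negatives Clamp negative differences to zero (default).
#' @return Numeric difference vector.
#' @export
subtract_tracks <- function(a, b, zero_negatives = TRUE) {
  a <- as_rpm(a); b <- as_rpm(b)
  if (length(a) != length(b)) stop("tracks have different lengths")
  d <- a - b
  if (zero_negatives) d <- pmax(d, 0)
  d
}

#' Average replicate tracks
#'
#' @param tracks Non-empty list of `signal_track`s or rpm vectors over
#'   the same fragment map.
#' @return Elementwise mean rpm vector.
#' @export
average_replicates <- function(tracks) {
  if (length(tracks) == 0L) stop("no tracks to average")
  m <- as_rpm_matrix(tracks)
  rowMeans(m)
}

#' Build a signal track from raw fragment counts
#'
#' @param raw Integer count vector (one entry per fragment of `map`).
#' @param map A `fragment_map` (optional; used for length validation and
#'   carried as a signature).
#' @param sample_id,cell_type,replicate Sample metadata.
#' @return A `signal_track`: list with `raw`, `rpm`, `total_reads`,
#'   `assigned_reads`, `skipped_reads` and the metadata.
#' @export
signal_track <- function(raw, map = NULL, sample_id = "sample",
                         cell_type = NA_character_,
                         replicate = NA_integer_) {
  if (!is.null(map) && length(raw) != nrow(map)) {
    stop("count vector length does not match the fragment map")
  }
  assigned <- attr(raw, "assigned") %||% sum(raw)
  skipped <- attr(raw, "skipped") %||% 0L
  structure(list(sample_id = sample_id, cell_type = cell_type,
                 replicate = replicate,
                 raw = as.integer(raw),
                 rpm = normalize_rpm(raw),
                 total_reads = assigned + skipped,
                 assigned_reads = assigned,
                 skipped_reads = skipped),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf(
    "signal track '%s' (%s, rep %s): %d fragments, %d assigned reads\n",
    x$sample_id, x$cell_type, x$replicate, length(x$raw), x$assigned_reads))
  invisible(x)
}

# accept a signal_track or a bare rpm vector
as_rpm <- function(x) {
  if (inherits(x, "signal_track")) x$rpm else as.numeric(x)
}

# list of tracks/vectors -> fragments x replicates matrix
as_rpm_matrix <- function(tracks) {
  if (is.matrix(tracks)) return(tracks)
  if (inherits(tracks, "signal_track") || is.numeric(tracks)) {
    tracks <- list(tracks)
  }
  cols <- lapply(tracks, as_rpm)
  n <- unique(vapply(cols, length, integer(1)))
  if (length(n) != 1L) stop("tracks are over different fragment maps")
  do.call(cbind, cols)
}

#' Write an rpm track as bedGraph
#'
#' One line per fragment, ordered by chromosome then start.
#'
#' @param x `signal_track` or rpm vector.
#' @param map A `fragment_map`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(x, map, path) {
  rpm <- as_rpm(x)
  stopifnot(length(rpm) == nrow(map))
  gr <- GenomicRanges::GRanges(map$chrom,
                               IRanges::IRanges(map$start + 1L, map$end),
                               score = rpm)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a per-fragment score track (bedGraph or GFF)
#'
#' Intervals must coincide with the fragments of `map`; fragments absent
#' from the file get score 0.
#'
#' @param path bedGraph or GFF file with one score per GATC fragment.
#' @param map A `fragment_map`.
#' @param format `"auto"` (by extension), `"bedGraph"` or `"gff"`.
#' @return Numeric score vector ordered by fragment id.
#' @export
read_track_scores <- function(path, map, format = c("auto", "bedGraph",
                                                    "gff")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("gff3?$", path, ignore.case = TRUE)) "gff"
              else "bedGraph"
  }
  gr <- if (format == "gff") rtracklayer::import(path, format = "gff3")
        else rtracklayer::import(path, format = "bedGraph")
  d <- as.data.frame(gr)
  key_file <- paste0(as.character(d$seqnames), ":", d$start - 1L)
  key_map <- paste0(map$chrom, ":", map$start)
  idx <- match(key_file, key_map)
  if (anyNA(idx)) {
    stop("intervals in ", path, " do not match the fragment map")
  }
  out <- numeric(nrow(map))
  out[idx] <- d$score
  out
}
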
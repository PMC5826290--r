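# Brute-force reference implementations and tiny fixture builders.
# Oracles are deliberately written in the most literal style possible
# (per-element loops, no vectorised shortcuts) so they share no code
# paths with the package implementations they check.

# fragment map from per-chromosome fragment length vectors,
# e.g. toy_map(chrA = c(2, 6, 6))
toy_map <- function(...) {
  chroms <- list(...)
  rows <- lapply(names(chroms), function(ch) {
    l <- as.integer(chroms[[ch]])
    data.frame(chrom = ch,
               start = cumsum(c(0L, l[-length(l)])),
               end = cumsum(l),
               stringsAsFactors = FALSE)
  })
  fragment_map(do.call(rbind, rows))
}

# literal run finder: maximal runs of >= 2 consecutive same-chromosome
# fragments with rpm > min_rpm
oracle_candidate_peaks <- function(rpm, map, min_rpm = 0) {
  out <- list()
  cur <- integer(0)
  flush <- function() {
    if (length(cur) >= 2L) {
      out[[length(out) + 1L]] <<- data.frame(
        first_id = cur[1L], last_id = cur[length(cur)],
        score = mean(rpm[cur]), height = max(rpm[cur]))
    }
    cur <<- integer(0)
  }
  for (i in seq_along(rpm)) {
    new_chrom <- length(cur) > 0L &&
      map$chrom[i] != map$chrom[cur[length(cur)]]
    if (new_chrom) flush()
    if (rpm[i] > min_rpm) cur <- c(cur, i) else flush()
  }
  flush()
  if (length(out) == 0L) {
    return(data.frame(first_id = integer(0), last_id = integer(0),
                      score = numeric(0), height = numeric(0)))
  }
  do.call(rbind, out)
}

# literal gene assignment: overlap at 0; else nearest per side within
# max_dist (ties broken by gene_id, matching the documented rule)
oracle_assign_genes <- function(peaks, genes, max_dist = 5000) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    pname <- sprintf("%s:%d-%d", p$chrom, p$start, p$end)
    for (k in seq_len(nrow(genes))) {
      g <- genes[k, ]
      if (g$chrom == p$chrom && g$start < p$end && g$end > p$start) {
        rows[[length(rows) + 1L]] <- data.frame(
          peak = pname, gene_id = g$gene_id, distance = 0L,
          stringsAsFactors = FALSE)
      }
    }
    for (side in c("left", "right")) {
      best <- NULL
      for (k in seq_len(nrow(genes))) {
        g <- genes[k, ]
        if (g$chrom != p$chrom) next
        if (g$start < p$end && g$end > p$start) next
        d <- if (side == "left" && g$end <= p$start) p$start - g$end
             else if (side == "right" && g$start >= p$end) g$start - p$end
             else next
        if (is.null(best) || d < best$d ||
              (d == best$d && g$gene_id < best$gene_id)) {
          best <- list(gene_id = g$gene_id, d = d)
        }
      }
      if (!is.null(best) && best$d <= max_dist) {
        rows[[length(rows) + 1L]] <- data.frame(
          peak = pname, gene_id = best$gene_id, distance = best$d,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(peak = character(0), gene_id = character(0),
                      distance = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# literal all-pairwise differential rule: fragment f is a hit for the
# ordered pair (A higher, B lower) when every replicate of A exceeds
# every replicate of B by more than the threshold at f
oracle_differential <- function(mats, threshold) {
  cts <- names(mats)
  nf <- nrow(mats[[1L]])
  rows <- list()
  for (f in seq_len(nf)) {
    for (a in cts) {
      for (b in cts) {
        if (a == b) next
        diffs <- c()
        for (ra in seq_len(ncol(mats[[a]]))) {
          for (rb in seq_len(ncol(mats[[b]]))) {
            diffs <- c(diffs, mats[[a]][f, ra] - mats[[b]][f, rb])
          }
        }
        if (all(diffs > threshold)) {
          rows[[length(rows) + 1L]] <- data.frame(
            fragment_id = f, higher = a, lower = b,
            magnitude = min(diffs), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(fragment_id = integer(0), higher = character(0),
                      lower = character(0), magnitude = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$fragment_id, out$higher, out$lower), , drop = FALSE]
}

# literal TSS-distance / CDS-overlap enhancer filters applied to merged
# differential runs; returns accepted regions as chrom:start-end keys
oracle_enhancer_regions <- function(tracks, map, ann, diff_threshold = 10,
                                    tss_min_dist = 2000) {
  mats <- lapply(tracks, function(t) do.call(cbind, lapply(t, function(x) {
    if (inherits(x, "signal_track")) x$rpm else x
  })))
  hits <- oracle_differential(mats, diff_threshold)
  ids <- sort(unique(hits$fragment_id))
  regions <- list()
  cur <- integer(0)
  flush <- function() {
    if (length(cur) > 0L) regions[[length(regions) + 1L]] <<- cur
    cur <<- integer(0)
  }
  for (id in ids) {
    if (length(cur) > 0L &&
          (id != cur[length(cur)] + 1L ||
             map$chrom[id] != map$chrom[cur[length(cur)]])) flush()
    cur <- c(cur, id)
  }
  flush()
  accepted <- character(0)
  for (r in regions) {
    s <- map$start[r[1L]]
    e <- map$end[r[length(r)]]
    ch <- map$chrom[r[1L]]
    dmin <- Inf
    for (k in seq_len(nrow(ann$tss))) {
      t <- ann$tss[k, ]
      if (t$chrom != ch) next
      d <- if (t$pos >= s && t$pos < e) 0L
           else if (t$pos < s) s - t$pos else t$pos - (e - 1L)
      dmin <- min(dmin, d)
    }
    if (dmin <= tss_min_dist) next
    cds_hit <- FALSE
    for (k in seq_len(nrow(ann$cds))) {
      cc <- ann$cds[k, ]
      if (cc$chrom == ch && cc$start < e && cc$end > s) cds_hit <- TRUE
    }
    if (cds_hit) next
    accepted <- c(accepted, sprintf("%s:%d-%d", ch, s, e))
  }
  sort(accepted)
}

# random rpm track that mixes zeros, low values and occasional spikes,
# exercising run boundaries of every flavour
random_rpm <- function(n) {
  x <- stats::runif(n, 0, 4)
  x[stats::runif(n) < 0.45] <- 0
  spikes <- stats::runif(n) < 0.05
  x[spikes] <- stats::runif(sum(spikes), 30, 80)
  x
}
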
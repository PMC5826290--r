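#' Specify a synthetic CATaDa study
#'
#' Describes a small multi-chromosome genome with realistic GATC
#' spacing, cell-type accessibility landscapes containing shared and
#' cell-type-specific open regions (runs of at least two consecutive
#' high-signal fragments), replicate noise, and multinomial read
#' sampling at a configurable depth.
#'
#' Region strengths and background levels are expected-intensity units
#' on the rpm scale of a full-size genome; on a desk-scale fragment map
#' the realised rpm are a common constant multiple of these (per-track
#' rpm always sum to one million), which leaves every run-detection,
#' FDR and recovery property unchanged. Ground truth records the
#' realised expectation per fragment.
#'
#' @param seed Mandatory RNG seed.
#' @param n_chroms,chrom_length Genome shape (default 2 x 2 Mb).
#' @param gatc_mean_spacing Mean GATC spacing in bp (geometric model;
#'   must be >= 8). The fly genome has a median spacing of ~200 bp.
#' @param n_genes,gene_length Number of genes and length range in bp.
#' @param cell_types Character vector of cell-type names.
#' @param lineages Optional named vector mapping cell types to lineage
#'   labels; lineage-shared open regions are added when
#'   `n_lineage_regions > 0`.
#' @param replicates Replicates per cell type.
#' @param depth Reads sampled per replicate.
#' @param background_rpm Range of the uniform background intensity of
#'   fragments that are not fully closed.
#' @param closed_fraction Fraction of fragments with zero intensity
#'   (fully closed chromatin, inaccessible to Dam); these break runs of
#'   consecutive accessible fragments, as in real data.
#' @param n_shared_regions,n_specific_regions,n_lineage_regions Numbers
#'   of open-region runs shared by all cell types, specific to each
#'   cell type, and shared within each lineage.
#' @param region_width Range of run widths in fragments (>= 2).
#' @param region_strength Added intensity of an open region.
#' @param breadth Fraction of fragments given low non-zero
#'   accessibility per cell type (named vector or single value);
#'   stem-like types have a larger breadth.
#' @param low_rpm Intensity range of the low-accessibility class.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(seed,
                            n_chroms = 2L,
                            chrom_length = 2e6,
                            gatc_mean_spacing = 200,
                            n_genes = 60L,
                            gene_length = c(2000L, 8000L),
                            cell_types = c("stem", "neuron"),
                            lineages = NULL,
                            replicates = 2L,
                            depth = 1e6,
                            background_rpm = c(0, 2),
                            closed_fraction = 0.4,
                            n_shared_regions = 10L,
                            n_specific_regions = 10L,
                            n_lineage_regions = 0L,
                            region_width = c(2L, 3L),
                            region_strength = 50,
                            breadth = 0.15,
                            low_rpm = c(1, 3)) {
  if (missing(seed)) stop("seed is mandatory")
  if (gatc_mean_spacing < 8) {
    stop("gatc_mean_spacing below 8 bp risks motif collisions")
  }
  if (any(region_width < 2L)) stop("open regions must span >= 2 fragments")
  if (depth <= 0) stop("depth must be positive")
  if (region_strength <= max(background_rpm)) {
    stop("region strength must exceed the background level")
  }
  if (is.null(names(breadth))) {
    breadth <- stats::setNames(rep(breadth, length.out = length(cell_types)),
                               cell_types)
  }
  spec <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
               chrom_length = as.integer(chrom_length),
               gatc_mean_spacing = gatc_mean_spacing,
               n_genes = as.integer(n_genes),
               gene_length = as.integer(gene_length),
               cell_types = cell_types, lineages = lineages,
               replicates = as.integer(replicates), depth = depth,
               background_rpm = background_rpm,
               closed_fraction = closed_fraction,
               n_shared_regions = as.integer(n_shared_regions),
               n_specific_regions = as.integer(n_specific_regions),
               n_lineage_regions = as.integer(n_lineage_regions),
               region_width = as.integer(region_width),
               region_strength = region_strength,
               breadth = breadth, low_rpm = low_rpm)
  structure(spec, class = "simulation_spec")
}

#' Generate a synthetic genome, fragment map and annotation
#'
#' Random sequence with GATC motifs placed at geometrically distributed
#' spacings (accidental motifs are removed, so motif positions are
#' exactly the drawn ones), plus genes with TSS and single CDS
#' intervals placed so that both promoter-proximal and distal open
#' regions can exist. Deterministic per seed.
#'
#' @param spec A `simulation_spec`.
#' @return List with `genome` (named character), `map`
#'   (`fragment_map`) and `annotation` (`gene_annotation`).
#' @export
generate_genome <- function(spec) {
  with_seed(derive_seed(spec$seed, 1L), {
    chroms <- paste0("chrS", seq_len(spec$n_chroms))
    genome <- character(0)
    for (ch in chroms) {
      genome[[ch]] <- random_chromosome(spec$chrom_length,
                                        spec$gatc_mean_spacing)
    }
    map <- build_fragment_map(genome)
    ann <- random_annotation(chroms, spec)
    list(genome = genome, map = map, annotation = ann)
  })
}

# one chromosome: random ACGT with GATC exactly at geometric spacings
random_chromosome <- function(L, mean_spacing) {
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, L, replace = TRUE)
  # spacing between consecutive motif starts: 4 + geometric remainder
  p <- 1 / (mean_spacing - 3)
  n_draw <- ceiling(2 * L / mean_spacing) + 20L
  gaps <- 4L + stats::rgeom(n_draw, prob = p)
  sites <- cumsum(gaps)
  sites <- sites[sites <= L - 4L]
  motif <- c("G", "A", "T", "C")
  repeat {
    hits <- gatc_scan(s)
    extra <- setdiff(hits, sites)
    if (length(extra) == 0L && all(sites %in% hits)) break
    if (length(extra) > 0L) s[extra + 3L] <- "A"  # break accidental motifs
    for (q in sites) s[q + 1:4] <- motif
  }
  paste(s, collapse = "")
}

# 0-based GATC starts in a character vector of bases
gatc_scan <- function(s) {
  n <- length(s)
  if (n < 4L) return(integer(0))
  i <- seq_len(n - 3L)
  which(s[i] == "G" & s[i + 1L] == "A" & s[i + 2L] == "T" &
          s[i + 3L] == "C") - 1L
}

# genes in evenly spaced slots; TSS at the 5' end; one inset CDS each
random_annotation <- function(chroms, spec) {
  per <- ceiling(spec$n_genes / length(chroms))
  rows <- list()
  gi <- 0L
  for (ch in chroms) {
    slot <- spec$chrom_length %/% per
    for (k in seq_len(per)) {
      if (gi >= spec$n_genes) break
      gi <- gi + 1L
      len <- sample(seq(spec$gene_length[1L], spec$gene_length[2L]), 1L)
      lo <- (k - 1L) * slot + 500L
      hi <- k * slot - 500L - len
      if (hi <= lo) next
      start <- sample(seq(lo, hi), 1L)
      rows[[gi]] <- data.frame(
        gene_id = sprintf("gene%03d", gi), name = sprintf("g%03d", gi),
        chrom = ch, start = start, end = start + len,
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, rows)
  cds <- data.frame(chrom = genes$chrom, start = genes$start + 400L,
                    end = genes$end - 400L, gene_id = genes$gene_id,
                    stringsAsFactors = FALSE)
  gene_annotation(genes, cds = cds)
}

#' Simulate replicate signal tracks with known ground truth
#'
#' Per cell type, the expected fragment intensity is a uniform
#' background plus a low-accessibility class covering the `breadth`
#' fraction of fragments plus the strengths of shared, lineage and
#' cell-type-specific open regions (runs of >= 2 consecutive
#' fragments). Reads are drawn multinomially at the spec depth,
#' independently per replicate.
#'
#' @param spec A `simulation_spec`.
#' @param map A `fragment_map` (typically from [generate_genome()] or
#'   [simulate_fragment_map()]).
#' @param annotation Optional `gene_annotation`; when given, the ground
#'   truth marks which cell-type-specific regions satisfy the enhancer
#'   filters (> 2 kb from every TSS, no CDS overlap).
#' @param reads_as `"counts"` (default) or `"positions"`; the latter
#'   additionally returns per-read 5' placements drawn uniformly within
#'   each fragment, to exercise [count_reads_per_fragment()].
#' @return List with `tracks` (named list per cell type of
#'   `signal_track`s), `truth` (regions with per-cell-type membership,
#'   expected rpm matrix, differential pairs, enhancer flags) and
#'   optionally `reads`.
#' @export
simulate_tracks <- function(spec, map, annotation = NULL,
                            reads_as = c("counts", "positions")) {
  reads_as <- match.arg(reads_as)
  n <- nrow(map)
  cts <- spec$cell_types
  with_seed(derive_seed(spec$seed, 2L), {
    chrom_id <- match(map$chrom, chrom_levels(map))
    used <- logical(n)
    lineage_names <- if (!is.null(spec$lineages))
      unique(spec$lineages[cts]) else character(0)
    regions <- list()
    buffer <- logical(n)
    place <- function(owner, n_regions) {
      for (r in seq_len(n_regions)) {
        w <- sample(seq(spec$region_width[1L], spec$region_width[2L]), 1L)
        run <- place_run(w, used, chrom_id)
        if (is.null(run)) next
        block <- seq(run[1L] - min(run[1L] - 1L, 2L), min(n, run[2L] + 2L))
        used[block] <<- TRUE
        # open regions sit in locally closed chromatin: their immediate
        # flanks are silenced so runs terminate at the region edges
        buffer[setdiff(block, run[1L]:run[2L])] <<- TRUE
        regions[[length(regions) + 1L]] <<- data.frame(
          owner = owner, chrom = map$chrom[run[1L]],
          start = map$start[run[1L]], end = map$end[run[2L]],
          first_id = run[1L], last_id = run[2L],
          strength = spec$region_strength, stringsAsFactors = FALSE)
      }
    }
    place("shared", spec$n_shared_regions)
    for (ln in lineage_names) place(paste0("lineage:", ln),
                                    spec$n_lineage_regions)
    for (ct in cts) place(ct, spec$n_specific_regions)
    regions <- if (length(regions)) do.call(rbind, regions) else
      data.frame(owner = character(0), chrom = character(0),
                 start = integer(0), end = integer(0),
                 first_id = integer(0), last_id = integer(0),
                 strength = numeric(0), stringsAsFactors = FALSE)

    intensity <- matrix(0, n, length(cts), dimnames = list(NULL, cts))
    low_class <- list()
    for (ct in cts) {
      base <- stats::runif(n, spec$background_rpm[1L],
                           spec$background_rpm[2L])
      base[stats::runif(n) < spec$closed_fraction] <- 0
      base[buffer] <- 0
      n_low <- round(spec$breadth[[ct]] * n)
      low_idx <- sample(which(!used), min(n_low, sum(!used)))
      base[low_idx] <- base[low_idx] +
        stats::runif(length(low_idx), spec$low_rpm[1L], spec$low_rpm[2L])
      low_class[[ct]] <- sort(low_idx)
      for (i in seq_len(nrow(regions))) {
        own <- regions$owner[i]
        applies <- own == "shared" || own == ct ||
          (startsWith(own, "lineage:") && !is.null(spec$lineages) &&
             spec$lineages[[ct]] == sub("^lineage:", "", own))
        if (applies) {
          sel <- regions$first_id[i]:regions$last_id[i]
          base[sel] <- base[sel] + regions$strength[i]
        }
      }
      intensity[, ct] <- base
    }
    expected_rpm <- sweep(intensity, 2L, colSums(intensity), "/") * 1e6

    tracks <- list()
    reads <- if (reads_as == "positions") list() else NULL
    for (ct in cts) {
      prob <- intensity[, ct] / sum(intensity[, ct])
      tracks[[ct]] <- lapply(seq_len(spec$replicates), function(r) {
        counts <- as.integer(stats::rmultinom(1L, spec$depth, prob))
        if (reads_as == "positions") {
          reads[[paste0(ct, "_rep", r)]] <<- counts_to_reads(counts, map)
        }
        signal_track(counts, map, sample_id = paste0(ct, "_rep", r),
                     cell_type = ct, replicate = r)
      })
    }

    truth <- list(regions = regions, expected_rpm = expected_rpm,
                  low_class = low_class)
    if (!is.null(annotation)) {
      spec_regions <- regions[regions$owner %in% cts, , drop = FALSE]
      truth$enhancers <- annotate_true_enhancers(spec_regions, annotation)
    }
    out <- list(tracks = tracks, truth = truth)
    if (!is.null(reads)) out$reads <- reads
    out
  })
}

# first/last fragment ids of a free run of width w, or NULL
place_run <- function(w, used, chrom_id, max_tries = 200L) {
  n <- length(used)
  for (t in seq_len(max_tries)) {
    a <- sample.int(n - w + 1L, 1L)
    b <- a + w - 1L
    if (chrom_id[a] == chrom_id[b] && !any(used[a:b])) return(c(a, b))
  }
  NULL
}

# uniform read 5' positions within each fragment
counts_to_reads <- function(counts, map) {
  tot <- sum(counts)
  idx <- rep.int(seq_along(counts), counts)
  width <- (map$end - map$start)[idx]
  pos <- map$start[idx] + floor(stats::runif(tot) * width)
  data.frame(chrom = map$chrom[idx], pos = as.integer(pos),
             strand = sample(c("+", "-"), tot, replace = TRUE),
             stringsAsFactors = FALSE)
}

# apply the enhancer geometry filters to true specific regions
annotate_true_enhancers <- function(regions, ann) {
  if (nrow(regions) == 0L) return(cbind(regions, is_enhancer = logical(0)))
  flag <- vapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    t <- ann$tss[ann$tss$chrom == r$chrom, , drop = FALSE]
    tdist <- if (nrow(t) == 0L) Inf else
      min(pmax(0L, pmax(r$start - t$pos, t$pos - (r$end - 1L))))
    if (tdist <= 2000) return(FALSE)
    cds <- ann$cds
    !(nrow(cds) > 0L && any(cds$chrom == r$chrom & cds$start < r$end &
                              cds$end > r$start))
  }, logical(1))
  cbind(regions, is_enhancer = flag)
}

#' Simulate a fragment map without sequence
#'
#' Fragment lengths are geometric with the given mean; useful for
#' track-level simulations where the underlying sequence is never
#' consulted.
#'
#' @param n_fragments Total fragments.
#' @param mean_length Mean fragment length in bp.
#' @param n_chroms Number of chromosomes (fragments split evenly).
#' @param seed RNG seed.
#' @return A `fragment_map`.
#' @export
simulate_fragment_map <- function(n_fragments, mean_length = 200,
                                  n_chroms = 1L, seed = 1) {
  with_seed(seed, {
    lens <- 4L + stats::rgeom(n_fragments, prob = 1 / (mean_length - 3))
    per <- ceiling(n_fragments / n_chroms)
    chrom <- paste0("chrS", rep(seq_len(n_chroms), each = per)[
      seq_len(n_fragments)])
    parts <- lapply(split(lens, chrom), function(l) {
      data.frame(start = cumsum(c(0L, l[-length(l)])), end = cumsum(l))
    })
    df <- do.call(rbind, Map(function(ch, p) cbind(chrom = ch, p),
                             names(parts), parts))
    fragment_map(df)
  })
}

#' Simulate an exchangeable null track
#'
#' Fragment intensities are independent uniform draws (no spatial
#' structure) and reads are sampled multinomially, so per-fragment
#' values are exchangeable: the permutation null of the peak caller is
#' exact for such tracks.
#'
#' @param map A `fragment_map`.
#' @param depth Reads to sample.
#' @param seed RNG seed.
#' @param background_rpm Intensity range.
#' @return A `signal_track`.
#' @export
simulate_null_track <- function(map, depth = 1e5, seed = 1,
                                background_rpm = c(0, 2)) {
  with_seed(seed, {
    intensity <- stats::runif(nrow(map), background_rpm[1L],
                              background_rpm[2L])
    counts <- as.integer(stats::rmultinom(1L, depth,
                                          intensity / sum(intensity)))
    signal_track(counts, map, sample_id = sprintf("null_seed%d", seed))
  })
}

#' Simulate global accessibility landscapes (stem-like vs compacted)
#'
#' Direct model of genome-wide accessibility breadth: each fragment
#' belongs to a closed class (near-zero intensity), a low class
#' (expected 1-3 rpm; its share is the breadth parameter) or an open
#' class carrying the remaining read mass. With `depth` equal to one
#' million, one read equals one rpm, so the 1-3 rpm band fraction is
#' directly comparable across samples.
#'
#' @param map A `fragment_map`.
#' @param breadth Named vector: low-class fraction per cell type
#'   (stem-like types are broader).
#' @param zero_weight Named vector or single value: closed-class
#'   fraction per cell type.
#' @param replicates Replicates per cell type.
#' @param depth Reads per replicate (default 1e6).
#' @param seed RNG seed.
#' @return List with `tracks` (named list per cell type) and `classes`
#'   (per-fragment class per cell type).
#' @export
simulate_global_landscape <- function(map,
                                      breadth = c(stem = 0.35,
                                                  neuron = 0.25),
                                      zero_weight = 0.5,
                                      replicates = 2L, depth = 1e6,
                                      seed = 1) {
  cts <- names(breadth)
  if (is.null(names(zero_weight))) {
    zero_weight <- stats::setNames(rep(zero_weight,
                                       length.out = length(cts)), cts)
  }
  n <- nrow(map)
  with_seed(seed, {
    tracks <- list()
    classes <- list()
    for (ct in cts) {
      cl <- sample(c("zero", "low", "open"), n, replace = TRUE,
                   prob = c(zero_weight[[ct]], breadth[[ct]],
                            1 - zero_weight[[ct]] - breadth[[ct]]))
      intensity <- numeric(n)
      intensity[cl == "zero"] <- stats::runif(sum(cl == "zero"), 0, 0.5)
      intensity[cl == "low"] <- stats::runif(sum(cl == "low"), 1.2, 2.8)
      mass <- 1e6 - sum(intensity)
      n_open <- sum(cl == "open")
      intensity[cl == "open"] <- mass / n_open *
        stats::runif(n_open, 0.5, 1.5)
      prob <- intensity / sum(intensity)
      classes[[ct]] <- cl
      tracks[[ct]] <- lapply(seq_len(replicates), function(r) {
        counts <- as.integer(stats::rmultinom(1L, depth, prob))
        signal_track(counts, map, sample_id = paste0(ct, "_rep", r),
                     cell_type = ct, replicate = r)
      })
    }
    list(tracks = tracks, classes = classes)
  })
}

#' Write simulation ground truth as JSON
#'
#' @param truth The `truth` element of [simulate_tracks()] output.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(regions = truth$regions,
              low_class = truth$low_class,
              enhancers = truth$enhancers)
  jsonlite::write_json(out, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
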
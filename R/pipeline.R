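#' Read and validate a pipeline configuration
#'
#' The configuration is a single declarative YAML file (or an
#' equivalent named list) with paths, a sample sheet and thresholds:
#'
#' ```yaml
#' seed: 1
#' output_dir: out
#' genome: genome.fa
#' annotation: genes.gff3
#' samples:
#'   - {sample_id: s1, cell_type: stem, replicate: 1, reads: s1_reads.bed}
#' thresholds:
#'   fdr: 0.01        # peak significance
#'   diff_rpm: 20     # differential fragment rule
#'   enhancer_rpm: 10 # enhancer fragment rule
#'   gene_dist: 5000  # peak-to-gene distance
#'   tss_dist: 2000   # enhancer TSS exclusion
#'   band: [1, 3]     # low-accessibility rpm band
#' n_shuffles: 100
#' ```
#'
#' @param config Path to a YAML file or a named list.
#' @param overrides Named list of values replacing config entries.
#' @return A validated `catada_config` list with defaults filled in.
#' @export
read_config <- function(config, overrides = list()) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop_validation("config must be a YAML file or a list")
  cfg <- utils::modifyList(cfg, overrides)
  defaults <- list(seed = 1L, output_dir = "catada_out",
                   n_shuffles = 100L,
                   thresholds = list(fdr = 0.01, diff_rpm = 20,
                                     enhancer_rpm = 10, gene_dist = 5000,
                                     tss_dist = 2000, band = c(1, 3)))
  cfg <- utils::modifyList(defaults, cfg)
  thr <- unlist(cfg$thresholds[c("fdr", "diff_rpm", "enhancer_rpm",
                                 "gene_dist", "tss_dist")])
  if (any(thr <= 0)) stop_validation("thresholds must be positive")
  for (field in c("genome", "annotation")) {
    if (!is.null(cfg[[field]]) && !file.exists(cfg[[field]])) {
      stop_validation("%s file does not exist: %s", field, cfg[[field]])
    }
  }
  if (!is.null(cfg$samples)) {
    for (s in cfg$samples) {
      need <- c("sample_id", "cell_type", "replicate", "reads")
      if (!all(need %in% names(s))) {
        stop_validation("sample sheet rows need %s",
                        paste(need, collapse = ", "))
      }
      if (!file.exists(s$reads)) {
        stop_validation("reads file does not exist: %s", s$reads)
      }
    }
  }
  structure(cfg, class = c("catada_config", "list"))
}

#' Run one pipeline subcommand
#'
#' Subcommands wire the package stages into the published workflow:
#' `simulate`, `fragment-map`, `count`, `peaks`, `diff`, `enhancers`,
#' `overlap`, `global`, `aggregate`. Each writes its artifacts into the
#' configured output directory plus a `manifest.json` recording
#' parameters, seed and input checksums; deterministic stages reproduce
#' identical outputs when re-run with an identical config.
#'
#' @param name Subcommand name.
#' @param config Path to a YAML config or a named list (see
#'   [read_config()]).
#' @param overrides Named list of config overrides.
#' @return Invisibly, a named list of artifact paths written.
#' @export
run_catada <- function(name = c("simulate", "fragment-map", "count",
                                "peaks", "diff", "enhancers", "overlap",
                                "global", "aggregate"),
                       config, overrides = list()) {
  name <- match.arg(name)
  cfg <- read_config(config, overrides)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  fn <- switch(name,
               "simulate" = cmd_simulate,
               "fragment-map" = cmd_fragment_map,
               "count" = cmd_count,
               "peaks" = cmd_peaks,
               "diff" = cmd_diff,
               "enhancers" = cmd_enhancers,
               "overlap" = cmd_overlap,
               "global" = cmd_global,
               "aggregate" = cmd_aggregate)
  t0 <- Sys.time()
  artifacts <- fn(cfg)
  message(sprintf("[catada] %s finished in %.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  write_manifest(cfg, name, artifacts)
  invisible(artifacts)
}

write_manifest <- function(cfg, command, artifacts) {
  inputs <- c(genome = cfg$genome, annotation = cfg$annotation,
              unlist(lapply(cfg$samples, `[[`, "reads")))
  manifest <- list(command = command,
                   seed = cfg$seed,
                   thresholds = cfg$thresholds,
                   n_shuffles = cfg$n_shuffles,
                   inputs = if (length(inputs))
                     as.list(tools::md5sum(inputs)) else list(),
                   artifacts = as.list(artifacts))
  path <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

out_path <- function(cfg, ...) file.path(cfg$output_dir, paste0(...))

load_pipeline_inputs <- function(cfg, need_annotation = FALSE) {
  if (is.null(cfg$genome)) stop_validation("config lacks a genome path")
  genome <- read_genome(cfg$genome)
  map <- build_fragment_map(genome)
  ann <- NULL
  if (!is.null(cfg$annotation)) {
    ann <- read_gene_annotation(cfg$annotation)
  } else if (need_annotation) {
    stop_validation("this subcommand requires an annotation path")
  }
  list(genome = genome, map = map, annotation = ann)
}

load_sample_tracks <- function(cfg, map) {
  if (is.null(cfg$samples) || length(cfg$samples) == 0L) {
    stop_validation("config lacks a sample sheet")
  }
  tracks <- list()
  for (s in cfg$samples) {
    reads <- read_read_placements(s$reads)
    counts <- suppressWarnings(count_reads_per_fragment(reads, map))
    tracks[[s$cell_type]] <- c(tracks[[s$cell_type]], list(
      signal_track(counts, map, sample_id = s$sample_id,
                   cell_type = s$cell_type,
                   replicate = as.integer(s$replicate))))
  }
  tracks
}

cmd_simulate <- function(cfg) {
  spec_args <- cfg$simulate %||% list()
  spec <- do.call(simulation_spec, c(list(seed = cfg$seed), spec_args))
  gen <- generate_genome(spec)
  sim <- simulate_tracks(spec, gen$map, gen$annotation,
                         reads_as = "positions")
  art <- c(genome = out_path(cfg, "genome.fa"),
           annotation = out_path(cfg, "annotation.gff3"),
           fragment_map = out_path(cfg, "fragment_map.bed"),
           truth = out_path(cfg, "ground_truth.json"))
  write_genome(gen$genome, art[["genome"]])
  write_gene_annotation(gen$annotation, art[["annotation"]])
  write_fragment_map(gen$map, art[["fragment_map"]])
  write_ground_truth(sim$truth, art[["truth"]])
  for (nm in names(sim$reads)) {
    p <- out_path(cfg, nm, "_reads.bed")
    write_read_placements(sim$reads[[nm]], p)
    art[[paste0("reads_", nm)]] <- p
  }
  for (ct in names(sim$tracks)) {
    for (t in sim$tracks[[ct]]) {
      p <- out_path(cfg, t$sample_id, ".bedgraph")
      write_track_bedgraph(t, gen$map, p)
      art[[paste0("track_", t$sample_id)]] <- p
    }
  }
  art
}

cmd_fragment_map <- function(cfg) {
  io <- load_pipeline_inputs(cfg)
  art <- c(fragment_map = out_path(cfg, "fragment_map.bed"))
  write_fragment_map(io$map, art[["fragment_map"]])
  art
}

cmd_count <- function(cfg) {
  io <- load_pipeline_inputs(cfg)
  tracks <- load_sample_tracks(cfg, io$map)
  art <- character(0)
  for (ct in names(tracks)) {
    for (t in tracks[[ct]]) {
      p <- out_path(cfg, t$sample_id, ".bedgraph")
      write_track_bedgraph(t, io$map, p)
      art[[paste0("track_", t$sample_id)]] <- p
    }
  }
  art
}

cmd_peaks <- function(cfg) {
  io <- load_pipeline_inputs(cfg)
  tracks <- load_sample_tracks(cfg, io$map)
  art <- character(0)
  k <- 0L
  for (ct in names(tracks)) {
    k <- k + 1L
    sets <- lapply(tracks[[ct]], function(t) {
      call_significant_peaks(t, io$map, fdr_threshold = cfg$thresholds$fdr,
                             n_shuffles = cfg$n_shuffles,
                             seed = derive_seed(cfg$seed, k))
    })
    final <- if (length(sets) > 1L) intersect_replicate_peaks(sets)
             else sets[[1L]]
    p <- out_path(cfg, ct, "_peaks.bed")
    write_peaks(final, p)
    art[[paste0("peaks_", ct)]] <- p
    g <- out_path(cfg, ct, "_peaks.gff3")
    write_peaks(final, g, format = "gff3")
    art[[paste0("peaks_gff_", ct)]] <- g
    if (!is.null(io$annotation)) {
      ga <- assign_peaks_to_genes(final, io$annotation,
                                  max_dist = cfg$thresholds$gene_dist)
      gp <- out_path(cfg, ct, "_peak_genes.tsv")
      utils::write.table(ga, gp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      art[[paste0("genes_", ct)]] <- gp
    }
  }
  art
}

cmd_diff <- function(cfg) {
  io <- load_pipeline_inputs(cfg)
  tracks <- load_sample_tracks(cfg, io$map)
  if (length(tracks) < 2L) stop_validation("diff needs >= 2 cell types")
  frag <- find_differential_fragments(tracks,
                                      threshold = cfg$thresholds$diff_rpm)
  regions <- call_differential_regions(tracks, io$map,
                                       fdr_threshold = cfg$thresholds$fdr,
                                       n_shuffles = cfg$n_shuffles,
                                       seed = cfg$seed)
  art <- c(differential_fragments = out_path(cfg,
                                             "differential_fragments.tsv"))
  utils::write.table(as.data.frame(frag), art[[1L]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(regions)) {
    p <- out_path(cfg, "regions_", nm, ".bed")
    write_peaks(regions[[nm]], p)
    art[[paste0("regions_", nm)]] <- p
  }
  merged <- union_regions(regions, io$map)
  if (nrow(merged) > 1L) {
    mat <- build_region_matrix(merged, tracks)
    mp <- out_path(cfg, "region_matrix.tsv")
    utils::write.table(data.frame(region = rownames(mat), mat,
                                  check.names = FALSE),
                       mp, sep = "\t", quote = FALSE, row.names = FALSE)
    art[["region_matrix"]] <- mp
    cl <- hierarchical_cluster(mat, k_major = cfg$k_major %||% 2L)
    cp <- out_path(cfg, "region_clusters.tsv")
    utils::write.table(data.frame(region = names(cl$labels),
                                  cluster = cl$labels),
                       cp, sep = "\t", quote = FALSE, row.names = FALSE)
    art[["region_clusters"]] <- cp
    fa <- out_path(cfg, "region_sequences.fasta")
    export_region_sequences(as.data.frame(merged), io$genome,
                            clusters = cl$labels, path = fa)
    art[["region_sequences"]] <- fa
  }
  art
}

cmd_enhancers <- function(cfg) {
  io <- load_pipeline_inputs(cfg, need_annotation = TRUE)
  tracks <- load_sample_tracks(cfg, io$map)
  enh <- predict_enhancers(tracks, io$map, io$annotation,
                           diff_threshold = cfg$thresholds$enhancer_rpm,
                           tss_min_dist = cfg$thresholds$tss_dist)
  art <- c(enhancers_bed = out_path(cfg, "enhancers.bed"),
           enhancers_tsv = out_path(cfg, "enhancers.tsv"))
  write_enhancers(enh, art[["enhancers_bed"]], art[["enhancers_tsv"]])
  art
}

cmd_overlap <- function(cfg) {
  if (is.null(cfg$query_peaks) || is.null(cfg$reference_peaks)) {
    stop_validation("overlap needs query_peaks and reference_peaks paths")
  }
  io <- load_pipeline_inputs(cfg)
  query <- read_peaks(cfg$query_peaks)
  reference <- read_peaks(cfg$reference_peaks)
  frac <- peak_overlap_fraction(query, reference)
  mc <- monte_carlo_overlap(query, reference,
                            attr(io$map, "chrom_lengths"),
                            n = cfg$mc_simulations %||% 1000L,
                            seed = cfg$seed)
  art <- c(overlap_report = out_path(cfg, "overlap_report.tsv"))
  utils::write.table(
    data.frame(reference_overlap_fraction = frac$fraction,
               query_overlap_fraction = mc$fraction,
               observed = mc$observed, p_value = mc$p_value,
               n_simulations = mc$n_simulations, seed = mc$seed),
    art[[1L]], sep = "\t", quote = FALSE, row.names = FALSE)
  art
}

cmd_global <- function(cfg) {
  io <- load_pipeline_inputs(cfg)
  tracks <- load_sample_tracks(cfg, io$map)
  band <- cfg$thresholds$band
  flat <- unlist(tracks, recursive = FALSE)
  names(flat) <- vapply(flat, `[[`, character(1), "sample_id")
  rep_report <- accessibility_report(flat, band = band)
  art <- c(accessibility = out_path(cfg, "accessibility_report.tsv"))
  utils::write.table(rep_report, art[[1L]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  groups <- lapply(tracks, function(ts) {
    vapply(ts, function(t) band_fraction(t, band[1L], band[2L]), numeric(1))
  })
  if (length(groups) >= 2L && all(lengths(groups) >= 3L)) {
    cmpr <- compare_group_fractions(groups)
    gp <- out_path(cfg, "group_comparison.tsv")
    utils::write.table(cmpr$pairwise, gp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    art[["group_comparison"]] <- gp
  }
  art
}

cmd_aggregate <- function(cfg) {
  io <- load_pipeline_inputs(cfg, need_annotation = TRUE)
  tracks <- load_sample_tracks(cfg, io$map)
  anchors <- data.frame(chrom = io$annotation$tss$chrom,
                        pos = io$annotation$tss$pos,
                        strand = io$annotation$tss$strand)
  art <- character(0)
  for (ct in names(tracks)) {
    prof <- aggregate_at_points(average_replicates(tracks[[ct]]), io$map,
                                anchors,
                                flank = cfg$flank %||% 2000L,
                                bin = cfg$bin %||% 10L)
    p <- out_path(cfg, ct, "_tss_profile.tsv")
    write_profile(prof, p)
    art[[paste0("profile_", ct)]] <- p
  }
  art
}
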
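small_spec <- function(seed, ...) {
  simulation_spec(seed = seed, n_chroms = 2L, chrom_length = 60000L,
                  n_genes = 10L, depth = 2e5, n_shared_regions = 3L,
                  n_specific_regions = 2L, ...)
}

test_that("simulation specs validate their scientific constraints", {
  expect_error(simulation_spec(), "seed is mandatory")
  expect_error(simulation_spec(seed = 1, gatc_mean_spacing = 6),
               "motif collisions")
  expect_error(simulation_spec(seed = 1, region_width = c(1L, 2L)),
               ">= 2 fragments")
  expect_error(simulation_spec(seed = 1, depth = 0), "depth")
  expect_error(simulation_spec(seed = 1, region_strength = 1),
               "exceed the background")
})

test_that("genome generation is deterministic per seed", {
  spec <- small_spec(5)
  g1 <- generate_genome(spec)
  g2 <- generate_genome(spec)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$map, g2$map)
  expect_identical(g1$annotation$genes, g2$annotation$genes)
  g3 <- generate_genome(small_spec(6))
  expect_false(identical(g1$genome, g3$genome))
})

test_that("generated genomes carry GATC sites only where planted", {
  spec <- small_spec(7)
  gen <- generate_genome(spec)
  expect_identical(names(gen$genome), c("chrS1", "chrS2"))
  expect_identical(unname(nchar(gen$genome)), c(60000L, 60000L))
  # the fragment map equals a fresh scan of the emitted sequence
  expect_identical(gen$map, build_fragment_map(gen$genome))
})

test_that("median fragment length tracks the geometric spacing model", {
  meds <- vapply(1:5, function(s) {
    spec <- simulation_spec(seed = s, n_chroms = 1L, chrom_length = 100000L,
                            n_genes = 5L, gatc_mean_spacing = 200)
    median_fragment_spacing(generate_genome(spec)$map)
  }, numeric(1))
  target <- 200 * log(2)
  expect_gt(mean(meds), 0.8 * target)
  expect_lt(mean(meds), 1.2 * target)
})

test_that("simulated tracks are reproducible and regions span two or more fragments", {
  spec <- small_spec(8)
  gen <- generate_genome(spec)
  s1 <- simulate_tracks(spec, gen$map, gen$annotation)
  s2 <- simulate_tracks(spec, gen$map, gen$annotation)
  expect_identical(s1$truth$regions, s2$truth$regions)
  expect_identical(s1$tracks$stem[[1]]$raw, s2$tracks$stem[[1]]$raw)
  expect_true(all(s1$truth$regions$last_id - s1$truth$regions$first_id + 1L
                  >= 2L))
  expect_true(all(s1$truth$regions$owner %in% c("shared", "stem", "neuron")))
})

test_that("observed region rpm matches the multinomial expectation", {
  spec <- simulation_spec(seed = 9)  # defaults: depth 1e6
  map <- simulate_fragment_map(20000, seed = 2, n_chroms = 2L)
  sim <- simulate_tracks(spec, map)
  tr <- sim$truth$regions
  stem_regions <- tr[tr$owner %in% c("shared", "stem"), ]
  frag_ids <- unlist(Map(seq, stem_regions$first_id, stem_regions$last_id))
  expected <- sim$truth$expected_rpm[frag_ids, "stem"]
  observed <- rowMeans(cbind(sim$tracks$stem[[1]]$rpm[frag_ids],
                             sim$tracks$stem[[2]]$rpm[frag_ids]))
  expect_lt(max(abs(observed - expected) / expected), 0.1)
})

test_that("expected rpm always sums to one million per cell type", {
  spec <- small_spec(10)
  gen <- generate_genome(spec)
  sim <- simulate_tracks(spec, gen$map, gen$annotation)
  sums <- colSums(sim$truth$expected_rpm)
  expect_equal(unname(sums), rep(1e6, ncol(sim$truth$expected_rpm)))
})

test_that("read-position mode reproduces the per-fragment counts", {
  spec <- small_spec(11)
  gen <- generate_genome(spec)
  sim <- simulate_tracks(spec, gen$map, gen$annotation,
                         reads_as = "positions")
  counts <- count_reads_per_fragment(sim$reads$stem_rep1, gen$map)
  expect_identical(as.integer(counts), sim$tracks$stem[[1]]$raw)
})

test_that("cell-type-specific regions appear only in their own cell type", {
  spec <- small_spec(12)
  gen <- generate_genome(spec)
  sim <- simulate_tracks(spec, gen$map, gen$annotation)
  tr <- sim$truth$regions
  stem_only <- tr[tr$owner == "stem", ]
  for (i in seq_len(nrow(stem_only))) {
    ids <- stem_only$first_id[i]:stem_only$last_id[i]
    expect_gt(min(sim$truth$expected_rpm[ids, "stem"]),
              max(sim$truth$expected_rpm[ids, "neuron"]))
  }
})

test_that("true enhancer flags agree with the prediction filters", {
  spec <- small_spec(13)
  gen <- generate_genome(spec)
  sim <- simulate_tracks(spec, gen$map, gen$annotation)
  enh <- sim$truth$enhancers
  expect_true(is.logical(enh$is_enhancer))
  for (i in seq_len(nrow(enh))) {
    r <- enh[i, ]
    t <- gen$annotation$tss[gen$annotation$tss$chrom == r$chrom, ]
    d <- if (nrow(t) == 0) Inf else
      min(pmax(0, pmax(r$start - t$pos, t$pos - (r$end - 1))))
    cds <- gen$annotation$cds
    hit <- any(cds$chrom == r$chrom & cds$start < r$end & cds$end > r$start)
    expect_identical(enh$is_enhancer[i], d > 2000 && !hit)
  }
})

test_that("sequence-free fragment maps obey the requested shape", {
  map <- simulate_fragment_map(300, mean_length = 150, n_chroms = 3L,
                               seed = 4)
  expect_identical(nrow(map), 300L)
  expect_identical(length(attr(map, "chrom_lengths")), 3L)
  m <- median_fragment_spacing(map)
  expect_gt(m, 0.7 * 150 * log(2))
  expect_lt(m, 1.3 * 150 * log(2))
  expect_identical(map, simulate_fragment_map(300, mean_length = 150,
                                              n_chroms = 3L, seed = 4))
})

test_that("null tracks carry no spatial structure beyond exchangeability", {
  map <- simulate_fragment_map(500, seed = 5)
  tr <- simulate_null_track(map, depth = 5000, seed = 6)
  expect_identical(sum(tr$raw), 5000L)
  # lag-1 autocorrelation of an exchangeable track is near zero
  expect_lt(abs(cor(tr$rpm[-1], tr$rpm[-500])), 0.15)
})

test_that("global landscapes put the low class in the literal 1-3 rpm band", {
  map <- simulate_fragment_map(2000, seed = 7)
  sim <- simulate_global_landscape(map, breadth = c(stem = 0.3),
                                   replicates = 1L, seed = 8)
  cl <- sim$classes$stem
  rpm <- sim$tracks$stem[[1]]$rpm
  expect_gt(mean(rpm[cl == "low"] >= 1 & rpm[cl == "low"] <= 3), 0.5)
  expect_gt(mean(rpm[cl == "zero"] < 1), 0.7)
  expect_gt(mean(rpm[cl == "open"] > 3), 0.9)
})

test_that("ground truth JSON is written with full precision", {
  spec <- small_spec(14)
  gen <- generate_genome(spec)
  sim <- simulate_tracks(spec, gen$map, gen$annotation)
  js <- tempfile(fileext = ".json")
  write_ground_truth(sim$truth, js)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_identical(as.integer(back$regions$first_id),
                   sim$truth$regions$first_id)
  expect_identical(back$regions$owner, sim$truth$regions$owner)
  unlink(js)
})
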
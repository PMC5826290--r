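test_that("candidate peaks are maximal runs of at least two fragments", {
  map <- toy_map(chrA = c(4, 4, 4, 4, 4))
  cand <- enumerate_candidate_peaks(c(0, 5, 6, 0, 7), map, min_rpm = 1)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$first_id, 2L)
  expect_identical(cand$last_id, 3L)
  expect_equal(cand$score, 5.5)
  expect_equal(cand$height, 6)
})

test_that("an all-zero track yields no candidate peaks", {
  map <- toy_map(chrA = c(4, 4, 4))
  expect_identical(nrow(enumerate_candidate_peaks(c(0, 0, 0), map)), 0L)
})

test_that("runs never cross chromosome boundaries", {
  map <- toy_map(chrA = 10, chrB = 10)
  expect_identical(nrow(enumerate_candidate_peaks(c(5, 5), map)), 0L)
})

test_that("a run starting at the first fragment is scored correctly", {
  map <- toy_map(chrA = c(4, 4, 4, 4, 4, 4))
  cand <- enumerate_candidate_peaks(c(8, 10, 0, 0, 4, 6), map)
  expect_identical(cand$first_id, c(1L, 5L))
  expect_equal(cand$score, c(9, 5))
  expect_equal(cand$height, c(10, 6))
})

test_that("run enumeration matches the brute-force oracle on random tracks", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    map <- toy_map(chrA = rep(5, ceiling(n / 2)),
                   chrB = rep(5, floor(n / 2)))
    rpm <- random_rpm(nrow(map))
    min_rpm <- sample(c(0, 1, 2), 1)
    got <- enumerate_candidate_peaks(rpm, map, min_rpm = min_rpm)
    want <- oracle_candidate_peaks(rpm, map, min_rpm = min_rpm)
    expect_identical(got$first_id, want$first_id)
    expect_identical(got$last_id, want$last_id)
    expect_equal(got$score, want$score)
    expect_equal(got$height, want$height)
  }
})

test_that("permutation FDR is reproducible and monotone in score", {
  map <- toy_map(chrA = rep(5, 150))
  set.seed(62)
  rpm <- random_rpm(150)
  f1 <- estimate_peak_fdr(rpm, map, n_shuffles = 20, seed = 9)
  f2 <- estimate_peak_fdr(rpm, map, n_shuffles = 20, seed = 9)
  expect_identical(f1$table, f2$table)
  expect_true(all(diff(f1$table$fdr) <= 0))
  expect_true(all(f1$table$fdr >= 0 & f1$table$fdr <= 1))
})

test_that("an exchangeable uniform track gets FDR one everywhere", {
  map <- toy_map(chrA = rep(5, 60))
  f <- estimate_peak_fdr(rep(3, 60), map, n_shuffles = 10, seed = 1)
  expect_true(all(f$table$fdr == 1))
  expect_identical(nrow(call_significant_peaks(rep(3, 60), map,
                                               n_shuffles = 10, seed = 1)),
                   0L)
})

test_that("implanted high runs reach FDR below one percent", {
  # 10 runs at 50 rpm over sparse noise <= 2 rpm on 20000 fragments;
  # the map is large enough that shuffles almost never drop two 50 rpm
  # fragments side by side
  set.seed(63)
  map <- toy_map(chrA = rep(5, 20000))
  rpm <- runif(20000, 0, 2)
  rpm[runif(20000) < 0.5] <- 0
  starts <- seq(1000, 19000, by = 2000)
  for (s in starts) {
    rpm[s:(s + 2)] <- 50
    rpm[c(s - 1, s + 3)] <- 0
  }
  ft <- estimate_peak_fdr(rpm, map, n_shuffles = 50, seed = 10)
  expect_lt(fdr_lookup(ft, 50), 0.01)
  sig <- call_significant_peaks(rpm, map, n_shuffles = 50, seed = 10)
  expect_identical(sig$start, map$start[starts])
})

test_that("zero observed candidates produce an empty FDR table", {
  map <- toy_map(chrA = c(4, 4))
  f <- estimate_peak_fdr(c(0, 0), map, n_shuffles = 10, seed = 1)
  expect_identical(nrow(f$table), 0L)
  expect_true(is.na(fdr_lookup(f, 5)))
})

test_that("scores below every tabulated score look up to FDR one", {
  map <- toy_map(chrA = rep(5, 100))
  set.seed(64)
  rpm <- random_rpm(100)
  ft <- estimate_peak_fdr(rpm, map, n_shuffles = 10, seed = 2)
  expect_identical(fdr_lookup(ft, min(ft$table$score) - 1), 1)
})

test_that("raising the FDR threshold never removes a peak", {
  set.seed(65)
  map <- toy_map(chrA = rep(5, 500))
  rpm <- random_rpm(500)
  strict <- call_significant_peaks(rpm, map, fdr_threshold = 0.01,
                                   n_shuffles = 30, seed = 3)
  loose <- call_significant_peaks(rpm, map, fdr_threshold = 0.05,
                                  n_shuffles = 30, seed = 3)
  key <- function(p) paste(p$chrom, p$start, p$end)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("replicate intersection merges overlapping peaks to their union", {
  map <- toy_map(chrA = rep(5, 10))
  mk <- function(first, last) {
    peak_set(data.frame(chrom = "chrA", start = map$start[first],
                        end = map$end[last], first_id = first,
                        last_id = last, n_fragments = last - first + 1L,
                        score = 10, height = 12, fdr = 0.001,
                        stringsAsFactors = FALSE), map = map)
  }
  merged <- intersect_replicate_peaks(mk(1L, 2L), mk(2L, 3L))
  expect_identical(merged$first_id, 1L)
  expect_identical(merged$last_id, 3L)
  expect_identical(nrow(intersect_replicate_peaks(mk(1L, 2L), mk(5L, 6L))),
                   0L)
  again <- intersect_replicate_peaks(mk(4L, 5L), mk(4L, 5L))
  expect_identical(again$first_id, 4L)
  expect_identical(again$last_id, 5L)
})

test_that("replicate intersection is commutative and requires all replicates", {
  map <- toy_map(chrA = rep(5, 20))
  mk <- function(first, last) {
    peak_set(data.frame(chrom = "chrA", start = map$start[first],
                        end = map$end[last], first_id = first,
                        last_id = last, n_fragments = last - first + 1L,
                        score = 5, height = 6, fdr = 0.002,
                        stringsAsFactors = FALSE), map = map)
  }
  a <- mk(c(1L, 8L), c(3L, 9L))
  b <- mk(c(2L, 14L), c(4L, 15L))
  ab <- intersect_replicate_peaks(a, b)
  ba <- intersect_replicate_peaks(b, a)
  expect_identical(ab$start, ba$start)
  expect_identical(ab$end, ba$end)
  # three replicates: a fragment run present in only two of three dies
  c3 <- mk(c(2L, 8L), c(3L, 9L))
  all3 <- intersect_replicate_peaks(list(a, b, c3))
  expect_identical(all3$first_id, 1L)
  expect_identical(all3$last_id, 4L)
})

test_that("peak sets from different maps refuse to intersect", {
  map1 <- toy_map(chrA = rep(5, 10))
  map2 <- toy_map(chrA = rep(4, 10))
  p1 <- peak_set(data.frame(chrom = "chrA", start = 0L, end = 10L,
                            first_id = 1L, last_id = 2L, n_fragments = 2L,
                            score = 1, height = 1, fdr = 0.001),
                 map = map1)
  p2 <- peak_set(data.frame(chrom = "chrA", start = 0L, end = 8L,
                            first_id = 1L, last_id = 2L, n_fragments = 2L,
                            score = 1, height = 1, fdr = 0.001),
                 map = map2)
  expect_error(intersect_replicate_peaks(p1, p2), "different fragment maps")
})

test_that("peaks map to overlapping genes at distance zero", {
  peaks <- data.frame(chrom = "chrA", start = 1000L, end = 1500L)
  genes <- data.frame(gene_id = "gA", chrom = "chrA", start = 900L,
                      end = 1200L, strand = "+", stringsAsFactors = FALSE)
  got <- assign_peaks_to_genes(peaks, gene_annotation(genes))
  expect_identical(got$gene_id, "gA")
  expect_identical(got$distance, 0L)
})

test_that("only the nearest gene within 5 kb is assigned per side", {
  peaks <- data.frame(chrom = "chrA", start = 1000L, end = 1500L)
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chrA",
                      start = c(2000L, 4000L), end = c(3000L, 5000L),
                      strand = "+", stringsAsFactors = FALSE)
  got <- assign_peaks_to_genes(peaks, gene_annotation(genes))
  expect_identical(got$gene_id, "gA")
  expect_identical(got$distance, 500L)
})

test_that("genes beyond the distance limit are not assigned", {
  peaks <- data.frame(chrom = "chrA", start = 0L, end = 100L)
  genes <- data.frame(gene_id = "far", chrom = "chrA", start = 6100L,
                      end = 7000L, strand = "+", stringsAsFactors = FALSE)
  got <- assign_peaks_to_genes(peaks, gene_annotation(genes))
  expect_identical(nrow(got), 0L)
})

test_that("gene assignment matches the brute-force oracle on random layouts", {
  set.seed(66)
  for (i in 1:40) {
    n_genes <- sample(2:8, 1)
    starts <- sort(sample(seq(0, 40000, by = 100), n_genes))
    genes <- data.frame(gene_id = sprintf("g%02d", seq_len(n_genes)),
                        chrom = "chrA", start = starts,
                        end = starts + sample(500:3000, n_genes,
                                              replace = TRUE),
                        strand = "+", stringsAsFactors = FALSE)
    ps <- sort(sample(seq(0, 45000, by = 50), 3))
    peaks <- data.frame(chrom = "chrA", start = ps, end = ps + 400L)
    got <- assign_peaks_to_genes(peaks, gene_annotation(genes))
    want <- oracle_assign_genes(peaks, genes)
    key <- function(d) sort(paste(d$peak, d$gene_id, d$distance))
    expect_identical(key(got), key(want))
  }
})

test_that("peak sets round-trip through BED5 and GFF3", {
  map <- toy_map(chrA = rep(5, 10))
  peaks <- peak_set(data.frame(chrom = "chrA", start = c(0L, 25L),
                               end = c(10L, 40L), first_id = c(1L, 6L),
                               last_id = c(2L, 8L), n_fragments = c(2L, 3L),
                               score = c(1500.5, 42.25),
                               height = c(2100.75, 60.5),
                               fdr = c(0.001, 0.0099)), map = map)
  bed <- tempfile(fileext = ".bed")
  gff <- tempfile(fileext = ".gff3")
  write_peaks(peaks, bed)
  write_peaks(peaks, gff, format = "gff3")
  from_bed <- read_peaks(bed)
  expect_identical(from_bed$chrom, peaks$chrom)
  expect_identical(from_bed$start, peaks$start)
  expect_identical(from_bed$end, peaks$end)
  expect_equal(from_bed$height, peaks$height)
  from_gff <- read_peaks(gff)
  expect_identical(from_gff$start, peaks$start)
  expect_identical(from_gff$end, peaks$end)
  expect_equal(from_gff$height, peaks$height)
  expect_equal(from_gff$fdr, peaks$fdr)
  unlink(c(bed, gff))
})
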
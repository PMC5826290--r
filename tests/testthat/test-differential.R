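test_that("a fragment is differential only when every replicate pair differs", {
  tracks <- list(A = list(c(50, 50), c(45, 15)),
                 B = list(c(10, 10), c(12, 12)))
  # fragment 1: min(A)=45, max(B)=12, margin 33 > 20 -> included
  # fragment 2: 15 - 12 = 3 <= 20 -> excluded
  got <- find_differential_fragments(tracks, threshold = 20)
  expect_identical(got$fragment_id, 1L)
  expect_identical(got$higher, "A")
  expect_identical(got$lower, "B")
  expect_equal(got$magnitude, 33)
})

test_that("identical tracks across cell types yield no differential fragments", {
  x <- c(5, 80, 3)
  got <- find_differential_fragments(list(A = list(x, x), B = list(x, x)))
  expect_identical(nrow(got), 0L)
})

test_that("differential selection is invariant to cell-type relabeling", {
  set.seed(71)
  mk <- function() list(runif(100, 0, 60), runif(100, 0, 60))
  tracks <- list(A = mk(), B = mk(), C = mk())
  fwd <- find_differential_fragments(tracks)
  rev <- find_differential_fragments(tracks[c("C", "A", "B")])
  key <- function(d) sort(paste(d$fragment_id, d$higher, d$lower, d$magnitude))
  expect_identical(key(fwd), key(rev))
})

test_that("raising the rpm threshold never adds fragments", {
  set.seed(72)
  tracks <- list(A = list(runif(200, 0, 80), runif(200, 0, 80)),
                 B = list(runif(200, 0, 80), runif(200, 0, 80)))
  lo <- find_differential_fragments(tracks, threshold = 10)
  hi <- find_differential_fragments(tracks, threshold = 30)
  expect_true(all(hi$fragment_id %in% lo$fragment_id))
  expect_true(nrow(hi) <= nrow(lo))
})

test_that("differential selection matches the all-pairwise oracle", {
  set.seed(73)
  for (i in 1:30) {
    nf <- sample(20:120, 1)
    nreps <- sample(1:3, 2, replace = TRUE)
    mats <- list(A = matrix(runif(nf * nreps[1], 0, 70), nf),
                 B = matrix(runif(nf * nreps[2], 0, 70), nf))
    got <- find_differential_fragments(
      list(A = lapply(seq_len(nreps[1]), function(j) mats$A[, j]),
           B = lapply(seq_len(nreps[2]), function(j) mats$B[, j])),
      threshold = 20)
    want <- oracle_differential(mats, 20)
    key <- function(d) paste(d$fragment_id, d$higher, d$lower,
                             signif(d$magnitude, 10))
    expect_identical(key(got), key(want))
  }
})

test_that("a single cell type cannot be tested for differences", {
  expect_error(find_differential_fragments(list(A = list(c(1, 2)))),
               "at least two cell types")
})

test_that("adjacent differential fragments merge into regions", {
  map <- toy_map(chrA = rep(5, 6), chrB = rep(5, 4))
  merged <- merge_differential_fragments(c(2L, 3L, 5L, 7L, 8L), map)
  expect_identical(merged$first_id, c(2L, 5L, 7L))
  expect_identical(merged$last_id, c(3L, 5L, 8L))
  # fragments 6 (chrA) and 7 (chrB) stay apart even though ids adjoin
  merged2 <- merge_differential_fragments(c(6L, 7L), map)
  expect_identical(nrow(merged2), 2L)
  short_dropped <- merge_differential_fragments(c(2L, 5L, 6L), map,
                                                min_fragments = 2L)
  expect_identical(short_dropped$first_id, 5L)
  expect_identical(short_dropped$last_id, 6L)
})

test_that("differential regions appear only in the enriched direction", {
  set.seed(74)
  map <- toy_map(chrA = rep(5, 20000))
  base <- runif(20000, 0, 2)
  base[runif(20000) < 0.5] <- 0
  a <- base
  starts <- seq(1000, 19000, by = 2000)
  for (s in starts) {
    a[s:(s + 1)] <- 60
    a[c(s - 1, s + 2)] <- 0
  }
  b <- base
  tracks <- list(A = list(a, a), B = list(b, b))
  regions <- call_differential_regions(tracks, map, n_shuffles = 50,
                                       seed = 5)
  expect_identical(sort(names(regions)), c("A_vs_B", "B_vs_A"))
  expect_identical(regions$A_vs_B$first_id, as.integer(starts))
  expect_identical(nrow(regions$B_vs_A), 0L)
  # the differential fragments all fall inside the called regions
  frags <- find_differential_fragments(tracks, threshold = 20)
  inside <- vapply(frags$fragment_id, function(f) {
    any(regions$A_vs_B$first_id <= f & regions$A_vs_B$last_id >= f)
  }, logical(1))
  expect_true(mean(inside) == 1)
})

test_that("identical cell types produce empty comparisons both ways", {
  map <- toy_map(chrA = rep(5, 50))
  x <- c(rep(c(0, 10), 25))
  regions <- call_differential_regions(list(A = list(x), B = list(x)), map,
                                       n_shuffles = 10, seed = 1)
  expect_identical(nrow(regions$A_vs_B), 0L)
  expect_identical(nrow(regions$B_vs_A), 0L)
})

test_that("the region matrix averages member fragments and replicates", {
  map <- toy_map(chrA = rep(5, 4))
  regions <- data.frame(chrom = "chrA", start = 0L, end = 10L,
                        first_id = 1L, last_id = 2L)
  mat <- build_region_matrix(regions,
                             list(X = list(c(10, 20, 0, 0)),
                                  Y = list(c(4, 4, 0, 0), c(8, 8, 0, 0))))
  expect_equal(unname(mat[1, "X"]), 15)
  expect_equal(unname(mat[1, "Y"]), 6)
  expect_identical(dim(mat), c(1L, 2L))
  expect_identical(rownames(mat), "chrA:0-10")
})

test_that("region unions merge overlapping fragment runs across comparisons", {
  map <- toy_map(chrA = rep(5, 10))
  r1 <- merge_differential_fragments(c(2L, 3L), map)
  r2 <- merge_differential_fragments(c(3L, 4L, 8L), map)
  u <- union_regions(list(r1, r2), map)
  expect_identical(u$first_id, c(2L, 8L))
  expect_identical(u$last_id, c(4L, 8L))
})

test_that("clustering recovers two planted row patterns exactly", {
  set.seed(75)
  up <- t(replicate(15, c(50, 48, 5, 6) + rnorm(4, 0, 1)))
  down <- t(replicate(12, c(4, 6, 55, 52) + rnorm(4, 0, 1)))
  mat <- rbind(up, down)
  rownames(mat) <- sprintf("r%02d", seq_len(nrow(mat)))
  colnames(mat) <- c("stemA", "stemB", "neuA", "neuB")
  cl <- hierarchical_cluster(mat, k_major = 2)
  planted <- rep(1:2, c(15, 12))
  expect_identical(length(unique(cl$labels[planted == 1])), 1L)
  expect_identical(length(unique(cl$labels[planted == 2])), 1L)
  expect_false(cl$labels[1] == cl$labels[16])
})

test_that("cluster memberships ignore input row order", {
  set.seed(76)
  mat <- rbind(t(replicate(8, c(30, 2) + rnorm(2, 0, 0.5))),
               t(replicate(8, c(2, 30) + rnorm(2, 0, 0.5))))
  rownames(mat) <- sprintf("r%02d", 1:16)
  perm <- sample(16)
  cl1 <- hierarchical_cluster(mat, k_major = 2)
  cl2 <- hierarchical_cluster(mat[perm, ], k_major = 2)
  agree <- outer(cl1$labels, cl1$labels, "==")
  agree2 <- outer(cl2$labels[rownames(mat)], cl2$labels[rownames(mat)], "==")
  expect_identical(agree, agree2)
})

test_that("degenerate all-constant matrices collapse to one cluster", {
  mat <- matrix(3, 4, 2, dimnames = list(paste0("r", 1:4), c("A", "B")))
  expect_warning(cl <- hierarchical_cluster(mat), "single cluster")
  expect_identical(unname(cl$labels), rep(1L, 4))
})

test_that("k_major one puts every region in the same cluster", {
  mat <- matrix(c(1, 9, 2, 8), 2, dimnames = list(c("r1", "r2"),
                                                  c("A", "B")))
  cl <- hierarchical_cluster(mat, k_major = 1)
  expect_identical(unname(cl$labels), c(1L, 1L))
})

test_that("region sequences are exact genome substrings", {
  genome <- c(chrT = "AAGATCTTGATCAA")
  regions <- data.frame(chrom = "chrT", start = 2L, end = 8L)
  seqs <- export_region_sequences(regions, genome)
  expect_identical(as.character(seqs), c(`chrT:2-8` = "GATCTT"))
  labeled <- export_region_sequences(regions, genome, clusters = 2L)
  expect_identical(names(labeled), "chrT:2-8:2")
  empty <- export_region_sequences(regions[0, , drop = FALSE], genome)
  expect_identical(length(empty), 0L)
  bad <- data.frame(chrom = "chrT", start = 10L, end = 20L)
  expect_error(export_region_sequences(bad, genome), "outside genome bounds")
})

test_that("exported FASTA round-trips through the genome reader", {
  genome <- c(chrT = "AAGATCTTGATCAA")
  regions <- data.frame(chrom = "chrT", start = c(0L, 2L), end = c(2L, 8L))
  fa <- tempfile(fileext = ".fasta")
  export_region_sequences(regions, genome, path = fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_identical(as.character(back),
                   c(`chrT:0-2` = "AA", `chrT:2-8` = "GATCTT"))
  unlink(fa)
})
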
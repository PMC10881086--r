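test_that("stratified split hits per-type test counts and is exhaustive", {
  counts <- matrix(rpois(20 * 15, 2), 20, 15,
                   dimnames = list(sprintf("g%02d", 1:20),
                                   sprintf("c%02d", 1:15)))
  ref <- reference_dataset(counts, rep(c("A", "B", "C"), each = 5))
  s <- split_cells(ref, test_frac = 0.2, seed = 1)
  expect_setequal(c(s$train, s$test), ref$cell_ids)
  expect_length(intersect(s$train, s$test), 0L)
  # 5 cells per type, 20% -> exactly 1 test cell per type
  test_types <- ref$cell_types[match(s$test, ref$cell_ids)]
  expect_equal(unname(table(test_types)), rep(1L, 3), ignore_attr = TRUE)
})

test_that("a 10-cell type at test_frac 0.2 yields an 8/2 split", {
  counts <- matrix(rpois(5 * 20, 2), 5, 20,
                   dimnames = list(paste0("g", 1:5), sprintf("c%02d", 1:20)))
  ref <- reference_dataset(counts, rep(c("A", "B"), each = 10))
  s <- split_cells(ref, test_frac = 0.2, seed = 3)
  for (t in c("A", "B")) {
    ids <- ref$cell_ids[ref$cell_types == t]
    expect_length(intersect(s$test, ids), 2L)
    expect_length(intersect(s$train, ids), 8L)
  }
})

test_that("splits are seed-deterministic and vary across seeds", {
  ref <- small_ref()
  expect_identical(split_cells(ref, 0.2, seed = 5), split_cells(ref, 0.2, seed = 5))
  draws <- vapply(1:20, function(s)
    paste(sort(split_cells(ref, 0.2, seed = s)$test), collapse = ","),
    character(1))
  expect_gt(length(unique(draws)), 15)
})

test_that("a singleton cell type cannot be split and is named in the error", {
  counts <- matrix(1, 3, 4, dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  ref <- reference_dataset(counts, c("A", "A", "A", "lonely"))
  expect_error(split_cells(ref, 0.2, 1), "lonely")
})

test_that("proportion sampler covers vertices, faces and interior", {
  # all-pure: every row one-hot, types covered cyclically
  P <- sample_proportions(10, 3, frac_pure = 1, frac_sparse = 0, seed = 1)
  expect_true(all(rowSums(P == 1) == 1 & rowSums(P == 0) == 2))
  expect_true(max(colSums(P)) - min(colSums(P)) <= 1)
  # simplex invariant under the default strata mix
  P2 <- sample_proportions(500, 4, seed = 2)
  expect_true(all(abs(rowSums(P2) - 1) < 1e-9))
  expect_true(all(P2 >= 0))
  # sparse stratum has zeroed types
  P3 <- sample_proportions(100, 4, frac_pure = 0, frac_sparse = 1, seed = 3)
  expect_true(all(rowSums(P3 == 0) >= 1 & rowSums(P3 == 0) <= 3))
})

test_that("full-Dirichlet rows match the Dirichlet mean (Monte Carlo)", {
  P <- sample_proportions(100000, 3, alpha = 1, frac_pure = 0,
                          frac_sparse = 0, seed = 4)
  expect_true(all(abs(colMeans(P) - 1 / 3) < 0.01))
})

test_that("largest-remainder rounding is exact with lexicographic ties", {
  expect_equal(largest_remainder(c(0.5, 0.5), 3), c(2L, 1L))
  expect_equal(largest_remainder(c(1, 0), 10), c(10L, 0L))
  expect_equal(largest_remainder(c(0.2, 0.3, 0.5), 10), c(2L, 3L, 5L))
  set.seed(5)
  for (i in 1:50) {
    p <- as.vector(sample_proportions(1, 5, seed = i))
    n <- sample(10:100, 1)
    cnt <- largest_remainder(p, n)
    expect_equal(sum(cnt), n)
    expect_true(all(abs(cnt - p * n) < 1))
  }
})

test_that("a pure mixture over a single-cell type is a scaled cell", {
  counts <- matrix(c(5, 2, 0, 1, 3, 1, 2, 0, 4), 3, 3,
                   dimnames = list(c("g1", "g2", "g3"), c("c1", "c2", "c3")))
  ref <- reference_dataset(counts, c("A", "B", "B"))
  P <- matrix(c(1, 0), 1, 2, dimnames = list(NULL, c("A", "B")))
  mix <- synthesize_mixtures(ref, ref$cell_ids, P, n_cells_per_mixture = 10,
                             seed = 1)
  expect_equal(unname(mix$profiles[, 1]), 10 * unname(counts[, "c1"]))
  expect_equal(unname(mix$proportions[1, ]), c(1, 0))
})

test_that("realized proportions follow largest-remainder with documented ties", {
  ref <- tiny_ref()
  P <- matrix(c(0.5, 0.5), 1, 2, dimnames = list(NULL, c("A", "B")))
  mix <- synthesize_mixtures(ref, ref$cell_ids, P, n_cells_per_mixture = 3,
                             seed = 2)
  expect_equal(unname(mix$proportions[1, ]), c(2, 1) / 3)
})

test_that("mixture totals conserve the drawn cells' counts exactly", {
  ref <- small_ref()
  P <- sample_proportions(20, 3, seed = 6)
  colnames(P) <- sort(unique(ref$cell_types))
  mix <- synthesize_mixtures(ref, ref$cell_ids, P, n_cells_per_mixture = 30,
                             seed = 7)
  cell_totals <- colSums(ref$counts)
  for (i in seq_len(20)) {
    expect_identical(sum(mix$profiles[, i]),
                     sum(cell_totals[mix$draws[[i]]]))
  }
  # rounding bound: realized deviates from requested by < 1/n per type
  expect_true(all(abs(mix$proportions - P) < 1 / 30))
})

test_that("train and test partitions share no cells in their draw lists", {
  ref <- small_ref()
  s <- split_cells(ref, 0.25, seed = 8)
  P <- sample_proportions(30, 3, seed = 9)
  colnames(P) <- sort(unique(ref$cell_types))
  tr <- synthesize_mixtures(ref, s$train, P, 20, seed = 10, partition = "train")
  te <- synthesize_mixtures(ref, s$test, P, 20, seed = 11, partition = "test")
  used <- function(m) unique(ref$cell_ids[unlist(m$draws)])
  expect_length(intersect(used(tr), used(te)), 0L)
})

test_that("a positive proportion for a type missing from the subset errors", {
  ref <- tiny_ref()
  only_a <- ref$cell_ids[ref$cell_types == "A"]
  P <- matrix(c(0.5, 0.5), 1, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(
    synthesize_mixtures(ref, only_a, P, 10, seed = 1, partition = "test"),
    "test.*B")
})

test_that("mixture sets serialize to MTX bundle plus proportions.csv", {
  mix <- small_mixtures("test")
  dir <- file.path(tempdir(), "mixset")
  write_mixture_set(mix, dir)
  back <- read_counts_matrix(file.path(dir, "matrix.mtx"), "mtx")
  expect_equal(back$counts, mix$profiles)
  props <- read.csv(file.path(dir, "proportions.csv"), check.names = FALSE)
  expect_equal(as.matrix(props[, -1]), mix$proportions, ignore_attr = TRUE)
})
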
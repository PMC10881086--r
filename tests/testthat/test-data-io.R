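write_tiny_mtx <- function(dir) {
  dir.create(dir, showWarnings = FALSE)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 5", "3 2 2"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("gA", "gB", "gC"), file.path(dir, "genes.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  file.path(dir, "matrix.mtx")
}

test_that("MTX triplets expand to the dense matrix with sidecar ids", {
  path <- write_tiny_mtx(file.path(tempdir(), "mtx1"))
  out <- read_counts_matrix(path, "mtx")
  expect_equal(unname(out$counts),
               matrix(c(5, 0, 0, 0, 0, 2), nrow = 3, byrow = TRUE))
  expect_equal(out$gene_ids, c("gA", "gB", "gC"))
  expect_equal(out$column_ids, c("c1", "c2"))
})

test_that("malformed MTX header is rejected with the offending line", {
  dir <- file.path(tempdir(), "mtxbad"); dir.create(dir, showWarnings = FALSE)
  writeLines(c("not a header", "3 2 1", "1 1 5"), file.path(dir, "matrix.mtx"))
  writeLines(c("a", "b", "c"), file.path(dir, "genes.tsv"))
  writeLines(c("x", "y"), file.path(dir, "barcodes.tsv"))
  expect_error(read_counts_matrix(file.path(dir, "matrix.mtx"), "mtx"),
               "malformed.*not a header")
})

test_that("duplicate gene rows are collapsed by summation in CSV input", {
  path <- file.path(tempdir(), "dup.csv")
  writeLines(c("gene,c1", "GAPDH,1", "ACTB,2", "GAPDH,3"), path)
  out <- read_counts_matrix(path, "csv")
  expect_equal(out$counts["GAPDH", "c1"], 4)
  expect_equal(out$gene_ids, c("GAPDH", "ACTB"))
})

test_that("duplicate column ids are a validation error", {
  path <- file.path(tempdir(), "dupcol.csv")
  writeLines(c("gene,c1,c1", "gA,1,2"), path)
  expect_error(read_counts_matrix(path, "csv"), "duplicate column")
})

test_that("HDF5 writer/reader round-trips matrix and identifiers", {
  m <- matrix(rpois(12, 3), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  path <- file.path(tempdir(), "rt.h5")
  write_counts_h5(m, path)
  out <- read_counts_matrix(path, "h5")
  expect_equal(out$counts, m)
})

test_that("MTX writer/reader round-trips (read-write-read identity)", {
  m <- matrix(rpois(20, 2), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
  dir <- file.path(tempdir(), "mtxrt")
  write_counts_mtx(m, dir)
  out <- read_counts_matrix(file.path(dir, "matrix.mtx"), "mtx")
  expect_equal(out$counts, m)
})

make_ref <- function(counts, types = NULL) {
  if (is.null(types)) types <- rep(c("T1", "T2"), length.out = ncol(counts))
  reference_dataset(counts, types)
}

test_that("gene-space harmonization intersects, filters and sorts", {
  ref <- make_ref(matrix(c(1, 2, 0, 0, 3, 1), 3, 2,
                         dimnames = list(c("A", "B", "C"), c("c1", "c2"))))
  st <- spatial_dataset(matrix(1, 3, 2,
                               dimnames = list(c("B", "C", "D"), c("s1", "s2"))),
                        cbind(1:2, 1:2))
  expect_equal(harmonize_gene_space(ref, st)$gene_space, c("B", "C"))
  # gene B has 0 total reference counts -> filtered at min_counts = 1
  ref0 <- make_ref(matrix(c(2, 1, 0, 0, 5, 3), 3, 2, byrow = TRUE,
                          dimnames = list(c("A", "B", "C"), c("c1", "c2"))))
  expect_equal(harmonize_gene_space(ref0, st, min_counts = 1)$gene_space, "C")
  expect_error(harmonize_gene_space(
    ref, spatial_dataset(matrix(1, 1, 1, dimnames = list("Z", "s1")),
                         cbind(1, 1))),
    "no genes")
})

test_that("exactly the non-zero genes survive min_counts filtering", {
  set.seed(1)
  n_genes <- 200L
  counts <- matrix(rpois(n_genes * 10, 2) + 1, n_genes, 10,
                   dimnames = list(sprintf("g%03d", 1:n_genes),
                                   sprintf("c%02d", 1:10)))
  zero <- sample(n_genes, 20)  # force 10% all-zero
  counts[zero, ] <- 0
  ref <- make_ref(counts)
  st <- spatial_dataset(counts[, 1:2], cbind(1:2, 1:2),
                        spot_ids = c("s1", "s2"))
  got <- harmonize_gene_space(ref, st, min_counts = 1)$gene_space
  expected <- sort(rownames(counts)[rowSums(counts) > 0])
  expect_identical(got, expected)
  expect_length(got, 180L)
})

test_that("harmonization is invariant to input gene order", {
  set.seed(2)
  counts <- matrix(rpois(60, 2), 10, 6,
                   dimnames = list(sprintf("g%02d", 1:10), sprintf("c%d", 1:6)))
  ref <- make_ref(counts)
  perm <- sample(10)
  ref_p <- make_ref(counts[perm, ])
  st <- spatial_dataset(counts[, 1:3], cbind(1:3, 1:3),
                        spot_ids = paste0("s", 1:3))
  st_p <- spatial_dataset(counts[rev(perm), 1:3], cbind(1:3, 1:3),
                          spot_ids = paste0("s", 1:3))
  expect_identical(harmonize_gene_space(ref, st, min_counts = 1)$gene_space,
                   harmonize_gene_space(ref_p, st_p, min_counts = 1)$gene_space)
})

test_that("normalization scales columns, keeps zero columns, is idempotent", {
  spec <- structure(list(gene_space = c("a", "b", "c"), scale = 1e4,
                         log_transform = FALSE),
                    class = "normalization_spec")
  m <- matrix(c(1, 1, 2, 0, 0, 0), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  norm <- normalize_counts(m, spec)
  expect_equal(unname(norm[, 1]), c(2500, 2500, 5000))
  expect_equal(unname(norm[, 2]), c(0, 0, 0))
  # idempotence of the pre-log scaling
  expect_equal(normalize_counts(norm, spec), norm, tolerance = 1e-9)
  # column-sum invariant on a random matrix
  set.seed(3)
  big <- matrix(rpois(1000, 1), 50, 20,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:20)))
  spec_big <- structure(list(gene_space = sort(rownames(big)), scale = 1e4,
                             log_transform = FALSE),
                        class = "normalization_spec")
  cs <- colSums(normalize_counts(big, spec_big))
  nonzero <- colSums(big) > 0
  expect_true(all(abs(cs[nonzero] - 1e4) < 1e-6))
})

test_that("log transform and zero-filling of missing genes work", {
  spec <- structure(list(gene_space = c("a", "b", "c"), scale = 100,
                         log_transform = TRUE),
                    class = "normalization_spec")
  m <- matrix(c(1, 3), 2, 1, dimnames = list(c("a", "c"), "s1"))
  expect_warning(norm <- normalize_counts(m, spec), "zero-filled")
  expect_equal(unname(norm[, 1]), log1p(c(25, 0, 75)))
})

test_that("coordinate tables require the documented header", {
  path <- file.path(tempdir(), "coords.csv")
  writeLines(c("spot_id,x,y", "s1,0,0", "s2,1.5,2"), path)
  xy <- read_coords(path)
  expect_equal(rownames(xy), c("s1", "s2"))
  expect_equal(unname(xy["s2", ]), c(1.5, 2))
  writeLines(c("id,a,b", "s1,0,0"), path)
  expect_error(read_coords(path), "spot_id")
})
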
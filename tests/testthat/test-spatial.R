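test_that("unit-square kNN prefers edge neighbours over the diagonal", {
  coords <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  g <- build_spatial_graph(coords, k = 2)
  expect_setequal(g$neighbor_ids[1, ], c(2L, 3L))  # not the diagonal corner 4
  expect_setequal(g$neighbor_ids[4, ], c(2L, 3L))
  expect_equal(as.vector(g$neighbor_dists), rep(1, 8))
})

test_that("kNN matches an independent library oracle on random spots", {
  set.seed(40)
  coords <- matrix(runif(200), 100, 2)
  g <- build_spatial_graph(coords, k = 5)
  oracle <- FNN::get.knn(coords, k = 5)
  expect_equal(g$neighbor_ids, unname(oracle$nn.index))
  expect_equal(g$neighbor_dists, unname(oracle$nn.dist), tolerance = 1e-12)
})

test_that("duplicate coordinates pair up first with index tie-breaks", {
  coords <- rbind(c(0, 0), c(0, 0), c(5, 5), c(0, 0.1))
  g <- build_spatial_graph(coords, k = 2)
  expect_equal(g$neighbor_ids[1, 1], 2L)
  expect_equal(g$neighbor_ids[2, 1], 1L)
  expect_equal(g$neighbor_dists[1, 1], 0)
  expect_error(build_spatial_graph(coords, k = 4), "smaller")
})

test_that("extrinsic profiles sum the k nearest neighbours' raw counts", {
  set.seed(41)
  counts <- matrix(rpois(5 * 6, 4), 5, 6,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  coords <- cbind(seq_len(6), 0)  # a line: neighbours are adjacent spots
  st <- spatial_dataset(counts, coords)
  g1 <- build_spatial_graph(st, k = 1)
  E1 <- build_extrinsic_profiles(st, g1)
  expect_equal(unname(E1[, 1]), unname(counts[, 2]))  # k=1: nearest only
  g2 <- build_spatial_graph(st, k = 2)
  E2 <- build_extrinsic_profiles(st, g2)
  for (i in 1:6)
    expect_equal(sum(E2[, i]), sum(colSums(counts)[g2$neighbor_ids[i, ]]))
  # homogeneous tissue: every extrinsic profile is k times the shared vector
  same <- matrix(rep(c(3, 1, 0, 2, 5), 6), 5, 6,
                 dimnames = dimnames(counts))
  Eh <- build_extrinsic_profiles(spatial_dataset(same, coords), g2)
  expect_true(all(Eh == 2 * same))
})

make_reg_inputs <- function() {
  # 3 spots whose intrinsic profiles resemble their extrinsic profile to
  # different degrees
  st_norm <- cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  ext_norm <- cbind(c(1, 0, 0), c(0.5, 0.5, 0), c(1, 0, 0))
  ip <- matrix(c(0.8, 0.2, 0.6, 0.4, 0.3, 0.7), 3, 2, byrow = TRUE)
  ep <- matrix(c(0.5, 0.5, 0.5, 0.5, 0.9, 0.1), 3, 2, byrow = TRUE)
  list(st_norm = st_norm, ext_norm = ext_norm, ip = ip, ep = ep)
}

test_that("lambda_max = 0 is a bit-exact identity", {
  z <- make_reg_inputs()
  res <- spatial_regularize(z$ip, z$ep, z$st_norm, z$ext_norm, lambda_max = 0)
  expect_identical(res$regularized_props, z$ip)
  expect_true(all(res$lambda_per_spot == 0))
})

test_that("similarity extremes map to lambda_max and zero", {
  z <- make_reg_inputs()
  res <- spatial_regularize(z$ip, z$ep, z$st_norm, z$ext_norm,
                            lambda_max = 0.5)
  # spot 1 is identical to its surroundings (d = 0 -> lambda = lambda_max)
  expect_equal(res$lambda_per_spot[1], 0.5)
  expect_equal(res$regularized_props[1, ],
               0.5 * z$ip[1, ] + 0.5 * z$ep[1, ])
  # spot 3 is maximally dissimilar after min-max scaling -> untouched
  expect_equal(res$lambda_per_spot[3], 0)
  expect_equal(res$regularized_props[3, ], z$ip[3, ])
  # monotone: larger dissimilarity never gets a larger lambda
  ord <- order(res$intrinsic_extrinsic_dist)
  expect_true(all(diff(res$lambda_per_spot[ord]) <= 1e-12))
})

test_that("regularized rows are convex combinations on the simplex", {
  z <- make_reg_inputs()
  res <- spatial_regularize(z$ip, z$ep, z$st_norm, z$ext_norm,
                            lambda_max = 0.7, similarity = "pearson")
  expect_true(all(abs(rowSums(res$regularized_props) - 1) < 1e-6))
  lam <- res$lambda_per_spot
  expect_equal(res$regularized_props,
               (1 - lam) * z$ip + lam * z$ep, tolerance = 1e-12)
  expect_true(all(lam >= 0 & lam <= 0.7))
})

test_that("regularization does not roughen the two-region fixture", {
  fix <- small_spatial()
  m <- small_model()
  res <- deconvolute(m, fix$spatial, spatial = TRUE, k = 4, lambda_max = 0.5)
  g <- build_spatial_graph(fix$spatial, k = 4)
  roughness <- function(P) {
    mean(vapply(seq_len(nrow(P)), function(i)
      mean(rowMeans(abs(P[g$neighbor_ids[i, ], , drop = FALSE] -
                          matrix(P[i, ], g$k, ncol(P), byrow = TRUE)))),
      1))
  }
  expect_lte(roughness(res$regularized_props),
             roughness(res$intrinsic_props) + 1e-12)
})

test_that("distance maps are tidy and flag the region boundary", {
  fix <- small_spatial()
  m <- small_model()
  res <- deconvolute(m, fix$spatial, spatial = TRUE, k = 4)
  dm <- intrinsic_extrinsic_distance_map(res)
  expect_named(dm, c("spot_id", "x", "y", "distance"))
  expect_equal(nrow(dm), length(fix$spatial$spot_ids))
  # boundary columns (4, 5 on an 8-wide left/right split) are the least
  # spatially consistent
  boundary <- dm$x %in% c(4, 5)
  expect_gt(mean(dm$distance[boundary]), mean(dm$distance[!boundary]))
  expect_true(dm$x[which.max(dm$distance)] %in% c(4, 5))
  # homogeneous tissue: all distances equal (zero) by construction
  counts <- matrix(rep(c(3, 1, 2), 9), 3, 9,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:9)))
  st_h <- spatial_dataset(counts, expand.grid(x = 1:3, y = 1:3))
  gh <- build_spatial_graph(st_h, k = 2)
  Eh <- build_extrinsic_profiles(st_h, gh)
  spec <- structure(list(gene_space = paste0("g", 1:3), scale = 100,
                         log_transform = TRUE), class = "normalization_spec")
  res_h <- spatial_regularize(matrix(1 / 2, 9, 2), matrix(1 / 2, 9, 2),
                              normalize_counts(counts, spec),
                              normalize_counts(Eh, spec))
  expect_true(all(abs(res_h$intrinsic_extrinsic_dist) < 1e-9))
})

test_that("deconvolute without regularization returns intrinsic only", {
  fix <- small_spatial()
  res <- deconvolute(small_model(), fix$spatial)
  expect_null(res$regularized_props)
  expect_equal(nrow(res$intrinsic_props), length(fix$spatial$spot_ids))
  df <- as.data.frame(res)
  expect_true(all(c("spot_id", "x", "y") %in% names(df)))
})
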
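# Spatial regularization: extrinsic neighbourhood profiles from the k
# nearest spots, and a similarity-gated blend of intrinsic and extrinsic
# predictions.

#' Exact k-nearest-neighbour graph of spots
#'
#' Euclidean distances in coordinate units; exact search over all pairs.
#' Neighbour lists are sorted by ascending distance with ties broken by spot
#' index, and a spot is never its own neighbour.
#'
#' @param st a [spatial_dataset()] (or a spots x 2 coordinate matrix).
#' @param k neighbours per spot; `k < n_spots` required. Default 6 matches
#'   hexagonal-lattice platforms; use 4 for square grids.
#' @return object of class `spatial_graph`: list with `k`, `neighbor_ids`
#'   (spots x k index matrix), `neighbor_dists` (spots x k).
#' @export
build_spatial_graph <- function(st, k = 6L) {
  coords <- if (inherits(st, "spatial_dataset")) st$coords else as.matrix(st)
  n <- nrow(coords)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (k >= n) stop("k (", k, ") must be smaller than the number of spots (", n, ")")
  D <- as.matrix(stats::dist(coords))
  ids <- matrix(0L, n, k)
  dists <- matrix(0, n, k)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    ord <- order(d, seq_len(n))[seq_len(k)]
    ids[i, ] <- ord
    dists[i, ] <- d[ord]
  }
  structure(list(k = as.integer(k), neighbor_ids = ids,
                 neighbor_dists = dists),
            class = "spatial_graph")
}

#' Extrinsic neighbourhood profiles
#'
#' The extrinsic profile of a spot is the element-wise sum of the raw counts
#' of its k nearest neighbours (the spot itself excluded): a simulated sample
#' representing the transcriptional profile of the spot's surroundings.
#'
#' @param st a [spatial_dataset()].
#' @param graph a `spatial_graph` built on the same spots.
#' @return genes x spots count matrix.
#' @export
build_extrinsic_profiles <- function(st, graph) {
  n <- ncol(st$counts)
  stopifnot(nrow(graph$neighbor_ids) == n)
  A <- Matrix::sparseMatrix(i = as.vector(graph$neighbor_ids),
                            j = rep(seq_len(n), times = graph$k),
                            x = 1, dims = c(n, n))
  E <- as.matrix(st$counts %*% A)
  dimnames(E) <- dimnames(st$counts)
  E
}

cosine_sim_cols <- function(A, B) {
  num <- colSums(A * B)
  den <- sqrt(colSums(A^2)) * sqrt(colSums(B^2))
  ifelse(den > 0, num / den, 0)
}

pearson_sim_cols <- function(A, B) {
  Ac <- sweep(A, 2L, colMeans(A))
  Bc <- sweep(B, 2L, colMeans(B))
  cosine_sim_cols(Ac, Bc)
}

#' Spatially regularize predicted proportions
#'
#' Blends each spot's intrinsic prediction with its extrinsic (neighbourhood)
#' prediction according to how similar the spot's own transcriptional profile
#' is to its surroundings: per spot, a dissimilarity
#' `d_i = 1 - similarity(intrinsic_i, extrinsic_i)` on normalized profiles is
#' rescaled to \[0, 1\] (min-max by default), the blend weight is
#' `lambda_i = lambda_max * (1 - d_i)`, and the regularized composition is
#' `(1 - lambda_i) * intrinsic_i + lambda_i * extrinsic_i`. Spots that look
#' like their surroundings are smoothed most; spots transcriptionally unlike
#' their neighbourhood are left untouched. `lambda_max = 0` disables the
#' step bit-exactly.
#'
#' @param intrinsic_props,extrinsic_props spots x types proportion matrices
#'   (network predictions on intrinsic and extrinsic profiles).
#' @param st_norm,ext_norm normalized genes x spots expression of the
#'   intrinsic and extrinsic profiles (same spot order).
#' @param lambda_max maximal blend weight in \[0, 1\] (default 0.5).
#' @param similarity `"cosine"` (default) or `"pearson"`.
#' @param distance_scaling `"minmax"` (default; a spatially homogeneous
#'   tissue where all dissimilarities are equal maps to d = 0, i.e. maximal
#'   smoothing) or `"none"`.
#' @return object of class `spot_deconv`: list with `intrinsic_props`,
#'   `extrinsic_props`, `regularized_props`, `lambda_per_spot`,
#'   `intrinsic_extrinsic_dist` (raw, unscaled dissimilarities).
#' @export
spatial_regularize <- function(intrinsic_props, extrinsic_props,
                               st_norm, ext_norm, lambda_max = 0.5,
                               similarity = c("cosine", "pearson"),
                               distance_scaling = c("minmax", "none")) {
  similarity <- match.arg(similarity)
  distance_scaling <- match.arg(distance_scaling)
  stopifnot(lambda_max >= 0, lambda_max <= 1,
            all(dim(intrinsic_props) == dim(extrinsic_props)),
            ncol(st_norm) == nrow(intrinsic_props),
            ncol(ext_norm) == nrow(intrinsic_props))
  intrinsic_props <- as.matrix(intrinsic_props)
  extrinsic_props <- as.matrix(extrinsic_props)
  sim <- switch(similarity,
                cosine = cosine_sim_cols(st_norm, ext_norm),
                pearson = pearson_sim_cols(st_norm, ext_norm))
  d <- 1 - sim
  d_scaled <- d
  if (distance_scaling == "minmax") {
    rng <- range(d)
    d_scaled <- if (rng[2] > rng[1]) (d - rng[1]) / (rng[2] - rng[1])
                else rep(0, length(d))
  } else {
    d_scaled <- pmin(pmax(d_scaled, 0), 1)
  }
  lambda <- lambda_max * (1 - d_scaled)
  reg <- if (lambda_max == 0) intrinsic_props
         else (1 - lambda) * intrinsic_props + lambda * extrinsic_props
  structure(list(intrinsic_props = intrinsic_props,
                 extrinsic_props = extrinsic_props,
                 regularized_props = reg,
                 lambda_per_spot = lambda,
                 intrinsic_extrinsic_dist = d),
            class = "spot_deconv")
}

#' Deconvolute a spatial dataset with a trained model
#'
#' Predicts the composition of every spot's intrinsic profile and, when
#' `spatial = TRUE`, builds the k-nearest-neighbour extrinsic profiles,
#' predicts their composition with the same model, and applies
#' [spatial_regularize()]. Regularization assumes transcriptional continuity
#' between neighbouring spots; it is off by default and should stay off for
#' tissues where that assumption fails.
#'
#' @param model a `deconv_model`.
#' @param st a [spatial_dataset()].
#' @param spatial apply spatial regularization (default FALSE).
#' @param k neighbours for the extrinsic profiles (default 6).
#' @param lambda_max,similarity,distance_scaling see [spatial_regularize()].
#' @return a `spot_deconv` object (extrinsic/regularized components `NULL`
#'   when `spatial = FALSE`); spot ids and coordinates are attached.
#' @export
deconvolute <- function(model, st, spatial = FALSE, k = 6L, lambda_max = 0.5,
                        similarity = "cosine", distance_scaling = "minmax") {
  stopifnot(inherits(model, "deconv_model"), inherits(st, "spatial_dataset"))
  intrinsic <- predict(model, st)
  if (!spatial) {
    res <- structure(list(intrinsic_props = intrinsic,
                          extrinsic_props = NULL,
                          regularized_props = NULL,
                          lambda_per_spot = NULL,
                          intrinsic_extrinsic_dist = NULL),
                     class = "spot_deconv")
  } else {
    graph <- build_spatial_graph(st, k = k)
    ext_counts <- build_extrinsic_profiles(st, graph)
    extrinsic <- predict(model, ext_counts)
    st_norm <- normalize_counts(st$counts, model$norm_spec, warn_missing = FALSE)
    ext_norm <- normalize_counts(ext_counts, model$norm_spec, warn_missing = FALSE)
    res <- spatial_regularize(intrinsic, extrinsic, st_norm, ext_norm,
                              lambda_max = lambda_max,
                              similarity = similarity,
                              distance_scaling = distance_scaling)
  }
  res$spot_ids <- st$spot_ids
  res$coords <- st$coords
  res
}

#' @export
print.spot_deconv <- function(x, ...) {
  cat(sprintf("spot_deconv: %d spots x %d cell types%s\n",
              nrow(x$intrinsic_props), ncol(x$intrinsic_props),
              if (is.null(x$regularized_props)) " (no spatial regularization)"
              else " (spatially regularized)"))
  invisible(x)
}

#' @export
as.data.frame.spot_deconv <- function(x, ...) {
  props <- x$regularized_props %||% x$intrinsic_props
  df <- data.frame(spot_id = x$spot_ids %||% rownames(props), props,
                   check.names = FALSE)
  if (!is.null(x$coords)) { df$x <- x$coords[, 1]; df$y <- x$coords[, 2] }
  df
}

#' Spatial map of intrinsic-extrinsic dissimilarity
#'
#' Tidy table of each spot's dissimilarity between its own profile and its
#' neighbourhood profile, for exploring the spatial consistency of tissue
#' regions (large values mark boundaries and transcriptionally isolated
#' spots).
#'
#' @param result a `spot_deconv` computed with `spatial = TRUE`.
#' @param coords optional spots x 2 coordinates (default: those stored in
#'   the result).
#' @return data frame with columns `spot_id`, `x`, `y`, `distance`.
#' @export
intrinsic_extrinsic_distance_map <- function(result, coords = result$coords) {
  if (is.null(result$intrinsic_extrinsic_dist))
    stop("result has no spatial component; run deconvolute(spatial = TRUE)")
  data.frame(spot_id = result$spot_ids %||% rownames(coords),
             x = coords[, 1], y = coords[, 2],
             distance = result$intrinsic_extrinsic_dist,
             row.names = NULL)
}

#' Plot predicted proportions or dissimilarity on the spot layout
#' @param x a `spot_deconv` with coordinates.
#' @param type cell type to colour by, or `"distance"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.spot_deconv <- function(x, type = colnames(x$intrinsic_props)[1], ...) {
  if (is.null(x$coords)) stop("no coordinates attached")
  val <- if (identical(type, "distance")) {
    if (is.null(x$intrinsic_extrinsic_dist))
      stop("no distances; run with spatial = TRUE")
    x$intrinsic_extrinsic_dist
  } else {
    props <- x$regularized_props %||% x$intrinsic_props
    props[, type]
  }
  pal <- grDevices::hcl.colors(100, "viridis")
  col <- pal[pmin(100L, 1L + floor(99 * (val - min(val)) /
                                     max(1e-12, diff(range(val)))))]
  graphics::plot(x$coords[, 1], x$coords[, 2], col = col, pch = 16,
                 xlab = "x", ylab = "y", main = type, ...)
  invisible(x)
}
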
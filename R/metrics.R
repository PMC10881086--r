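# Evaluation statistics for deconvolution benchmarking, and clustering of
# spots on predicted proportions.

#' Pearson correlation coefficient
#'
#' Standard Pearson correlation; returns `NA` with a warning when either
#' vector has zero variance.
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in \[-1, 1\], or `NA`.
#' @export
pcc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: Pearson correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Lin's concordance correlation coefficient
#'
#' `2 cov(x,y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with population
#' (1/n) moments, so `ccc(x, x) == 1` exactly. Unlike Pearson correlation,
#' CCC penalizes departure from the identity line: a constant offset or a
#' slope different from 1 lowers it. Two equal constant vectors return 1 by
#' convention; unequal constants return the formula's value (0).
#' @param x,y numeric vectors of equal length >= 2.
#' @return concordance in \[-1, 1\]; `abs(ccc) <= abs(pcc)` always.
#' @export
ccc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) return(1)  # identical constants: perfect concordance
  2 * cxy / denom
}

#' Jensen-Shannon divergence between two composition vectors
#'
#' Base-2 logarithms, so the value lies in \[0, 1\]; `0 * log 0` is taken as
#' 0. Inputs are renormalized to sum to 1.
#' @param p,q non-negative vectors of equal length.
#' @return divergence in \[0, 1\]; symmetric in its arguments.
#' @export
jsd <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (any(p < 0) || any(q < 0)) stop("composition vectors must be non-negative")
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl2 <- function(a, b) {
    i <- a > 0
    sum(a[i] * (log2(a[i]) - log2(b[i])))
  }
  (kl2(p, m) + kl2(q, m)) / 2
}

#' Root mean squared error
#' @param x,y numeric vectors of equal length.
#' @return `sqrt(mean((x - y)^2))`.
#' @export
rmse <- function(x, y) {
  stopifnot(length(x) == length(y))
  sqrt(mean((x - y)^2))
}

#' Summarize agreement between two proportion matrices
#'
#' Computes PCC, CCC and RMSE with either reducer used in deconvolution
#' benchmarking: per cell type (across profiles, the default) or per profile
#' (across types), plus the mean per-profile JSD.
#'
#' @param truth,pred profiles x types matrices with matching dimensions.
#' @param by `"type"` (columns) or `"profile"` (rows).
#' @return data frame with one row per type or profile and columns `pcc`,
#'   `ccc`, `rmse`; mean JSD attached as attribute `mean_jsd`.
#' @export
proportion_agreement <- function(truth, pred, by = c("type", "profile")) {
  by <- match.arg(by)
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  stopifnot(all(dim(truth) == dim(pred)))
  slices <- if (by == "type") seq_len(ncol(truth)) else seq_len(nrow(truth))
  get <- function(m, i) if (by == "type") m[, i] else m[i, ]
  out <- data.frame(
    id = if (by == "type") colnames(truth) %||% as.character(slices)
         else rownames(truth) %||% as.character(slices),
    pcc = vapply(slices, function(i) pcc(get(truth, i), get(pred, i)), 1),
    ccc = vapply(slices, function(i) ccc(get(truth, i), get(pred, i)), 1),
    rmse = vapply(slices, function(i) rmse(get(truth, i), get(pred, i)), 1))
  attr(out, "mean_jsd") <-
    mean(vapply(seq_len(nrow(truth)),
                function(i) jsd(truth[i, ], pred[i, ]), 1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cluster spots on predicted cell-type proportions
#'
#' k-means (Euclidean) on the rows of a proportion matrix, with multiple
#' restarts keeping the lowest within-cluster sum of squares; deterministic
#' given the seed.
#'
#' @param props spots x types proportion matrix.
#' @param n_clusters number of clusters (>= 2, < number of spots).
#' @param seed RNG seed.
#' @param nstart random restarts (default 10).
#' @return object of class `spot_clusters`: list with `labels` (integer per
#'   spot, named), `centers`, `n_clusters`, `seed`.
#' @export
cluster_spots <- function(props, n_clusters, seed = 1L, nstart = 10L) {
  props <- as.matrix(props)
  if (n_clusters >= nrow(props))
    stop("n_clusters must be smaller than the number of spots")
  stopifnot(n_clusters >= 2L)
  set.seed(seed)
  km <- stats::kmeans(props, centers = n_clusters, nstart = nstart,
                      iter.max = 100L)
  labels <- km$cluster
  names(labels) <- rownames(props)
  structure(list(labels = labels, centers = km$centers,
                 n_clusters = as.integer(n_clusters), seed = as.integer(seed)),
            class = "spot_clusters")
}

#' @export
print.spot_clusters <- function(x, ...) {
  cat(sprintf("spot_clusters: %d spots in %d clusters (sizes %s)\n",
              length(x$labels), x$n_clusters,
              paste(table(x$labels), collapse = ", ")))
  invisible(x)
}
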
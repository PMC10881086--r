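# Simulation of mixed transcriptional profiles with known cell composition:
# the training/test material for the deconvolution network.

#' Stratified train/test split of reference cells
#'
#' Cells are split so that every cell type contributes to both subsets:
#' per type, `max(1, round(test_frac * n_t))` cells go to test.
#'
#' @param ref a [reference_dataset()]; every type needs at least 2 cells.
#' @param test_frac fraction of cells held out per type, in (0, 1).
#' @param seed RNG seed; the split is deterministic given the seed.
#' @return list with `train` and `test` cell-id vectors (disjoint,
#'   exhaustive).
#' @export
split_cells <- function(ref, test_frac = 0.2, seed = 1L) {
  stopifnot(test_frac > 0, test_frac < 1)
  tab <- table(ref$cell_types)
  if (any(tab < 2L))
    stop("cell type(s) with fewer than 2 cells cannot be split: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  set.seed(seed)
  test <- character(0)
  for (t in names(tab)) {
    ids <- ref$cell_ids[ref$cell_types == t]
    n_test <- min(length(ids) - 1L, max(1L, round(test_frac * length(ids))))
    test <- c(test, sample(ids, n_test))
  }
  list(train = setdiff(ref$cell_ids, test), test = test)
}

rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  g <- matrix(stats::rgamma(n * K, shape = alpha), n, K, byrow = TRUE)
  g / rowSums(g)
}

#' Sample cell-type proportion vectors for mixture simulation
#'
#' Three strata cover the simplex: `round(frac_pure * n)` one-hot rows
#' assigned to types cyclically (vertices), `round(frac_sparse * n)` rows
#' where a uniformly chosen non-empty strict subset of types is zeroed before
#' a Dirichlet draw on the survivors (faces), and full Dirichlet rows for the
#' remainder (interior). This guarantees the network sees extreme as well as
#' balanced compositions.
#'
#' @param n_profiles number of rows.
#' @param n_types number of cell types (>= 2).
#' @param alpha Dirichlet concentration (default 1: uniform on the simplex).
#' @param frac_pure fraction of one-hot rows (default 0.1).
#' @param frac_sparse fraction of sparse rows (default 0.3);
#'   `frac_pure + frac_sparse <= 1`.
#' @param seed RNG seed.
#' @return `n_profiles` x `n_types` row-stochastic matrix.
#' @export
sample_proportions <- function(n_profiles, n_types, alpha = 1,
                               frac_pure = 0.1, frac_sparse = 0.3,
                               seed = 1L) {
  stopifnot(n_types >= 2, alpha > 0, frac_pure >= 0, frac_sparse >= 0,
            frac_pure + frac_sparse <= 1)
  set.seed(seed)
  n_pure <- round(frac_pure * n_profiles)
  n_sparse <- round(frac_sparse * n_profiles)
  n_full <- n_profiles - n_pure - n_sparse
  P <- matrix(0, n_profiles, n_types)
  if (n_pure > 0) {
    for (i in seq_len(n_pure)) P[i, ((i - 1L) %% n_types) + 1L] <- 1
  }
  for (i in seq_len(n_sparse)) {
    n_zero <- sample.int(n_types - 1L, 1L)
    zero <- sample.int(n_types, n_zero)
    keep <- setdiff(seq_len(n_types), zero)
    P[n_pure + i, keep] <- rdirichlet(1L, rep(alpha, length(keep)))
  }
  if (n_full > 0)
    P[(n_pure + n_sparse + 1L):n_profiles, ] <-
      rdirichlet(n_full, rep(alpha, n_types))
  P
}

#' Largest-remainder rounding of proportions to integer cell counts
#'
#' Floors `p * n` and distributes the remaining cells to the largest
#' fractional remainders; ties are broken by position (lexicographic type
#' order), making realized compositions deterministic.
#'
#' @param p proportion vector (sums to ~1).
#' @param n total integer to distribute.
#' @return integer vector summing exactly to `n`.
#' @export
largest_remainder <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    rem <- raw - base
    add <- order(-rem, seq_along(p))[seq_len(short)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Synthesize mixed transcriptional profiles from a reference
#'
#' For every proportion row, the number of cells per type is the
#' largest-remainder rounding of `proportion * n_cells_per_mixture`; cells
#' are drawn uniformly with replacement within type from `cell_ids`, and the
#' profile is the element-wise sum of the drawn cells' raw count vectors
#' (total counts are conserved exactly). Stored proportions are the realized
#' post-rounding fractions.
#'
#' @param ref a [reference_dataset()].
#' @param cell_ids subset of reference cells to draw from (e.g. the train or
#'   test side of [split_cells()]).
#' @param proportions profiles x types row-stochastic matrix; column names,
#'   if present, must name cell types, otherwise sorted type order is used.
#' @param n_cells_per_mixture cells summed per profile (default 50).
#' @param seed RNG seed.
#' @param partition label recorded on the result (`"train"` or `"test"`).
#' @return object of class `mixture_set`: list with `profiles`
#'   (genes x profiles counts), `proportions` (realized, profiles x types),
#'   `cell_type_order`, `partition`, `draws` (list of drawn cell indices,
#'   kept for conservation checks).
#' @export
synthesize_mixtures <- function(ref, cell_ids, proportions,
                                n_cells_per_mixture = 50L, seed = 1L,
                                partition = "train") {
  proportions <- as.matrix(proportions)
  types <- colnames(proportions)
  all_types <- sort(unique(ref$cell_types))
  if (is.null(types)) {
    if (ncol(proportions) != length(all_types))
      stop("unnamed proportion matrix must have one column per reference type")
    types <- all_types
    colnames(proportions) <- types
  }
  sel <- match(cell_ids, ref$cell_ids)
  if (anyNA(sel)) stop("unknown cell ids in subset")
  by_type <- split(sel, ref$cell_types[sel])
  used <- types[colSums(proportions > 0) > 0]
  missing <- setdiff(used, names(by_type))
  if (length(missing))
    stop("cell type(s) with positive proportion absent from the '", partition,
         "' subset: ", paste(missing, collapse = ", "))

  set.seed(seed)
  n_prof <- nrow(proportions)
  K <- length(types)
  realized <- matrix(0, n_prof, K, dimnames = list(NULL, types))
  draws <- vector("list", n_prof)
  di <- dj <- vector("list", n_prof)
  for (i in seq_len(n_prof)) {
    cnt <- largest_remainder(proportions[i, ], n_cells_per_mixture)
    realized[i, ] <- cnt / n_cells_per_mixture
    picked <- integer(0)
    for (k in seq_len(K)) {
      if (cnt[k] == 0L) next
      pool <- by_type[[types[k]]]
      picked <- c(picked, pool[sample.int(length(pool), cnt[k], replace = TRUE)])
    }
    draws[[i]] <- picked
    di[[i]] <- picked
    dj[[i]] <- rep.int(i, length(picked))
  }
  # genes x profiles = counts %*% (cells x profiles draw-multiplicity matrix)
  D <- Matrix::sparseMatrix(i = unlist(di), j = unlist(dj), x = 1,
                            dims = c(ncol(ref$counts), n_prof))
  profiles <- as.matrix(ref$counts %*% D)
  storage.mode(profiles) <- "double"
  rownames(profiles) <- ref$gene_ids
  colnames(profiles) <- sprintf("%s_mix%05d", partition, seq_len(n_prof))
  rownames(realized) <- colnames(profiles)
  structure(list(profiles = profiles, proportions = realized,
                 cell_type_order = types, partition = partition,
                 draws = draws),
            class = "mixture_set")
}

#' @export
print.mixture_set <- function(x, ...) {
  cat(sprintf("mixture_set (%s): %d profiles x %d genes, %d cell types\n",
              x$partition, ncol(x$profiles), nrow(x$profiles),
              length(x$cell_type_order)))
  invisible(x)
}

#' Write a mixture set to disk
#'
#' Profiles go to an MTX triplet bundle, realized proportions to
#' `proportions.csv` (profile id x cell types).
#' @param mix a `mixture_set`.
#' @param dir output directory.
#' @export
write_mixture_set <- function(mix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts_mtx(mix$profiles, dir)
  utils::write.csv(data.frame(profile_id = rownames(mix$proportions),
                              mix$proportions, check.names = FALSE),
                   file.path(dir, "proportions.csv"), row.names = FALSE)
  invisible(dir)
}
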
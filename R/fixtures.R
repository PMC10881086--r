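# Synthetic data with known ground truth: scRNA-seq references with
# marker-block structure, spot lattices with regional compositions, and
# single-cell-resolution spatial datasets for the binning-based evaluation.

#' Simulate an annotated scRNA-seq reference
#'
#' Negative-binomial marker-block model. Each cell type owns a disjoint block
#' of `markers_per_type` genes whose expected expression is multiplied by
#' `fold_change` in cells of that type. Gene baseline rates are Gamma
#' distributed with mean `base_mean`; each cell carries a log-normal library
#' size factor with coefficient of variation `library_cv`; counts are drawn
#' from a negative binomial with size (dispersion) parameter `dispersion`.
#' Ground-truth marker blocks are attached as the `markers` element.
#'
#' @param n_genes total genes (default 500).
#' @param n_types number of cell types (default 5).
#' @param n_cells_per_type cells simulated per type (default 200).
#' @param markers_per_type marker genes per type; blocks are disjoint, so
#'   `markers_per_type * n_types <= n_genes`.
#' @param fold_change multiplicative marker effect in the owning type
#'   (default 8; 1 gives a null dataset with no separability).
#' @param base_mean mean of the per-gene baseline NB rate (default 2).
#' @param dispersion NB size parameter (default 2; smaller = noisier).
#' @param library_cv coefficient of variation of per-cell library factors.
#' @param seed RNG seed; the dataset is bit-reproducible given the seed.
#' @return a [reference_dataset()] with an extra `markers` element (named list
#'   of marker gene ids per type).
#' @export
simulate_reference <- function(n_genes = 500L, n_types = 5L,
                               n_cells_per_type = 200L,
                               markers_per_type = 25L, fold_change = 8,
                               base_mean = 2, dispersion = 2,
                               library_cv = 0.2, seed = 1L) {
  stopifnot(n_types >= 2, fold_change >= 1,
            markers_per_type * n_types <= n_genes)
  set.seed(seed)
  n_cells <- n_types * n_cells_per_type
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  types <- sprintf("type%d", seq_len(n_types))
  cell_types <- rep(types, each = n_cells_per_type)
  cell_ids <- sprintf("cell%04d", seq_len(n_cells))

  base <- stats::rgamma(n_genes, shape = 2, scale = base_mean / 2)
  sdlog <- sqrt(log(1 + library_cv^2))
  libf <- stats::rlnorm(n_cells, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  markers <- lapply(seq_len(n_types), function(t)
    gene_ids[((t - 1L) * markers_per_type + 1L):(t * markers_per_type)])
  names(markers) <- types
  # every type's marker block shares one baseline-rate template, so the
  # expected per-cell total is identical across types: after depth
  # normalization the marker blocks are the only composition signal, which
  # keeps the fixture's ground truth (markers) exact for attribution tests
  block_template <- stats::rgamma(markers_per_type, shape = 2,
                                  scale = base_mean / 2)
  for (t in types) base[match(markers[[t]], gene_ids)] <- block_template

  fold <- matrix(1, n_genes, n_types, dimnames = list(gene_ids, types))
  for (t in types) fold[markers[[t]], t] <- fold_change

  mu <- fold[, match(cell_types, types), drop = FALSE] *
    outer(base, libf)
  counts <- matrix(stats::rnbinom(length(mu), size = dispersion, mu = mu),
                   n_genes, n_cells, dimnames = list(gene_ids, cell_ids))
  ref <- reference_dataset(counts, cell_types)
  ref$markers <- markers
  ref
}

#' Simulate a spot-lattice spatial dataset from a reference
#'
#' Spots sit on a `grid[1]` x `grid[2]` rectangular lattice (unit spacing).
#' Each spot belongs to a region given by `region_of`, its composition is a
#' Dirichlet draw concentrated around the region's archetype, and its counts
#' are synthesized by summing sampled reference cells exactly as
#' [synthesize_mixtures()] does.
#'
#' @param ref a [reference_dataset()].
#' @param grid integer vector (rows, cols) of the spot lattice.
#' @param archetypes regions x types row-stochastic matrix of mean
#'   compositions. Default: two region archetypes, each dominated by a
#'   different half of the cell types.
#' @param region_of function mapping (x, y) vectors to region indices
#'   (1-based). Default splits the lattice at the median column into a
#'   left/right region.
#' @param concentration Dirichlet concentration around the archetype
#'   (larger = tighter; default 30).
#' @param n_cells_per_spot cells summed into each spot (default 20).
#' @param seed RNG seed.
#' @return list with `spatial` (a [spatial_dataset()]), `true_props`
#'   (spots x types realized proportions), `region` (region index per spot).
#' @export
simulate_spatial <- function(ref, grid = c(10L, 10L), archetypes = NULL,
                             region_of = NULL, concentration = 30,
                             n_cells_per_spot = 20L, seed = 1L) {
  types <- sort(unique(ref$cell_types))
  K <- length(types)
  if (is.null(archetypes)) {
    half <- ceiling(K / 2)
    a1 <- ifelse(seq_len(K) <= half, 0.9 / half, 0.1 / (K - half))
    a2 <- ifelse(seq_len(K) > half, 0.9 / (K - half), 0.1 / half)
    archetypes <- rbind(a1 / sum(a1), a2 / sum(a2))
  }
  archetypes <- as.matrix(archetypes)
  if (ncol(archetypes) != K)
    stop("archetypes must have one column per cell type (", K, ")")
  xy <- expand.grid(x = seq_len(grid[2]), y = seq_len(grid[1]))
  n_spots <- nrow(xy)
  if (is.null(region_of)) {
    cut <- stats::median(seq_len(grid[2]))
    region_of <- function(x, y) ifelse(x <= cut, 1L, 2L)
  }
  region <- region_of(xy$x, xy$y)
  if (any(region < 1L | region > nrow(archetypes)))
    stop("region_of returned indices outside archetype rows")

  set.seed(seed)
  props <- t(vapply(seq_len(n_spots), function(i) {
    a <- archetypes[region[i], ] * concentration
    g <- stats::rgamma(K, shape = pmax(a, 1e-8))
    g / sum(g)
  }, numeric(K)))
  colnames(props) <- types
  mix <- synthesize_mixtures(ref, ref$cell_ids, props,
                             n_cells_per_mixture = n_cells_per_spot,
                             seed = seed + 1L)
  spot_ids <- sprintf("spot%04d", seq_len(n_spots))
  colnames(mix$profiles) <- spot_ids
  st <- spatial_dataset(mix$profiles, as.matrix(xy), spot_ids = spot_ids)
  rownames(mix$proportions) <- spot_ids
  list(spatial = st, true_props = mix$proportions, region = region)
}

#' Simulate a single-cell-resolution spatial dataset
#'
#' Places `n_cells` cells uniformly on the unit square split into two
#' vertical regions; each cell's type is drawn from its region's type
#' distribution and its expression vector is a reference cell of that type
#' sampled with replacement. Used with [bin_single_cell_st()] to emulate the
#' evaluation protocol in which multi-cell spots with known composition are
#' built by binning neighbouring cells of imaging-based platforms.
#'
#' @param ref a [reference_dataset()].
#' @param n_cells number of cells (default 2000).
#' @param region_probs 2 x types matrix of type probabilities per region.
#'   Default mirrors the two-region archetypes of [simulate_spatial()].
#' @param seed RNG seed.
#' @return list with `counts` (genes x cells), `coords` (cells x 2),
#'   `labels` (type per cell), `region` (region per cell).
#' @export
simulate_single_cell_st <- function(ref, n_cells = 2000L, region_probs = NULL,
                                    seed = 1L) {
  types <- sort(unique(ref$cell_types))
  K <- length(types)
  if (is.null(region_probs)) {
    half <- ceiling(K / 2)
    a1 <- ifelse(seq_len(K) <= half, 0.9 / half, 0.1 / (K - half))
    a2 <- ifelse(seq_len(K) > half, 0.9 / (K - half), 0.1 / half)
    region_probs <- rbind(a1 / sum(a1), a2 / sum(a2))
  }
  set.seed(seed)
  coords <- cbind(x = stats::runif(n_cells), y = stats::runif(n_cells))
  region <- ifelse(coords[, "x"] <= 0.5, 1L, 2L)
  labels <- vapply(region, function(r)
    sample(types, 1L, prob = region_probs[r, ]), character(1))
  by_type <- split(seq_along(ref$cell_types), ref$cell_types)
  src <- vapply(labels, function(t)
    by_type[[t]][sample.int(length(by_type[[t]]), 1L)], integer(1))
  counts <- ref$counts[, src, drop = FALSE]
  colnames(counts) <- sprintf("sc%05d", seq_len(n_cells))
  rownames(coords) <- colnames(counts)
  list(counts = counts, coords = coords, labels = labels, region = region)
}

#' Bin single-cell-resolution spatial data into multi-cell spots
#'
#' Aggregates cells into square bins of side `bin_size`: each occupied bin
#' becomes one spot whose counts are the sum of its member cells' counts,
#' whose true composition is the frequency of member cell types, and whose
#' coordinate is the bin centre. Total counts are conserved exactly.
#'
#' @param counts genes x cells count matrix.
#' @param coords cells x 2 coordinate matrix.
#' @param labels cell-type label per cell.
#' @param bin_size side length of the square bins (coordinate units).
#' @return list with `spatial` (a [spatial_dataset()]) and `true_props`
#'   (spots x types, types in sorted label order).
#' @export
bin_single_cell_st <- function(counts, coords, labels, bin_size) {
  if (ncol(counts) == 0L) stop("no cells to bin")
  stopifnot(bin_size > 0, nrow(coords) == ncol(counts),
            length(labels) == ncol(counts))
  bx <- floor(coords[, 1] / bin_size)
  by <- floor(coords[, 2] / bin_size)
  key <- paste(bx, by, sep = "_")
  bins <- unique(key)
  types <- sort(unique(labels))
  idx <- split(seq_along(key), factor(key, levels = bins))
  prof <- vapply(idx, function(i)
    rowSums(counts[, i, drop = FALSE]), numeric(nrow(counts)))
  props <- t(vapply(idx, function(i) {
    f <- table(factor(labels[i], levels = types))
    as.numeric(f) / length(i)
  }, numeric(length(types))))
  colnames(props) <- types
  centers <- t(vapply(idx, function(i) {
    c((floor(coords[i[1], 1] / bin_size) + 0.5) * bin_size,
      (floor(coords[i[1], 2] / bin_size) + 0.5) * bin_size)
  }, numeric(2)))
  spot_ids <- sprintf("bin_%s", bins)
  colnames(prof) <- spot_ids
  rownames(prof) <- rownames(counts)
  rownames(props) <- spot_ids
  st <- spatial_dataset(prof, centers, spot_ids = spot_ids)
  list(spatial = st, true_props = props)
}
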
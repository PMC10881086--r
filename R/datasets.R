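#' Annotated single-cell reference dataset
#'
#' Bundles a raw gene x cell count matrix with one cell-type label per cell.
#' This is the reference from which mixed transcriptional profiles with known
#' composition are simulated.
#'
#' @param counts non-negative integer matrix, genes as rows and cells as
#'   columns. Row and column names are used as gene and cell identifiers when
#'   `gene_ids`/`cell_ids` are not given.
#' @param cell_types character vector, one label per cell; at least two
#'   distinct labels must be present.
#' @param gene_ids,cell_ids optional identifier vectors overriding dimnames.
#'
#' @return An object of class `reference_dataset`: a list with elements
#'   `counts`, `gene_ids`, `cell_ids`, `cell_types`.
#' @export
reference_dataset <- function(counts, cell_types, gene_ids = rownames(counts),
                              cell_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("counts must carry gene and cell identifiers (dimnames or explicit arguments)")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers in reference; collapse them first (see read_counts_matrix)")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell identifiers in reference")
  if (length(gene_ids) != nrow(counts) || length(cell_ids) != ncol(counts))
    stop("identifier lengths do not match count-matrix dimensions")
  if (length(cell_types) != ncol(counts))
    stop("need exactly one cell-type label per cell")
  if (any(counts < 0)) stop("counts must be non-negative")
  cell_types <- as.character(cell_types)
  if (length(unique(cell_types)) < 2L)
    stop("reference must contain at least two distinct cell types")
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(list(counts = counts, gene_ids = as.character(gene_ids),
                 cell_ids = as.character(cell_ids), cell_types = cell_types),
            class = "reference_dataset")
}

#' Spatial transcriptomics dataset
#'
#' A gene x spot count matrix together with 2-D spot coordinates in the
#' platform's units (arbitrary origin).
#'
#' @param counts non-negative count matrix, genes x spots.
#' @param coords numeric matrix or data frame with one row per spot and two
#'   columns (x, y). Row order must match the columns of `counts`.
#' @param gene_ids,spot_ids optional identifiers overriding dimnames.
#'
#' @return An object of class `spatial_dataset`: list with `counts`,
#'   `gene_ids`, `spot_ids`, `coords` (spots x 2 matrix).
#' @export
spatial_dataset <- function(counts, coords, gene_ids = rownames(counts),
                            spot_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  storage.mode(coords) <- "double"
  if (is.null(gene_ids) || is.null(spot_ids))
    stop("counts must carry gene and spot identifiers")
  if (anyDuplicated(spot_ids)) stop("duplicate spot identifiers")
  if (nrow(coords) != ncol(counts))
    stop("coordinate table must have one row per spot")
  if (any(counts < 0)) stop("counts must be non-negative")
  dimnames(counts) <- list(gene_ids, spot_ids)
  rownames(coords) <- spot_ids
  colnames(coords) <- c("x", "y")
  structure(list(counts = counts, gene_ids = as.character(gene_ids),
                 spot_ids = as.character(spot_ids), coords = coords),
            class = "spatial_dataset")
}

#' @export
print.reference_dataset <- function(x, ...) {
  tab <- table(x$cell_types)
  cat(sprintf("reference_dataset: %d genes x %d cells, %d cell types\n",
              nrow(x$counts), ncol(x$counts), length(tab)))
  cat("  ", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d genes x %d spots\n", nrow(x$counts), ncol(x$counts)))
  rx <- range(x$coords[, 1]); ry <- range(x$coords[, 2])
  cat(sprintf("  x in [%g, %g], y in [%g, %g]\n", rx[1], rx[2], ry[1], ry[2]))
  invisible(x)
}
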
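# Reading/writing count matrices, gene-space harmonization, normalization.

#' Read a gene x column count matrix
#'
#' Supported formats: MatrixMarket coordinate triplets with `genes.tsv` /
#' `barcodes.tsv` sidecars (the 10x-style layout), dense CSV with gene ids in
#' the first column and column ids in the header, and a simple HDF5 layout
#' (`/matrix`, `/genes`, `/barcodes`) as written by [write_counts_h5()].
#' Duplicate gene symbols are collapsed by summation; duplicate column ids are
#' an error.
#'
#' @param path path to the `.mtx`, `.csv` or `.h5` file.
#' @param format one of `"mtx"`, `"csv"`, `"h5"`. Guessed from the file
#'   extension when missing.
#' @param genes_file,barcodes_file sidecar paths for the MTX format; default
#'   `genes.tsv` and `barcodes.tsv` next to the matrix file. Two-column TSVs
#'   are tolerated (first column used).
#' @return list with `counts` (dense base matrix with dimnames), `gene_ids`,
#'   `column_ids`.
#' @export
read_counts_matrix <- function(path, format = c("auto", "mtx", "csv", "h5"),
                               genes_file = NULL, barcodes_file = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", h5 = "h5", hdf5 = "h5",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  out <- switch(format,
    mtx = read_mtx_triplet(path, genes_file, barcodes_file),
    csv = read_dense_csv(path),
    h5  = read_counts_h5(path))
  out$counts <- collapse_duplicate_genes(out$counts)
  out$gene_ids <- rownames(out$counts)
  if (anyDuplicated(out$column_ids))
    stop("duplicate column (cell/spot) identifiers in ", path)
  out
}

read_mtx_triplet <- function(path, genes_file, barcodes_file) {
  header <- readLines(path, n = 1L)
  if (!grepl("^%%MatrixMarket", header))
    stop("malformed MatrixMarket header in ", path, ": '", header, "'")
  m <- as.matrix(Matrix::readMM(path))
  dir <- dirname(path)
  if (is.null(genes_file)) genes_file <- file.path(dir, "genes.tsv")
  if (is.null(barcodes_file)) barcodes_file <- file.path(dir, "barcodes.tsv")
  if (!file.exists(genes_file)) stop("gene sidecar not found: ", genes_file)
  if (!file.exists(barcodes_file)) stop("barcode sidecar not found: ", barcodes_file)
  genes <- utils::read.table(genes_file, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  cols <- utils::read.table(barcodes_file, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)[[1L]]
  if (length(genes) != nrow(m))
    stop("genes.tsv has ", length(genes), " entries but matrix has ", nrow(m), " rows")
  if (length(cols) != ncol(m))
    stop("barcodes.tsv has ", length(cols), " entries but matrix has ", ncol(m), " columns")
  dimnames(m) <- list(genes, cols)
  list(counts = m, gene_ids = genes, column_ids = cols)
}

read_dense_csv <- function(path) {
  # data.frame subsetting deduplicates names, so take column ids from the
  # raw header to catch duplicates faithfully
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  col_ids <- header[-1L]
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("malformed dense CSV ", path, ": need a gene-id column plus data columns")
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("malformed dense CSV ", path, ": non-numeric entries")
  dimnames(m) <- list(genes, col_ids)
  list(counts = m, gene_ids = genes, column_ids = col_ids)
}

read_counts_h5 <- function(path, matrix_name = "matrix", genes_name = "genes",
                           barcodes_name = "barcodes") {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("HDF5 input requires the 'rhdf5' package")
  m <- rhdf5::h5read(path, matrix_name)
  genes <- as.character(rhdf5::h5read(path, genes_name))
  cols <- as.character(rhdf5::h5read(path, barcodes_name))
  m <- as.matrix(m)
  dimnames(m) <- list(genes, cols)
  list(counts = m, gene_ids = genes, column_ids = cols)
}

#' Write a count matrix to the package's HDF5 layout
#'
#' Layout: datasets `/matrix` (dense genes x columns), `/genes`, `/barcodes`.
#' @param counts matrix with dimnames.
#' @param path output file (overwritten).
#' @export
write_counts_h5 <- function(counts, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("HDF5 output requires the 'rhdf5' package")
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(unname(as.matrix(counts)), path, "matrix")
  rhdf5::h5write(rownames(counts), path, "genes")
  rhdf5::h5write(colnames(counts), path, "barcodes")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Write a count matrix as an MTX triplet bundle
#'
#' @param counts matrix with dimnames.
#' @param dir output directory (created); writes `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`.
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a spot coordinate table
#'
#' CSV/TSV with header columns `spot_id`, `x`, `y`.
#' @param path file path.
#' @return spots x 2 numeric matrix with spot ids as row names.
#' @export
read_coords <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  need <- c("spot_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("coordinate table must have header columns spot_id, x, y")
  m <- as.matrix(df[, c("x", "y")])
  rownames(m) <- as.character(df$spot_id)
  m
}

collapse_duplicate_genes <- function(m) {
  g <- rownames(m)
  if (!anyDuplicated(g)) return(m)
  out <- rowsum(m, group = g, reorder = FALSE)
  # rowsum orders groups by first appearance when reorder = FALSE
  out[match(unique(g), rownames(out)), , drop = FALSE]
}

#' Harmonize reference and spatial gene spaces
#'
#' Builds the shared, ordered gene space the network is trained and applied
#' on: the intersection of reference and spatial gene ids, minus reference
#' genes with fewer than `min_counts` total counts or expressed in fewer than
#' `min_cells_frac` of reference cells, in lexicographic order. The result
#' also fixes the count normalization applied identically to simulated
#' mixtures and spots (counts-per-`scale`, then log1p).
#'
#' @param ref a [reference_dataset()].
#' @param st a [spatial_dataset()].
#' @param min_counts drop genes with total reference counts below this.
#' @param min_cells_frac drop genes expressed (count > 0) in less than this
#'   fraction of reference cells.
#' @param scale counts-per-X normalization target (default 10,000).
#' @param log_transform apply `log(1 + x)` after scaling (default TRUE).
#' @param exclude_regex optional regex; matching gene ids (e.g. mitochondrial
#'   `"^mt-"`) are removed. Off by default.
#' @return object of class `normalization_spec`: list with `gene_space`,
#'   `scale`, `log_transform`.
#' @export
harmonize_gene_space <- function(ref, st, min_counts = 0L, min_cells_frac = 0,
                                 scale = 1e4, log_transform = TRUE,
                                 exclude_regex = NULL) {
  stopifnot(min_counts >= 0, min_cells_frac >= 0, min_cells_frac <= 1, scale > 0)
  shared <- intersect(ref$gene_ids, st$gene_ids)
  if (length(shared) == 0L)
    stop("reference and spatial datasets share no genes (reference e.g. ",
         paste(utils::head(ref$gene_ids, 3), collapse = ","), "; spatial e.g. ",
         paste(utils::head(st$gene_ids, 3), collapse = ","), ")")
  sub <- ref$counts[shared, , drop = FALSE]
  keep <- rowSums(sub) >= min_counts &
    rowMeans(sub > 0) >= min_cells_frac
  gene_space <- sort(shared[keep])
  if (!is.null(exclude_regex))
    gene_space <- gene_space[!grepl(exclude_regex, gene_space)]
  if (length(gene_space) == 0L)
    stop("no genes survive filtering; relax min_counts/min_cells_frac")
  structure(list(gene_space = gene_space, scale = scale,
                 log_transform = log_transform),
            class = "normalization_spec")
}

#' @export
print.normalization_spec <- function(x, ...) {
  cat(sprintf("normalization_spec: %d genes, counts-per-%g%s\n",
              length(x$gene_space), x$scale,
              if (x$log_transform) " + log1p" else ""))
  invisible(x)
}

#' Normalize a count matrix on a fixed gene space
#'
#' Reindexes rows to `spec$gene_space` (by row name; genes absent from the
#' input are zero-filled), scales every column to sum `spec$scale` (all-zero
#' columns stay zero), and applies `log(1 + x)` when `spec$log_transform`.
#'
#' @param counts gene x column matrix. If it has row names they are used for
#'   reindexing; otherwise rows must already be ordered as the gene space.
#' @param spec a `normalization_spec` from [harmonize_gene_space()].
#' @param warn_missing warn when genes of the space are absent from the input.
#' @return numeric matrix `length(gene_space)` x `ncol(counts)`.
#' @export
normalize_counts <- function(counts, spec, warn_missing = TRUE) {
  counts <- as.matrix(counts)
  gs <- spec$gene_space
  if (!is.null(rownames(counts))) {
    idx <- match(gs, rownames(counts))
    miss <- sum(is.na(idx))
    if (miss == length(gs)) stop("input shares no genes with the gene space")
    if (miss > 0 && warn_missing)
      warning(miss, " gene(s) of the model gene space absent from input; zero-filled")
    out <- matrix(0, length(gs), ncol(counts),
                  dimnames = list(gs, colnames(counts)))
    out[!is.na(idx), ] <- counts[idx[!is.na(idx)], , drop = FALSE]
    counts <- out
  } else if (nrow(counts) != length(gs)) {
    stop("unnamed input must already have one row per gene-space gene")
  } else {
    rownames(counts) <- gs
  }
  tot <- colSums(counts)
  sf <- ifelse(tot > 0, spec$scale / tot, 0)
  norm <- sweep(counts, 2L, sf, "*")
  if (isTRUE(spec$log_transform)) norm <- log1p(norm)
  norm
}
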
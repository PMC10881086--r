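# Gradient-based interpretation: which genes drive the predicted proportion
# of a cell type.

# Gradient of output[, target] w.r.t. the input rows, for all profiles at
# once. X is n x genes (already normalized).
input_gradient <- function(model, X, target_idx) {
  fwd <- nn_forward(model$params, X)
  P <- fwd$H[[length(model$params$W) + 1L]]
  # d p_t / d z_j = p_t (delta_tj - p_j), row-wise
  dZ <- -P * P[, target_idx]
  dZ[, target_idx] <- dZ[, target_idx] + P[, target_idx]
  nn_backward(model$params, fwd, dZ, want_input_grad = TRUE)$input
}

#' Gene attribution scores for one cell type
#'
#' Attributes the predicted proportion of `target_type` to input genes,
#' averaged over the supplied profiles. `"gradient_x_input"` (default) is the
#' mean of (d output\[target\] / d input_g) * input_g; `"integrated_gradients"`
#' accumulates the gradient along the straight path from the all-zero
#' baseline to each profile (trapezoidal Riemann sum with `n_steps` steps),
#' multiplied by the input. Integrated gradients satisfy the completeness
#' identity: per profile, attributions sum to
#' `output(profile) - output(baseline)` up to the Riemann error, which
#' shrinks as `n_steps` grows.
#'
#' @param model a `deconv_model`.
#' @param profiles genes x profiles matrix of *normalized* expression on the
#'   model gene space (e.g. `normalize_counts(counts, model$norm_spec)`).
#' @param target_type a label from `model$cell_type_order`.
#' @param method `"gradient_x_input"` or `"integrated_gradients"`.
#' @param n_steps Riemann steps for integrated gradients (default 50).
#' @return named numeric vector of scores over `model$gene_space`.
#' @export
gene_scores <- function(model, profiles, target_type,
                        method = c("gradient_x_input", "integrated_gradients"),
                        n_steps = 50L) {
  method <- match.arg(method)
  t_idx <- match(target_type, model$cell_type_order)
  if (is.na(t_idx))
    stop("unknown cell type '", target_type, "'; valid: ",
         paste(model$cell_type_order, collapse = ", "))
  X <- t(as.matrix(profiles))
  if (ncol(X) != length(model$gene_space))
    stop("profiles must be on the model gene space (", length(model$gene_space),
         " genes)")
  if (method == "gradient_x_input") {
    G <- input_gradient(model, X, t_idx)
    scores <- colMeans(G * X)
  } else {
    # trapezoidal rule over alpha in [0, 1]
    alphas <- seq(0, 1, length.out = n_steps + 1L)
    w <- rep(1, n_steps + 1L); w[c(1L, n_steps + 1L)] <- 0.5
    w <- w / n_steps
    acc <- matrix(0, nrow(X), ncol(X))
    for (s in seq_along(alphas))
      acc <- acc + w[s] * input_gradient(model, alphas[s] * X, t_idx)
    scores <- colMeans(acc * X)
  }
  names(scores) <- model$gene_space
  scores
}

#' Gene-score table across all cell types
#'
#' Runs [gene_scores()] for every cell type of the model and assembles a
#' genes x types score matrix. By default the profiles each type is scored on
#' are simulated pure profiles of that type (so the attribution answers
#' "which genes drive this type's detection"); alternatively a fixed profile
#' matrix can be supplied and shared across types.
#'
#' @param model a `deconv_model`.
#' @param ref a [reference_dataset()] used to simulate pure profiles
#'   (required unless `profiles` is given).
#' @param profiles optional genes x profiles normalized matrix used for every
#'   type (e.g. real spots).
#' @param method,n_steps see [gene_scores()].
#' @param n_pure pure profiles simulated per type (default 20).
#' @param n_cells_per_mixture cells per simulated pure profile (default 50).
#' @param seed RNG seed for the pure-profile simulation.
#' @return object of class `gene_score_table`: list with `scores`
#'   (genes x types), `method`, `n_steps`, `reference_profiles` (provenance
#'   string).
#' @export
gene_score_table <- function(model, ref = NULL, profiles = NULL,
                             method = "gradient_x_input", n_steps = 50L,
                             n_pure = 20L, n_cells_per_mixture = 50L,
                             seed = 1L) {
  types <- model$cell_type_order
  S <- matrix(NA_real_, length(model$gene_space), length(types),
              dimnames = list(model$gene_space, types))
  for (k in seq_along(types)) {
    if (is.null(profiles)) {
      if (is.null(ref)) stop("need either a reference dataset or profiles")
      P <- matrix(0, n_pure, length(types), dimnames = list(NULL, types))
      P[, k] <- 1
      mix <- synthesize_mixtures(ref, ref$cell_ids, P,
                                 n_cells_per_mixture = n_cells_per_mixture,
                                 seed = seed + k, partition = "train")
      prof_k <- normalize_counts(mix$profiles, model$norm_spec,
                                 warn_missing = FALSE)
    } else {
      prof_k <- as.matrix(profiles)
    }
    S[, k] <- gene_scores(model, prof_k, types[k], method = method,
                          n_steps = n_steps)
  }
  structure(list(scores = S, method = method, n_steps = as.integer(n_steps),
                 reference_profiles = if (is.null(profiles))
                   sprintf("%d simulated pure profiles per type", n_pure)
                 else "user-supplied profiles"),
            class = "gene_score_table")
}

#' @export
print.gene_score_table <- function(x, ...) {
  cat(sprintf("gene_score_table: %d genes x %d types (%s, on %s)\n",
              nrow(x$scores), ncol(x$scores), x$method, x$reference_profiles))
  invisible(x)
}

#' Top-ranked genes for a cell type
#'
#' Genes sorted by descending attribution score; ties broken by gene id.
#' `n` larger than the gene count returns the full ranking.
#'
#' @param table a `gene_score_table` (or a named score vector).
#' @param type cell-type label (ignored for a plain vector).
#' @param n number of genes (default 25).
#' @return character vector of gene ids.
#' @export
top_genes <- function(table, type = NULL, n = 25L) {
  stopifnot(n >= 1L)
  s <- if (inherits(table, "gene_score_table")) {
    if (is.null(type)) stop("specify a cell type")
    if (!type %in% colnames(table$scores))
      stop("unknown cell type '", type, "'; valid: ",
           paste(colnames(table$scores), collapse = ", "))
    stats::setNames(table$scores[, type], rownames(table$scores))
  } else table
  ord <- order(-s, names(s))
  names(s)[ord][seq_len(min(n, length(s)))]
}

#' Write a gene-score table to CSV (+ metadata JSON sidecar)
#' @param table a `gene_score_table`.
#' @param path CSV output path; the sidecar gets a `.json` extension.
#' @export
write_gene_scores <- function(table, path) {
  utils::write.csv(data.frame(gene = rownames(table$scores), table$scores,
                              check.names = FALSE),
                   path, row.names = FALSE)
  jsonlite::write_json(list(method = table$method, n_steps = table$n_steps,
                            reference_profiles = table$reference_profiles),
                       sub("\\.csv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
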
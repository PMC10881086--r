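# End-to-end orchestration: reference + spatial data in, proportion tables,
# evaluation report, trained model and diagnostics out.

#' Default pipeline configuration
#'
#' Nested list of every tunable of the pipeline; any element can be
#' overridden through `...` of [run_deconvolute()]. The effective
#' configuration of a run is written next to its outputs.
#'
#' @return nested list with elements `filter` (min_counts, min_cells_frac,
#'   exclude_regex), `sampler` (n_train, n_test, n_cells_per_mixture, alpha,
#'   frac_pure, frac_sparse, test_cell_frac), `model` (see
#'   [deconv_config()]), `spatial` (enabled, k, lambda_max, similarity,
#'   distance_scaling), and `seed`.
#' @export
default_run_config <- function() {
  list(filter = list(min_counts = 1L, min_cells_frac = 0,
                     exclude_regex = NULL),
       sampler = list(n_train = 2000L, n_test = 500L,
                      n_cells_per_mixture = 50L, alpha = 1,
                      frac_pure = 0.1, frac_sparse = 0.3,
                      test_cell_frac = 0.2),
       model = as.list(unclass(deconv_config())),
       spatial = list(enabled = FALSE, k = 6L, lambda_max = 0.5,
                      similarity = "cosine", distance_scaling = "minmax"),
       seed = 1L)
}

modify_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- modify_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full deconvolution pipeline
#'
#' Harmonize gene spaces, split reference cells, simulate training and test
#' mixtures, train the network, evaluate it on held-out mixtures, predict
#' spot compositions and (optionally) regularize them spatially. All outputs
#' (proportion CSVs, evaluation report, saved model, diagnostics, effective
#' config, log) are written to `out_dir`, making the run self-describing.
#'
#' @param ref a [reference_dataset()].
#' @param st a [spatial_dataset()].
#' @param out_dir output directory (created).
#' @param config nested configuration, see [default_run_config()].
#' @param ... convenience overrides merged into `config`, e.g.
#'   `spatial = list(enabled = TRUE)` or `seed = 7`.
#' @return invisibly, a list with `model`, `evaluation`, `result`
#'   (a `spot_deconv`), and `config`.
#' @export
run_deconvolute <- function(ref, st, out_dir, config = default_run_config(),
                            ...) {
  config <- modify_config(config, list(...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(logcon), add = TRUE)
  stage <- "setup"
  tryCatch({
    stage <- "harmonize"
    spec <- harmonize_gene_space(ref, st,
                                 min_counts = config$filter$min_counts,
                                 min_cells_frac = config$filter$min_cells_frac,
                                 exclude_regex = config$filter$exclude_regex)
    log_line(logcon, "harmonize: ", length(spec$gene_space), " shared genes")

    stage <- "simulate"
    sp <- config$sampler
    split <- split_cells(ref, test_frac = sp$test_cell_frac,
                         seed = config$seed)
    types <- sort(unique(ref$cell_types))
    p_train <- sample_proportions(sp$n_train, length(types), alpha = sp$alpha,
                                  frac_pure = sp$frac_pure,
                                  frac_sparse = sp$frac_sparse,
                                  seed = config$seed + 1L)
    p_test <- sample_proportions(sp$n_test, length(types), alpha = sp$alpha,
                                 frac_pure = sp$frac_pure,
                                 frac_sparse = sp$frac_sparse,
                                 seed = config$seed + 2L)
    colnames(p_train) <- colnames(p_test) <- types
    train_set <- synthesize_mixtures(ref, split$train, p_train,
                                     n_cells_per_mixture = sp$n_cells_per_mixture,
                                     seed = config$seed + 3L, partition = "train")
    test_set <- synthesize_mixtures(ref, split$test, p_test,
                                    n_cells_per_mixture = sp$n_cells_per_mixture,
                                    seed = config$seed + 4L, partition = "test")
    log_line(logcon, "simulate: ", sp$n_train, " train + ", sp$n_test,
             " test mixtures")

    stage <- "train"
    mcfg <- do.call(deconv_config, config$model)
    mcfg$seed <- as.integer(config$seed + 5L)
    model <- train_deconv(train_set, spec, config = mcfg)
    log_line(logcon, "train: best val loss ",
             format(min(model$history$val_loss), digits = 5), " at epoch ",
             model$best_epoch)

    stage <- "evaluate"
    ev <- evaluate_deconv(model, test_set)
    log_line(logcon, sprintf("evaluate: mean PCC %.3f, mean CCC %.3f",
                             ev$overall$pcc, ev$overall$ccc))

    stage <- "predict"
    res <- deconvolute(model, st, spatial = isTRUE(config$spatial$enabled),
                       k = config$spatial$k,
                       lambda_max = config$spatial$lambda_max,
                       similarity = config$spatial$similarity,
                       distance_scaling = config$spatial$distance_scaling)
    log_line(logcon, "predict: ", length(st$spot_ids), " spots",
             if (isTRUE(config$spatial$enabled)) " (spatially regularized)")

    stage <- "write"
    write_props <- function(m, file)
      utils::write.csv(data.frame(spot_id = st$spot_ids, m,
                                  check.names = FALSE),
                       file.path(out_dir, file), row.names = FALSE)
    write_props(res$intrinsic_props, "proportions_intrinsic.csv")
    if (!is.null(res$regularized_props)) {
      write_props(res$extrinsic_props, "proportions_extrinsic.csv")
      write_props(res$regularized_props, "proportions_regularized.csv")
      utils::write.csv(data.frame(spot_id = st$spot_ids,
                                  x = st$coords[, 1], y = st$coords[, 2],
                                  lambda = res$lambda_per_spot,
                                  distance = res$intrinsic_extrinsic_dist),
                       file.path(out_dir, "diagnostics.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(ev$per_type, file.path(out_dir, "evaluation_per_type.csv"),
                     row.names = FALSE)
    jsonlite::write_json(ev$overall, file.path(out_dir, "evaluation_overall.json"),
                         auto_unbox = TRUE, digits = NA)
    save_deconv_model(model, file.path(out_dir, "model"))
    jsonlite::write_json(config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    log_line(logcon, "done")
    invisible(list(model = model, evaluation = ev, result = res,
                   config = config))
  }, error = function(e) {
    log_line(logcon, "FAILED at stage '", stage, "': ", conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Compute and write gene-attribution scores for a saved model
#'
#' @param model_dir directory written by [save_deconv_model()] (or a
#'   `deconv_model` object).
#' @param ref a [reference_dataset()] to simulate pure profiles from.
#' @param out_dir output directory.
#' @param methods attribution methods to run.
#' @param n_steps integrated-gradients steps.
#' @param seed RNG seed.
#' @return invisibly, the list of `gene_score_table`s.
#' @export
run_interpret <- function(model_dir, ref, out_dir,
                          methods = "gradient_x_input", n_steps = 50L,
                          seed = 1L) {
  model <- if (inherits(model_dir, "deconv_model")) model_dir
           else load_deconv_model(model_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- lapply(methods, function(m) {
    tab <- gene_score_table(model, ref = ref, method = m, n_steps = n_steps,
                            seed = seed)
    write_gene_scores(tab, file.path(out_dir, paste0("gene_scores_", m, ".csv")))
    tab
  })
  names(tables) <- methods
  invisible(tables)
}
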
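# The proportion-regression network: a fully connected net with a softmax
# head mapping a normalized expression vector to a point on the cell-type
# simplex. Forward pass, backpropagation, Adam, inverted dropout and early
# stopping are implemented here on top of base matrix algebra; all
# randomness (weight init, shuffling, dropout) flows through R's RNG, so
# training is exactly reproducible given the seed.

#' Model hyperparameters
#'
#' @param hidden_sizes widths of the hidden layers (default `c(200, 200)`).
#' @param activation hidden activation: `"relu"` or `"prelu"` (PReLU carries
#'   one learnable slope per hidden layer, initialized at 0.25).
#' @param dropout inverted-dropout rate on hidden activations, in \[0, 1).
#' @param loss training loss: `"kl"` (Kullback-Leibler divergence of the
#'   predicted from the true composition, the default), `"mse"`, or `"mae"`.
#' @param batch_size minibatch size (default 64).
#' @param max_epochs epoch budget (default 60).
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (default 10); the best-validation weights are restored.
#' @param learning_rate Adam step size (default 1e-3).
#' @param weight_decay decoupled L2 weight decay applied to weight matrices
#'   (not biases) at every update, as a per-step shrink of
#'   `learning_rate * weight_decay`. Shrinks weights on uninformative genes
#'   that the loss gradient never touches, which improves calibration and
#'   concentrates gradient attribution on genuinely informative inputs.
#'   Default 2.
#' @param seed RNG seed controlling weight init, shuffling and dropout.
#' @return list of class `deconv_model_config`.
#' @export
deconv_config <- function(hidden_sizes = c(200L, 200L),
                          activation = c("relu", "prelu"),
                          dropout = 0.25,
                          loss = c("kl", "mse", "mae"),
                          batch_size = 64L, max_epochs = 60L,
                          early_stop_patience = 10L,
                          learning_rate = 1e-3, weight_decay = 2,
                          seed = 1L) {
  activation <- match.arg(activation)
  loss <- match.arg(loss)
  stopifnot(length(hidden_sizes) >= 1L, all(hidden_sizes > 0),
            dropout >= 0, dropout < 1, batch_size >= 1, max_epochs >= 1,
            learning_rate > 0, weight_decay >= 0)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 activation = activation, dropout = dropout, loss = loss,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "deconv_model_config")
}

init_params <- function(n_in, hidden, n_out, activation) {
  dims <- c(n_in, hidden, n_out)
  L <- length(dims) - 1L
  W <- b <- vector("list", L)
  for (l in seq_len(L)) {
    # He initialization for rectifier nets
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                  sd = sqrt(2 / dims[l])),
                     dims[l], dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  alpha <- if (activation == "prelu") rep(0.25, L - 1L) else NULL
  list(W = W, b = b, alpha = alpha)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Forward pass. X is n x genes. Returns activations for backprop.
# During training, `masks` holds pre-drawn inverted-dropout masks.
nn_forward <- function(params, X, masks = NULL) {
  L <- length(params$W)
  H <- vector("list", L + 1L)  # H[[1]] = input, H[[l+1]] = layer l output
  Zs <- vector("list", L)
  H[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- H[[l]] %*% params$W[[l]]
    Z <- sweep(Z, 2L, params$b[[l]], "+")
    Zs[[l]] <- Z
    if (l < L) {
      A <- if (is.null(params$alpha)) pmax(Z, 0)
           else ifelse(Z > 0, Z, params$alpha[l] * Z)
      if (!is.null(masks)) A <- A * masks[[l]]
      H[[l + 1L]] <- A
    } else {
      H[[l + 1L]] <- softmax_rows(Z)
    }
  }
  list(H = H, Z = Zs)
}

nn_loss <- function(P, Y, loss) {
  eps <- 1e-12
  switch(loss,
    kl  = mean(rowSums(Y * (log(Y + eps) - log(P + eps)))),
    mse = mean((P - Y)^2),
    mae = mean(abs(P - Y)))
}

# Gradient of the mean loss w.r.t. the pre-softmax logits (n x K).
loss_logit_grad <- function(P, Y, loss) {
  n <- nrow(P)
  if (loss == "kl") return((P - Y) / n)
  g <- if (loss == "mse") 2 * (P - Y) / (n * ncol(P))
       else sign(P - Y) / (n * ncol(P))
  P * (g - rowSums(g * P))  # softmax Jacobian applied row-wise
}

# Backpropagation. Returns gradients of W, b, alpha, and (optionally) the
# gradient w.r.t. the input rows, given dZ at the output logits.
nn_backward <- function(params, fwd, dZ, masks = NULL, want_input_grad = FALSE) {
  L <- length(params$W)
  gW <- gb <- vector("list", L)
  galpha <- if (!is.null(params$alpha)) numeric(L - 1L) else NULL
  delta <- dZ
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fwd$H[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L || want_input_grad) {
      dA <- delta %*% t(params$W[[l]])
      if (l > 1L) {
        Zprev <- fwd$Z[[l - 1L]]
        if (!is.null(masks)) dA <- dA * masks[[l - 1L]]
        if (is.null(params$alpha)) {
          delta <- dA * (Zprev > 0)
        } else {
          galpha[l - 1L] <- sum(dA * Zprev * (Zprev <= 0))
          delta <- dA * ifelse(Zprev > 0, 1, params$alpha[l - 1L])
        }
      } else {
        return(list(W = gW, b = gb, alpha = galpha, input = dA))
      }
    }
  }
  list(W = gW, b = gb, alpha = galpha, input = NULL)
}

adam_init <- function(params) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(params$W), vW = zero_like(params$W),
       mb = zero_like(params$b), vb = zero_like(params$b),
       ma = if (!is.null(params$alpha)) params$alpha * 0 else NULL,
       va = if (!is.null(params$alpha)) params$alpha * 0 else NULL,
       t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v, decay = 0) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / c1) / (sqrt(v / c2) + eps) - lr * decay * p
    list(p = p, m = m, v = v)
  }
  for (l in seq_along(params$W)) {
    u <- upd(params$W[[l]], grads$W[[l]], state$mW[[l]], state$vW[[l]],
             decay = weight_decay)  # decoupled decay on weights only
    params$W[[l]] <- u$p; state$mW[[l]] <- u$m; state$vW[[l]] <- u$v
    u <- upd(params$b[[l]], grads$b[[l]], state$mb[[l]], state$vb[[l]])
    params$b[[l]] <- u$p; state$mb[[l]] <- u$m; state$vb[[l]] <- u$v
  }
  if (!is.null(params$alpha) && !is.null(grads$alpha)) {
    u <- upd(params$alpha, grads$alpha, state$ma, state$va)
    params$alpha <- u$p; state$ma <- u$m; state$va <- u$v
  }
  list(params = params, state = state)
}

#' Train the deconvolution network on simulated mixtures
#'
#' Fits a fully connected network with softmax head to predict cell-type
#' proportions from normalized mixed transcriptional profiles. A validation
#' slice is carved from the training profiles for early stopping; the weights
#' achieving the best validation loss are kept.
#'
#' @param train_set a `mixture_set` from [synthesize_mixtures()].
#' @param norm_spec the `normalization_spec` shared between simulated
#'   mixtures and spots (from [harmonize_gene_space()]).
#' @param val_fraction fraction of profiles held out for validation-based
#'   early stopping (default 0.1).
#' @param config a [deconv_config()].
#' @param verbose print per-epoch losses.
#' @return object of class `deconv_model`: trained parameters plus the
#'   input/output contract (`gene_space`, `cell_type_order`, `norm_spec`,
#'   `config`) and a per-epoch `history` data frame (columns `epoch`,
#'   `train_loss`, `val_loss`).
#' @seealso [predict.deconv_model()], [evaluate_deconv()], [gene_scores()]
#' @export
train_deconv <- function(train_set, norm_spec, val_fraction = 0.1,
                         config = deconv_config(), verbose = FALSE) {
  stopifnot(inherits(train_set, "mixture_set"),
            val_fraction > 0, val_fraction < 1)
  types <- train_set$cell_type_order
  if (length(types) < 2L) stop("need at least 2 cell types")
  X <- t(normalize_counts(train_set$profiles, norm_spec))
  Y <- as.matrix(train_set$proportions[, types, drop = FALSE])
  n <- nrow(X)

  set.seed(config$seed)
  n_val <- max(1L, round(val_fraction * n))
  val_idx <- sample.int(n, n_val)
  Xv <- X[val_idx, , drop = FALSE]; Yv <- Y[val_idx, , drop = FALSE]
  Xt <- X[-val_idx, , drop = FALSE]; Yt <- Y[-val_idx, , drop = FALSE]

  params <- init_params(ncol(X), config$hidden_sizes, length(types),
                        config$activation)
  state <- adam_init(params)
  keep <- 1 - config$dropout
  n_train <- nrow(Xt)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, params = params, epoch = 0L)
  stall <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n_train)
    batch_losses <- numeric(0)
    for (start in seq(1L, n_train, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n_train)]
      Xb <- Xt[idx, , drop = FALSE]; Yb <- Yt[idx, , drop = FALSE]
      masks <- NULL
      if (config$dropout > 0) {
        masks <- lapply(config$hidden_sizes, function(h)
          matrix((stats::runif(length(idx) * h) < keep) / keep,
                 length(idx), h))
      }
      fwd <- nn_forward(params, Xb, masks)
      P <- fwd$H[[length(fwd$H)]]
      l_b <- nn_loss(P, Yb, config$loss)
      if (!is.finite(l_b))
        stop("training loss became non-finite; check the input scale ",
             "(counts must be normalized) or lower the learning rate")
      batch_losses <- c(batch_losses, l_b)
      grads <- nn_backward(params, fwd, loss_logit_grad(P, Yb, config$loss),
                           masks)
      st <- adam_step(params, grads, state, config$learning_rate,
                      config$weight_decay)
      params <- st$params; state <- st$state
    }
    Pv <- nn_forward(params, Xv)$H[[length(config$hidden_sizes) + 2L]]
    val_loss <- nn_loss(Pv, Yv, config$loss)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(batch_losses),
                                         val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      mean(batch_losses), val_loss))
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$early_stop_patience) break
    }
  }

  structure(list(params = best$params,
                 gene_space = norm_spec$gene_space,
                 cell_type_order = types,
                 norm_spec = norm_spec,
                 config = config,
                 history = history,
                 best_epoch = best$epoch),
            class = "deconv_model")
}

#' Predict cell-type proportions for new profiles
#'
#' Input profiles are reindexed to the model's gene space (genes missing from
#' the input are zero-filled, with a warning when the overlap drops below
#' 90%), normalized with the model's stored normalization, and pushed through
#' the network. Every output row lies on the simplex.
#'
#' @param object a `deconv_model`.
#' @param newdata genes x profiles count matrix with gene row names, a
#'   [spatial_dataset()], or a `mixture_set`.
#' @param ... unused.
#' @return profiles x types proportion matrix (rows sum to 1).
#' @export
predict.deconv_model <- function(object, newdata, ...) {
  counts <- if (inherits(newdata, "spatial_dataset")) newdata$counts
            else if (inherits(newdata, "mixture_set")) newdata$profiles
            else as.matrix(newdata)
  if (!is.null(rownames(counts))) {
    overlap <- mean(object$gene_space %in% rownames(counts))
    if (overlap == 0) stop("input shares no genes with the model gene space")
    if (overlap < 0.9)
      warning(sprintf("only %.0f%% of the model gene space present in input; missing genes zero-filled",
                      100 * overlap))
  }
  X <- t(normalize_counts(counts, object$norm_spec, warn_missing = FALSE))
  P <- nn_forward(object$params, X)$H[[length(object$params$W) + 1L]]
  dimnames(P) <- list(colnames(counts), object$cell_type_order)
  P
}

#' @export
print.deconv_model <- function(x, ...) {
  cat(sprintf("deconv_model: %d genes -> [%s] -> %d cell types (softmax)\n",
              length(x$gene_space),
              paste(x$config$hidden_sizes, collapse = ", "),
              length(x$cell_type_order)))
  cat(sprintf("  loss %s, trained %d epoch(s), best validation %.5f at epoch %d\n",
              x$config$loss, nrow(x$history),
              min(x$history$val_loss), x$best_epoch))
  invisible(x)
}

#' @export
summary.deconv_model <- function(object, ...) {
  n_par <- sum(vapply(object$params$W, length, 1L)) +
    sum(vapply(object$params$b, length, 1L)) +
    length(object$params$alpha)
  cat("Cell-type deconvolution network\n")
  print(object)
  cat(sprintf("  %d trainable parameters; activation %s, dropout %.2f\n",
              n_par, object$config$activation, object$config$dropout))
  cat("  cell types:", paste(object$cell_type_order, collapse = ", "), "\n")
  invisible(object)
}

#' Training-history curves
#' @param x a `deconv_model`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.deconv_model <- function(x, ...) {
  graphics::matplot(x$history$epoch,
                    cbind(x$history$train_loss, x$history$val_loss),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = paste(x$config$loss, "loss"), ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}

#' @export
coef.deconv_model <- function(object, ...) object$params

#' Evaluate a trained model on held-out mixtures
#'
#' Per cell type, predicted vs. true proportions across profiles are scored
#' with Pearson correlation, Lin's concordance correlation and RMSE; overall
#' scores are the per-type means plus the mean per-profile Jensen-Shannon
#' divergence between predicted and true compositions.
#'
#' @param model a `deconv_model`.
#' @param test_set a `mixture_set` built from cells disjoint from training.
#' @return object of class `deconv_eval`: list with `per_type` (data frame),
#'   `overall` (named list: pcc, ccc, rmse, jsd), `n_test_profiles`.
#' @export
evaluate_deconv <- function(model, test_set) {
  pred <- predict(model, test_set)
  truth <- as.matrix(test_set$proportions[, model$cell_type_order, drop = FALSE])
  per_type <- data.frame(
    cell_type = model$cell_type_order,
    pcc = vapply(seq_len(ncol(truth)), function(k) pcc(truth[, k], pred[, k]), 1),
    ccc = vapply(seq_len(ncol(truth)), function(k) ccc(truth[, k], pred[, k]), 1),
    rmse = vapply(seq_len(ncol(truth)), function(k) rmse(truth[, k], pred[, k]), 1),
    row.names = NULL)
  jsd_i <- vapply(seq_len(nrow(truth)), function(i) jsd(truth[i, ], pred[i, ]), 1)
  structure(list(per_type = per_type,
                 overall = list(pcc = mean(per_type$pcc),
                                ccc = mean(per_type$ccc),
                                rmse = mean(per_type$rmse),
                                jsd = mean(jsd_i)),
                 n_test_profiles = nrow(truth)),
            class = "deconv_eval")
}

#' @export
print.deconv_eval <- function(x, ...) {
  cat(sprintf("deconv_eval on %d held-out profiles\n", x$n_test_profiles))
  print(x$per_type, digits = 3)
  cat(sprintf("overall: mean PCC %.3f, mean CCC %.3f, mean RMSE %.4f, mean JSD %.4f\n",
              x$overall$pcc, x$overall$ccc, x$overall$rmse, x$overall$jsd))
  invisible(x)
}

#' Save / load a trained model
#'
#' The model directory holds `weights.rds` (parameters), `contract.json`
#' (gene space, cell-type order, normalization, hyperparameters) and
#' `history.csv`.
#' @param model a `deconv_model`.
#' @param dir directory to create.
#' @export
save_deconv_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$params, file.path(dir, "weights.rds"))
  contract <- list(gene_space = model$gene_space,
                   cell_type_order = model$cell_type_order,
                   norm_spec = list(gene_space = model$norm_spec$gene_space,
                                    scale = model$norm_spec$scale,
                                    log_transform = model$norm_spec$log_transform),
                   config = unclass(model$config),
                   best_epoch = model$best_epoch)
  jsonlite::write_json(contract, file.path(dir, "contract.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(model$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname save_deconv_model
#' @param dir model directory written by [save_deconv_model()].
#' @export
load_deconv_model <- function(dir) {
  cpath <- file.path(dir, "contract.json")
  if (!file.exists(cpath)) stop("not a model directory (missing contract.json): ", dir)
  contract <- jsonlite::read_json(cpath, simplifyVector = TRUE)
  ns <- structure(list(gene_space = contract$norm_spec$gene_space,
                       scale = contract$norm_spec$scale,
                       log_transform = contract$norm_spec$log_transform),
                  class = "normalization_spec")
  cfg <- do.call(deconv_config, contract$config[
    setdiff(names(contract$config), character(0))])
  structure(list(params = readRDS(file.path(dir, "weights.rds")),
                 gene_space = contract$gene_space,
                 cell_type_order = contract$cell_type_order,
                 norm_spec = ns, config = cfg,
                 history = utils::read.csv(file.path(dir, "history.csv")),
                 best_epoch = contract$best_epoch),
            class = "deconv_model")
}
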
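# Shared synthetic fixtures and cached trained models. Training is the
# expensive step, so models are trained once per test run and reused.

.fixture_cache <- new.env(parent = emptyenv())

# 3-type separable reference with disjoint marker blocks
small_ref <- function() {
  if (is.null(.fixture_cache$ref))
    .fixture_cache$ref <- simulate_reference(
      n_genes = 150L, n_types = 3L, n_cells_per_type = 60L,
      markers_per_type = 15L, fold_change = 8, seed = 42L)
  .fixture_cache$ref
}

spec_for <- function(ref) {
  structure(list(gene_space = sort(ref$gene_ids), scale = 1e4,
                 log_transform = TRUE),
            class = "normalization_spec")
}

small_mixtures <- function(partition = "train") {
  key <- paste0("mix_", partition)
  if (is.null(.fixture_cache[[key]])) {
    ref <- small_ref()
    split <- split_cells(ref, test_frac = 0.25, seed = 7L)
    n <- if (partition == "train") 1500L else 150L
    P <- sample_proportions(n, 3L, seed = if (partition == "train") 8L else 9L)
    colnames(P) <- sort(unique(ref$cell_types))
    .fixture_cache[[key]] <- synthesize_mixtures(
      ref, split[[partition]], P, n_cells_per_mixture = 50L,
      seed = if (partition == "train") 10L else 11L, partition = partition)
  }
  .fixture_cache[[key]]
}

# cached trained model on the small separable fixture
small_model <- function(loss = "kl") {
  key <- paste0("model_", loss)
  if (is.null(.fixture_cache[[key]])) {
    cfg <- deconv_config(hidden_sizes = c(128L, 128L), loss = loss,
                         max_epochs = 40L, early_stop_patience = 8L,
                         seed = 13L)
    .fixture_cache[[key]] <- train_deconv(small_mixtures("train"),
                                          spec_for(small_ref()),
                                          config = cfg)
  }
  .fixture_cache[[key]]
}

# two-region spot lattice from the small reference
small_spatial <- function() {
  if (is.null(.fixture_cache$spatial))
    .fixture_cache$spatial <- simulate_spatial(small_ref(), grid = c(8L, 8L),
                                               seed = 21L)
  .fixture_cache$spatial
}

# tiny hand-built reference for exact-arithmetic tests
tiny_ref <- function() {
  counts <- matrix(c(5, 0, 1,
                     2, 3, 0,
                     0, 1, 4), nrow = 3, byrow = TRUE,
                   dimnames = list(c("gA", "gB", "gC"),
                                   c("c1", "c2", "c3")))
  reference_dataset(counts, c("A", "A", "B"))
}

# single-layer softmax toy model with known weights (3 genes, 2 types)
toy_linear_model <- function() {
  W <- matrix(c(1.0, -0.5,
                -0.3, 0.8,
                0.2, 0.1), nrow = 3, byrow = TRUE)
  b <- c(0.1, -0.2)
  structure(list(params = list(W = list(W), b = list(b), alpha = NULL),
                 gene_space = c("g1", "g2", "g3"),
                 cell_type_order = c("A", "B"),
                 norm_spec = structure(list(gene_space = c("g1", "g2", "g3"),
                                            scale = 1e4, log_transform = TRUE),
                                       class = "normalization_spec"),
                 config = deconv_config(hidden_sizes = 1L),
                 history = data.frame(), best_epoch = 0L),
            class = "deconv_model")
}
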
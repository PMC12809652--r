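# Shared fixtures, built lazily and cached for the session. Heavy fixtures
# (trained networks) are computed once and reused across test files.

fixture_env <- new.env(parent = emptyenv())

# Small fast generator configuration used throughout the unit tests.
tiny_config <- function(...) {
  defaults <- list(n_samples = 4, grid_shape = c(2, 2), n_replicates = 2,
                   native_step = 4, seed = 42)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# Light single-position configuration for conformal replication studies.
light_config <- function(n, seed, ...) {
  defaults <- list(n_samples = n, grid_shape = c(1, 1), n_replicates = 1,
                   native_step = 4, seed = seed)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

soc_labels <- function(dataset) {
  vapply(dataset$samples, function(s) s$true_soc, numeric(1))
}

# Small test backbone: quick to train, same structure as the default.
test_backbone <- function(dropout = 0.2) {
  backbone_config(conv_blocks = list(c(8, 7, 2), c(16, 5, 2)),
                  dense_blocks = list(c(64, dropout), c(32, dropout)))
}

# Heteroscedastic-recovery fixture: het_gaussian trained on the known-noise
# benchmark (n = 2000), evaluated on a fresh draw.
het_fixture <- function() {
  if (is.null(fixture_env$het)) {
    bm <- simulate_het_benchmark(2000, seed = 11)
    bb <- backbone_config(conv_blocks = list(c(8, 5, 2), c(16, 5, 2)),
                          dense_blocks = list(c(64, 0.1), c(32, 0.1)))
    model <- uq_train("het_gaussian", bm$x, bm$y, backbone = bb,
                      training = training_config(epochs = 200,
                                                 batch_size = 256,
                                                 learning_rate = 2e-3,
                                                 seed = 2, patience = 1e9))
    test <- simulate_het_benchmark(1000, seed = 99)
    fixture_env$het <- list(model = model, test = test,
                            preds = uq_predict(model, test$x))
  }
  fixture_env$het
}

# Conformalization-ablation fixture: all five UQ heads trained once on a
# desk-scale synthetic dataset (900 samples, single grid position, two
# replicates, 330-channel model grid).
ablation_fixture <- function() {
  if (is.null(fixture_env$ablation)) {
    ds <- generate_dataset(light_config(900, seed = 21, n_replicates = 2))
    pd <- preprocess_dataset(ds, preprocess_config(grid_step = 5))
    # each head hand-tuned separately (the usual practice) so that
    # accuracies are comparable across methods
    abl <- suppressWarnings(ablate_conformalization(
      pd$x, pd$y, methods = uq_methods(), calibration_size = 100,
      test_fraction = 1 / 3, backbone = test_backbone(),
      training = training_config(epochs = 80, batch_size = 64, seed = 5),
      method_config = list(n_mc_passes = 30, ensemble_size = 3),
      per_method = list(
        het_gaussian = list(
          training = training_config(epochs = 120, batch_size = 48, seed = 5),
          method_config = list(warmup_frac = 0.4)),
        quantile = list(
          training = training_config(epochs = 120, batch_size = 32, seed = 5))),
      n_cal_repeats = 5))
    # held-out test block mirrors ablate_conformalization's internal split
    idx <- serdsuq:::with_seed(serdsuq:::derive_seed(5, "ablate_split"),
                               sample.int(length(pd$y)))
    test_idx <- idx[seq_len(round(length(pd$y) / 3))]
    fixture_env$ablation <- list(abl = abl, pd = pd, test_idx = test_idx)
  }
  fixture_env$ablation
}
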
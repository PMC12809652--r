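# Small shared regression problem: 16-channel spectra, linear latent signal.
toy_problem <- function(n = 80, seed = 5, noise = 0.05, const = NULL) {
  set.seed(seed)
  x <- matrix(rnorm(n * 16), n)
  y <- if (is.null(const)) x[, 1] + 0.5 * x[, 2] + rnorm(n, 0, noise) else
    rep(const, n)
  list(x = x, y = y)
}

toy_backbone <- backbone_config(conv_blocks = list(c(4, 5, 2)),
                                dense_blocks = list(c(16, 0.1)))
toy_training <- function(seed = 1, epochs = 60) {
  training_config(epochs = epochs, batch_size = 16, seed = seed,
                  validation_fraction = 0)
}

test_that("config validation rejects malformed backbones and training settings", {
  expect_error(backbone_config(conv_blocks = list()), "conv_blocks")
  expect_error(backbone_config(dense_blocks = list(c(8, 1.2))), "dense_blocks")
  expect_error(training_config(epochs = 0), "epochs")
  expect_error(training_config(batch_size = -1), "batch_size")
  expect_error(uq_train("het_gaussian", matrix(1, 3, 4), 1:2), "shape mismatch")
})

test_that("every method learns a noiseless constant to MAE < 0.05", {
  d <- toy_problem(n = 60, const = 2.7)
  for (m in uq_methods()) {
    model <- suppressWarnings(
      uq_train(m, d$x, d$y, backbone = toy_backbone,
               training = toy_training(epochs = 40),
               method_config = list(n_mc_passes = 10, ensemble_size = 2)))
    p <- uq_predict(model, d$x)
    expect_lt(mean(abs(p$y_hat - d$y)), 0.05, label = paste(m, "MAE"))
    expect_true(all(p$sigma_hat >= 0), label = paste(m, "sigma sign"))
  }
})

test_that("training and prediction are deterministic under a fixed seed", {
  d <- toy_problem()
  for (m in c("het_gaussian", "mc_dropout", "bayes_backprop")) {
    m1 <- uq_train(m, d$x, d$y, backbone = toy_backbone,
                   training = toy_training(seed = 9, epochs = 15),
                   method_config = list(n_mc_passes = 8))
    m2 <- uq_train(m, d$x, d$y, backbone = toy_backbone,
                   training = toy_training(seed = 9, epochs = 15),
                   method_config = list(n_mc_passes = 8))
    expect_identical(uq_predict(m1, d$x), uq_predict(m2, d$x),
                     label = paste(m, "determinism"))
  }
})

test_that("monte-carlo predictions are independent of row order and batch composition", {
  d <- toy_problem()
  m <- uq_train("mc_dropout", d$x, d$y, backbone = toy_backbone,
                training = toy_training(epochs = 15),
                method_config = list(n_mc_passes = 12))
  full <- uq_predict(m, d$x)
  shuf <- sample(nrow(d$x))
  p_shuf <- uq_predict(m, d$x[shuf, ])
  expect_equal(p_shuf$y_hat, full$y_hat[shuf], tolerance = 1e-10)
  expect_equal(p_shuf$sigma_hat, full$sigma_hat[shuf], tolerance = 1e-10)
  sub <- uq_predict(m, d$x[3:7, ])
  expect_equal(sub$y_hat, full$y_hat[3:7], tolerance = 1e-10)
})

test_that("zero stochasticity collapses sigma to zero", {
  d <- toy_problem()
  bb_nodrop <- backbone_config(conv_blocks = list(c(4, 5, 2)),
                               dense_blocks = list(c(16, 0)))
  m <- uq_train("mc_dropout", d$x, d$y, backbone = bb_nodrop,
                training = toy_training(epochs = 10),
                method_config = list(n_mc_passes = 10))
  expect_equal(uq_predict(m, d$x)$sigma_hat, rep(0, nrow(d$x)))
  # ensemble of bit-identical members (duplicate seeds) -> zero spread
  expect_warning(
    ens <- make_ensemble(c(4, 4), d$x, d$y, backbone = toy_backbone,
                         training = toy_training(epochs = 10)),
    "duplicate")
  expect_equal(uq_predict(ens, d$x)$sigma_hat, rep(0, nrow(d$x)))
  expect_error(make_ensemble(integer(0), d$x, d$y), "empty")
})

test_that("distinct-seed ensembles disagree somewhere; spread uses the sample SD", {
  d <- toy_problem(noise = 0.3)
  ens <- make_ensemble(c(1, 2, 3), d$x, d$y, backbone = toy_backbone,
                       training = toy_training(epochs = 15))
  p <- uq_predict(ens, d$x)
  expect_gt(max(p$sigma_hat), 0)
  # aggregation arithmetic: mean and (n-1)-denominator SD of member outputs
  member_preds <- vapply(ens$members, function(mm) {
    sc <- mm$scaling
    xs <- sweep(sweep(d$x, 2, sc$xm), 2, sc$xs, `/`)
    sc$ym + sc$ys * serdsuq:::nn_forward(mm$net, xs, mode = "eval")$out[, 1]
  }, numeric(nrow(d$x)))
  expect_equal(p$y_hat, rowMeans(member_preds), tolerance = 1e-12)
  expect_equal(p$sigma_hat, apply(member_preds, 1, sd), tolerance = 1e-12)
})

test_that("quantile head derives sigma from the inter-quantile span with crossing clipped", {
  d <- toy_problem(n = 200, noise = 0.4)
  m <- uq_train("quantile", d$x, d$y, backbone = toy_backbone,
                training = toy_training(epochs = 40))
  p <- uq_predict(m, d$x)
  expect_true(all(p$sigma_hat >= 0))
  # reconstruct from raw head outputs: sorted quantiles, span / (2 qnorm(.95))
  sc <- m$scaling
  xs <- sweep(sweep(d$x, 2, sc$xm), 2, sc$xs, `/`)
  out <- serdsuq:::nn_forward(m$net, xs, mode = "eval")$out
  qs <- t(apply(out, 1, sort))
  expect_equal(p$y_hat, sc$ym + sc$ys * qs[, 2], tolerance = 1e-12)
  expect_equal(p$sigma_hat, sc$ys * (qs[, 3] - qs[, 1]) / (2 * qnorm(0.95)),
               tolerance = 1e-12)
})

test_that("checkpoints round-trip through save/load", {
  d <- toy_problem()
  m <- uq_train("het_gaussian", d$x, d$y, backbone = toy_backbone,
                training = toy_training(epochs = 10))
  dir <- withr::local_tempdir()
  save_uq_model(m, dir)
  expect_true(file.exists(file.path(dir, "config.json")))
  back <- load_uq_model(dir)
  expect_identical(uq_predict(back, d$x), uq_predict(m, d$x))
})

test_that("the five heads reach comparable accuracy on the synthetic benchmark", {
  fx <- ablation_fixture()
  x_test <- fx$pd$x[fx$test_idx, , drop = FALSE]
  y_test <- fx$pd$y[fx$test_idx]
  r2 <- vapply(fx$abl$models, function(m) {
    p <- uq_predict(m, x_test)
    expect_true(all(p$sigma_hat >= 0))
    accuracy_metrics(y_test, p$y_hat)$r2
  }, numeric(1))
  expect_lt(max(r2) - min(r2), 0.1)
  expect_true(all(r2 > 0.5))  # all heads actually learn the task
})

test_that("manual models satisfy the prediction contract", {
  m <- uq_manual_model(function(x) list(y_hat = rowSums(x),
                                        sigma_hat = rep(1, nrow(x))))
  p <- uq_predict(m, diag(3))
  expect_equal(p$y_hat, rep(1, 3))
  expect_equal(p$sigma_hat, rep(1, 3))
})
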
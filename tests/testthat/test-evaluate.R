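test_that("empirical coverage counts boundary values as covered and ignores order", {
  ints <- data.frame(lower = c(0, 0, 0), upper = c(1, 1, 1))
  expect_equal(empirical_coverage(c(0.5, 1, 0), ints), 1)
  expect_equal(empirical_coverage(c(2, -1, 5), ints), 0)
  y <- runif(10); iv <- data.frame(lower = y - c(rep(0.1, 9), -0.2),
                                   upper = y + 0.1)
  expect_equal(empirical_coverage(y, iv), 0.9)
  o <- sample(10)
  expect_equal(empirical_coverage(y[o], iv[o, ]), 0.9)
  expect_error(empirical_coverage(numeric(0), iv[0, ]), "nonempty")
})

test_that("coverage curves match the Gaussian closed form when sigma is known", {
  set.seed(8)
  n <- 5000
  sigma <- runif(n, 0.3, 1)
  y_hat <- rnorm(n)
  y <- y_hat + rnorm(n, 0, sigma)
  cc <- coverage_curve(y, data.frame(y_hat = y_hat, sigma_hat = sigma))
  expect_lte(cc$calibration_rmse, 0.03)
  # degenerate sigma = 0 with nonzero errors -> zero coverage at all levels
  cc0 <- coverage_curve(y + 1, data.frame(y_hat = y, sigma_hat = 0))
  expect_true(all(cc0$coverage_by_level == 0))
  expect_error(coverage_curve(y, data.frame(y_hat = y, sigma_hat = 1),
                              levels = c(0.5, 1)), "levels")
})

test_that("calibration RMSE is zero iff empirical equals nominal at every level", {
  set.seed(1)
  # exact-quantile construction: y placed at known quantiles
  y_hat <- rep(0, 1000); sigma <- rep(1, 1000)
  u <- (seq_len(1000) - 0.5) / 1000
  y <- qnorm(u)  # symmetric, matches nominal coverage closely
  cc <- coverage_curve(y, data.frame(y_hat = y_hat, sigma_hat = sigma))
  expect_lt(cc$calibration_rmse, 0.005)
  expect_true(cc$calibration_rmse > 0)  # finite-sample, not exactly zero
})

test_that("uncertainty metrics follow their definitions", {
  y <- c(1, 2, 3, 4)
  preds <- data.frame(y_hat = c(1.1, 1.8, 3.4, 3.9),
                      sigma_hat = c(0.2, 0.3, 0.5, 0.4))
  um <- uncertainty_metrics(y, preds)
  err <- abs(y - preds$y_hat)
  expect_equal(um$sharpness, median(preds$sigma_hat))
  expect_equal(um$consistency, var(preds$sigma_hat))
  expect_equal(um$informativeness, cor(err, preds$sigma_hat))
  # sigma proportional to |error| -> informativeness exactly 1
  preds2 <- data.frame(y_hat = preds$y_hat, sigma_hat = err)
  expect_equal(uncertainty_metrics(y, preds2)$informativeness, 1)
  # constant sigma flagged, not silently zero
  preds3 <- data.frame(y_hat = preds$y_hat, sigma_hat = rep(0.3, 4))
  expect_warning(um3 <- uncertainty_metrics(y, preds3), "undefined")
  expect_true(is.na(um3$informativeness))
  expect_equal(um3$consistency, 0)
})

test_that("accuracy metrics follow their standard definitions", {
  y <- c(1, 2, 4)
  expect_equal(accuracy_metrics(y, y), list(r2 = 1, mae = 0, mape = 0, rmse = 0))
  am <- accuracy_metrics(y, rep(mean(y), 3))
  expect_equal(am$r2, 0)
  am2 <- accuracy_metrics(y, c(1.5, 1.5, 5))
  expect_equal(am2$mae, mean(c(0.5, 0.5, 1)))
  expect_equal(am2$mape, mean(c(0.5 / 1, 0.5 / 2, 1 / 4)) * 100)
  expect_equal(am2$rmse, sqrt(mean(c(0.25, 0.25, 1))))
  expect_equal(am2$r2, 1 - 1.5 / sum((y - mean(y))^2))
  expect_error(accuracy_metrics(c(0, 1), c(1, 1)), "MAPE")
})

test_that("median-coverage-error selection picks the representative model", {
  expect_equal(serdsuq:::lower_median_index(c(0.01, 0.03, 0.08)), 2)
  expect_equal(serdsuq:::lower_median_index(c(0.08, 0.01, 0.03)), 3)
  # even count: lower median, deterministically
  expect_equal(serdsuq:::lower_median_index(c(0.04, 0.01, 0.08, 0.02)), 4)
})

# Cheap injectable trainer: ridge-free least squares on the first channels,
# with a fixed sigma; lets cross-validation logic be tested without
# network training.
linear_trainer <- function(method, x, y, backbone = NULL, training = NULL,
                           method_config = NULL) {
  k <- min(6, ncol(x))
  X <- cbind(1, x[, seq_len(k), drop = FALSE])
  beta <- qr.coef(qr(X), y)
  sigma <- sd(y - X %*% beta)
  uq_manual_model(function(newx) {
    yh <- drop(cbind(1, newx[, seq_len(k), drop = FALSE]) %*% beta)
    list(y_hat = yh, sigma_hat = rep(sigma, length(yh)))
  })
}

test_that("cross-validation assigns exactly one conformalized prediction per sample", {
  set.seed(3)
  n <- 120
  x <- matrix(rnorm(n * 10), n)
  y <- x[, 1] + rnorm(n, 0, 0.3) + 3
  plan <- cv_plan(n_folds = 4, n_repeats_per_fold = 3, calibration_size = 25,
                  seed = 2)
  # constant-sigma trainer: informativeness warnings are expected
  res <- suppressWarnings(
    cross_validate(x, y, "het_gaussian", plan, train_fun = linear_trainer))
  expect_equal(sort(res$predictions$index), 1:n)
  expect_false(anyNA(res$predictions$y_hat))
  expect_false(anyNA(res$predictions$lower))
  expect_equal(length(res$reports), 4)
  expect_true(all(res$selected %in% 1:3))
  # fold labels partition the samples
  expect_equal(as.numeric(table(res$predictions$fold)), rep(30, 4))
  # bit-reproducible under the same plan seed
  res2 <- suppressWarnings(
    cross_validate(x, y, "het_gaussian", plan, train_fun = linear_trainer))
  expect_identical(res$predictions, res2$predictions)
})

test_that("ablation with a fixed well-specified linear model leaves coverage unchanged at q_hat ~ 0", {
  set.seed(9)
  n <- 400
  x <- matrix(rnorm(n * 8), n)
  y <- x[, 1] + rnorm(n) + 5  # sigma exactly 1, model sigma_hat ~ 1
  abl <- ablate_conformalization(x, y, methods = "het_gaussian",
                                 calibration_size = 60,
                                 train_fun = linear_trainer,
                                 training = training_config(seed = 4),
                                 n_cal_repeats = 3)
  # a well-calibrated fixed model: before and after differ only slightly
  expect_lt(abs(abl$delta["het_gaussian", "90%"]), 0.05)
  expect_lt(abs(abl$before["het_gaussian", "90%"] - 0.9), 0.06)
})

test_that("report rendering and plotting run on real pipeline objects", {
  set.seed(5)
  y <- rnorm(50, 3)
  preds <- data.frame(y_hat = y + rnorm(50, 0, 0.4),
                      sigma_hat = runif(50, 0.3, 0.6))
  adj <- conformal_calibrate(predictions = preds, y_cal = y)
  rep <- uncertainty_report(y, preds, adj)
  expect_s3_class(rep, "uncertainty_report")
  expect_true(all(rep$coverage_by_level >= 0 & rep$coverage_by_level <= 1))
  expect_output(print(rep), "coverage")
  txt <- format_coverage_table(list(before = matrix(0.5, 1, 2,
                                                    dimnames = list("m", c("RMSE", "90%"))),
                                    after = matrix(0.9, 1, 2,
                                                   dimnames = list("m", c("RMSE", "90%"))),
                                    delta = matrix(0.4, 1, 2,
                                                   dimnames = list("m", c("RMSE", "90%")))))
  expect_match(txt, "after conformalization")
  skip_if_not_installed("ggplot2")
  cc <- coverage_curve(y, preds, adj)
  p <- plot_calibration_curve(list(model = cc))
  expect_s3_class(p, "ggplot")
})
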
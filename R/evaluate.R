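#' Empirical coverage of prediction intervals
#'
#' Fraction of true values falling inside their interval; boundary values
#' count as covered (the convention favouring the guarantee direction).
#'
#' @param y_true True values.
#' @param intervals Data frame with `lower` and `upper` (one row per value).
#' @export
empirical_coverage <- function(y_true, intervals) {
  if (!length(y_true) || nrow(intervals) != length(y_true)) {
    stop("y_true and intervals must be nonempty and of equal length",
         call. = FALSE)
  }
  mean(y_true >= intervals$lower & y_true <= intervals$upper)
}

#' Default confidence-level ladder for calibration curves
#'
#' 5% to 95% in 5% steps plus 99%.
#' @export
coverage_levels <- function() c(seq(0.05, 0.95, by = 0.05), 0.99)

#' Coverage curve and calibration RMSE
#'
#' For each confidence level L, central intervals are built as
#' `y_hat +/- z_L * sigma` where `z_L` is the standard-normal quantile for
#' central mass L and `sigma` is the conformally calibrated SD
#' (`mode = "after"`, requires `adj`) or the model's raw `sigma_hat`
#' (`mode = "before"`). The calibration RMSE is the root-mean-square gap
#' between empirical and nominal coverage over the level ladder.
#'
#' @param y_true True values.
#' @param preds Data frame with `y_hat`, `sigma_hat`.
#' @param adj A `conformal_adjustment`, or `NULL` for before-calibration
#'   mode.
#' @param levels Confidence levels in (0, 1); default [coverage_levels()].
#' @return List with `coverage_by_level` (named vector), `calibration_rmse`
#'   and `mode`.
#' @export
coverage_curve <- function(y_true, preds, adj = NULL,
                           levels = coverage_levels()) {
  if (any(levels <= 0 | levels >= 1)) {
    stop_field("levels", "must lie strictly inside (0, 1)")
  }
  sigma <- if (!is.null(adj)) {
    as.numeric(calibrated_sigma(preds$sigma_hat, adj))
  } else {
    preds$sigma_hat
  }
  cov <- vapply(levels, function(L) {
    zl <- stats::qnorm((1 + L) / 2)
    mean(y_true >= preds$y_hat - zl * sigma &
           y_true <= preds$y_hat + zl * sigma)
  }, numeric(1))
  names(cov) <- sprintf("%g%%", 100 * levels)
  list(coverage_by_level = cov,
       calibration_rmse = sqrt(mean((cov - levels)^2)),
       mode = if (is.null(adj)) "before" else "after")
}

#' Sharpness, consistency and informativeness of uncertainty estimates
#'
#' Sharpness is the median predicted SD (narrower is more precise);
#' consistency the variance of predicted SDs (lower is more stable);
#' informativeness the Pearson correlation between predicted SD and
#' absolute prediction error (higher is more risk-sensitive). With constant
#' SDs the correlation is undefined: it is returned as `NA` with a warning,
#' never silently 0.
#'
#' @param y_true True values.
#' @param preds Data frame with `y_hat`, `sigma_hat`.
#' @param sigma Optional SD vector overriding `preds$sigma_hat` (e.g. the
#'   calibrated sigma).
#' @return List with `sharpness`, `consistency`, `informativeness`.
#' @export
uncertainty_metrics <- function(y_true, preds, sigma = NULL) {
  if (!length(y_true)) stop("empty input", call. = FALSE)
  s <- if (is.null(sigma)) preds$sigma_hat else as.numeric(sigma)
  err <- abs(y_true - preds$y_hat)
  info <- if (stats::sd(s) < 1e-12) {
    warning("constant predicted sigma: informativeness undefined (NA)")
    NA_real_
  } else {
    stats::cor(err, s)
  }
  list(sharpness = stats::median(s), consistency = stats::var(s),
       informativeness = info)
}

#' Point-prediction accuracy metrics
#'
#' `R2 = 1 - SS_res / SS_tot`, mean absolute error, mean absolute
#' percentage error (`|y - y_hat| / |y| * 100`, requires nonzero truths)
#' and root-mean-square error.
#'
#' @param y_true True values.
#' @param y_pred Point predictions.
#' @return List with `r2`, `mae`, `mape`, `rmse`.
#' @export
accuracy_metrics <- function(y_true, y_pred) {
  if (!length(y_true) || length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must be nonempty and of equal length",
         call. = FALSE)
  }
  if (any(y_true == 0)) stop("MAPE undefined: y_true contains zeros",
                             call. = FALSE)
  r <- y_true - y_pred
  list(r2 = 1 - sum(r^2) / sum((y_true - mean(y_true))^2),
       mae = mean(abs(r)),
       mape = mean(abs(r) / abs(y_true)) * 100,
       rmse = sqrt(mean(r^2)))
}

#' Full uncertainty report
#'
#' Bundles accuracy, the three uncertainty quality metrics (on the
#' calibrated SD when `adj` is given), 90% empirical coverage and the
#' coverage curve with its calibration RMSE.
#'
#' @inheritParams coverage_curve
#' @export
uncertainty_report <- function(y_true, preds, adj = NULL,
                               levels = coverage_levels()) {
  sigma <- if (!is.null(adj)) {
    as.numeric(calibrated_sigma(preds$sigma_hat, adj))
  } else {
    preds$sigma_hat
  }
  curve <- coverage_curve(y_true, preds, adj, levels)
  z <- if (!is.null(adj)) adj$z else default_z()
  cov90 <- mean(y_true >= preds$y_hat - z * sigma &
                  y_true <= preds$y_hat + z * sigma)
  structure(list(accuracy = accuracy_metrics(y_true, preds$y_hat),
                 uncertainty = uncertainty_metrics(y_true, preds, sigma),
                 coverage_90 = cov90,
                 coverage_by_level = curve$coverage_by_level,
                 calibration_rmse = curve$calibration_rmse,
                 mode = curve$mode),
            class = "uncertainty_report")
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat(sprintf("<uncertainty_report> (%s conformalization)\n", x$mode))
  cat(sprintf("  R2 %.3f | MAE %.3f | MAPE %.1f%% | RMSE %.3f\n",
              x$accuracy$r2, x$accuracy$mae, x$accuracy$mape, x$accuracy$rmse))
  cat(sprintf("  coverage(90%%) %.3f | calibration RMSE %.3f\n",
              x$coverage_90, x$calibration_rmse))
  cat(sprintf("  sharpness %.3f | consistency %.4f | informativeness %s\n",
              x$uncertainty$sharpness, x$uncertainty$consistency,
              ifelse(is.na(x$uncertainty$informativeness), "NA",
                     sprintf("%.3f", x$uncertainty$informativeness))))
  invisible(x)
}

#' Cross-validation plan
#'
#' @param n_folds Number of folds (default 10).
#' @param n_repeats_per_fold Models trained per fold, each with a fresh
#'   random calibration split (default 10).
#' @param calibration_size Held-out calibration samples per model
#'   (default 100).
#' @param seed Integer seed.
#' @export
cv_plan <- function(n_folds = 10, n_repeats_per_fold = 10,
                    calibration_size = 100, seed = 1) {
  check_number(n_folds, "n_folds", min = 2, integer = TRUE)
  check_number(n_repeats_per_fold, "n_repeats_per_fold", min = 1, integer = TRUE)
  check_number(calibration_size, "calibration_size", min = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats_per_fold = as.integer(n_repeats_per_fold),
                 calibration_size = as.integer(calibration_size),
                 seed = as.integer(seed)), class = "cv_plan")
}

# Lower median: deterministic selection for even counts.
lower_median_index <- function(v) {
  order(v)[ceiling(length(v) / 2)]
}

#' Cross-validated, conformalized evaluation
#'
#' For each fold: `n_repeats_per_fold` models are trained on the training
#' folds minus a fresh random calibration split, conformalized on that
#' split, and evaluated on the held-out fold. Per fold, the model with the
#' median absolute 90% coverage error is selected (the representative run,
#' not the best), and its conformalized predictions on the held-out fold
#' are kept, so every sample in the dataset receives exactly one aggregated
#' prediction.
#'
#' @param x Input matrix (samples x channels).
#' @param y Labels.
#' @param method A method name from [uq_methods()].
#' @param plan A [cv_plan()].
#' @param backbone,training,method_config Passed to the trainer.
#' @param train_fun Trainer with the signature of [uq_train()]
#'   (injectable for custom or inexpensive base models).
#' @param alpha,z Conformal parameters.
#' @return List with `predictions` (one row per sample: `y`, `y_hat`,
#'   `sigma` (calibrated), `lower`, `upper`, `fold`), per-fold `reports`,
#'   and the selected repeat indices.
#' @export
cross_validate <- function(x, y, method, plan = cv_plan(),
                           backbone = backbone_config(),
                           training = training_config(),
                           method_config = list(),
                           train_fun = uq_train,
                           alpha = 0.1, z = default_z()) {
  n <- length(y)
  if (n < plan$n_folds * 2) stop("dataset too small for the fold count",
                                 call. = FALSE)
  folds <- with_seed(derive_seed(plan$seed, "folds"), {
    sample(rep_len(seq_len(plan$n_folds), n))
  })
  min_train <- min(table(folds))
  if (plan$calibration_size >= n - max(table(folds))) {
    stop("calibration_size leaves no training data", call. = FALSE)
  }
  out <- data.frame(index = seq_len(n), y = y, y_hat = NA_real_,
                    sigma = NA_real_, lower = NA_real_, upper = NA_real_,
                    fold = folds)
  reports <- vector("list", plan$n_folds)
  selected <- integer(plan$n_folds)
  for (f in seq_len(plan$n_folds)) {
    test_idx <- which(folds == f)
    pool <- which(folds != f)
    runs <- lapply(seq_len(plan$n_repeats_per_fold), function(r) {
      cal_idx <- with_seed(derive_seed(plan$seed, sprintf("cal_%d_%d", f, r)),
                           sample(pool, plan$calibration_size))
      tr_idx <- setdiff(pool, cal_idx)
      tr <- training
      tr$seed <- derive_seed(plan$seed, sprintf("train_%d_%d", f, r))
      model <- train_fun(method, x[tr_idx, , drop = FALSE], y[tr_idx],
                         backbone = backbone, training = tr,
                         method_config = method_config)
      adj <- conformal_calibrate(model, x[cal_idx, , drop = FALSE],
                                 y[cal_idx], alpha = alpha, z = z)
      preds <- uq_predict(model, x[test_idx, , drop = FALSE])
      ints <- predict_interval(preds$y_hat, preds$sigma_hat, adj)
      list(model = model, adj = adj, preds = preds,
           coverage = empirical_coverage(y[test_idx], ints))
    })
    errs <- vapply(runs, function(r) abs(r$coverage - (1 - alpha)), numeric(1))
    sel <- lower_median_index(errs)
    selected[f] <- sel
    best <- runs[[sel]]
    sig <- as.numeric(calibrated_sigma(best$preds$sigma_hat, best$adj))
    ints <- predict_interval(best$preds$y_hat, best$preds$sigma_hat, best$adj)
    out$y_hat[test_idx] <- best$preds$y_hat
    out$sigma[test_idx] <- sig
    out$lower[test_idx] <- ints$lower
    out$upper[test_idx] <- ints$upper
    reports[[f]] <- uncertainty_report(y[test_idx], best$preds, best$adj)
  }
  list(predictions = out, reports = reports, selected = selected,
       plan = plan)
}

#' Conformalization ablation
#'
#' Trains each method once on a train/calibration/test split and tabulates
#' empirical coverage across confidence levels before conformalization
#' (raw `sigma_hat`), after (calibrated sigma), and their delta
#' (after - before). On aleatoric-dominated data, deterministic heads
#' (heteroscedastic Gaussian, quantile) are expected near-calibrated before
#' conformalization while pure-epistemic spreads (ensembles, MC dropout)
#' under-cover; after conformalization all methods are guaranteed at the
#' nominal level marginally.
#'
#' @param x,y Dataset.
#' @param methods Character vector of methods from [uq_methods()].
#' @param calibration_size Held-out calibration samples.
#' @param test_fraction Fraction held out for testing.
#' @param levels Confidence levels to tabulate.
#' @param backbone,training,method_config,train_fun,alpha,z As in
#'   [cross_validate()].
#' @param per_method Optional named list of per-method overrides, each a
#'   list with any of `backbone`, `training`, `method_config` — mirroring
#'   the usual practice of hand-tuning each uncertainty head separately so
#'   that accuracies are comparable.
#' @param n_cal_repeats Number of independent calibration re-splits
#'   averaged in the after/delta rows (reduces split noise; the model is
#'   trained once).
#' @return List with matrices `before`, `after`, `delta` (methods x levels,
#'   plus a calibration RMSE column) and the per-method models.
#' @export
ablate_conformalization <- function(x, y, methods = uq_methods(),
                                    calibration_size = 100,
                                    test_fraction = 0.25,
                                    levels = c(0.1, 0.2, 0.5, 0.8, 0.9, 0.95, 0.99),
                                    backbone = backbone_config(),
                                    training = training_config(),
                                    method_config = list(),
                                    train_fun = uq_train,
                                    alpha = 0.1, z = default_z(),
                                    per_method = list(),
                                    n_cal_repeats = 5) {
  if (!length(methods)) stop("need >= 1 method", call. = FALSE)
  n <- length(y)
  idx <- with_seed(derive_seed(training$seed, "ablate_split"), sample.int(n))
  n_test <- round(test_fraction * n)
  test_idx <- idx[seq_len(n_test)]
  pool <- idx[-seq_len(n_test)]
  # calibration pool disjoint from training data: re-splits draw from it
  n_cal_pool <- min(2L * calibration_size, length(pool) - calibration_size)
  if (n_cal_pool < calibration_size) {
    stop("dataset too small for the requested calibration_size", call. = FALSE)
  }
  cal_pool <- pool[seq_len(n_cal_pool)]
  train_idx <- pool[-seq_len(n_cal_pool)]
  mk_row <- function(curve) c(RMSE = curve$calibration_rmse,
                              curve$coverage_by_level)
  before <- after <- NULL
  models <- list()
  for (m in methods) {
    ov <- per_method[[m]] %||% list()
    model <- train_fun(m, x[train_idx, , drop = FALSE], y[train_idx],
                       backbone = ov$backbone %||% backbone,
                       training = ov$training %||% training,
                       method_config = ov$method_config %||% method_config)
    models[[m]] <- model
    preds <- uq_predict(model, x[test_idx, , drop = FALSE])
    b <- mk_row(coverage_curve(y[test_idx], preds, NULL, levels))
    a_rows <- vapply(seq_len(n_cal_repeats), function(r) {
      cal_idx <- with_seed(derive_seed(training$seed, sprintf("abl_cal_%s_%d", m, r)),
                           sample(cal_pool, calibration_size))
      adj <- conformal_calibrate(model, x[cal_idx, , drop = FALSE],
                                 y[cal_idx], alpha = alpha, z = z)
      mk_row(coverage_curve(y[test_idx], preds, adj, levels))
    }, numeric(length(levels) + 1))
    a <- rowMeans(a_rows)
    before <- rbind(before, b)
    after <- rbind(after, a)
  }
  rownames(before) <- rownames(after) <- methods
  list(before = before, after = after, delta = after - before,
       models = models, levels = levels)
}

#' Render an ablation result as text tables
#'
#' @param ablation Result of [ablate_conformalization()].
#' @export
format_coverage_table <- function(ablation) {
  fmt <- function(m, title) {
    paste0(title, "\n",
           paste(utils::capture.output(print(round(m, 3))), collapse = "\n"))
  }
  paste(fmt(ablation$after, "(a) after conformalization"),
        fmt(ablation$before, "(b) before conformalization"),
        fmt(ablation$delta, "(c) delta (after - before)"), sep = "\n\n")
}

#' Calibration-curve plot (expected vs achieved coverage)
#'
#' Draws empirical coverage against nominal level for one or more coverage
#' curves, with the diagonal marking perfect calibration. Requires ggplot2.
#'
#' @param curves Named list of results from [coverage_curve()].
#' @export
plot_calibration_curve <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    cv <- curves[[nm]]$coverage_by_level
    lv <- as.numeric(sub("%", "", names(cv))) / 100
    data.frame(model = nm, nominal = lv, empirical = as.numeric(cv))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nominal, y = .data$empirical,
                                   colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Expected coverage", y = "Achieved coverage") +
    ggplot2::theme_minimal()
}
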
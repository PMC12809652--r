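#' Default normal multiplier for 90% central coverage
#'
#' The exact standard-normal 95th percentile (~1.6449), conventionally
#' displayed as 1.64: under a Gaussian residual assumption, `y_hat +/- z *
#' sigma_hat` is a central 90% interval.
#'
#' @export
default_z <- function() stats::qnorm(0.95)

#' Nonconformity score
#'
#' `s(x, y) = max(y - (y_hat + z * sigma_hat), (y_hat - z * sigma_hat) - y)`:
#' the signed distance from the true value to the nearest boundary of the
#' heuristic interval `y_hat +/- z * sigma_hat` — negative when the truth
#' falls inside the interval, positive outside.
#'
#' @param y True values (vectorised).
#' @param y_hat Point predictions.
#' @param sigma_hat Predicted standard deviations (>= 0).
#' @param z Normal multiplier (> 0), default [default_z()].
#' @return Numeric vector of scores.
#' @export
#' @examples
#' nonconformity_score(2, 2, 0.5, z = 1.64)  # -0.82: inside the interval
nonconformity_score <- function(y, y_hat, sigma_hat, z = default_z()) {
  if (any(!is.finite(y)) || any(!is.finite(y_hat)) || any(!is.finite(sigma_hat))) {
    stop("non-finite inputs to nonconformity_score", call. = FALSE)
  }
  if (any(sigma_hat < 0)) stop_field("sigma_hat", "must be >= 0")
  check_number(z, "z", min = 1e-12)
  pmax(y - (y_hat + z * sigma_hat), (y_hat - z * sigma_hat) - y)
}

#' Finite-sample conformal quantile
#'
#' The k-th smallest score with `k = ceiling((n + 1) * (1 - alpha))`. When
#' `k > n` (calibration set too small for the requested level) the `+Inf`
#' sentinel is returned, yielding unbounded intervals and preserving the
#' finite-sample guarantee.
#'
#' @param scores Nonempty vector of nonconformity scores.
#' @param alpha Miscoverage level in (0, 1).
#' @export
#' @examples
#' conformal_quantile(1:19, alpha = 0.1)  # 18: k = ceiling(20 * 0.9)
conformal_quantile <- function(scores, alpha = 0.1) {
  if (!length(scores)) stop("empty score vector", call. = FALSE)
  check_number(alpha, "alpha", min = 1e-12, max = 1 - 1e-12)
  n <- length(scores)
  k <- ceiling((n + 1) * (1 - alpha))
  if (k > n) return(Inf)
  sort(scores, method = "radix")[k]
}

#' Split-conformal calibration
#'
#' Computes nonconformity scores on a held-out calibration set and the
#' finite-sample quantile adjustment `q_hat`. The calibration records must
#' be disjoint from the model's training data (caller contract).
#'
#' @param model A `uq_model` or `uq_manual_model` (or `NULL` when
#'   `predictions` are supplied directly).
#' @param x_cal Calibration inputs (matrix), ignored when `predictions`
#'   given.
#' @param y_cal Calibration ground-truth values.
#' @param alpha Miscoverage level (default 0.1 for 90% coverage).
#' @param z Normal multiplier (default [default_z()]).
#' @param predictions Optional data frame with `y_hat`, `sigma_hat`
#'   (bypasses `model`).
#' @return A `conformal_adjustment` with fields `alpha`, `z`, `scores`,
#'   `q_hat`, `n`.
#' @export
conformal_calibrate <- function(model = NULL, x_cal = NULL, y_cal,
                                alpha = 0.1, z = default_z(),
                                predictions = NULL) {
  if (!length(y_cal)) stop("empty calibration set", call. = FALSE)
  if (is.null(predictions)) {
    if (is.null(model)) stop("supply a model or predictions", call. = FALSE)
    predictions <- uq_predict(model, x_cal)
  }
  if (nrow(predictions) != length(y_cal)) {
    stop("calibration predictions and labels differ in length", call. = FALSE)
  }
  scores <- nonconformity_score(y_cal, predictions$y_hat,
                                predictions$sigma_hat, z)
  structure(list(alpha = alpha, z = z, scores = scores,
                 q_hat = conformal_quantile(scores, alpha),
                 n = length(scores)),
            class = "conformal_adjustment")
}

#' @export
print.conformal_adjustment <- function(x, ...) {
  cat(sprintf("<conformal_adjustment> n = %d, alpha = %.3g, z = %.4f, q_hat = %.4g\n",
              x$n, x$alpha, x$z, x$q_hat))
  invisible(x)
}

#' Calibrated prediction interval
#'
#' `C(x) = [y_hat - z * sigma_hat - q_hat, y_hat + z * sigma_hat + q_hat]`.
#' A negative `q_hat` narrows the heuristic interval; the `+Inf` sentinel
#' yields an unbounded interval.
#'
#' @param y_hat,sigma_hat Predictions (vectorised).
#' @param adj A `conformal_adjustment`.
#' @return Data frame with `lower`, `upper` and the nominal `level`.
#' @export
predict_interval <- function(y_hat, sigma_hat, adj) {
  stopifnot(inherits(adj, "conformal_adjustment"))
  half <- adj$z * sigma_hat + adj$q_hat
  data.frame(lower = y_hat - half, upper = y_hat + half,
             level = 1 - adj$alpha)
}

#' Calibrated standard deviation
#'
#' Folds the conformal adjustment into the model's predicted SD:
#' `sigma = sigma_hat + q_hat / z`, so that `y_hat +/- z * sigma`
#' reproduces the calibrated 90% interval exactly, and intervals at any
#' other level can be rebuilt as `y_hat +/- z_L * sigma` (well-calibrated
#' under a Gaussian residual assumption; only the nominal level is
#' guaranteed). A negative calibrated SD is clamped to 0 with a warning
#' (the raw value is returned in the `"raw"` attribute).
#'
#' @param sigma_hat Predicted SDs.
#' @param adj A `conformal_adjustment`.
#' @export
calibrated_sigma <- function(sigma_hat, adj) {
  stopifnot(inherits(adj, "conformal_adjustment"))
  sigma <- sigma_hat + adj$q_hat / adj$z
  if (any(sigma < 0)) {
    warning(sprintf("%d calibrated sigma value(s) < 0 clamped to 0 (min raw = %.4g)",
                    sum(sigma < 0), min(sigma)))
  }
  structure(pmax(sigma, 0), raw = sigma)
}

#' Serialise / restore calibration state
#'
#' JSON round-trip of a `conformal_adjustment` (alpha, z, scores, q_hat, n,
#' optional model checkpoint reference) for calibrate-once / predict-many
#' workflows.
#'
#' @param adj A `conformal_adjustment`.
#' @param path JSON file path.
#' @param model_ref Optional checkpoint path recorded alongside.
#' @export
write_adjustment <- function(adj, path, model_ref = NULL) {
  stopifnot(inherits(adj, "conformal_adjustment"))
  obj <- unclass(adj)
  obj$model_ref <- model_ref
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "string")
  invisible(path)
}

#' @rdname write_adjustment
#' @export
read_adjustment <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(alpha = obj$alpha, z = obj$z, scores = as.numeric(obj$scores),
                 q_hat = as.numeric(obj$q_hat), n = obj$n),
            class = "conformal_adjustment")
}
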
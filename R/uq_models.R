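#' Backbone architecture configuration
#'
#' A compact 1D-CNN regression backbone: convolutional blocks (conv + ReLU +
#' batch normalisation + max pooling) followed by dense blocks (fully
#' connected + ReLU + dropout) and a linear head of 1-3 outputs depending on
#' the uncertainty method. The default (16/32/64 channels, kernel 7, pool 2;
#' dense 128 and 64 with dropout 0.2) is sized for CPU training and is fully
#' configurable.
#'
#' @param conv_blocks List of `c(channels, kernel, pool)` triples (>= 1).
#' @param dense_blocks List of `c(width, dropout_rate)` pairs (>= 1),
#'   dropout rates in `[0, 1)`.
#' @param batchnorm Use batch normalisation in conv blocks.
#' @param prior_sd Gaussian prior SD for variational (Bayes-by-backprop)
#'   weights.
#' @return A validated `backbone_config`.
#' @export
backbone_config <- function(conv_blocks = list(c(16, 7, 2), c(32, 7, 2), c(64, 7, 2)),
                            dense_blocks = list(c(128, 0.2), c(64, 0.2)),
                            batchnorm = TRUE, prior_sd = 1) {
  if (!length(conv_blocks)) stop_field("conv_blocks", "need >= 1 conv block")
  if (!length(dense_blocks)) stop_field("dense_blocks", "need >= 1 dense block")
  for (cb in conv_blocks) {
    if (length(cb) != 3 || any(cb < 1) || cb[3] < 1) {
      stop_field("conv_blocks", "each block must be c(channels, kernel, pool)")
    }
  }
  for (db in dense_blocks) {
    if (length(db) != 2 || db[1] < 1 || db[2] < 0 || db[2] >= 1) {
      stop_field("dense_blocks", "each block must be c(width, dropout in [0,1))")
    }
  }
  check_number(prior_sd, "prior_sd", min = 1e-6)
  structure(list(conv_blocks = conv_blocks, dense_blocks = dense_blocks,
                 batchnorm = batchnorm, prior_sd = prior_sd),
            class = "backbone_config")
}

#' Training configuration
#'
#' @param epochs Number of passes over the training data.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param seed Integer seed fixing initialisation, batch order and any
#'   stochastic regularisation; the same seed and config reproduce the
#'   fitted model bit-for-bit.
#' @param validation_fraction Fraction of the training data held out for
#'   checkpointing (the returned model carries the weights with the best
#'   validation loss); set 0 to disable. Automatically disabled when the
#'   split would hold fewer than 20 observations.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param verbose Print loss every 10 epochs.
#' @export
training_config <- function(epochs = 100, batch_size = 32,
                            learning_rate = 1e-3, seed = 1,
                            validation_fraction = 0.15, patience = 40,
                            verbose = FALSE) {
  check_number(epochs, "epochs", min = 1, integer = TRUE)
  check_number(batch_size, "batch_size", min = 1, integer = TRUE)
  check_number(learning_rate, "learning_rate", min = 1e-12)
  check_number(seed, "seed", integer = TRUE)
  check_number(validation_fraction, "validation_fraction", min = 0, max = 0.5)
  check_number(patience, "patience", min = 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 validation_fraction = validation_fraction,
                 patience = patience,
                 verbose = isTRUE(verbose)), class = "training_config")
}

uq_methods <- function() {
  c("het_gaussian", "quantile", "mc_dropout", "bayes_backprop", "deep_ensemble")
}

default_method_config <- function(method) {
  list(n_mc_passes = 50, ensemble_size = 5,
       quantile_levels = c(0.05, 0.5, 0.95),
       warmup_frac = 0.3)
}

#' Train an uncertainty-quantifying regression model
#'
#' Fits the shared 1D-CNN backbone with one of five uncertainty heads, all
#' exposing the uniform contract `predict(x) -> (y_hat, sigma_hat)`:
#'
#' * `het_gaussian` — two-output head (mean, log-SD) minimising the Gaussian
#'   negative log-likelihood; `sigma_hat` is the learned aleatoric SD.
#' * `quantile` — three quantile heads (default levels 0.05/0.5/0.95) with
#'   pinball loss; `y_hat` is the median head and `sigma_hat =
#'   (q95 - q05) / (2 z)` with `z = qnorm(0.95)`, so an input's SD is
#'   directly computable from the inter-quantile span.
#' * `mc_dropout` — squared-error backbone; at prediction time `n_mc_passes`
#'   stochastic forward passes (one shared dropout mask per pass) give the
#'   mean and sample SD.
#' * `bayes_backprop` — mean-field Gaussian weight posteriors trained on the
#'   variational ELBO (one posterior draw per step); prediction averages
#'   `n_mc_passes` posterior draws.
#' * `deep_ensemble` — `ensemble_size` independently initialised
#'   squared-error backbones; prediction is the mean and sample SD of the
#'   member point predictions.
#'
#' Inputs are standardised per channel and labels standardised, with
#' statistics fit on the training split only; `sigma_hat` is rescaled back
#' to label units.
#'
#' @param method One of [uq_methods()].
#' @param x Numeric matrix (samples x channels).
#' @param y Numeric label vector.
#' @param backbone A [backbone_config()].
#' @param training A [training_config()].
#' @param method_config Optional overrides: `n_mc_passes`, `ensemble_size`,
#'   `quantile_levels`.
#' @return A fitted `uq_model`.
#' @export
uq_train <- function(method, x, y, backbone = backbone_config(),
                     training = training_config(), method_config = list()) {
  method <- match.arg(method, uq_methods())
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) != length(y)) {
    stop(sprintf("shape mismatch: %d spectra but %d labels", nrow(x),
                 length(y)), call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("x and y must be free of NA", call. = FALSE)
  mc <- utils::modifyList(default_method_config(method), method_config)

  if (method == "deep_ensemble") {
    seeds <- training$seed + seq_len(mc$ensemble_size) - 1L
    return(make_ensemble(seeds, x, y, backbone = backbone,
                         training = training, method_config = mc))
  }

  xm <- colMeans(x); xs <- pmax(apply(x, 2, stats::sd), 1e-8)
  ym <- mean(y); ys <- max(stats::sd(y), 1e-8)
  xstd <- sweep(sweep(x, 2, xm), 2, xs, `/`)
  ystd <- (y - ym) / ys

  n_val <- floor(training$validation_fraction * nrow(x))
  if (n_val >= 20) {
    vi <- with_seed(derive_seed(training$seed, "valsplit"),
                    sample.int(nrow(x), n_val))
    X_val <- xstd[vi, , drop = FALSE]; y_val <- ystd[vi]
    xstd <- xstd[-vi, , drop = FALSE]; ystd <- ystd[-vi]
  } else {
    X_val <- NULL; y_val <- NULL
  }

  out_dim <- switch(method, het_gaussian = 2L, quantile = 3L, 1L)
  loss_fn <- switch(method,
    het_gaussian = loss_gaussian_nll,
    quantile = make_pinball_loss(mc$quantile_levels),
    loss_mse)
  variational <- method == "bayes_backprop"
  net <- nn_init(backbone, ncol(x), out_dim,
                 seed = derive_seed(training$seed, "init"),
                 variational = variational)
  kl_scale <- if (variational) 1 / nrow(x) else 0
  epochs <- training$epochs
  if (method == "het_gaussian") {
    # mean-warmup: fit the mean head alone for the first part of training
    warm <- max(1L, as.integer((mc$warmup_frac %||% 0.3) * epochs))
    net <- nn_train(net, xstd, ystd, loss_mean_warmup, epochs = warm,
                    batch_size = training$batch_size,
                    lr = training$learning_rate,
                    seed = derive_seed(training$seed, "warmup"),
                    kl_scale = kl_scale, verbose = training$verbose)
    epochs <- max(1L, epochs - warm)
  }
  net <- nn_train(net, xstd, ystd, loss_fn, epochs = epochs,
                  batch_size = training$batch_size,
                  lr = training$learning_rate,
                  seed = derive_seed(training$seed, "train"),
                  kl_scale = kl_scale, verbose = training$verbose,
                  X_val = X_val, y_val = y_val, patience = training$patience)
  structure(list(method = method, net = net, backbone = backbone,
                 method_config = mc, rng_seed = training$seed,
                 scaling = list(xm = xm, xs = xs, ym = ym, ys = ys)),
            class = "uq_model")
}

#' Train a deep ensemble from explicit member seeds
#'
#' Each member is an independently initialised and independently trained
#' squared-error backbone; random initialisation drives members into
#' different local minima, so the spread of their point predictions
#' estimates epistemic uncertainty. Duplicate seeds produce bit-identical
#' members and are warned about (they reduce hypothesis diversity).
#'
#' @param member_seeds Integer vector of member seeds (>= 1 member; >= 2 for
#'   a nonzero spread).
#' @inheritParams uq_train
#' @export
make_ensemble <- function(member_seeds, x, y, backbone = backbone_config(),
                          training = training_config(), method_config = list()) {
  if (!length(member_seeds)) stop("empty member seed list", call. = FALSE)
  if (anyDuplicated(member_seeds)) {
    warning("duplicate ensemble member seeds reduce hypothesis diversity")
  }
  mc <- utils::modifyList(default_method_config("deep_ensemble"), method_config)
  mc$ensemble_size <- length(member_seeds)
  members <- lapply(member_seeds, function(s) {
    tr <- training; tr$seed <- as.integer(s)
    uq_train("mc_dropout", x, y, backbone = backbone, training = tr,
             method_config = mc)
  })
  structure(list(method = "deep_ensemble", members = members,
                 member_seeds = as.integer(member_seeds),
                 method_config = mc, rng_seed = training$seed),
            class = "uq_model")
}

#' Wrap a fixed prediction function as a UQ model
#'
#' For calibration experiments with a fixed (possibly deliberately
#' miscalibrated) base regressor: `fun(x)` must return a list or data frame
#' with `y_hat` and `sigma_hat` for each row of `x`.
#'
#' @param fun Prediction function.
#' @param method Label stored on the model.
#' @export
uq_manual_model <- function(fun, method = "manual") {
  structure(list(method = method, fun = fun), class = "uq_manual_model")
}

#' Band-contrast features from raw SERDS samples
#'
#' Cheap spectral features for fixed baseline regressors: for each sample,
#' the replicate- and grid-averaged laser-1 spectrum is reduced to local
#' band contrasts (mean intensity in a window around each organic band
#' minus its flanking background) plus the total mean intensity.
#'
#' @param dataset A `serds_dataset`.
#' @return Numeric feature matrix (samples x 4).
#' @export
stub_features <- function(dataset) {
  axis <- dataset$axis
  bands <- data.frame(center = c(1340, 1600, 1450), width = c(25, 20, 12))
  t(vapply(dataset$samples, function(s) {
    m <- apply(s$measurements[, 1, , , drop = FALSE], 4, mean) /
      s$integration_time
    f <- vapply(seq_len(nrow(bands)), function(i) {
      c0 <- bands$center[i]; w <- bands$width[i]
      inb <- abs(axis - c0) <= 2 * w
      flank <- abs(axis - c0) > 3 * w & abs(axis - c0) <= 6 * w
      mean(m[inb]) - mean(m[flank])
    }, numeric(1))
    c(f, mean(m))
  }, numeric(4)))
}

#' Fit a fixed linear band regressor
#'
#' A deliberately simple base model for conformal calibration experiments:
#' ordinary least squares of SOC on [stub_features()], with a constant
#' predicted SD equal to `sigma_scale` times the training residual SD.
#' `sigma_scale < 1` produces a deliberately over-confident (mis-scaled)
#' model, useful for demonstrating that the conformal guarantee holds
#' regardless of the base model's calibration.
#'
#' @param dataset A `serds_dataset` used for fitting.
#' @param sigma_scale Multiplier on the residual SD (1 = honestly scaled).
#' @return A `uq_manual_model` whose prediction function takes a feature
#'   matrix from [stub_features()].
#' @export
fit_stub_regressor <- function(dataset, sigma_scale = 1) {
  F_tr <- stub_features(dataset)
  y <- vapply(dataset$samples, function(s) s$true_soc, numeric(1))
  X <- cbind(1, F_tr)
  beta <- qr.coef(qr(X), y)
  sigma <- stats::sd(y - X %*% beta) * sigma_scale
  uq_manual_model(function(x) {
    yh <- drop(cbind(1, x) %*% beta)
    list(y_hat = yh, sigma_hat = rep(sigma, length(yh)))
  }, method = "stub_band_lm")
}

#' Predict SOC and its uncertainty
#'
#' Uniform prediction contract for all methods: point prediction `y_hat`
#' and nonnegative standard deviation `sigma_hat` per input row.
#' Predictions are deterministic given the fitted parameters, method config
#' and the model's seed, and independent of row order.
#'
#' @param model A `uq_model` or `uq_manual_model`.
#' @param x Numeric matrix (or vector for a single spectrum) with the
#'   backbone's input length.
#' @return Data frame with columns `y_hat` and `sigma_hat`.
#' @export
uq_predict <- function(model, x) {
  UseMethod("uq_predict")
}

#' @export
uq_predict.uq_manual_model <- function(model, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  p <- model$fun(x)
  data.frame(y_hat = p$y_hat, sigma_hat = p$sigma_hat)
}

#' @export
uq_predict.uq_model <- function(model, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (model$method == "deep_ensemble") {
    # members contribute deterministic point predictions (no dropout)
    preds <- vapply(model$members, function(m) {
      sc <- m$scaling
      xstd <- sweep(sweep(x, 2, sc$xm), 2, sc$xs, `/`)
      sc$ym + sc$ys * nn_forward(m$net, xstd, mode = "eval")$out[, 1]
    }, numeric(nrow(x)))
    preds <- matrix(preds, nrow = nrow(x))
    mu <- rowMeans(preds)
    sd_ <- if (ncol(preds) > 1) apply(preds, 1, stats::sd) else rep(0, nrow(x))
    return(data.frame(y_hat = mu, sigma_hat = sd_))
  }
  sc <- model$scaling
  if (ncol(x) != length(sc$xm)) {
    stop(sprintf("input has %d channels; model expects %d", ncol(x),
                 length(sc$xm)), call. = FALSE)
  }
  xstd <- sweep(sweep(x, 2, sc$xm), 2, sc$xs, `/`)

  if (model$method == "het_gaussian") {
    out <- nn_forward(model$net, xstd, mode = "eval")$out
    mu <- sc$ym + sc$ys * out[, 1]
    sigma <- sc$ys * exp(6 * tanh(out[, 2] / 6))
  } else if (model$method == "quantile") {
    out <- nn_forward(model$net, xstd, mode = "eval")$out
    qs <- t(apply(out, 1, sort))  # clip crossing quantiles to ordering
    z <- stats::qnorm(0.95)
    mu <- sc$ym + sc$ys * qs[, 2]
    sigma <- sc$ys * (qs[, 3] - qs[, 1]) / (2 * z)
  } else {  # mc_dropout / bayes_backprop: n_mc_passes stochastic passes
    n_pass <- model$method_config$n_mc_passes
    sample_w <- model$method == "bayes_backprop"
    mode <- if (model$method == "mc_dropout") "mc" else "eval"
    draws <- with_seed(derive_seed(model$rng_seed, "predict"), {
      vapply(seq_len(n_pass), function(p) {
        nn_forward(model$net, xstd, mode = mode,
                   sample_weights = sample_w)$out[, 1]
      }, numeric(nrow(x)))
    })
    draws <- matrix(draws, nrow = nrow(x))
    mu <- sc$ym + sc$ys * rowMeans(draws)
    sigma <- if (n_pass > 1) sc$ys * apply(draws, 1, stats::sd) else
      rep(0, nrow(x))
  }
  data.frame(y_hat = mu, sigma_hat = pmax(sigma, 0))
}

#' @export
predict.uq_model <- function(object, newdata, ...) uq_predict(object, newdata)

#' @export
print.uq_model <- function(x, ...) {
  cat(sprintf("<uq_model> method: %s", x$method))
  if (x$method == "deep_ensemble") {
    cat(sprintf(" (%d members)", length(x$members)))
  }
  cat("\n")
  invisible(x)
}

#' Save / load a fitted UQ model
#'
#' Checkpoints are a directory holding a weights blob plus a JSON config
#' (method, backbone, seeds, standardisation constants).
#'
#' @param model A `uq_model`.
#' @param dir Checkpoint directory.
#' @export
save_uq_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(method = model$method, rng_seed = model$rng_seed,
              method_config = model$method_config)
  if (!is.null(model$scaling)) cfg$scaling <- model$scaling
  if (!is.null(model$backbone)) cfg$backbone <- unclass(model$backbone)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  saveRDS(model, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_uq_model
#' @export
load_uq_model <- function(dir) {
  readRDS(file.path(dir, "weights.rds"))
}
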
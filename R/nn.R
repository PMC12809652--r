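# Minimal 1D-CNN engine: im2col convolutions, batch norm, max pooling,
# dense layers, dropout; reverse-mode gradients written out by hand and
# checked against finite differences in the test suite. Supports
# deterministic weights or mean-field Gaussian variational weights
# (Bayes-by-backprop). All matrix work goes through BLAS.

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

# Build the layer list from a backbone description. Input is (n, L, 1).
nn_init <- function(backbone, input_len, output_dim, seed,
                    variational = FALSE) {
  with_seed(seed, {
    layers <- list()
    L <- input_len; C <- 1L
    add_weights <- function(lay, nr, nc, fan_in) {
      W <- he_init(nr, nc, fan_in)
      if (variational) {
        lay$par <- list(W_mu = W, W_rho = matrix(-5, nr, nc),
                        b_mu = rep(0, nc), b_rho = rep(-5, nc))
      } else {
        lay$par <- list(W = W, b = rep(0, nc))
      }
      lay
    }
    for (cb in backbone$conv_blocks) {
      k <- cb[2]; Cout <- cb[1]; pool <- cb[3]
      if (L < k) stop("input too short for conv kernel", call. = FALSE)
      layers[[length(layers) + 1L]] <-
        add_weights(list(type = "conv", k = k, cin = C, cout = Cout),
                    k * C, Cout, k * C)
      L <- L - k + 1L; C <- Cout
      if (isTRUE(backbone$batchnorm)) {
        layers[[length(layers) + 1L]] <-
          list(type = "batchnorm", ch = C,
               par = list(gamma = rep(1, C), beta = rep(0, C)),
               rm = rep(0, C), rv = rep(1, C), momentum = 0.9, eps = 1e-5)
      }
      layers[[length(layers) + 1L]] <- list(type = "relu")
      if (pool > 1) {
        layers[[length(layers) + 1L]] <- list(type = "maxpool", p = pool)
        L <- L %/% pool
      }
      if (L < 1) stop("backbone pools away all spatial extent", call. = FALSE)
    }
    layers[[length(layers) + 1L]] <- list(type = "flatten", L = L, C = C)
    d <- L * C
    for (db in backbone$dense_blocks) {
      w <- db[1]; rate <- db[2]
      layers[[length(layers) + 1L]] <-
        add_weights(list(type = "dense"), d, w, d)
      layers[[length(layers) + 1L]] <- list(type = "relu")
      if (rate > 0) {
        layers[[length(layers) + 1L]] <- list(type = "dropout", rate = rate)
      }
      d <- w
    }
    layers[[length(layers) + 1L]] <- add_weights(list(type = "dense"), d,
                                                 output_dim, d)
    list(layers = layers, input_len = input_len, output_dim = output_dim,
         variational = variational, prior_sd = backbone$prior_sd %||% 1)
  })
}

# Materialise weights for one forward pass. Deterministic layers return
# their stored weights; variational layers sample W = mu + softplus(rho)*eps.
draw_weights <- function(lay, variational, sample = TRUE) {
  if (!variational || is.null(lay$par$W_mu)) {
    return(list(W = lay$par$W, b = lay$par$b, eps_W = NULL, eps_b = NULL))
  }
  if (sample) {
    eps_W <- matrix(stats::rnorm(length(lay$par$W_mu)), nrow(lay$par$W_mu))
    eps_b <- stats::rnorm(length(lay$par$b_mu))
  } else {
    eps_W <- matrix(0, nrow(lay$par$W_mu), ncol(lay$par$W_mu))
    eps_b <- rep(0, length(lay$par$b_mu))
  }
  list(W = lay$par$W_mu + softplus(lay$par$W_rho) * eps_W,
       b = lay$par$b_mu + softplus(lay$par$b_rho) * eps_b,
       eps_W = eps_W, eps_b = eps_b)
}

# mode: "train" (batch-norm batch stats, per-element dropout),
#       "eval"  (running stats, no dropout),
#       "mc"    (running stats, one shared dropout mask per pass — a single
#                thinned-network hypothesis, row-order independent).
nn_forward <- function(model, X, mode = "eval", keep_cache = FALSE,
                       sample_weights = (mode == "train")) {
  n <- nrow(X)
  A <- array(X, dim = c(n, ncol(X), 1L))
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    lay <- model$layers[[i]]
    cache <- NULL
    if (lay$type == "conv") {
      wt <- draw_weights(lay, model$variational, sample_weights)
      dm <- dim(A); L <- dm[2]; L_out <- L - lay$k + 1L
      idx <- as.vector(outer(seq_len(L_out), 0:(lay$k - 1L), `+`))
      Xc <- A[, idx, , drop = FALSE]
      dim(Xc) <- c(n * L_out, lay$k * lay$cin)
      Z <- Xc %*% wt$W
      Z <- sweep(Z, 2, wt$b, `+`)
      out <- Z; dim(out) <- c(n, L_out, lay$cout)
      cache <- list(Xc = Xc, wt = wt, L_in = L, L_out = L_out)
      A <- out
    } else if (lay$type == "batchnorm") {
      dm <- dim(A); m <- dm[1] * dm[2]
      Xm <- A; dim(Xm) <- c(m, dm[3])
      if (mode == "train") {
        mu <- colMeans(Xm)
        xc <- sweep(Xm, 2, mu)
        va <- colMeans(xc^2)
        model$layers[[i]]$rm <- lay$momentum * lay$rm + (1 - lay$momentum) * mu
        model$layers[[i]]$rv <- lay$momentum * lay$rv + (1 - lay$momentum) * va
      } else {
        mu <- lay$rm; va <- lay$rv
        xc <- sweep(Xm, 2, mu)
      }
      istd <- 1 / sqrt(va + lay$eps)
      xhat <- sweep(xc, 2, istd, `*`)
      out <- sweep(sweep(xhat, 2, lay$par$gamma, `*`), 2, lay$par$beta, `+`)
      dim(out) <- dm
      cache <- list(xhat = xhat, istd = istd, dm = dm)
      A <- out
    } else if (lay$type == "relu") {
      if (keep_cache) cache <- list(mask = A > 0)
      A <- pmax(A, 0)
    } else if (lay$type == "maxpool") {
      dm <- dim(A); p <- lay$p; L_out <- dm[2] %/% p
      L_use <- L_out * p
      out <- A[, seq(1, L_use, by = p), , drop = FALSE]
      arg <- array(1L, dim(out))
      if (p > 1) for (w in 2:p) {
        s <- A[, seq(w, L_use, by = p), , drop = FALSE]
        m <- s > out
        out[m] <- s[m]; arg[m] <- w
      }
      cache <- list(arg = arg, dm = dm, L_use = L_use)
      A <- out
    } else if (lay$type == "flatten") {
      cache <- list(dm = dim(A))
      dim(A) <- c(n, prod(dim(A)[-1]))
    } else if (lay$type == "dense") {
      wt <- draw_weights(lay, model$variational, sample_weights)
      cache <- list(A = A, wt = wt)
      A <- sweep(A %*% wt$W, 2, wt$b, `+`)
    } else if (lay$type == "dropout") {
      if (mode == "train") {
        mask <- (matrix(stats::runif(length(A)), nrow(A)) > lay$rate) /
          (1 - lay$rate)
      } else if (mode == "mc") {
        unit <- (stats::runif(ncol(A)) > lay$rate) / (1 - lay$rate)
        mask <- matrix(unit, nrow(A), ncol(A), byrow = TRUE)
      } else {
        mask <- NULL
      }
      if (!is.null(mask)) A <- A * mask
      cache <- list(mask = mask)
    }
    if (keep_cache) caches[[i]] <- cache
  }
  list(out = A, caches = caches, model = model)
}

# Reverse pass. Returns a list of per-layer gradient lists (named like the
# parameters). For variational layers, gradients w.r.t. mu and rho are
# produced via the reparameterisation trick; the KL term is added by the
# optimiser step (closed form, does not need the data pass).
nn_backward <- function(model, caches, dOut) {
  grads <- vector("list", length(model$layers))
  dA <- dOut
  for (i in rev(seq_along(model$layers))) {
    lay <- model$layers[[i]]
    cache <- caches[[i]]
    if (lay$type == "dense") {
      dW <- crossprod(cache$A, dA)
      db <- colSums(dA)
      dA <- dA %*% t(cache$wt$W)
      grads[[i]] <- weight_grads(lay, model$variational, dW, db, cache$wt)
    } else if (lay$type == "dropout") {
      if (!is.null(cache$mask)) dA <- dA * cache$mask
    } else if (lay$type == "flatten") {
      dim(dA) <- cache$dm
    } else if (lay$type == "maxpool") {
      dm <- cache$dm; p <- lay$p
      dX <- array(0, dm)
      for (w in seq_len(p)) {
        sel <- cache$arg == w
        tmp <- array(0, dim(cache$arg))
        tmp[sel] <- dA[sel]
        idx <- seq(w, cache$L_use, by = p)
        dX[, idx, ] <- dX[, idx, , drop = FALSE] + tmp
      }
      dA <- dX
    } else if (lay$type == "relu") {
      dA <- dA * cache$mask
    } else if (lay$type == "batchnorm") {
      dm <- cache$dm; m <- dm[1] * dm[2]
      dY <- dA; dim(dY) <- c(m, dm[3])
      dgamma <- colSums(dY * cache$xhat)
      dbeta <- colSums(dY)
      dxhat <- sweep(dY, 2, lay$par$gamma, `*`)
      t1 <- sweep(dxhat, 2, colMeans(dxhat))
      t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
      dX <- sweep(t1 - t2, 2, cache$istd, `*`)
      dim(dX) <- dm
      dA <- dX
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
    } else if (lay$type == "conv") {
      dm <- c(nrow(cache$Xc) / cache$L_out, cache$L_out, lay$cout)
      dZ <- dA; dim(dZ) <- c(dm[1] * dm[2], lay$cout)
      dW <- crossprod(cache$Xc, dZ)
      db <- colSums(dZ)
      dXc <- dZ %*% t(cache$wt$W)
      dim(dXc) <- c(dm[1], cache$L_out, lay$k, lay$cin)
      dX <- array(0, c(dm[1], cache$L_in, lay$cin))
      for (j in seq_len(lay$k)) {
        idx <- j:(j + cache$L_out - 1L)
        tap <- dXc[, , j, , drop = FALSE]
        dim(tap) <- c(dm[1], cache$L_out, lay$cin)
        dX[, idx, ] <- dX[, idx, , drop = FALSE] + tap
      }
      dA <- dX
      grads[[i]] <- weight_grads(lay, model$variational, dW, db, cache$wt)
    }
  }
  grads
}

weight_grads <- function(lay, variational, dW, db, wt) {
  if (!variational || is.null(lay$par$W_mu)) return(list(W = dW, b = db))
  sig_W <- softplus(lay$par$W_rho); sig_b <- softplus(lay$par$b_rho)
  list(W_mu = dW,
       W_rho = dW * wt$eps_W * stats::plogis(lay$par$W_rho),
       b_mu = db,
       b_rho = db * wt$eps_b * stats::plogis(lay$par$b_rho))
}

# Closed-form KL(N(mu, sigma^2) || N(0, prior^2)) gradients, scaled by
# `scale` (1 / n_train so the per-epoch KL weight is the standard ELBO one).
add_kl_grads <- function(model, grads, scale) {
  p2 <- model$prior_sd^2
  for (i in seq_along(model$layers)) {
    lay <- model$layers[[i]]
    if (is.null(lay$par$W_mu)) next
    for (nm in c("W", "b")) {
      mu <- lay$par[[paste0(nm, "_mu")]]
      rho <- lay$par[[paste0(nm, "_rho")]]
      sig <- softplus(rho)
      dmu <- scale * mu / p2
      dsig <- scale * (sig / p2 - 1 / sig)
      grads[[i]][[paste0(nm, "_mu")]] <-
        grads[[i]][[paste0(nm, "_mu")]] + dmu
      grads[[i]][[paste0(nm, "_rho")]] <-
        grads[[i]][[paste0(nm, "_rho")]] + dsig * stats::plogis(rho)
    }
  }
  grads
}

## ---- Losses (operate on the network's raw output matrix) -----------------

loss_mse <- function(out, y) {
  r <- out[, 1] - y
  list(loss = mean(r^2), dOut = matrix(2 * r / length(y), ncol = 1))
}

# Squared-error warmup loss for the heteroscedastic head: fits the mean
# output only (sigma-head gradient zeroed). Used for the first phase of
# het_gaussian training, a standard stabilisation for Gaussian NLL.
loss_mean_warmup <- function(out, y) {
  r <- out[, 1] - y
  list(loss = mean(r^2),
       dOut = cbind(2 * r / length(y), rep(0, length(y))))
}

# Gaussian negative log-likelihood with outputs (mean, log-sigma); the
# log-sigma head is squashed to [-6, 6] by a smooth tanh for stability.
loss_gaussian_nll <- function(out, y) {
  mu <- out[, 1]
  s <- 6 * tanh(out[, 2] / 6)
  e2 <- exp(-2 * s)
  r <- y - mu
  n <- length(y)
  dmu <- -r * e2 / n
  ds <- (1 - r^2 * e2) / n
  ds_raw <- ds * (1 - (s / 6)^2)
  list(loss = mean(s + 0.5 * r^2 * e2), dOut = cbind(dmu, ds_raw))
}

make_pinball_loss <- function(taus) {
  force(taus)
  function(out, y) {
    n <- length(y)
    L <- 0
    dOut <- matrix(0, n, length(taus))
    for (j in seq_along(taus)) {
      r <- y - out[, j]
      L <- L + mean(pmax(taus[j] * r, (taus[j] - 1) * r))
      dOut[, j] <- ifelse(r > 0, -taus[j], 1 - taus[j]) / n
    }
    list(loss = L, dOut = dOut)
  }
}

## ---- Adam ----------------------------------------------------------------

adam_init <- function(model) {
  lapply(model$layers, function(lay) {
    if (is.null(lay$par)) return(NULL)
    lapply(lay$par, function(p) list(m = p * 0, v = p * 0))
  })
}

adam_step <- function(model, opt, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(model$layers)) {
    if (is.null(grads[[i]])) next
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      st <- opt[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      model$layers[[i]]$par[[nm]] <- model$layers[[i]]$par[[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
      opt[[i]][[nm]] <- st
    }
  }
  list(model = model, opt = opt)
}

## ---- Training loop -------------------------------------------------------

# Training loop: Adam with two-step learning-rate decay, optional
# validation-based checkpointing (the returned model carries the weights
# with the best validation loss) and early stopping on `patience` epochs
# without improvement.
nn_train <- function(model, X, y, loss_fn, epochs, batch_size, lr, seed,
                     kl_scale = 0, verbose = FALSE,
                     X_val = NULL, y_val = NULL, patience = Inf) {
  n <- nrow(X)
  opt <- adam_init(model)
  t <- 0L
  lr0 <- lr
  best <- list(loss = Inf, model = model, since = 0L)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      # step decay: 10x total reduction over the run, in two steps
      lr <- lr0 * if (ep > 0.75 * epochs) 0.1 else
        if (ep > 0.5 * epochs) sqrt(0.1) else 1
      ord <- sample.int(n)
      for (b in seq(1, n, by = batch_size)) {
        idx <- ord[b:min(b + batch_size - 1L, n)]
        fw <- nn_forward(model, X[idx, , drop = FALSE], mode = "train",
                         keep_cache = TRUE)
        model <- fw$model  # batch-norm running stats
        ls <- loss_fn(fw$out, y[idx])
        if (!is.finite(ls$loss)) {
          stop(sprintf("training failure: non-finite loss at epoch %d, step %d (lr = %g)",
                       ep, t + 1L, lr), call. = FALSE)
        }
        grads <- nn_backward(model, fw$caches, ls$dOut)
        if (kl_scale > 0) grads <- add_kl_grads(model, grads, kl_scale)
        t <- t + 1L
        upd <- adam_step(model, opt, grads, lr, t)
        model <- upd$model; opt <- upd$opt
      }
      if (!is.null(X_val)) {
        out <- nn_forward(model, X_val, mode = "eval",
                          sample_weights = FALSE)$out
        vl <- loss_fn(out, y_val)$loss
        if (is.finite(vl) && vl < best$loss) {
          best$loss <- vl; best$model <- model; best$since <- 0L
        } else {
          best$since <- best$since + 1L
          if (best$since >= patience) break
        }
      }
      if (verbose && ep %% 10 == 0) {
        message(sprintf("epoch %d: batch loss %.4f", ep, ls$loss))
      }
    }
  })
  if (!is.null(X_val) && is.finite(best$loss)) best$model else model
}
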
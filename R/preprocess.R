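#' Preprocessing configuration
#'
#' Holds the signal-chain parameters: Savitzky-Golay window/order, the
#' uniform target wavenumber grid, and the wavelet depth used by common-mode
#' rejection. Defaults follow the standard SERDS chain for this task:
#' window 11 / order 2, grid 350-2000 cm^-1 at 1 cm^-1. The target grid is
#' half-open `[start, stop)`, which yields exactly 1650 channels at the
#' defaults.
#'
#' @param sg_window Savitzky-Golay window length (odd, > `sg_polyorder`).
#' @param sg_polyorder Savitzky-Golay polynomial order.
#' @param grid_start,grid_stop,grid_step Target grid (cm^-1).
#' @param cmr_levels Wavelet decomposition depth for the common-mode
#'   baseline estimate (approximation scale `2^cmr_levels` points).
#' @return A validated `preprocess_config` list.
#' @export
preprocess_config <- function(sg_window = 11, sg_polyorder = 2,
                              grid_start = 350, grid_stop = 2000,
                              grid_step = 1, cmr_levels = 6) {
  check_number(sg_window, "sg_window", min = 3, integer = TRUE)
  check_number(sg_polyorder, "sg_polyorder", min = 0, integer = TRUE)
  if (sg_window %% 2 == 0) stop_field("sg_window", "must be odd")
  if (sg_window <= sg_polyorder) {
    stop_field("sg_window", "must exceed sg_polyorder")
  }
  check_number(grid_step, "grid_step", min = 1e-9)
  if (grid_stop <= grid_start) stop_field("grid_stop", "must exceed grid_start")
  check_number(cmr_levels, "cmr_levels", min = 1, integer = TRUE)
  structure(list(sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 grid_start = grid_start, grid_stop = grid_stop,
                 grid_step = grid_step, cmr_levels = as.integer(cmr_levels)),
            class = "preprocess_config")
}

## ---- Daubechies-4 discrete wavelet transform (periodic) -----------------

d4_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- c(h[4], -h[3], h[2], -h[1])
  list(h = h, g = g)
}

dwt_step <- function(x) {
  f <- d4_filters()
  n <- length(x)
  i <- seq(1, n, by = 2)
  pos <- cbind(i, i %% n + 1, (i + 1) %% n + 1, (i + 2) %% n + 1)
  xm <- matrix(x[pos], ncol = 4)
  list(a = drop(xm %*% f$h), d = drop(xm %*% f$g))
}

idwt_step <- function(a, d) {
  f <- d4_filters()
  n <- 2L * length(a)
  i <- seq(1, n, by = 2)
  pos <- cbind(i, i %% n + 1, (i + 1) %% n + 1, (i + 2) %% n + 1)
  x <- numeric(n)
  for (k in 1:4) {
    idx <- pos[, k]
    x[idx] <- x[idx] + f$h[k] * a + f$g[k] * d
  }
  x
}

# One pass of the multi-level D4 approximation: decompose `levels` times,
# zero all detail coefficients, reconstruct. The signal is reflected at
# both ends (by one approximation scale) so the periodic transform sees no
# boundary jump, then cropped.
wavelet_approx <- function(x, levels) {
  n <- length(x)
  block <- 2^levels
  # antisymmetric (point-reflection) padding: continuous in value and slope
  kl <- seq(min(block + 1L, n), 2L)
  kr <- seq(n - 1L, max(n - block, 1L))
  left <- 2 * x[1] - x[kl]
  right <- 2 * x[n] - x[kr]
  xp <- c(left, x, right)
  pad <- (block - length(xp) %% block) %% block
  if (pad > 0) xp <- c(xp, xp[seq(length(xp), length(xp) - pad + 1)])
  # detrend so the periodic transform sees no wrap-around jump; the linear
  # part is restored afterwards (it belongs to the smooth background)
  np <- length(xp)
  slope <- (xp[np] - xp[1]) / (np - 1)
  line <- xp[1] + slope * (seq_len(np) - 1)
  a <- xp - line
  for (l in seq_len(levels)) a <- dwt_step(a)$a
  for (l in seq_len(levels)) a <- idwt_step(a, numeric(length(a)))
  (a + line)[length(left) + seq_len(n)]
}

# Smooth background estimate: iterated peak-masked wavelet approximation.
wavelet_baseline <- function(x, levels, n_iter = 4) {
  n <- length(x)
  if (2^levels * 4 > n) {
    stop(sprintf("cmr_levels = %d too deep for vector of length %d",
                 levels, n), call. = FALSE)
  }
  b <- wavelet_approx(x, levels)
  for (i in seq_len(n_iter - 1)) {
    # flag channels rising clearly above the current approximation (narrow
    # Raman-scale peaks), widen the runs to catch peak tails, and bridge
    # them by interpolation from the surrounding background before
    # re-approximating; misflagged smooth regions are harmless because
    # interpolating across them reproduces the signal
    margin <- stats::mad(x - b)
    mask <- (x - b) > margin
    mask <- stats::filter(as.numeric(mask), rep(1, 15), sides = 2) > 0
    mask[is.na(mask)] <- FALSE
    work <- x
    if (any(mask) && !all(mask)) {
      work[mask] <- stats::approx(which(!mask), x[!mask],
                                  xout = which(mask), rule = 2)$y
    }
    b <- wavelet_approx(work, levels)
  }
  b
}

## ---- Operations ----------------------------------------------------------

#' Multiplicative scatter correction
#'
#' Fits each spectrum `x` against a reference by ordinary least squares,
#' `x ~ a + b * ref`, and returns `(x - a) / b`, removing additive and
#' multiplicative scattering artifacts. With `reference = "mean"` the mean
#' spectrum, normalised to unit mean intensity, is used — the normalisation
#' makes the correction invariant to a global intensity scale. An explicit
#' reference spectrum is used as-is (so the reference maps to itself).
#'
#' @param spectra List of [spectrum()] objects on one common axis.
#' @param reference `"mean"` or a [spectrum()].
#' @param b_tol Slope magnitude below which a spectrum is reported as
#'   degenerate (it carries no signal proportional to the reference).
#' @return List of corrected spectra.
#' @export
msc_correct <- function(spectra, reference = "mean", b_tol = 1e-8) {
  if (!length(spectra)) stop("msc_correct: empty spectra list", call. = FALSE)
  for (s in spectra) check_common_axis(spectra[[1]], s)
  if (identical(reference, "mean")) {
    if (length(spectra) < 1) stop("need >= 1 spectra for mean reference", call. = FALSE)
    m <- rowMeans(vapply(spectra, function(s) s$intensity,
                         numeric(length(spectra[[1]]$intensity))))
    ref <- m / mean(m)
  } else if (inherits(reference, "spectrum")) {
    check_common_axis(spectra[[1]], reference, "spectrum and reference")
    ref <- reference$intensity
  } else {
    stop_field("reference", "must be \"mean\" or a spectrum")
  }
  vr <- stats::var(ref)
  if (vr < 1e-24) stop("msc_correct: reference is constant", call. = FALSE)
  lapply(seq_along(spectra), function(i) {
    x <- spectra[[i]]$intensity
    b <- stats::cov(ref, x) / vr
    a <- mean(x) - b * mean(ref)
    if (abs(b) < b_tol) {
      id <- spectra[[i]]$meta$sample_id %||% sprintf("spectrum %d", i)
      stop(sprintf("msc_correct: degenerate spectrum (%s): |b| = %.3g < %g",
                   id, abs(b), b_tol), call. = FALSE)
    }
    spectrum(spectra[[i]]$axis, (x - a) / b, spectra[[i]]$meta)
  })
}

#' Average replicates and normalise by integration time
#'
#' For each (grid position, laser) replicate set: optionally apply MSC
#' across the replicates (reference: unit-mean mean spectrum), then take the
#' arithmetic mean and divide by the integration time.
#'
#' @param sample A `raw_sample`.
#' @param msc Apply MSC across each replicate set before averaging.
#' @return A list over grid positions; each element a list of two
#'   [spectrum()] objects (lasers 1 and 2).
#' @export
average_replicates <- function(sample, msc = TRUE) {
  stopifnot(inherits(sample, "raw_sample"))
  d <- dim(sample$measurements)
  if (d[3] < 1) stop("average_replicates: empty replicate set", call. = FALSE)
  lapply(seq_len(d[1]), function(g) {
    lapply(1:2, function(l) {
      reps <- lapply(seq_len(d[3]), function(r) {
        spectrum(sample$axis, sample$measurements[g, l, r, ],
                 meta = list(sample_id = sample$sample_id))
      })
      if (msc) reps <- msc_correct(reps, "mean")
      m <- rowMeans(vapply(reps, function(s) s$intensity,
                           numeric(length(sample$axis))))
      spectrum(sample$axis, m / sample$integration_time,
               meta = list(sample_id = sample$sample_id, grid = g, laser = l,
                           stage = "replicate_average"))
    })
  })
}

#' Common-mode rejection of the shared background
#'
#' Estimates each channel's smooth background by a multi-level wavelet
#' approximation (Daubechies-4, detail coefficients zeroed up to
#' `cmr_levels`), regresses the laser-2 background on the laser-1 background
#' (scale + offset), and subtracts the fitted shared component from both
#' channels. Narrow Raman-scale features live in the detail coefficients and
#' are preserved.
#'
#' @param s1,s2 [spectrum()] objects on a common axis (lasers 1 and 2).
#' @param config A [preprocess_config()] (uses `cmr_levels`).
#' @return List with corrected `s1` and `s2`.
#' @export
common_mode_reject <- function(s1, s2, config = preprocess_config()) {
  check_common_axis(s1, s2)
  b1 <- wavelet_baseline(s1$intensity, config$cmr_levels)
  b2 <- wavelet_baseline(s2$intensity, config$cmr_levels)
  v1 <- stats::var(b1)
  if (v1 > 1e-12 * (1 + mean(b1)^2)) {
    beta <- stats::cov(b1, b2) / v1
    alpha <- mean(b2) - beta * mean(b1)
    shared2 <- alpha + beta * b1
  } else {
    shared2 <- b2  # background too flat to align; remove each side's own
  }
  list(s1 = spectrum(s1$axis, s1$intensity - b1,
                     utils::modifyList(s1$meta, list(stage = "cmr"))),
       s2 = spectrum(s2$axis, s2$intensity - shared2,
                     utils::modifyList(s2$meta, list(stage = "cmr"))))
}

#' SERDS difference spectrum
#'
#' Elementwise `laser2 - laser1`. Raman bands shift with the excitation
#' wavelength while fluorescence does not, so the shared fluorescence
#' background cancels and a derivative-like Raman signature remains.
#'
#' @param s1,s2 [spectrum()] objects on a common axis.
#' @export
serds_difference <- function(s1, s2) {
  check_common_axis(s1, s2)
  spectrum(s1$axis, s2$intensity - s1$intensity,
           utils::modifyList(s1$meta, list(stage = "serds_difference")))
}

#' Pointwise mean over grid-position spectra
#'
#' @param spectra Nonempty list of [spectrum()] objects on a common axis.
#' @export
average_grid <- function(spectra) {
  if (!length(spectra)) stop("average_grid: empty spectrum list", call. = FALSE)
  for (s in spectra) check_common_axis(spectra[[1]], s)
  m <- rowMeans(vapply(spectra, function(s) s$intensity,
                       numeric(length(spectra[[1]]$intensity))))
  spectrum(spectra[[1]]$axis, m,
           utils::modifyList(spectra[[1]]$meta, list(stage = "grid_average")))
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing via [signal::sgolayfilt()].
#' Edge policy: asymmetric full-window polynomial fits at the ends (the
#' filter's transient matrices), so every output point is a degree-
#' `polyorder` local fit; polynomials of degree <= `polyorder` are
#' reproduced exactly everywhere.
#'
#' @param s A [spectrum()].
#' @param window Odd window length, > `polyorder`, <= spectrum length.
#' @param polyorder Polynomial order.
#' @export
savgol_smooth <- function(s, window = 11, polyorder = 2) {
  check_number(window, "window", min = 3, integer = TRUE)
  check_number(polyorder, "polyorder", min = 0, integer = TRUE)
  if (window %% 2 == 0) stop_field("window", "must be odd")
  if (window <= polyorder) stop_field("window", "must exceed polyorder")
  if (window > length(s$intensity)) {
    stop_field("window", "must not exceed spectrum length")
  }
  y <- signal::sgolayfilt(s$intensity, p = polyorder, n = window)
  spectrum(s$axis, y, utils::modifyList(s$meta, list(stage = "savgol")))
}

#' Resample onto the uniform model grid
#'
#' Linear interpolation onto the half-open grid `[grid_start, grid_stop)` at
#' `grid_step` — exactly 1650 channels at the defaults (350-2000 cm^-1,
#' 1 cm^-1 step).
#'
#' @param s A [spectrum()] whose axis covers the target grid.
#' @param config A [preprocess_config()].
#' @export
resample_uniform <- function(s, config = preprocess_config()) {
  n <- floor((config$grid_stop - config$grid_start) / config$grid_step + 1e-9)
  grid <- config$grid_start + config$grid_step * (seq_len(n) - 1)
  if (min(s$axis) > grid[1] + 1e-9 || max(s$axis) < grid[n] - 1e-9) {
    stop(sprintf("input axis [%.1f, %.1f] does not cover target grid [%.1f, %.1f]",
                 min(s$axis), max(s$axis), grid[1], grid[n]), call. = FALSE)
  }
  y <- stats::approx(s$axis, s$intensity, xout = grid)$y
  spectrum(grid, y, utils::modifyList(s$meta, list(stage = "resampled")))
}

#' Full preprocessing chain for one sample
#'
#' MSC across each replicate set, replicate averaging + integration-time
#' normalisation, per-grid-position common-mode rejection, SERDS
#' differencing (laser2 - laser1), grid averaging, Savitzky-Golay smoothing,
#' and resampling onto the uniform model grid — in that fixed order.
#'
#' @param sample A `raw_sample`.
#' @param config A [preprocess_config()].
#' @return The single model-input [spectrum()].
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_config(n_samples = 1, grid_shape = c(1, 1),
#'                                         n_replicates = 2, seed = 3))
#' s <- preprocess_sample(ds$samples[[1]])
#' length(s$intensity)  # 1650 at default grid
preprocess_sample <- function(sample, config = preprocess_config()) {
  run_stage_fn <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }
  per_grid <- run_stage_fn("average_replicates", average_replicates(sample))
  diffs <- run_stage_fn("common_mode_rejection + serds_difference", {
    lapply(per_grid, function(pair) {
      cm <- common_mode_reject(pair[[1]], pair[[2]], config)
      serds_difference(cm$s1, cm$s2)
    })
  })
  avg <- run_stage_fn("average_grid", average_grid(diffs))
  sm <- run_stage_fn("savgol_smooth",
                     savgol_smooth(avg, config$sg_window, config$sg_polyorder))
  out <- run_stage_fn("resample_uniform", resample_uniform(sm, config))
  out$meta <- utils::modifyList(out$meta,
                                list(sample_id = sample$sample_id,
                                     stage = "preprocessed"))
  out
}

#' Preprocess a whole dataset into a model matrix
#'
#' @param dataset A `serds_dataset`.
#' @param config A [preprocess_config()].
#' @return List with `x` (samples x channels matrix), `y` (SOC labels),
#'   `axis` and `sample_ids`.
#' @export
preprocess_dataset <- function(dataset, config = preprocess_config()) {
  stopifnot(inherits(dataset, "serds_dataset"))
  specs <- lapply(dataset$samples, preprocess_sample, config = config)
  x <- do.call(rbind, lapply(specs, function(s) s$intensity))
  list(x = x,
       y = vapply(dataset$samples, function(s) s$true_soc, numeric(1)),
       axis = specs[[1]]$axis,
       sample_ids = vapply(dataset$samples, function(s) s$sample_id, character(1)))
}
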
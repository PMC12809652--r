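#' Configuration for the synthetic dual-laser SERDS generator
#'
#' The generator emulates the statistical structure of dual-laser SERDS
#' measurements of soil: a dominant smooth fluorescence background shared (up
#' to a small perturbation) by the two closely gapped laser channels, Raman
#' bands that shift with the excitation wavelength, SOC-dependent organic
#' band amplitudes, multiplicative/additive scattering variation, replicate
#' noise, a per-sample albedo-like reflectance confounder, and
#' heteroscedastic label-conditional noise.
#'
#' Default sizes are desk-scale (3x3 grid, 3 replicates); the full
#' acquisition protocol (10x10 grid, 15 replicates per laser, 200 ms
#' integration) is available as [full_scale_config()].
#'
#' @param n_samples Number of soil samples to simulate.
#' @param soc_range Range (min, max) of SOC labels in % by mass.
#' @param grid_shape Measurement grid (rows, cols) per sample.
#' @param n_replicates Replicates per laser per grid position.
#' @param laser_shift Wavenumber gap (cm^-1) between the two excitations.
#' @param fluorescence_amplitude_ratio Peak fluorescence intensity relative to
#'   the nominal unit Raman band amplitude; must be >= 1 unless exactly 0
#'   (fluorescence disabled).
#' @param heteroscedastic_coeffs `c(c0, c1)` of the label-noise model
#'   `sd(soc) = c0 + c1 * soc` (% SOC).
#' @param albedo_sd Log-scale SD of the per-sample multiplicative
#'   reflectance factor (log-normal, median 1).
#' @param noise_sd SD of additive replicate-level intensity noise (counts).
#' @param dark_offset Constant additive detector offset (counts).
#' @param integration_time Integration time in seconds.
#' @param native_range Native wavenumber span (cm^-1) of raw measurements;
#'   must cover the preprocessing target grid.
#' @param native_step Native axis step (cm^-1).
#' @param seed Integer seed; fully determines the generated dataset.
#' @return A validated `synthetic_config` list.
#' @seealso [generate_dataset()], [soc_to_raman()], [heteroscedastic_sd()]
#' @export
synthetic_config <- function(n_samples = 300,
                             soc_range = c(0.28, 6.95),
                             grid_shape = c(3, 3),
                             n_replicates = 3,
                             laser_shift = 10,
                             fluorescence_amplitude_ratio = 10,
                             heteroscedastic_coeffs = c(0.1, 0.05),
                             albedo_sd = 0.2,
                             noise_sd = 0.02,
                             dark_offset = 0.05,
                             integration_time = 0.2,
                             native_range = c(300, 2050),
                             native_step = 2,
                             seed = 1) {
  check_number(n_samples, "n_samples", min = 1, integer = TRUE)
  if (length(soc_range) != 2 || soc_range[1] <= 0 || soc_range[2] >= 100 ||
      soc_range[1] >= soc_range[2]) {
    stop_field("soc_range", "must be (min, max) within (0, 100)")
  }
  if (length(grid_shape) != 2 || any(grid_shape < 1) ||
      any(grid_shape != round(grid_shape))) {
    stop_field("grid_shape", "must be two positive integers")
  }
  check_number(n_replicates, "n_replicates", min = 1, integer = TRUE)
  check_number(laser_shift, "laser_shift", min = 0.5)
  if (fluorescence_amplitude_ratio != 0) {
    check_number(fluorescence_amplitude_ratio, "fluorescence_amplitude_ratio", min = 1)
  }
  if (length(heteroscedastic_coeffs) != 2) {
    stop_field("heteroscedastic_coeffs", "must be c(c0, c1)")
  }
  sds <- heteroscedastic_sd(soc_range, heteroscedastic_coeffs)
  if (any(sds <= 0)) {
    stop_field("heteroscedastic_coeffs", "must yield sd > 0 over soc_range")
  }
  check_number(albedo_sd, "albedo_sd", min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(integration_time, "integration_time", min = 1e-6)
  check_number(native_step, "native_step", min = 1e-3)
  if (length(native_range) != 2 || native_range[1] >= native_range[2]) {
    stop_field("native_range", "must be (min, max) with min < max")
  }
  check_number(seed, "seed", integer = TRUE)
  structure(list(
    n_samples = as.integer(n_samples), soc_range = as.numeric(soc_range),
    grid_shape = as.integer(grid_shape), n_replicates = as.integer(n_replicates),
    laser_shift = laser_shift,
    fluorescence_amplitude_ratio = fluorescence_amplitude_ratio,
    heteroscedastic_coeffs = as.numeric(heteroscedastic_coeffs),
    albedo_sd = albedo_sd, noise_sd = noise_sd, dark_offset = dark_offset,
    integration_time = integration_time,
    native_range = as.numeric(native_range), native_step = native_step,
    seed = as.integer(seed)), class = "synthetic_config")
}

#' Full acquisition-scale generator configuration
#'
#' Preset matching the full measurement protocol: a 10x10 grid, 15 replicates
#' per laser per position (3000 measurements per sample) and 200 ms
#' integration time.
#'
#' @param ... Overrides passed to [synthetic_config()].
#' @export
full_scale_config <- function(...) {
  args <- list(...)
  defaults <- list(grid_shape = c(10, 10), n_replicates = 15,
                   integration_time = 0.2)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

# SOC-dependent organic Raman bands: center (cm^-1), width (cm^-1 SD), and
# maximum amplitude. Stand-ins for organic-matter vibrational bands
# (aromatic ring breathing, carbohydrate C-O, disordered-carbon D band, CH2
# deformation, aromatic C=C G band, amide I); not calibrated cross-sections.
soc_band_table <- function() {
  data.frame(
    center = c(1003, 1090, 1340, 1450, 1600, 1660),
    width  = c(6, 12, 25, 12, 20, 14),
    amax   = c(0.6, 0.5, 1.0, 0.7, 1.0, 0.5)
  )
}

# Mineral bands independent of SOC (quartz-like, carbonate-like); these are
# Raman features too, so they shift with the excitation laser.
mineral_band_table <- function() {
  data.frame(center = c(465, 1085), width = c(8, 10), amax = c(0.3, 0.2))
}

#' Band amplitude as a function of SOC
#'
#' Amplitudes follow a saturating (Michaelis-Menten-like) law
#' `a(soc) = amax * soc / (soc + K)` with half-saturation `K = 3` % SOC:
#' monotone increasing in SOC but deliberately nonlinear.
#'
#' @param soc SOC in % (vectorised).
#' @param amax Maximum band amplitude.
#' @param K Half-saturation constant (% SOC).
#' @export
soc_band_amplitude <- function(soc, amax = 1, K = 3) {
  amax * soc / (soc + K)
}

#' SOC-dependent Raman band contribution
#'
#' Sum of fixed Gaussian-shaped organic bands (see `soc_band_table`) whose
#' amplitudes are monotone in SOC via [soc_band_amplitude()]. At `soc = 0`
#' the contribution is identically zero.
#'
#' @param soc SOC in % (scalar, >= 0).
#' @param axis Wavenumber axis (cm^-1).
#' @return Intensity vector on `axis`.
#' @export
soc_to_raman <- function(soc, axis) {
  check_number(soc, "soc", min = 0)
  bands <- soc_band_table()
  out <- numeric(length(axis))
  for (i in seq_len(nrow(bands))) {
    a <- soc_band_amplitude(soc, bands$amax[i])
    out <- out + a * exp(-0.5 * ((axis - bands$center[i]) / bands$width[i])^2)
  }
  out
}

mineral_raman <- function(axis) {
  bands <- mineral_band_table()
  out <- numeric(length(axis))
  for (i in seq_len(nrow(bands))) {
    out <- out + bands$amax[i] *
      exp(-0.5 * ((axis - bands$center[i]) / bands$width[i])^2)
  }
  out
}

#' Heteroscedastic label-noise standard deviation
#'
#' Linear noise model `sd(soc) = c0 + c1 * soc` (% SOC), monotone in SOC for
#' `c1 >= 0`. Used to perturb the spectrum-label consistency of generated
#' samples.
#'
#' @param soc SOC in % (vectorised).
#' @param coeffs `c(c0, c1)`.
#' @export
heteroscedastic_sd <- function(soc, coeffs = c(0.1, 0.05)) {
  if (length(coeffs) != 2) stop_field("coeffs", "must be c(c0, c1)")
  coeffs[1] + coeffs[2] * soc
}

# Fluorescence shape parameters derived deterministically from the latent
# SOC via low-discrepancy scrambling (golden-ratio multiples mod 1): the
# parameters vary erratically from sample to sample — so the background
# carries no usable smooth information about SOC — yet two samples with
# equal SOC share an identical background, making the clean (zero-noise,
# unit-albedo) measurement a function of SOC alone.
fluorescence_params <- function(soc_latent) {
  phi <- (sqrt(5) - 1) / 2
  u <- (soc_latent * phi * 10^(1:5)) %% 1
  list(center = 700 + 700 * u[1], width = 250 + 200 * u[2],
       slope = 2 * u[3] - 1, curv = 2 * u[4] - 1, asym = 0.5 + u[5])
}

# Per-sample fluorescence background: low-order polynomial + broad Gaussian
# hump, peak-normalised, scaled by the configured fluorescence:Raman ratio.
# Laser 2 sees the same shape with a small multiplicative tilt so that
# common-mode rejection has a realistic (non-identical) shared background.
make_fluorescence <- function(axis, params, ratio, tilt = 0.02) {
  t <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
  shape <- 0.6 + 0.25 * params$slope * t + 0.15 * params$curv * t^2 +
    1.5 * exp(-0.5 * ((axis - params$center) / params$width)^2)
  shape <- pmax(shape, 0)
  base <- ratio * shape / max(shape)
  list(l1 = base, l2 = base * (1 + tilt * params$asym * t))
}

# Noiseless per-laser intensities for a given latent SOC: fluorescence
# (shared across lasers up to a small tilt) plus Raman, where laser 2's
# Raman component is laser 1's translated by the laser gap.
clean_channels <- function(soc_latent, axis, config) {
  fl <- make_fluorescence(axis, fluorescence_params(soc_latent),
                          config$fluorescence_amplitude_ratio)
  raman1 <- soc_to_raman(soc_latent, axis) + mineral_raman(axis)
  raman2 <- soc_to_raman(soc_latent, axis - config$laser_shift) +
    mineral_raman(axis - config$laser_shift)
  list(fl$l1 + raman1, fl$l2 + raman2)
}

#' Generate a synthetic SERDS dataset
#'
#' Draws `n_samples` soil samples. For each: a latent SOC driving the
#' spectrum is drawn uniformly over `soc_range`; the recorded label adds
#' heteroscedastic noise `N(0, sd(soc)^2)` (clamped into range); a per-sample
#' albedo factor is drawn log-normally; each measurement is
#' `integration_time * albedo * (fluorescence + raman) + dark_offset +
#' replicate noise`. Laser 2's Raman component is the laser-1 component
#' translated by `laser_shift` on the wavenumber axis while its fluorescence
#' is near-identical — the SERDS premise that differencing exploits.
#'
#' @param config A [synthetic_config()].
#' @return A `serds_dataset`: list of `raw_sample` objects plus the config.
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_config(n_samples = 2, seed = 7))
#' ds$samples[[1]]$true_soc
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, config)
  }
  axis <- seq(config$native_range[1], config$native_range[2],
              by = config$native_step)
  n_grid <- prod(config$grid_shape)
  n_rep <- config$n_replicates
  n_pts <- length(axis)

  samples <- with_seed(config$seed, {
    lapply(seq_len(config$n_samples), function(i) {
      soc_latent <- stats::runif(1, config$soc_range[1], config$soc_range[2])
      sdn <- heteroscedastic_sd(soc_latent, config$heteroscedastic_coeffs)
      true_soc <- min(max(soc_latent + stats::rnorm(1, 0, sdn),
                          config$soc_range[1]), config$soc_range[2])
      albedo <- exp(stats::rnorm(1, 0, config$albedo_sd))
      clean <- clean_channels(soc_latent, axis, config)

      meas <- array(NA_real_, dim = c(n_grid, 2, n_rep, n_pts))
      for (g in seq_len(n_grid)) {
        for (l in 1:2) {
          base <- config$integration_time * albedo * clean[[l]] +
            config$dark_offset
          noise <- matrix(stats::rnorm(n_rep * n_pts, 0, config$noise_sd),
                          nrow = n_rep)
          meas[g, l, , ] <- matrix(base, nrow = n_rep, ncol = n_pts,
                                   byrow = TRUE) + noise
        }
      }
      structure(list(sample_id = sprintf("S%04d", i), true_soc = true_soc,
                     soc_latent = soc_latent, albedo = albedo,
                     measurements = meas, axis = axis,
                     integration_time = config$integration_time),
                class = "raw_sample")
    })
  })
  structure(list(samples = samples, config = config, axis = axis),
            class = "serds_dataset")
}

#' @export
print.serds_dataset <- function(x, ...) {
  cat(sprintf("<serds_dataset> %d samples, grid %dx%d, %d replicates/laser, %d native channels\n",
              length(x$samples), x$config$grid_shape[1], x$config$grid_shape[2],
              x$config$n_replicates, length(x$axis)))
  invisible(x)
}

#' Simulate a heteroscedastic regression benchmark
#'
#' A spectral toy problem with known input-dependent noise for validating
#' uncertainty heads: a latent scalar `x1 ~ U(range)` scales a fixed
#' Gaussian spectral profile; the response is `y = x1 + N(0, (c0 +
#' c1*|x1|)^2)`. The true conditional SD is returned so recovery of the
#' noise law can be scored directly.
#'
#' @param n Number of observations.
#' @param n_channels Spectral input length.
#' @param coeffs `c(c0, c1)` of the noise law `sd = c0 + c1 * |x1|`.
#' @param range Range of the latent scalar.
#' @param seed Integer seed.
#' @return List with `x` (n x n_channels matrix), `y`, `sigma_true`, `x1`.
#' @export
simulate_het_benchmark <- function(n, n_channels = 32, coeffs = c(0.1, 0.5),
                                   range = c(-2, 2), seed = 1) {
  with_seed(seed, {
    x1 <- stats::runif(n, range[1], range[2])
    ch <- seq_len(n_channels)
    profile <- exp(-0.5 * ((ch - n_channels / 3) / (n_channels / 10))^2)
    x <- outer(x1, profile) +
      matrix(stats::rnorm(n * n_channels, 0, 0.01), nrow = n)
    sigma_true <- coeffs[1] + coeffs[2] * abs(x1)
    y <- x1 + stats::rnorm(n, 0, sigma_true)
    list(x = x, y = y, sigma_true = sigma_true, x1 = x1)
  })
}
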
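make_spec <- function(int, axis = seq_along(int)) spectrum(axis, int)

test_that("MSC recovers affine distortions and maps the reference to itself", {
  axis <- 1:100
  ref <- spectrum(axis, sin(axis / 7) + 2)
  x <- spectrum(axis, 2 * ref$intensity + 3)
  out <- msc_correct(list(ref, x), reference = ref)
  expect_equal(out[[1]]$intensity, ref$intensity, tolerance = 1e-12)
  expect_equal(out[[2]]$intensity, ref$intensity, tolerance = 1e-12)
})

test_that("MSC is idempotent against a fixed reference", {
  axis <- 1:80
  ref <- spectrum(axis, cos(axis / 9) + 2)
  x <- spectrum(axis, 1.7 * ref$intensity - 0.4 + 0.01 * sin(axis))
  once <- msc_correct(list(x), reference = ref)
  twice <- msc_correct(once, reference = ref)
  expect_equal(twice[[1]]$intensity, once[[1]]$intensity, tolerance = 1e-10)
})

test_that("MSC rejects degenerate spectra by name", {
  axis <- 1:50
  ref <- spectrum(axis, sin(axis / 5))
  flat <- spectrum(axis, rep(2, 50), meta = list(sample_id = "FLAT1"))
  expect_error(msc_correct(list(flat), reference = ref), "FLAT1")
})

test_that("replicate averaging divides by the integration time", {
  axis <- seq(300, 2050, by = 50)
  v <- sin(axis / 100) + 2
  meas <- array(0, dim = c(1, 2, 2, length(axis)))
  meas[1, 1, 1, ] <- v;     meas[1, 1, 2, ] <- 3 * v
  meas[1, 2, 1, ] <- v;     meas[1, 2, 2, ] <- v
  raw <- structure(list(sample_id = "T", true_soc = 1, measurements = meas,
                        axis = axis, integration_time = 0.2),
                   class = "raw_sample")
  out <- average_replicates(raw, msc = FALSE)
  expect_equal(out[[1]][[1]]$intensity, 2 * v / 0.2, tolerance = 1e-12)
  expect_equal(out[[1]][[2]]$intensity, v / 0.2, tolerance = 1e-12)
  # empty replicate set is rejected
  raw$measurements <- meas[, , 0, , drop = FALSE]
  expect_error(average_replicates(raw), "empty replicate")
})

test_that("common-mode rejection removes shared smooth background, keeps narrow peaks", {
  axis <- seq(350, 2000, by = 2)
  bg <- 50 * exp(-((axis - 1100) / 500)^2) + 10 + 0.004 * axis
  peak <- 3 * exp(-0.5 * ((axis - 1340) / 10)^2)
  cfg <- preprocess_config(cmr_levels = 6)
  # fully shared background -> both residuals ~ 0 relative to input scale
  out <- common_mode_reject(spectrum(axis, bg), spectrum(axis, bg), cfg)
  expect_lt(max(abs(out$s1$intensity)), 0.02 * max(bg))
  expect_lt(max(abs(out$s2$intensity)), 0.02 * max(bg))
  # narrow peak survives within 10%
  out <- common_mode_reject(spectrum(axis, bg + peak), spectrum(axis, bg), cfg)
  got <- max(out$s1$intensity[abs(axis - 1340) < 30])
  expect_equal(got, 3, tolerance = 0.1)
  # zero background: outputs equal inputs within tolerance
  out <- common_mode_reject(spectrum(axis, peak), spectrum(axis, 0 * peak), cfg)
  expect_equal(out$s1$intensity, peak, tolerance = 0.1)
  # too-deep decomposition is rejected
  expect_error(common_mode_reject(spectrum(1:32, rnorm(32)),
                                  spectrum(1:32, rnorm(32)),
                                  preprocess_config(cmr_levels = 6)),
               "cmr_levels")
})

test_that("SERDS differencing is elementwise laser2 - laser1 and antisymmetric", {
  s1 <- make_spec(c(1, 2, 3)); s2 <- make_spec(c(2, 2, 2))
  expect_equal(serds_difference(s1, s2)$intensity, c(1, 0, -1))
  expect_equal(serds_difference(s1, s1)$intensity, c(0, 0, 0))
  expect_equal(serds_difference(s2, s1)$intensity,
               -serds_difference(s1, s2)$intensity)
  expect_error(serds_difference(s1, make_spec(c(1, 2), axis = c(1, 2))),
               "axis")
})

test_that("grid averaging is the pointwise mean", {
  a <- make_spec(c(1, 1)); b <- make_spec(c(3, 5))
  expect_equal(average_grid(list(a, b))$intensity, c(2, 3))
  expect_equal(average_grid(list(a, a))$intensity, a$intensity)
  expect_equal(average_grid(list(b, make_spec(-c(3, 5))))$intensity, c(0, 0))
  expect_error(average_grid(list()), "empty")
})

test_that("Savitzky-Golay (11, 2) reproduces quadratics exactly and matches the normal-equations oracle", {
  axis <- 1:101
  for (coefs in list(c(2, 0, 0), c(1, -3, 0.5), c(-4, 0.2, -0.01))) {
    q <- coefs[1] + coefs[2] * axis + coefs[3] * axis^2
    sm <- savgol_smooth(spectrum(axis, q), 11, 2)
    expect_equal(sm$intensity[6:96], q[6:96], tolerance = 1e-8)
  }
  # constant input unchanged
  expect_equal(savgol_smooth(spectrum(axis, rep(5, 101)), 11, 2)$intensity,
               rep(5, 101), tolerance = 1e-10)
  # unit impulse: center output = central weight of the local quadratic fit,
  # solved here from the 11-point order-2 normal equations
  imp <- rep(0, 101); imp[51] <- 1
  sm <- savgol_smooth(spectrum(axis, imp), 11, 2)
  V <- outer(-5:5, 0:2, `^`)
  w_center <- (V %*% solve(crossprod(V), t(V)))[6, 6]
  expect_equal(sm$intensity[51], w_center, tolerance = 1e-10)
  expect_error(savgol_smooth(spectrum(axis, imp), 10, 2), "odd")
  expect_error(savgol_smooth(spectrum(axis, imp), 3, 4), "polyorder")
})

test_that("uniform resampling yields the half-open grid and is exact on linear data", {
  s <- spectrum(seq(300, 2050, by = 7), 2 * seq(300, 2050, by = 7))
  out <- resample_uniform(s, preprocess_config())
  expect_length(out$intensity, 1650)
  expect_equal(out$axis[1], 350)
  expect_equal(out$axis[1650], 1999)
  expect_equal(out$intensity, 2 * out$axis, tolerance = 1e-9)
  # identity on the target grid
  grid <- 350:1999
  s2 <- spectrum(grid, sin(grid / 40))
  expect_equal(resample_uniform(s2, preprocess_config())$intensity,
               s2$intensity, tolerance = 1e-12)
  # insufficient coverage is an error
  expect_error(resample_uniform(spectrum(400:2100, rnorm(1701)),
                                preprocess_config()), "cover")
})

test_that("the full chain is deterministic and scale-invariant", {
  ds <- generate_dataset(tiny_config(n_samples = 1))
  s <- ds$samples[[1]]
  out1 <- preprocess_sample(s)
  out2 <- preprocess_sample(s)
  expect_identical(out1, out2)
  expect_length(out1$intensity, 1650)
  # uniform intensity scaling across all replicates leaves the output
  # unchanged (MSC against the unit-mean reference removes it)
  s_scaled <- s
  s_scaled$measurements <- s$measurements * 3.7
  out3 <- preprocess_sample(s_scaled)
  expect_equal(out3$intensity, out1$intensity, tolerance = 1e-8)
})

test_that("stage failures carry the stage name", {
  ds <- generate_dataset(tiny_config(n_samples = 1, native_range = c(340, 1400)))
  expect_error(preprocess_sample(ds$samples[[1]]), "resample_uniform")
  ds2 <- generate_dataset(tiny_config(n_samples = 1, native_range = c(340, 900)))
  expect_error(preprocess_sample(ds2$samples[[1]]), "common_mode")
})

test_that("common-mode rejection plus differencing suppresses fluorescence energy >= 10x", {
  cfg <- light_config(2, seed = 9)
  ds <- generate_dataset(cfg)
  for (s in ds$samples) {
    per_grid <- average_replicates(s)
    raw_energy <- sum(per_grid[[1]][[1]]$intensity^2)
    out <- preprocess_sample(s)
    # compare on the common model grid, per-channel mean energy
    raw_rs <- resample_uniform(per_grid[[1]][[1]], preprocess_config())
    expect_gt(mean(raw_rs$intensity^2) / mean(out$intensity^2), 10)
  }
})

test_that("chain output on clean Raman-only input matches the frozen snapshot", {
  cfg <- synthetic_config(n_samples = 1, grid_shape = c(1, 1),
                          n_replicates = 2, native_step = 2,
                          fluorescence_amplitude_ratio = 0, noise_sd = 0,
                          albedo_sd = 0, seed = 123)
  out <- preprocess_sample(generate_dataset(cfg)$samples[[1]])
  expect_length(out$intensity, 1650)
  snap_channels <- c(650, 990, 1000, 1260)
  expect_equal(out$intensity[snap_channels],
               c(-2.9590597392, -0.6449879699, 0.4367685734, 0.6637345005),
               tolerance = 1e-8)
})
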
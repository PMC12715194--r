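test_that("mean residue ellipticity follows the normalisation formula", {
  expect_equal(mean_residue_ellipticity(0, 3.5e-6, 392, 0.1), 0)
  expect_equal(mean_residue_ellipticity(-10, 3.5e-6, 392, 0.1),
               100 * (-10) / (3.5e-6 * 392 * 0.1))
  expect_equal(mean_residue_ellipticity(-20, 3.5e-6, 392, 0.1),
               2 * mean_residue_ellipticity(-10, 3.5e-6, 392, 0.1))
  expect_error(mean_residue_ellipticity(-10, 0, 392, 0.1), "> 0")
})

test_that("simulated melt passes through the baseline midpoint at t_mid", {
  cfg <- melt_sim_config(dH_unfold = -44, t_mid = 30,
                         baselines = list(bf0 = 2, bf1 = 0, bu0 = -6, bu1 = 0),
                         temp_grid = seq(10, 50, by = 5), noise_sd = 0)
  melt <- simulate_cd_melt(cfg)
  expect_equal(melt$signal[melt$temperature_C == 30], (2 - 6) / 2)
})

test_that("two-state melt fit recovers noiseless generating parameters", {
  melt <- simulate_cd_melt(melt_sim_config(dH_unfold = -44, t_mid = 31.3))
  fit <- fit_two_state_melt(melt$temperature_C, melt$signal)
  expect_lt(abs(fit$dH - (-44)) / 44, 1e-6)
  expect_lt(abs(fit$t_mid - 31.3) / 31.3, 1e-6)
  expect_error(fit_two_state_melt(seq(10, 50, 2), rep(1, 21)), "flat")
  expect_error(fit_two_state_melt(c(10, 20, 30), c(1, 2, 3)), ">= 5")
})

test_that("melt fit parameters are invariant to affine signal rescaling", {
  melt <- simulate_cd_melt(melt_sim_config(noise_sd = 50, seed = 8))
  f0 <- fit_two_state_melt(melt$temperature_C, melt$signal)
  f_shift <- fit_two_state_melt(melt$temperature_C, melt$signal + 1234)
  f_scale <- fit_two_state_melt(melt$temperature_C, melt$signal * 0.25 - 40)
  expect_equal(f_shift$dH, f0$dH, tolerance = 1e-6)
  expect_equal(f_shift$t_mid, f0$t_mid, tolerance = 1e-6)
  expect_equal(f_scale$dH, f0$dH, tolerance = 1e-6)
  expect_equal(f_scale$t_mid, f0$t_mid, tolerance = 1e-6)
  ## the constant lands in the baselines
  expect_equal(unname(f_shift$baselines[c("bf0", "bu0")]),
               unname(f0$baselines[c("bf0", "bu0")]) + 1234, tolerance = 1e-4)
})

test_that("noisy melts stay centered on the generating truth", {
  ## 3% of the transition amplitude, 50 independent single melts: the
  ## enthalpy median holds a 2 kcal/mol band; the midpoint distribution
  ## is centred on the truth (single fits carry a small upward skew
  ## that replicate averaging removes)
  amp <- abs(diff(range(simulate_cd_melt(melt_sim_config())$signal)))
  fits <- vapply(1:50, function(s) {
    m <- simulate_cd_melt(melt_sim_config(noise_sd = 0.03 * amp, seed = s))
    f <- fit_two_state_melt(m$temperature_C, m$signal)
    c(f$dH, f$t_mid)
  }, numeric(2))
  expect_lt(abs(median(fits[1, ]) - (-44)), 2)
  expect_lt(abs(median(fits[2, ]) - 31.3), 0.5)
})

test_that("emission peak finding reaches sub-nanometre precision", {
  wl <- seq(300, 400, by = 1)
  ## on-grid symmetric Gaussian
  expect_equal(emission_peak(wl, exp(-(wl - 340)^2 / (2 * 12^2))), 340)
  ## off-grid centres, widths >= 10 nm: error below 0.1 nm
  for (centre in c(337.4, 341.7, 352.3)) {
    got <- emission_peak(wl, exp(-(wl - centre)^2 / (2 * 10^2)))
    expect_lt(abs(got - centre), 0.1)
  }
  ## plateau of equal maxima resolves to its centre
  flat <- c(rep(0, 10), rep(1, 5), rep(0, 10))
  expect_equal(emission_peak(seq_along(flat) + 300, flat), 313)
  expect_error(emission_peak(wl, seq_along(wl)), "monotone")
  expect_error(emission_peak(1:3, c(1, 2, 1)), ">= 5")
})

test_that("peak shift series tracks planted blue shifts against the warm end", {
  spectra <- simulate_emission_spectra(temperatures = seq(10, 30, 2),
                                       shift_per_degC = 0.15, noise_sd = 0)
  shifts <- peak_shift_series(spectra)
  truth <- attr(spectra, "truth")
  expect_equal(shifts$shift_nm[shifts$temperature_C == 30], 0)
  ## quadratic refinement of a sampled Gaussian is exact to ~0.01 nm
  expect_equal(shifts$peak_nm, truth$peak_nm, tolerance = 1e-4)
  sl <- coef(lm(shift_nm ~ temperature_C, data = shifts))[2]
  expect_equal(unname(sl), 0.15, tolerance = 1e-3)
  ## cooling shifts are negative (blue)
  expect_true(all(shifts$shift_nm[shifts$temperature_C < 30] < 0))
  ## identical spectra: all shifts zero
  same <- lapply(c(10, 20, 30), function(t) {
    s <- spectra[[1]]; attr(s, "temperature_C") <- t; s
  })
  expect_true(all(peak_shift_series(same)$shift_nm == 0))
  ## order invariance
  perm <- peak_shift_series(spectra[c(5, 1, 8, 3, 2, 4, 7, 6, 9, 10, 11)])
  expect_equal(perm, shifts)
  expect_error(peak_shift_series(spectra[1]), ">= 2")
})
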
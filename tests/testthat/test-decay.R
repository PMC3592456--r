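test_that("the FRET-quenched donor decay matches steady-state efficiency", {
  t <- seq(0, 60, 0.001)
  expect_equal(donor_decay(0, 4.3, t), exp(-t / 4.3))
  half <- donor_decay(1 / 4.3, 4.3, t)
  expect_equal(half, exp(-t / (4.3 / 2)), tolerance = 1e-12)
  expect_error(donor_decay(0.3, 4.3, c(-1, 0)), "non-negative")

  ph <- test_photophysics()
  kt <- transfer_rate(0.8, 22, ph)
  e_ss <- 1 - basefret:::trapz(t, donor_decay(kt, 4.3, t)) /
    basefret:::trapz(t, donor_decay(0, 4.3, t))
  expect_equal(e_ss, efficiency(0.8, 22, ph), tolerance = 1e-6)
})

test_that("the total decay mixes donor, uncoupled and other species", {
  t <- small_times()
  p11 <- decay_model_params(amplitude = 100)
  expect_equal(total_decay(p11, 0.4, 4.3, t),
               100 * donor_decay(0.4, 4.3, t), tolerance = 1e-12)
  p01 <- decay_model_params(coupled_fraction = 0)
  expect_equal(total_decay(p01, 5, 4.3, t), exp(-t / 4.3), tolerance = 1e-12)
  pm <- decay_model_params(coupled_fraction = 0.5, donor_fraction = 0.9,
                           other_lifetime = 1.7)
  lhs <- total_decay(pm, 0.4, 4.3, t)
  rhs <- 0.9 * 0.5 * (donor_decay(0.4, 4.3, t) + donor_decay(0, 4.3, t)) +
    0.1 * exp(-t / 1.7)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(decay_model_params(coupled_fraction = 1.2), "fractions")
})

test_that("FFT reconvolution equals the direct convolution sum", {
  set.seed(14)
  t <- tcspc_times(256, 25)
  irf <- gaussian_irf(t, fwhm_ps = 300, peak_ns = 2)
  model <- stats::runif(256)
  conv <- convolve_irf(model, irf)
  h <- irf$counts / sum(irf$counts)
  direct <- vapply(seq_along(model), function(i) {
    sum(model[1:i] * rev(h[1:i]))
  }, 0)
  expect_lt(max(abs(conv - direct)) / max(direct), 1e-9)
  # area conservation (for a model that has decayed away before the window
  # ends, so no intensity is pushed past the truncation)
  decayed <- donor_decay(0.8, 2, t)
  expect_equal(sum(convolve_irf(decayed, irf)), sum(decayed),
               tolerance = 1e-8)

  # a delta IRF shifts without reshaping
  delta <- decay_curve(t, c(rep(0, 10), 1, rep(0, 245)))
  shifted <- convolve_irf(model, delta)
  expect_equal(shifted[11:256], model[1:246], tolerance = 1e-12)

  bad <- gaussian_irf(tcspc_times(256, 50), fwhm_ps = 300, peak_ns = 2)
  expect_error(convolve_irf(decay_curve(t, model), bad), "spacing")
})

test_that("reduced chi-square uses Poisson weights and degrees of freedom", {
  t <- small_times()
  model <- 1e4 * donor_decay(0.2, 4.3, t) + 50
  expect_equal(reduced_chi2(model, model), 0)
  measured <- model + sqrt(model)
  model2 <- 2 * model - measured       # doubled residuals, same weights
  r1 <- reduced_chi2(measured, model, n_fitted_params = 2)
  r2 <- reduced_chi2(measured, model2, n_fitted_params = 2)
  expect_equal(r2 / r1, 4, tolerance = 1e-9)
  expect_error(reduced_chi2(model[1:3], model[1:3], n_fitted_params = 5),
               "channels")

  # Poisson draws from the true model give chi2_r near one
  irf <- gaussian_irf(t, peak_ns = 1)
  conv <- convolve_irf(1e4 * donor_decay(0.25, 4.3, t), irf)
  expected <- conv / max(conv) * 1e4
  chis <- vapply(1:20, function(s) {
    counts <- basefret:::with_seed(s, function() {
      stats::rpois(length(expected), expected)
    })
    reduced_chi2(decay_curve(t, counts), decay_curve(t, expected),
                 n_fitted_params = 0, fit_range = c(0.5, 20), times = t)
  }, 0)
  expect_equal(mean(chis), 1, tolerance = 0.1)
})

test_that("synthetic TCSPC curves honor the acquisition defaults", {
  t <- tcspc_times()
  expect_length(t, 2048)
  expect_equal(max(t) + t[2] - t[1], 100, tolerance = 1e-9)
  irf <- gaussian_irf(t)
  model <- total_decay(decay_model_params(), 0.3, 4.3, t)
  d1 <- simulate_tcspc(model, irf, peak_counts = 10000, seed = 5)
  d2 <- simulate_tcspc(model, irf, peak_counts = 10000, seed = 5)
  d3 <- simulate_tcspc(model, irf, peak_counts = 10000, seed = 6)
  expect_identical(d1$counts, d2$counts)
  expect_false(identical(d1$counts, d3$counts))
  expect_equal(d1$n_channels, 2048L)
  # peak expectation: the top channel fluctuates around peak_counts
  reps <- vapply(1:10, function(s) {
    max(simulate_tcspc(model, irf, 10000, seed = s)$counts)
  }, 0)
  expect_equal(mean(reps), 10000, tolerance = 0.05)
})
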
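# forward model: geometry -> dipoles -> sampling -> Forster -> decay

tiny_curve <- function(donor_pos, acceptor_pos, geometry_id = 1L, seed = 1,
                       n_samples = 400, n = 512, window = 20) {
  t <- tcspc_times(n, window)
  fret_curve(
    decay = NULL, irf = gaussian_irf(t, peak_ns = 1),
    donor = list(position = donor_pos, strand = "I"),
    acceptor = list(position = acceptor_pos, strand = "II"),
    geometry_id = geometry_id, photophysics = test_photophysics(),
    n_samples = n_samples, seed = seed
  )
}

tiny_geometry <- function() {
  geometry_spec("duplex", sequence = paste0("ATCF", strrep("G", 12), "AT"))
}

test_that("degenerate distributions reproduce the static geometry", {
  cv <- tiny_curve(4, 10)
  spec <- fit_spec(list(cv), tiny_geometry(),
                   fixed = list(theta_fwhm = 0.02, phi_fwhm = 0.02),
                   dynamics = list(in_plane = "harmonic"))
  fwd <- forward_model(spec)
  m <- build_geometry(spec$geometries[[1]])
  reg <- probe_registry()
  d <- basefret:::probe_site_dipole(m, cv$donor, reg$tCO, reg$tCO$bend_angle)
  a <- basefret:::probe_site_dipole(m, cv$acceptor, reg$tCnitro,
                                    reg$tCnitro$bend_angle)
  k2_static <- kappa(d$direction, a$direction, a$center - d$center)^2
  expect_equal(fwd$curves$kappa_sq, k2_static, tolerance = 1e-4)
  kt <- transfer_rate(k2_static, center_distance(d$center, a$center),
                      cv$photophysics)
  analytic <- convolve_irf(total_decay(decay_model_params(), kt, 4.3,
                                       cv$irf$time), cv$irf)
  expect_equal(fwd$model_counts[[1]], analytic, tolerance = 1e-3)
})

test_that("FRET shortens the donor decay and follows the helical phase", {
  spec <- fit_spec(purrr::map(5:13, ~ tiny_curve(4, 4 + .x + 1)),
                   tiny_geometry())
  fwd <- forward_model(spec)
  expect_true(all(fwd$curves$k_T > 0))
  e <- fwd$curves$E
  expect_false(all(diff(e) < 0))   # non-monotonic: orientation modulation
  expect_gt(max(e) - min(e), 0.1)
})

test_that("pooled chi-square is near zero on noise-free data and near one on Poisson data", {
  base <- fit_spec(purrr::map(c(5, 8), ~ tiny_curve(4, 4 + .x + 1)),
                   tiny_geometry(), fixed = list(theta_fwhm = 13,
                                                 phi_fwhm = 2))
  fwd <- forward_model(base)
  noisefree <- purrr::map(seq_along(base$dataset), function(i) {
    cv <- base$dataset[[i]]
    e <- fwd$model_counts[[i]]
    cv$decay <- decay_curve(cv$irf$time, e / max(e) * 1e4)
    cv$seed <- cv$seed   # same sampling seed: model reproduces data exactly
    cv
  })
  spec_nf <- fit_spec(noisefree, tiny_geometry(),
                      free = list(theta_fwhm = c(3, 35)),
                      fixed = list(phi_fwhm = 2))
  expect_lt(global_chi2(c(theta_fwhm = 13), spec_nf), 1e-6)

  poisson <- purrr::map(seq_along(base$dataset), function(i) {
    cv <- base$dataset[[i]]
    e <- fwd$model_counts[[i]]
    cv$decay <- decay_curve(cv$irf$time, basefret:::with_seed(40 + i,
      function() stats::rpois(length(e), e / max(e) * 1e4)))
    cv
  })
  spec_p <- fit_spec(poisson, tiny_geometry(),
                     free = list(theta_fwhm = c(3, 35)),
                     fixed = list(phi_fwhm = 2))
  expect_equal(global_chi2(c(theta_fwhm = 13), spec_p), 1, tolerance = 0.1)
})

test_that("constraint-violating kinks are rejected with a sentinel", {
  u <- list(sequence = "ATCGG")
  geom <- geometry_spec("kinked", unit1 = u, unit2 = list(sequence = "GGTAC"))
  t <- tcspc_times(512, 20)
  cv <- fret_curve(
    decay = decay_curve(t, rep(100, 512)),
    irf = gaussian_irf(t, peak_ns = 1),
    donor = list(position = 4, strand = "I"),
    acceptor = list(position = 7, strand = "II"),
    photophysics = test_photophysics(), n_samples = 200, seed = 2
  )
  spec <- fit_spec(list(cv), geom,
                   free = list(v_z = c(-2, 12)),
                   fixed = list(v_x = 0, v_y = 0, alpha = 0, beta = 0,
                                gamma = 0, theta_fwhm = 13, phi_fwhm = 2))
  v <- global_chi2(c(v_z = 0), spec)     # unit 2 collapsed onto unit 1
  expect_true(is.infinite(v))
  expect_gt(nrow(attr(v, "violations")), 0)
  expect_true(is.finite(global_chi2(c(v_z = 3.38), spec)))
})

test_that("steric and connectivity screening match their thresholds", {
  u1 <- build_duplex("ATCGA")
  u2 <- build_duplex("TTAGC")
  cont <- join_units(u1, u2, step_as_kink(helix_step("B")))
  expect_true(check_constraints(cont)$pass)

  collapsed <- join_units(u1, u2, kink_parameters())
  res <- check_constraints(collapsed)
  expect_false(res$pass)
  expect_true("steric" %in% res$violations$type)

  far <- join_units(u1, u2, kink_parameters(v_z = 15))
  resf <- check_constraints(far)
  expect_false(resf$pass)
  expect_true("connectivity" %in% resf$violations$type)

  # enlarging the van der Waals radius never turns a fail into a pass
  tight <- join_units(u1, u2, kink_parameters(v_x = 2.5, v_z = 2.2,
                                              beta = 30))
  fails <- vapply(c(0.8, 1.0, 1.3, 1.6, 2.0), function(r) {
    !check_constraints(tight, constraint_spec(vdw_radius = r))$pass
  }, TRUE)
  expect_true(all(diff(fails) >= 0))
})
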
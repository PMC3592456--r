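test_that("harmonic Boltzmann densities are calibrated Gaussians", {
  pdf <- boltzmann_pdf(potential_spec("harmonic", target_fwhm = 13))
  expect_equal(pdf$fwhm, 13, tolerance = 0.1)
  expect_equal(basefret:::trapz(pdf$angle, pdf$density), 1, tolerance = 1e-6)
  sigma <- calibrate_width("harmonic", 0.1, 295, 13)
  expect_equal(sigma, 13 / (2 * sqrt(2 * log(2))), tolerance = 1e-6)
})

test_that("Lennard-Jones densities are asymmetric toward bond stretch", {
  lj <- boltzmann_pdf(potential_spec("lennard_jones", target_fwhm = 13))
  expect_equal(lj$fwhm, 13, tolerance = 13 * 0.005)
  expect_equal(basefret:::trapz(lj$angle, lj$density), 1, tolerance = 1e-6)
  mu <- basefret:::trapz(lj$angle, lj$angle * lj$density)
  m2 <- basefret:::trapz(lj$angle, (lj$angle - mu)^2 * lj$density)
  m3 <- basefret:::trapz(lj$angle, (lj$angle - mu)^3 * lj$density)
  expect_gt(m3 / m2^1.5, 0)
  # re-measuring the FWHM of a freshly calibrated density is self-consistent
  for (target in c(5, 13, 25)) {
    p <- boltzmann_pdf(potential_spec("lennard_jones", target_fwhm = target))
    expect_equal(p$fwhm, target, tolerance = target * 0.005)
  }
})

test_that("the zero-width limit concentrates all mass", {
  p <- boltzmann_pdf(potential_spec("harmonic", target_fwhm = 0.02))
  inside <- abs(p$angle) <= 0.1
  expect_equal(basefret:::trapz_masked(p$angle, p$density, inside), 1,
               tolerance = 1e-6)
})

test_that("orientation sampling is reproducible and matches its density", {
  p_in <- boltzmann_pdf(potential_spec("harmonic", target_fwhm = 13))
  p_out <- boltzmann_pdf(potential_spec("harmonic", target_fwhm = 2))
  s1 <- sample_orientations(p_in, p_out, 1e5, seed = 7)
  s2 <- sample_orientations(p_in, p_out, 1e5, seed = 7)
  expect_identical(s1, s2)
  s3 <- sample_orientations(p_in, p_out, 1e5, seed = 8)
  expect_false(identical(s1$theta, s3$theta))
  expect_equal(2 * sqrt(2 * log(2)) * stats::sd(s1$theta), 13,
               tolerance = 0.3)
  expect_lt(max(abs(s1$phi)), 15)

  wide <- boltzmann_pdf(potential_spec("harmonic", target_fwhm = 55))
  expect_error(sample_orientations(p_in, wide, 10, seed = 1), "wide")
})

test_that("aligned Cartesian mapping anchors the mode at the dipole", {
  frame <- ref_frame()
  e1 <- c(0, 1, 0)
  v0 <- to_cartesian_aligned(list(theta = 0, phi = 0), e1, frame)
  expect_equal(as.numeric(v0$vectors), e1, tolerance = 1e-12)
  v90 <- to_cartesian_aligned(list(theta = 90, phi = 0), e1, frame)
  # in-plane perpendicular of (0,1,0) with base normal z
  expect_equal(abs(sum(v90$vectors * e1)), 0, tolerance = 1e-12)
  expect_equal(v90$vectors[1, 3], 0, tolerance = 1e-12)

  p_in <- boltzmann_pdf(potential_spec("harmonic", target_fwhm = 13))
  p_out <- boltzmann_pdf(potential_spec("harmonic", target_fwhm = 4))
  s <- sample_orientations(p_in, p_out, 5e4, seed = 3)
  vs <- to_cartesian_aligned(s, e1, frame)
  expect_true(all(abs(sqrt(rowSums(vs$vectors^2)) - 1) < 1e-10))
  # no pole pile-up: no vector within 5 degrees of the base normal
  expect_lt(max(abs(vs$vectors[, 3])), cos(5 * pi / 180))
  # empirical in-plane spread reproduces the input FWHM
  ang <- atan2(vs$vectors[, 1] * -1, vs$vectors[, 2]) * 180 / pi
  expect_equal(2 * sqrt(2 * log(2)) * stats::sd(ang), 13, tolerance = 0.4)
  # resultant length approaches 1 for narrow distributions
  narrow <- to_cartesian_aligned(
    sample_orientations(boltzmann_pdf(potential_spec("harmonic", 0.5)),
                        boltzmann_pdf(potential_spec("harmonic", 0.5)),
                        2e4, seed = 5), e1, frame)
  expect_gt(sqrt(sum(colMeans(narrow$vectors)^2)), 0.9999)
})

test_that("sampled mean kappa-squared is stable across seeds", {
  p_in <- boltzmann_pdf(potential_spec("lennard_jones", target_fwhm = 13))
  p_out <- boltzmann_pdf(potential_spec("harmonic", target_fwhm = 2))
  frame <- ref_frame()
  e_d <- c(0, 1, 0)
  e_a <- as.numeric(rotation_matrix("z", 140) %*% c(0, 1, 0))
  r <- c(4, 2, 20)
  k2 <- vapply(1:20, function(s) {
    vd <- to_cartesian_aligned(sample_orientations(p_in, p_out, 1000,
                                                   seed = s), e_d, frame)
    va <- to_cartesian_aligned(sample_orientations(p_in, p_out, 1000,
                                                   seed = s + 1000), e_a,
                               frame)
    mean_kappa_sq(vd, va, r)
  }, 0)
  expect_lt(stats::sd(k2), 0.1)
})
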
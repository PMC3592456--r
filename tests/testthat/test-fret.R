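test_that("kappa reproduces the canonical orientations and stays bounded", {
  expect_equal(kappa(c(0, 0, 1), c(0, 0, 1), c(0, 0, 10)), -2)
  expect_equal(kappa(c(1, 0, 0), c(1, 0, 0), c(0, 0, 10)), 1)
  expect_equal(kappa(c(1, 0, 0), c(0, 1, 0), c(0, 0, 10)), 0)
  expect_error(kappa(c(1, 0, 0), c(1, 0, 0), c(0, 0, 0)), "degenerate")

  set.seed(21)
  md <- random_unit_rows(1e5)
  ma <- random_unit_rows(1e5)
  rh <- random_unit_rows(1e5)
  k <- rowSums(md * ma) - 3 * rowSums(md * rh) * rowSums(ma * rh)
  expect_true(all(k >= -2 - 1e-12 & k <= 2 + 1e-12))
  # symmetry under donor/acceptor exchange
  for (i in 1:50) {
    expect_equal(kappa(md[i, ], ma[i, ], rh[i, ] * 7),
                 kappa(ma[i, ], md[i, ], rh[i, ] * 7), tolerance = 1e-12)
  }
})

test_that("center distance is the Euclidean norm", {
  expect_equal(center_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(center_distance(c(1, 1, 1), c(1, 1, 1)), 0)
  set.seed(2)
  for (i in 1:20) {
    p <- stats::rnorm(3); q <- stats::rnorm(3); t <- stats::rnorm(3)
    expect_equal(center_distance(p + t, q + t),
                 sqrt(sum((p - q)^2)), tolerance = 1e-12)
  }
})

test_that("the Forster radius carries the textbook constant and scaling", {
  expect_equal(forster_radius(0, 1e13, 1.4), 0)
  r1 <- forster_radius(0.3, 1e13, 1.4)
  expect_equal(forster_radius(0.3, 2e13, 1.4), r1 * 2^(1 / 6),
               tolerance = 1e-12)
  # frozen from an independent evaluation of
  # (8.79e-5 * (2/3) * 0.3 * 1e13 / 1.4^4)^(1/6) before implementation
  expect_equal(r1, 18.91259, tolerance = 1e-6)
})

test_that("rate and efficiency obey the isotropic-average convention", {
  ph <- photophysics(quantum_yield = 0.3, overlap_integral = 1e13,
                     refractive_index = 1.4, donor_lifetime = 4.3)
  r0 <- ph$forster_radius
  expect_equal(transfer_rate(2 / 3, r0, ph), 1 / 4.3, tolerance = 1e-12)
  expect_equal(transfer_rate(0, 30, ph), 0)
  expect_equal(transfer_rate(1, 10, ph) / transfer_rate(1, 20, ph), 64,
               tolerance = 1e-9)
  expect_equal(efficiency(2 / 3, r0, ph), 0.5, tolerance = 1e-12)
  expect_equal(efficiency(2 / 3, 1e-3, ph), 1, tolerance = 1e-6)
  expect_equal(efficiency(0, 20, ph), 0)
  e <- vapply(seq(5, 60, 2.5), function(r) efficiency(1, r, ph), 0)
  expect_true(all(diff(e) < 0))
})

test_that("mean kappa-squared equals the ordered-pair average exactly", {
  v <- matrix(c(1, 0, 0), 1, 3)
  expect_equal(mean_kappa_sq(v, v, c(0, 0, 5)), 1, tolerance = 1e-12)
  set.seed(9)
  md <- random_unit_rows(40)
  ma <- random_unit_rows(50)
  r <- c(3, -2, 8)
  naive <- mean(outer(seq_len(40), seq_len(50), Vectorize(function(i, j) {
    kappa(md[i, ], ma[j, ], r)^2
  })))
  expect_equal(mean_kappa_sq(md, ma, r), naive, tolerance = 1e-12)
  expect_error(mean_kappa_sq(md[0, , drop = FALSE], ma, r), "nonempty")
})

test_that("independent isotropic sets average to 2/3", {
  set.seed(33)
  reps <- vapply(1:8, function(i) {
    mean_kappa_sq(random_unit_rows(2000), random_unit_rows(2000), c(0, 0, 25))
  }, 0)
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 2 / 3), 3 * max(se, 0.005))
})

test_that("static efficiency is invariant under rigid motion of the model", {
  m <- build_duplex("AFGCATGCAQT")
  ph <- test_photophysics()
  donor <- list(position = 2, strand = "I")
  acceptor <- list(position = 10, strand = "I")
  e0 <- fret_observables(m, donor, acceptor, ph)$E
  set.seed(12)
  mt <- basefret:::transform_model(m, random_rotation(), stats::rnorm(3))
  e1 <- fret_observables(mt, donor, acceptor, ph)$E
  expect_equal(e1, e0, tolerance = 1e-9)
})

test_that("efficiency versus separation shows the helical period", {
  seq1 <- paste0("ATCF", strrep("G", 36), "AT")
  m <- build_duplex(seq1)
  ph <- test_photophysics()
  seps <- 3:32
  e <- vapply(seps, function(s) {
    basefret:::screened_efficiency(
      m, tibble::tibble(position = 4, strand = "I"),
      tibble::tibble(position = 4 + s + 1, strand = "II"),
      ph, "tCO", "tCnitro"
    )
  }, 0)
  peaks <- which(diff(sign(diff(e))) == -2) + 1
  expect_gte(length(peaks), 2)
  # helical fingerprint: kappa^2 modulates with the helical repeat; being a
  # square it carries the 10-pair fundamental and its 5-pair harmonic, so
  # the dominant recurrence is the repeat or its half
  detr <- stats::resid(stats::lm(e ~ poly(seps, 3)))
  dp <- unname(dominant_period(seps, detr))
  expect_true(abs(dp - 10) <= 1.5 || abs(dp - 5) <= 1)
})

test_that("pair screening ranks efficiency changes between structures", {
  straight <- build_duplex(paste0("ATCG", strrep("G", 8), "ATCGATCG"))
  u1 <- build_duplex("ATCGGGGGGG")
  u2 <- build_duplex("ATCGATCGAT")
  kinked <- join_units(u1, u2, kink_parameters(0, 0, 3.38, 20, 57, 20))
  ph <- test_photophysics()
  tbl <- screen_pairs(straight, kinked,
                      donor_positions = 5:7, acceptor_positions = 12:14, ph)
  expect_equal(nrow(tbl), 9L)
  expect_true(all(diff(abs(tbl$dE)) <= 1e-12))
  expect_gt(max(abs(tbl$dE)), 0.1)

  same <- screen_pairs(straight, straight, 5:7, 12:14, ph)
  expect_true(all(abs(same$dE) < 1e-12))

  expect_warning(
    collided <- screen_pairs(straight, kinked,
                             donor_positions = tibble::tibble(position = 5,
                                                              strand = "I"),
                             acceptor_positions = tibble::tibble(position = 5,
                                                                 strand = "I"),
                             ph),
    "collision"
  )
  expect_equal(nrow(collided), 0L)
})
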
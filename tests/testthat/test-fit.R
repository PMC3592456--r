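# optimization machinery on small, fast problems

make_vz_problem <- function(noise = FALSE, seed = 5) {
  geom <- geometry_spec("kinked", unit1 = list(sequence = "ATCGG"),
                        unit2 = list(sequence = "GGTAC"))
  t <- tcspc_times(512, 20)
  truth <- list(v_x = 0, v_y = 0, v_z = 3.3, alpha = 36, beta = 0,
                gamma = 0, theta_fwhm = 13, phi_fwhm = 2)
  curves <- purrr::map(1:3, function(i) {
    fret_curve(
      decay = NULL, irf = gaussian_irf(t, peak_ns = 1),
      donor = list(position = 5 - i + 1, strand = "I"),
      acceptor = list(position = 5 + i, strand = "II"),
      photophysics = test_photophysics(), n_samples = 300,
      seed = 100 + i
    )
  })
  gen <- fit_spec(curves, geom, fixed = truth, seed = seed)
  fwd <- forward_model(gen)
  ds <- purrr::map(seq_along(curves), function(i) {
    cv <- curves[[i]]
    e <- fwd$model_counts[[i]] / max(fwd$model_counts[[i]]) * 1e4
    counts <- if (noise) {
      basefret:::with_seed(seed + i, function() stats::rpois(length(e), e))
    } else {
      e
    }
    cv$decay <- decay_curve(t, counts)
    if (noise) cv$seed <- cv$seed + 5000L  # analysis-side resampling
    cv
  })
  fit_spec(ds, geom, free = list(v_z = c(-2, 12)),
           fixed = truth[setdiff(names(truth), "v_z")], seed = seed)
}

fast_ctrl <- list(lhs_n = 25, anneal_maxit = 40, refine_maxit = 40,
                  pattern_maxeval = 80, polish_repetitions = 1)

test_that("a noise-free single-parameter problem recovers the truth", {
  spec <- make_vz_problem(noise = FALSE)
  fit <- fit_parameters(spec, control = fast_ctrl)
  expect_equal(fit$par[["v_z"]], 3.3, tolerance = 14 * 1e-3)
  expect_lt(fit$chi2r, 1e-4)
  expect_s3_class(fit, "fret_fit")
})

test_that("fits are deterministic for identical specs and seeds", {
  spec <- make_vz_problem(noise = TRUE)
  f1 <- fit_parameters(spec, control = fast_ctrl)
  f2 <- fit_parameters(spec, control = fast_ctrl)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$chi2r, f2$chi2r)
})

test_that("tidy and glance summarize fits in the broom idiom", {
  spec <- make_vz_problem(noise = TRUE)
  fit <- fit_parameters(spec, control = fast_ctrl)
  td <- generics::tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(td$term, "v_z")
  gl <- generics::glance(fit)
  expect_named(gl, c("chi2r", "n", "p", "n_curves", "method", "n_eval"))
  expect_equal(gl$n_curves, 3L)
})

test_that("F-statistic intervals bracket the estimate and flag bounds", {
  spec <- make_vz_problem(noise = TRUE)
  fit <- fit_parameters(spec, control = fast_ctrl)
  ci <- confidence_interval(fit, "v_z")
  expect_lte(ci$low, fit$par[["v_z"]])
  expect_gte(ci$high, fit$par[["v_z"]])
  expect_false(ci$open_low)
  expect_false(ci$open_high)
  expect_lt(ci$high - ci$low, 2)          # well-determined parameter

  # on noise-free data the interval closes tightly around the truth
  spec_nf <- make_vz_problem(noise = FALSE)
  fit_nf <- fit_parameters(spec_nf, control = fast_ctrl)
  ci_nf <- confidence_interval(fit_nf, "v_z")
  expect_true(ci_nf$low <= 3.3 && 3.3 <= ci_nf$high)
})

test_that("chi-square surfaces locate the generating parameters", {
  spec <- make_vz_problem(noise = TRUE)
  surf <- map_chi2_surface(spec, c("v_z", "beta"),
                           list(seq(2.4, 4.2, 0.3), seq(0, 12, 4)))
  expect_s3_class(surf, "fret_surface")
  expect_equal(dim(surf$chi2), c(7L, 4L))
  expect_equal(unname(surf$minimum["v_z"]), 3.3, tolerance = 0.35)
  expect_equal(unname(surf$minimum["beta"]), 0, tolerance = 4)
  td <- generics::tidy(surf)
  expect_named(td, c("v_z", "beta", "chi2"))
  expect_equal(nrow(td), 28L)
})

test_that("repetition averaging damps the sampling scatter of chi-square", {
  spec <- make_vz_problem(noise = TRUE)
  point <- c(v_z = 3.0)
  singles <- vapply(1:6, function(tag) {
    ctx <- basefret:::prepare_context(spec, resample_tag = tag)
    global_chi2(point, spec, ctx)
  }, 0)
  triples <- vapply(list(1:3, 4:6), function(tags) {
    mean(vapply(tags, function(tag) {
      ctx <- basefret:::prepare_context(spec, resample_tag = tag)
      global_chi2(point, spec, ctx)
    }, 0))
  }, 0)
  expect_lt(abs(diff(triples)), max(stats::sd(singles), 1e-12) * 2.5)
})

test_that("surface scans honor the 180-degree twist-sum periodicity", {
  # two-unit construct at beta = 0: the static efficiency versus the Euler
  # angle sum repeats every 180 degrees
  geom <- geometry_spec("kinked", unit1 = list(sequence = "ATCGG"),
                        unit2 = list(sequence = "GGTAC"))
  ph <- test_photophysics()
  sig <- seq(0, 358, by = 2)
  e <- vapply(sig, function(s) {
    m <- build_geometry(geom, kink_parameters(0, 0, 3.38, s, 0, 0))
    basefret:::screened_efficiency(
      m, tibble::tibble(position = 3, strand = "I"),
      tibble::tibble(position = 8, strand = "II"), ph, "tCO", "tCnitro"
    )
  }, 0)
  shifted <- e[c(91:180, 1:90)]
  expect_gt(stats::cor(e, shifted), 0.95)
  expect_equal(unname(dominant_period(sig, e)), 180, tolerance = 1e-9)
})
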
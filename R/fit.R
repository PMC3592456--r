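# Global parameter optimization: compass pattern search for the
# non-differentiable sampling-stage parameters, latin-hypercube prescreen +
# simulated annealing + bounded gradient refinement for kink parameters,
# F-statistic confidence intervals, and chi-square surfaces.

#' Fit free parameters of a global decay analysis
#'
#' Strategy dispatch follows the nature of the free parameters: when any of
#' them touches the random-sampling stage (`theta_fwhm`, `phi_fwhm`,
#' `bend_*`) the objective is non-differentiable and a compass pattern
#' search is used; when kink parameters are free the search is a
#' latin-hypercube prescreen, constraint-aware simulated annealing and a
#' bounded quasi-Newton refinement; purely smooth nuisance parameters go
#' straight to bounded quasi-Newton. Objective evaluations use fixed
#' per-curve sampling seeds, so the fit is reproducible for a fixed spec.
#'
#' @param spec A [fit_spec()] with at least one free parameter and measured
#'   decays on every curve.
#' @param start Optional named vector of starting values (defaults to the
#'   bound midpoints).
#' @param control List of budgets: `pattern_maxeval` (default 400),
#'   `anneal_maxit` (default 300), `lhs_n` (default 200), `refine_maxit`
#'   (default 100), `pattern_tol` (default 1e-3, fraction of the bound
#'   range), `polish_repetitions` (default 3; sampling repetitions averaged
#'   in the final kink-polish stage).
#' @return A `fret_fit` object: best parameters, global and per-curve
#'   reduced chi-square, evaluation log, seeds and the spec.
#' @export
fit_parameters <- function(spec, start = NULL, control = list()) {
  stopifnot(inherits(spec, "fit_spec"))
  if (length(spec$free) == 0) stop("no free parameters", call. = FALSE)
  ctrl <- utils::modifyList(list(pattern_maxeval = 400, anneal_maxit = 300,
                                 lhs_n = 200, refine_maxit = 100,
                                 pattern_tol = 1e-3,
                                 polish_repetitions = 3), control)
  ctxs <- purrr::map(seq_len(spec$repetitions),
                     function(r) prepare_context(spec, resample_tag = r - 1L))
  ctx <- ctxs[[1]]
  nms <- names(spec$free)
  lo <- vapply(spec$free, `[`, 0, 1)
  hi <- vapply(spec$free, `[`, 0, 2)
  names(lo) <- names(hi) <- nms

  n_eval <- 0L
  penalized <- function(x) {
    names(x) <- nms
    x <- clamp(x, lo, hi)   # SANN proposals may step outside the bounds
    n_eval <<- n_eval + 1L
    v <- global_chi2(x, spec, ctxs[[1]])
    if (!is.finite(v)) {
      viol <- attr(v, "violations")
      depth <- if (!is.null(viol) && nrow(viol)) sum(pmax(viol$value, 1)) else 1
      return(1e6 * (1 + depth))
    }
    if (length(ctxs) > 1) {
      for (cc in ctxs[-1]) v <- v + global_chi2(x, spec, cc)
      v <- v / length(ctxs)
    }
    v
  }

  sampling_free <- any(nms %in% c("theta_fwhm", "phi_fwhm") |
                         startsWith(nms, "bend_"))
  kink_free <- any(nms %in% kink_param_names)
  method <- if (sampling_free) "pattern" else if (kink_free) "anneal" else
    "gradient"

  x0 <- if (!is.null(start)) {
    stopifnot(all(nms %in% names(start)))
    clamp(start[nms], lo, hi)
  } else {
    (lo + hi) / 2
  }

  if (method == "pattern") {
    cand <- lhs_prescreen(penalized, lo, hi, n = 80, seed = spec$seed,
                          keep = 4)
    cand <- c(cand, list(list(par = x0, value = penalized(x0))))
    ref <- purrr::map(cand, function(cd) {
      pattern_search(penalized, cd$par, lo, hi, maxeval = 250, step0 = 0.15)
    })
    best <- ref[[which.min(purrr::map_dbl(ref, "value"))]]
    # kappa-squared is invariant under donor/acceptor exchange, so probe
    # bend pairs have a near-twin solution with the two bends swapped;
    # restart from the mirrored point and keep the better basin
    bends <- grep("^bend_", nms, value = TRUE)
    if (length(bends) == 2) {
      sw <- best$par
      sw[bends] <- sw[rev(bends)]
      ps <- pattern_search(penalized, sw, lo, hi, maxeval = 250,
                           step0 = 0.08)
      if (ps$value < best$value) best <- ps
    }
    pol <- pattern_search(penalized, best$par, lo, hi,
                          maxeval = ctrl$pattern_maxeval,
                          tol = ctrl$pattern_tol, step0 = 0.05)
    if (pol$value < best$value) best <- pol
  } else if (method == "anneal") {
    cand <- lhs_prescreen(penalized, lo, hi, n = ctrl$lhs_n,
                          seed = spec$seed, keep = 2)
    # planar stage: kinks with small beta live in the beta = 0 subspace,
    # where alpha and gamma collapse to their sum and the landscape is
    # exactly 180-degree periodic in that sum; a 4-parameter search
    # (translation + alpha over one period) locates that family directly
    if (all(kink_param_names %in% nms)) {
      sub <- c("v_x", "v_y", "v_z", "alpha")
      lo_s <- lo[sub]
      hi_s <- hi[sub]
      lo_s["alpha"] <- max(lo[["alpha"]], -90)
      hi_s["alpha"] <- min(hi[["alpha"]], 90)
      expand <- function(x) {
        full <- (lo + hi) / 2
        full[c("beta", "gamma")] <- 0
        full[sub] <- x
        full[nms]
      }
      fn_sub <- function(x) penalized(expand(x))
      # deterministic scan over the twist sum (the nonconvex direction of
      # the planar family; the translation is fitted at each node)
      vsub0 <- c("v_x", "v_y", "v_z")
      sig_nodes <- seq(lo_s[["alpha"]] + 7.5, hi_s[["alpha"]], by = 15)
      planar <- purrr::map(sig_nodes, function(sig) {
        fnv <- function(v) fn_sub(c(v, alpha = sig))
        ps <- pattern_search(fnv, c(v_x = 0, v_y = 0, v_z = 3.4),
                             lo[vsub0], hi[vsub0], maxeval = 60, step0 = 0.2)
        list(par = c(ps$par, alpha = sig), value = ps$value)
      })
      ordp <- order(purrr::map_dbl(planar, "value"))[1:3]
      cand <- c(cand, purrr::map(planar[ordp], function(cd) {
        ps <- pattern_search(fn_sub, cd$par, lo_s, hi_s,
                             maxeval = 150, step0 = 0.1)
        list(par = expand(ps$par), value = ps$value)
      }))
    }
    # bent-kink stage: strongly bent junctions live in narrow 6-D basins a
    # space-filling search rarely hits, but they are indexed well by the
    # Euler structure; seed a coarse (beta, alpha+gamma, alpha-gamma) grid
    # and fit the translation quickly at each node
    if (all(kink_param_names %in% nms)) {
      vsub <- c("v_x", "v_y", "v_z")
      sig_rng <- if (!is.null(spec$kink_prior)) spec$kink_prior else c(0, 315)
      sig_grid <- seq(sig_rng[1] + 15, sig_rng[2], by = 45)
      grid_cand <- list()
      for (beta0 in c(25, 60)) {
        for (sig in sig_grid) {
          for (del in c(0, 120, 240)) {
            al <- wrap_angle((sig + del) / 2)
            ga <- wrap_angle((sig - del) / 2)
            fnv <- function(v) {
              full <- (lo + hi) / 2
              full[vsub] <- v
              full["alpha"] <- al
              full["beta"] <- beta0
              full["gamma"] <- ga
              penalized(full[nms])
            }
            ps <- pattern_search(fnv, c(v_x = 0, v_y = 0, v_z = 3.4),
                                 lo[vsub], hi[vsub], maxeval = 45,
                                 step0 = 0.2)
            full <- (lo + hi) / 2
            full[vsub] <- ps$par
            full["alpha"] <- al
            full["beta"] <- beta0
            full["gamma"] <- ga
            grid_cand <- c(grid_cand, list(list(par = full[nms],
                                                value = ps$value)))
          }
        }
      }
      ord <- order(purrr::map_dbl(grid_cand, "value"))
      cand <- c(cand, grid_cand[ord[seq_len(min(3, length(ord)))]])
    }
    if (!is.null(start)) cand <- c(cand, list(list(par = x0,
                                                   value = penalized(x0))))
    ref <- purrr::map(cand, function(cd) {
      pattern_search(penalized, cd$par, lo, hi, maxeval = 250, step0 = 0.12)
    })
    # polish the two best local candidates with a simplex (it follows the
    # curved valleys compass moves cannot) before picking the winner
    ord2 <- if (length(nms) < 2) integer(0) else
      order(purrr::map_dbl(ref, "value"))[seq_len(min(2, length(ref)))]
    for (i in ord2) {
      nm2 <- tryCatch(
        stats::optim(ref[[i]]$par, penalized, method = "Nelder-Mead",
                     control = list(maxit = 300, reltol = 1e-8,
                                    parscale = (hi - lo) / 10)),
        error = function(e) NULL
      )
      if (!is.null(nm2) && is.finite(nm2$value) &&
          nm2$value < ref[[i]]$value) {
        ref[[i]] <- list(par = clamp(nm2$par, lo, hi), value = nm2$value)
      }
    }
    best <- ref[[which.min(purrr::map_dbl(ref, "value"))]]
    ann <- with_seed(derive_seed(spec$seed, 7L), function() {
      stats::optim(best$par, penalized, method = "SANN",
                   control = list(maxit = ctrl$anneal_maxit,
                                  temp = 2, tmax = 5,
                                  parscale = (hi - lo) / 25))
    })
    ann_par <- clamp(ann$par, lo, hi)
    ann_val <- penalized(ann_par)
    if (ann_val < best$value) best <- list(par = ann_par, value = ann_val)
    g <- refine_bounded(penalized, best$par, lo, hi, ctrl$refine_maxit)
    if (g$value < best$value) best <- g
    nm <- if (length(nms) < 2) NULL else tryCatch(
      stats::optim(best$par, penalized, method = "Nelder-Mead",
                   control = list(maxit = 400, reltol = 1e-8,
                                  parscale = (hi - lo) / 10)),
      error = function(e) NULL
    )
    if (!is.null(nm) && is.finite(nm$value) && nm$value < best$value) {
      best <- list(par = clamp(nm$par, lo, hi), value = nm$value)
    }
    pol <- pattern_search(penalized, best$par, lo, hi,
                          maxeval = ctrl$pattern_maxeval,
                          tol = 2e-4, step0 = 0.04)
    if (pol$value < best$value) best <- pol
    # the chi-square valley runs along alpha + gamma (exactly so at beta =
    # 0); axis-aligned moves cannot track that diagonal, so polish once in
    # rotated (alpha+gamma, alpha-gamma) coordinates
    if (all(c("alpha", "gamma") %in% nms)) {
      to_rot <- function(x) {
        y <- x
        y["alpha"] <- x[["alpha"]] + x[["gamma"]]
        y["gamma"] <- x[["alpha"]] - x[["gamma"]]
        y
      }
      from_rot <- function(y) {
        x <- y
        x["alpha"] <- (y[["alpha"]] + y[["gamma"]]) / 2
        x["gamma"] <- (y[["alpha"]] - y[["gamma"]]) / 2
        x
      }
      fn_rot <- function(y) penalized(from_rot(y))
      lo_r <- to_rot(lo)
      hi_r <- to_rot(hi)
      lo_r[c("alpha", "gamma")] <- lo[["alpha"]] + lo[["gamma"]]
      hi_r[c("alpha", "gamma")] <- hi[["alpha"]] + hi[["gamma"]]
      rot <- pattern_search(fn_rot, to_rot(best$par), lo_r, hi_r,
                            maxeval = 350, tol = 1e-4, step0 = 0.03)
      if (rot$value < best$value) {
        best <- list(par = clamp(from_rot(rot$par), lo, hi),
                     value = rot$value)
      }
    }
    # final polish against the sampling-averaged objective: the location of
    # the minimum is a better estimator once chi2 is averaged over several
    # independent dipole samplings (sampling scatter no longer tugs it)
    reps_pol <- ctrl$polish_repetitions
    if (reps_pol > 1) {
      ctxs_pol <- purrr::map(seq_len(reps_pol), function(r) {
        prepare_context(spec, resample_tag = r - 1L)
      })
      fn_avg <- function(x) {
        names(x) <- nms
        x <- clamp(x, lo, hi)
        n_eval <<- n_eval + 1L
        vs <- vapply(ctxs_pol, function(cc) {
          v <- global_chi2(x, spec, cc)
          if (is.finite(v)) v else NA_real_
        }, 0)
        if (anyNA(vs)) 1e6 else mean(vs)
      }
      nm3 <- if (length(nms) < 2) NULL else tryCatch(
        stats::optim(best$par, fn_avg, method = "Nelder-Mead",
                     control = list(maxit = 300, reltol = 1e-9,
                                    parscale = (hi - lo) / 10)),
        error = function(e) NULL
      )
      par_avg <- if (!is.null(nm3) && is.finite(nm3$value)) {
        clamp(nm3$par, lo, hi)
      } else {
        best$par
      }
      ps3 <- pattern_search(fn_avg, par_avg, lo, hi, maxeval = 250,
                            step0 = 0.02, tol = 1e-4)
      best <- list(par = ps3$par, value = penalized(ps3$par))
    }
  } else {
    best <- refine_bounded(penalized, x0, lo, hi, ctrl$refine_maxit)
  }

  par <- best$par
  names(par) <- nms
  fwd <- forward_model(spec, par)
  structure(list(
    par = par, chi2r = best$value, per_curve = fwd$curves,
    n = sum(purrr::map_dbl(ctx$curves, ~ sum(.x$mask))),
    p = length(nms), bounds = list(lower = lo, upper = hi),
    method = method, n_eval = n_eval, seed = spec$seed, spec = spec
  ), class = "fret_fit")
}

#' @export
print.fret_fit <- function(x, ...) {
  cat(sprintf("<fret_fit> %s search, %d evaluation(s)\n", x$method, x$n_eval))
  cat(sprintf(" global reduced chi2 = %.4f (n = %d, p = %d)\n",
              x$chi2r, x$n, x$p))
  for (nm in names(x$par)) cat(sprintf("  %-12s %10.4f\n", nm, x$par[[nm]]))
  invisible(x)
}

# compass (coordinate) pattern search with step halving on scaled coordinates
pattern_search <- function(fn, x0, lo, hi, maxeval = 400, tol = 1e-3,
                           step0 = 0.25) {
  scale <- hi - lo
  x <- clamp(x0, lo, hi)
  fx <- fn(x)
  step <- step0
  k <- length(x)
  used <- 1L
  while (used < maxeval && step > tol) {
    improved <- FALSE
    for (j in seq_len(k)) {
      for (sgn in c(1, -1)) {
        cand <- x
        cand[j] <- clamp(x[j] + sgn * step * scale[j], lo[j], hi[j])
        if (cand[j] == x[j]) next
        fc <- fn(cand)
        used <- used + 1L
        if (fc < fx) {
          x <- cand
          fx <- fc
          improved <- TRUE
          break
        }
        if (used >= maxeval) break
      }
      if (used >= maxeval) break
    }
    if (!improved) step <- step / 2
  }
  list(par = x, value = fx)
}

lhs_prescreen <- function(fn, lo, hi, n = 200, seed = 1, keep = 1) {
  k <- length(lo)
  pts <- with_seed(derive_seed(seed, 3L), function() lhs::randomLHS(n, k))
  vals <- numeric(n)
  for (i in seq_len(n)) vals[i] <- fn(lo + pts[i, ] * (hi - lo))
  ord <- order(vals)[seq_len(min(keep, n))]
  purrr::map(ord, function(i) {
    list(par = stats::setNames(lo + pts[i, ] * (hi - lo), names(lo)),
         value = vals[i])
  })
}

refine_bounded <- function(fn, x0, lo, hi, maxit = 100) {
  res <- tryCatch(
    stats::optim(x0, fn, method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(maxit = maxit,
                                parscale = pmax(hi - lo, 1e-8) / 10)),
    error = function(e) NULL
  )
  if (is.null(res) || !is.finite(res$value)) {
    return(pattern_search(fn, x0, lo, hi, maxeval = 150, step0 = 0.05))
  }
  list(par = clamp(res$par, lo, hi), value = res$value)
}

#' F-statistic confidence interval of a fitted parameter
#'
#' The interval is the set of parameter values whose reduced chi-square
#' (with the remaining free parameters re-optimized) stays below
#' `chi2_min * (1 + p/(n-p) * F(p, n-p, 1-level))`, located by outward march
#' plus bisection in each direction. Ends clipped by the parameter bounds
#' are flagged open-ended.
#'
#' @param fit A `fret_fit`.
#' @param parameter Name of one free parameter.
#' @param level Confidence level (default 0.95, the P = 0.05 criterion).
#' @param reoptimize Re-optimize the other free parameters at each probe
#'   value (default `TRUE` when any exist).
#' @param n_steps March resolution (fraction of the bound range is
#'   1/`n_steps`).
#' @return A tibble: parameter, estimate, low, high, open_low, open_high,
#'   threshold.
#' @export
confidence_interval <- function(fit, parameter, level = 0.95,
                                reoptimize = TRUE, n_steps = 25) {
  stopifnot(inherits(fit, "fret_fit"), parameter %in% names(fit$par))
  spec <- fit$spec
  ctx <- prepare_context(spec)
  n <- fit$n
  p <- fit$p
  threshold <- fit$chi2r * (1 + p / (n - p) * stats::qf(level, p, n - p))
  others <- setdiff(names(fit$par), parameter)
  lo <- fit$bounds$lower
  hi <- fit$bounds$upper

  prof <- function(val) {
    if (length(others) == 0 || !reoptimize) {
      par <- fit$par
      par[parameter] <- val
      v <- global_chi2(par, spec, ctx)
      return(if (is.finite(v)) v else Inf)
    }
    fn <- function(x) {
      par <- fit$par
      par[others] <- x
      par[parameter] <- val
      v <- global_chi2(par, spec, ctx)
      if (is.finite(v)) v else 1e6
    }
    pattern_search(fn, fit$par[others], lo[others], hi[others],
                   maxeval = 60, step0 = 0.1)$value
  }

  march <- function(dir) {
    bound <- if (dir > 0) hi[[parameter]] else lo[[parameter]]
    step <- (hi[[parameter]] - lo[[parameter]]) / n_steps
    x_in <- fit$par[[parameter]]
    repeat {
      x_out <- x_in + dir * step
      if ((dir > 0 && x_out >= bound) || (dir < 0 && x_out <= bound)) {
        if (prof(bound) <= threshold) return(list(x = bound, open = TRUE))
        x_out <- bound
      }
      if (prof(x_out) > threshold) break
      x_in <- x_out
      if (x_in == bound) return(list(x = bound, open = TRUE))
    }
    for (i in 1:20) {
      mid <- (x_in + x_out) / 2
      if (prof(mid) <= threshold) x_in <- mid else x_out <- mid
      if (abs(x_out - x_in) < step / 50) break
    }
    list(x = (x_in + x_out) / 2, open = FALSE)
  }

  lo_end <- march(-1)
  hi_end <- march(1)
  tibble::tibble(
    parameter = parameter, estimate = fit$par[[parameter]],
    low = lo_end$x, high = hi_end$x,
    open_low = lo_end$open, open_high = hi_end$open,
    threshold = threshold
  )
}

#' Map a chi-square surface over two parameters
#'
#' Evaluates (or optimizes, if other free parameters remain) the global
#' reduced chi-square on a two-parameter grid, averaging over repeated
#' samplings of the dipole distributions with per-repetition seeds; the raw
#' averaged matrix is retained (interpolation, if any, is for display only).
#'
#' @param spec A [fit_spec()]; the two scanned parameters need not be listed
#'   free.
#' @param parameters Character vector of two parameter names.
#' @param grids List of two numeric grid vectors.
#' @param repetitions Number of sampling repetitions averaged per grid point.
#' @param optimize_others Optimize remaining free parameters at each point
#'   (pattern search, small budget); otherwise they sit at their fixed/bound
#'   midpoint values.
#' @return A `fret_surface`: grids, averaged chi2 matrix, and the per-point
#'   minimum location.
#' @export
map_chi2_surface <- function(spec, parameters, grids, repetitions = 1,
                             optimize_others = FALSE) {
  stopifnot(length(parameters) == 2, length(grids) == 2)
  others <- setdiff(names(spec$free), parameters)
  g1 <- grids[[1]]
  g2 <- grids[[2]]
  mat <- matrix(NA_real_, length(g1), length(g2))
  for (rep_i in seq_len(repetitions)) {
    ctx <- prepare_context(spec, resample_tag = rep_i)
    for (i in seq_along(g1)) {
      for (j in seq_along(g2)) {
        par <- stats::setNames(c(g1[i], g2[j]), parameters)
        v <- if (length(others) && optimize_others) {
          lo <- vapply(spec$free[others], `[`, 0, 1)
          hi <- vapply(spec$free[others], `[`, 0, 2)
          fn <- function(x) {
            p2 <- c(par, stats::setNames(x, others))
            vv <- global_chi2(p2, spec, ctx)
            if (is.finite(vv)) vv else 1e6
          }
          pattern_search(fn, (lo + hi) / 2, lo, hi, maxeval = 40,
                         step0 = 0.2)$value
        } else {
          vv <- global_chi2(par, spec, ctx)
          if (is.finite(vv)) vv else NA_real_   # rejected: excluded from scale
        }
        mat[i, j] <- if (rep_i == 1) v else mat[i, j] + v
      }
    }
  }
  mat <- mat / repetitions
  idx <- which(mat == min(mat, na.rm = TRUE), arr.ind = TRUE)[1, ]
  structure(list(parameters = parameters, grid1 = g1, grid2 = g2,
                 chi2 = mat, repetitions = repetitions,
                 minimum = stats::setNames(c(g1[idx[1]], g2[idx[2]]),
                                           parameters)),
            class = "fret_surface")
}

#' @export
print.fret_surface <- function(x, ...) {
  cat(sprintf("<fret_surface> %s x %s (%d x %d), %d repetition(s)\n",
              x$parameters[1], x$parameters[2], length(x$grid1),
              length(x$grid2), x$repetitions))
  cat(sprintf(" minimum chi2 = %.4f at (%s = %.4g, %s = %.4g)\n",
              min(x$chi2, na.rm = TRUE), x$parameters[1], x$minimum[1],
              x$parameters[2], x$minimum[2]))
  invisible(x)
}

#' Tidy a fitted surface into a long tibble
#' @param x A `fret_surface`.
#' @param ... Unused.
#' @return Tibble with the two parameter columns and `chi2`.
#' @export
tidy.fret_surface <- function(x, ...) {
  out <- tidyr::expand_grid(p1 = x$grid1, p2 = x$grid2)
  out$chi2 <- as.vector(t(x$chi2))
  names(out)[1:2] <- x$parameters
  out
}

#' Dominant oscillation period of a scanned quantity
#'
#' Detrends a regularly sampled scan (for example efficiency or chi-square
#' versus the Euler angle sum) and reads the period of the dominant Fourier
#' component. The scan is assumed to cover an integer number of periods.
#'
#' @param x Regular grid (degrees or any unit); the last point must not
#'   duplicate the first.
#' @param y Values on the grid.
#' @return The dominant period, in the units of `x`.
#' @export
dominant_period <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 8)
  span <- diff(range(x)) + (x[2] - x[1])
  amp <- Mod(stats::fft(y - mean(y)))[2:floor(n / 2)]
  span / which.max(amp)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the parameters of a global fit
#'
#' @param x A `fret_fit`.
#' @param conf.int Compute F-statistic confidence intervals per parameter
#'   (can be slow; default `FALSE`).
#' @param conf.level Confidence level.
#' @param ... Passed to [confidence_interval()].
#' @return A tibble with one row per fitted parameter.
#' @export
tidy.fret_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  out <- tibble::tibble(term = names(x$par), estimate = unname(x$par))
  if (conf.int) {
    ci <- dplyr::bind_rows(purrr::map(names(x$par), function(nm) {
      confidence_interval(x, nm, level = conf.level, ...)
    }))
    out$conf.low <- ci$low
    out$conf.high <- ci$high
  }
  out
}

#' One-row summary of a global fit
#'
#' @param x A `fret_fit`.
#' @param ... Unused.
#' @return A tibble: chi2r, n, p, n_curves, method, n_eval.
#' @export
glance.fret_fit <- function(x, ...) {
  tibble::tibble(chi2r = x$chi2r, n = x$n, p = x$p,
                 n_curves = length(x$spec$dataset),
                 method = x$method, n_eval = x$n_eval)
}
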
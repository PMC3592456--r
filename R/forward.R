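# Forward model: chains geometry construction, probe dipole resolution,
# directional sampling, Forster arithmetic and decay reconvolution into the
# per-curve model decays that the global fit compares with measured data.

#' Describe a buildable geometry
#'
#' Either a single duplex or two duplex units joined by a kink. Unit models
#' are built lazily and cached; for kinked geometries the kink can be left
#' unset and supplied at evaluation time (that is what a kink fit varies).
#'
#' @param kind `"duplex"` or `"kinked"`.
#' @param sequence,strand2,step_table,pair_table,form Duplex arguments, see
#'   [build_duplex()].
#' @param unit1,unit2 For kinked geometries: lists of duplex arguments.
#' @param kink Optional [kink_parameters()].
#' @return A `geometry_spec` object.
#' @export
geometry_spec <- function(kind = c("duplex", "kinked"), sequence = NULL,
                          strand2 = NULL, step_table = NULL, pair_table = NULL,
                          form = "B", unit1 = NULL, unit2 = NULL, kink = NULL) {
  kind <- match.arg(kind)
  if (kind == "duplex" && is.null(sequence)) {
    stop("duplex geometry needs a sequence", call. = FALSE)
  }
  if (kind == "kinked" && (is.null(unit1) || is.null(unit2))) {
    stop("kinked geometry needs unit1 and unit2", call. = FALSE)
  }
  structure(list(kind = kind, sequence = sequence, strand2 = strand2,
                 step_table = step_table, pair_table = pair_table, form = form,
                 unit1 = unit1, unit2 = unit2, kink = kink,
                 cache = new.env(parent = emptyenv())),
            class = "geometry_spec")
}

build_unit <- function(args) {
  do.call(build_duplex, args)
}

#' Build the model a geometry spec describes
#'
#' @param geom A [geometry_spec()].
#' @param kink Optional [kink_parameters()] overriding the spec's own.
#' @return An `na_model`.
#' @export
build_geometry <- function(geom, kink = NULL) {
  stopifnot(inherits(geom, "geometry_spec"))
  if (geom$kind == "duplex") {
    if (is.null(geom$cache$model)) {
      geom$cache$model <- build_duplex(geom$sequence, step_table = geom$step_table,
                                       pair_table = geom$pair_table,
                                       strand2 = geom$strand2, form = geom$form)
    }
    return(geom$cache$model)
  }
  if (is.null(geom$cache$u1)) {
    geom$cache$u1 <- build_unit(geom$unit1)
    geom$cache$u2 <- build_unit(geom$unit2)
  }
  kink <- if (!is.null(kink)) as_kink(kink) else geom$kink
  if (is.null(kink)) stop("kinked geometry evaluated without kink parameters",
                          call. = FALSE)
  join_units(geom$cache$u1, geom$cache$u2, kink)
}

#' A single curve of a FRET dataset
#'
#' Bundles one measured (or synthetic) donor decay with its IRF, the
#' donor/acceptor probe positions in the geometry, the per-curve decay
#' nuisance parameters, the photophysics, and the sampling settings for the
#' dipole directional distributions.
#'
#' @param decay Measured [decay_curve()] (may be `NULL` for pure simulation).
#' @param irf IRF [decay_curve()] on the same grid.
#' @param donor,acceptor Lists `list(position, strand, probe)`; `probe`
#'   defaults to the shipped tCO / tCnitro.
#' @param geometry_id Index into the fit spec's geometry list.
#' @param photophysics A [photophysics()] object.
#' @param decay_params A [decay_model_params()]; the amplitude is profiled
#'   analytically during fitting.
#' @param n_samples Vectors per dipole distribution (N = 1000 gives 10^6
#'   donor-acceptor orientation combinations per curve).
#' @param seed Per-curve sampling seed.
#' @param fit_range Optional `c(t_min, t_max)` ns; default starts 0.5 ns
#'   before the IRF peak.
#' @return A `fret_curve` object.
#' @export
fret_curve <- function(decay = NULL, irf, donor, acceptor, geometry_id = 1L,
                       photophysics, decay_params = decay_model_params(),
                       n_samples = 1000, seed = 1, fit_range = NULL) {
  donor <- normalize_site(donor, "tCO")
  acceptor <- normalize_site(acceptor, "tCnitro")
  structure(list(decay = decay, irf = irf, donor = donor, acceptor = acceptor,
                 geometry_id = geometry_id, photophysics = photophysics,
                 decay_params = decay_params, n_samples = n_samples,
                 seed = seed, fit_range = fit_range),
            class = "fret_curve")
}

normalize_site <- function(site, default_probe) {
  if (is.null(site$probe)) site$probe <- default_probe
  if (is.null(site$strand)) site$strand <- "I"
  stopifnot(is.numeric(site$position))
  site
}

#' Global fit specification
#'
#' Everything a global decay analysis needs: the dataset (curves), the
#' geometries they live in, which parameters are free (with bounds), the
#' values of the fixed ones, the dynamics model for the dipole
#' distributions, geometric constraints for kink searches, and the master
#' seed.
#'
#' Free parameters are named: `theta_fwhm`, `phi_fwhm` (degrees; widths of
#' the in-plane and out-of-plane directional densities), `bend_<probe>`
#' (degrees; out-of-plane dipole bend of a registered probe, for example
#' `bend_tCO`), and the kink parameters `v_x`, `v_y`, `v_z` (Angstrom),
#' `alpha`, `beta`, `gamma` (degrees).
#'
#' @param dataset List of [fret_curve()]s.
#' @param geometries List of [geometry_spec()]s.
#' @param free Named list of `c(lower, upper)` bounds.
#' @param fixed Named list of fixed parameter values (defaults:
#'   `theta_fwhm = 13`, `phi_fwhm = 2`; probe bends default to the registry).
#' @param dynamics List: `in_plane` (`"lennard_jones"` or `"harmonic"`),
#'   `depth` (eV), `temperature` (K).
#' @param constraints A [constraint_spec()], or `NULL` to disable screening.
#' @param seed Master seed for objective-side sampling.
#' @param kink_prior Optional `c(lo, hi)` window (degrees) expressing a
#'   preference for solutions with `alpha + gamma` inside the window (used
#'   to resolve the 180-degree Euler degeneracy; off when `NULL`).
#' @param repetitions Number of independent dipole samplings the fit
#'   objective is averaged over (default 1 = single fixed-seed sampling;
#'   averaging tames the Monte-Carlo scatter of the sampled kappa-squared
#'   at the cost of proportionally more computation).
#' @return A `fit_spec` object.
#' @export
fit_spec <- function(dataset, geometries, free = list(), fixed = list(),
                     dynamics = list(), constraints = constraint_spec(),
                     seed = 1, kink_prior = NULL, repetitions = 1) {
  stopifnot(length(dataset) >= 1)
  if (inherits(geometries, "geometry_spec")) geometries <- list(geometries)
  dyn <- utils::modifyList(
    list(in_plane = "lennard_jones", depth = 0.1, temperature = 295), dynamics
  )
  fx <- utils::modifyList(list(theta_fwhm = 13, phi_fwhm = 2), fixed)
  if (length(free)) {
    bad <- names(free)[!vapply(free, function(b) length(b) == 2 &&
                                 all(is.finite(b)) && b[1] < b[2], TRUE)]
    if (length(bad)) stop("free parameter bounds malformed: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(dataset = dataset, geometries = geometries, free = free,
                 fixed = fx, dynamics = dyn, constraints = constraints,
                 seed = seed, kink_prior = kink_prior,
                 repetitions = max(1L, as.integer(repetitions))),
            class = "fit_spec")
}

kink_param_names <- c("v_x", "v_y", "v_z", "alpha", "beta", "gamma")
smooth_param_names <- function(free) {
  setdiff(names(free), c("theta_fwhm", "phi_fwhm",
                         grep("^bend_", names(free), value = TRUE)))
}

# ---- evaluation context -----------------------------------------------------

# Precomputes everything that does not change across objective evaluations:
# cached unit models, per-curve IRF FFTs, fit masks, Poisson weights and the
# uniform draws feeding the inverse-CDF sampler.
prepare_context <- function(spec, resample_tag = 0L) {
  ctx <- new.env(parent = emptyenv())
  ctx$curves <- purrr::map(spec$dataset, function(cv) {
    irf <- cv$irf
    n <- irf$n_channels
    m <- stats::nextn(2L * n - 1L, 2)
    h <- irf$counts / sum(irf$counts)
    irf_fft <- stats::fft(c(h, rep(0, m - n)))
    meas <- if (!is.null(cv$decay)) cv$decay$counts else NULL
    fr <- cv$fit_range
    if (is.null(fr)) {
      # start just before the IRF peak; stop where the decay fades into
      # sparse channels (the measured-count Poisson weights 1/max(I,1) are
      # increasingly biased below a few tens of counts)
      t_end <- if (!is.null(meas) && any(meas >= 30)) {
        max(irf$time[meas >= 30])
      } else {
        max(irf$time)
      }
      fr <- c(irf$time[which.max(irf$counts)] - 0.5, t_end)
    }
    mask <- irf$time >= fr[1] & irf$time <= fr[2]
    seed_u <- derive_seed(cv$seed, resample_tag)
    u <- with_seed(seed_u, function() {
      list(td = stats::runif(cv$n_samples), pd = stats::runif(cv$n_samples),
           ta = stats::runif(cv$n_samples), pa = stats::runif(cv$n_samples))
    })
    list(n = n, m = m, irf_fft = irf_fft, times = irf$time, mask = mask,
         meas = meas, w = if (!is.null(meas)) 1 / pmax(meas, 1) else NULL,
         u = u)
  })
  ctx
}

fft_convolve_cached <- function(x, cc) {
  z <- Re(stats::fft(stats::fft(c(x, rep(0, cc$m - cc$n))) * cc$irf_fft,
                     inverse = TRUE)) / cc$m
  pmax(z[1:cc$n], 0)
}

# merge free-par vector over fixed values
resolve_params <- function(par, spec) {
  p <- spec$fixed
  for (nm in names(par)) p[[nm]] <- unname(par[[nm]])
  p
}

resolve_bend <- function(params, probe_name) {
  key <- paste0("bend_", probe_name)
  if (!is.null(params[[key]])) return(params[[key]])
  probe_registry()[[probe_name]]$bend_angle
}

params_kink <- function(params) {
  if (!all(kink_param_names %in% names(params))) return(NULL)
  kink_parameters(params$v_x, params$v_y, params$v_z,
                  params$alpha, params$beta, params$gamma)
}

# Evaluate all model curves for a parameter set. Returns NULL (with
# violations attribute) when constraints reject the geometry.
eval_forward <- function(par, spec, ctx) {
  params <- resolve_params(par, spec)
  key <- sprintf("%s|%.8g|%.8g", spec$dynamics$in_plane, params$theta_fwhm,
                 params$phi_fwhm)
  if (is.null(ctx$pdf_key) || ctx$pdf_key != key) {
    p_in <- boltzmann_pdf(potential_spec(spec$dynamics$in_plane,
                                         target_fwhm = params$theta_fwhm,
                                         depth = spec$dynamics$depth,
                                         temperature = spec$dynamics$temperature))
    p_out <- boltzmann_pdf(potential_spec("harmonic",
                                          target_fwhm = params$phi_fwhm,
                                          temperature = spec$dynamics$temperature))
    if (pdf_tail_mass(p_out, 85) >= 1e-9) {
      stop("out-of-plane distribution too wide (phi guard)", call. = FALSE)
    }
    ctx$pdf_key <- key
    ctx$q_in <- inverse_cdf_fun(p_in)
    ctx$q_out <- inverse_cdf_fun(p_out)
  }
  q_in <- ctx$q_in
  q_out <- ctx$q_out
  kink <- params_kink(params)
  models <- vector("list", length(spec$geometries))
  all_viol <- list()
  for (g in seq_along(spec$geometries)) {
    models[[g]] <- build_geometry(spec$geometries[[g]], kink = kink)
    if (!is.null(spec$constraints) && max(models[[g]]$units) > 1) {
      chk <- check_constraints(models[[g]], spec$constraints)
      if (!chk$pass) all_viol <- c(all_viol, list(chk$violations))
    }
  }
  if (!is.null(spec$kink_prior) && !is.null(kink)) {
    ag <- (kink[["alpha"]] + kink[["gamma"]]) %% 360
    if (ag < spec$kink_prior[1] || ag > spec$kink_prior[2]) {
      all_viol <- c(all_viol, list(tibble::tibble(
        type = "prior", detail = "alpha+gamma outside preference window",
        value = ag
      )))
    }
  }
  if (length(all_viol)) {
    return(structure(list(violations = dplyr::bind_rows(all_viol)),
                     class = "fret_rejected"))
  }

  reg <- probe_registry()
  purrr::map(seq_along(spec$dataset), function(i) {
    cv <- spec$dataset[[i]]
    cc <- ctx$curves[[i]]
    model <- models[[cv$geometry_id]]
    pd <- reg[[cv$donor$probe]]
    pa <- reg[[cv$acceptor$probe]]
    dip_d <- probe_site_dipole(model, cv$donor, pd,
                               resolve_bend(params, cv$donor$probe))
    dip_a <- probe_site_dipole(model, cv$acceptor, pa,
                               resolve_bend(params, cv$acceptor$probe))
    vd <- aligned_set(cc$u$td, cc$u$pd, q_in, q_out, dip_d)
    va <- aligned_set(cc$u$ta, cc$u$pa, q_in, q_out, dip_a)
    r_vec <- dip_a$center - dip_d$center
    k2 <- mean_kappa_sq(vd, va, r_vec)
    R <- sqrt(sum(r_vec^2))
    kt <- transfer_rate(k2, R, cv$photophysics)
    shape <- total_decay(cv$decay_params, kt, cv$photophysics$donor_lifetime,
                         cc$times)
    conv <- fft_convolve_cached(shape, cc)
    list(curve = i, kappa_sq = k2, R = R, k_T = kt,
         E = kt / (kt + 1 / cv$photophysics$donor_lifetime),
         model_counts = conv)
  })
}

probe_site_dipole <- function(model, site, probe, bend) {
  frame <- if (site$strand == "I") model$base_frames_1[[site$position]] else
    model$base_frames_2[[site$position]]
  local_dir <- bent_dipole_local(probe$dipole_direction, bend)
  list(center = as.numeric(frame$origin + frame$axes %*% probe$dipole_center),
       direction = unit_vec(as.numeric(frame$axes %*% local_dir)),
       frame = frame)
}

aligned_set <- function(u_theta, u_phi, q_in, q_out, dip) {
  samples <- list(theta = q_in(u_theta), phi = q_out(u_phi))
  to_cartesian_aligned(samples, dip$direction, dip$frame, center = dip$center)
}

#' Run the forward model of a fit specification
#'
#' Builds the geometries, resolves and samples the probe dipoles, computes
#' the Forster quantities and returns the per-curve model decays (IRF
#' convolved, amplitude profiled against the measured decay when present).
#'
#' @param spec A [fit_spec()].
#' @param par Optional named vector of free-parameter values to evaluate.
#' @return A list: `curves` (tibble with kappa_sq, R, E, k_T, amplitude,
#'   chi2r per curve), `model_counts` (list of numeric vectors), and
#'   `rejected`/`violations` when constraints discard the geometry.
#' @export
forward_model <- function(spec, par = NULL) {
  stopifnot(inherits(spec, "fit_spec"))
  ctx <- prepare_context(spec)
  res <- eval_forward(par, spec, ctx)
  if (inherits(res, "fret_rejected")) {
    return(list(rejected = TRUE, violations = res$violations))
  }
  rows <- purrr::map(seq_along(res), function(i) {
    r <- res[[i]]
    cc <- ctx$curves[[i]]
    amp <- 1
    chi2 <- NA_real_
    if (!is.null(cc$meas)) {
      amp <- profile_amplitude(cc, r$model_counts)
      chi2 <- sum(cc$w[cc$mask] *
                    (cc$meas[cc$mask] - amp * r$model_counts[cc$mask])^2) /
        (sum(cc$mask) - length(spec$free))
    }
    tibble::tibble(curve = i, kappa_sq = r$kappa_sq, R = r$R, E = r$E,
                   k_T = r$k_T, amplitude = amp, chi2r = chi2)
  })
  list(curves = dplyr::bind_rows(rows),
       model_counts = purrr::map(seq_along(res), function(i) {
         amp <- rows[[i]]$amplitude
         res[[i]]$model_counts * amp
       }),
       rejected = FALSE)
}

profile_amplitude <- function(cc, model_counts) {
  mm <- cc$mask
  num <- sum(cc$w[mm] * cc$meas[mm] * model_counts[mm])
  den <- sum(cc$w[mm] * model_counts[mm]^2)
  if (den <= 0) return(0)
  max(num / den, 0)
}

#' Pooled reduced chi-square of a parameter vector
#'
#' Single reduced chi-square pooling Poisson-weighted residuals over every
#' curve of the dataset (`n` = unmasked channels summed over curves, `p` =
#' number of free parameters). Geometries rejected by the constraints yield
#' `Inf` carrying a `violations` attribute — a sentinel, not a value
#' comparable with valid fits.
#'
#' @param par Named vector of free-parameter values.
#' @param spec A [fit_spec()] whose curves carry measured decays.
#' @param ctx Internal evaluation context (rebuilt when `NULL`).
#' @return Reduced chi-square, or `Inf` with attribute `violations`.
#' @export
global_chi2 <- function(par, spec, ctx = NULL) {
  if (is.null(ctx)) ctx <- prepare_context(spec)
  res <- eval_forward(par, spec, ctx)
  if (inherits(res, "fret_rejected")) {
    out <- Inf
    attr(out, "violations") <- res$violations
    return(out)
  }
  ss <- 0
  n_tot <- 0
  for (i in seq_along(res)) {
    cc <- ctx$curves[[i]]
    if (is.null(cc$meas)) stop("curve ", i, " has no measured decay",
                               call. = FALSE)
    amp <- profile_amplitude(cc, res[[i]]$model_counts)
    mm <- cc$mask
    ss <- ss + sum(cc$w[mm] * (cc$meas[mm] - amp * res[[i]]$model_counts[mm])^2)
    n_tot <- n_tot + sum(mm)
  }
  p <- length(spec$free)
  ss / (n_tot - p)
}
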
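#' Photophysical parameters of a FRET pair
#'
#' Container for the spectroscopic quantities entering the Forster rate: the
#' donor quantum yield in absence of acceptor, the donor-emission /
#' acceptor-absorption spectral overlap integral, the refractive index, the
#' donor lifetime, and (optionally precomputed) the critical Forster
#' distance. If `forster_radius` is omitted it is computed from the other
#' parameters with the isotropic orientation average (kappa-squared = 2/3)
#' baked in, so that the transfer rate carries orientation separately as
#' `(3/2) kappa^2`.
#'
#' @param quantum_yield Donor quantum yield, in (0, 1].
#' @param overlap_integral Spectral overlap J, M^-1 cm^-1 nm^4.
#' @param refractive_index Medium refractive index (dimensionless).
#' @param donor_lifetime Donor lifetime without acceptor, ns.
#' @param forster_radius Optional critical distance R0, Angstrom.
#' @return A `photophysics` list with all five fields populated.
#' @examples
#' ph <- photophysics(quantum_yield = 0.3, overlap_integral = 1e13,
#'                    refractive_index = 1.4, donor_lifetime = 4.3)
#' ph$forster_radius
#' @export
photophysics <- function(quantum_yield = NULL, overlap_integral = NULL,
                         refractive_index = NULL, donor_lifetime,
                         forster_radius = NULL) {
  if (!is_number(donor_lifetime) || donor_lifetime <= 0) {
    stop("donor_lifetime must be positive", call. = FALSE)
  }
  if (is.null(forster_radius)) {
    forster_radius <- forster_radius(
      quantum_yield = quantum_yield, overlap_integral = overlap_integral,
      refractive_index = refractive_index
    )
  } else if (!is_number(forster_radius) || forster_radius < 0) {
    stop("forster_radius must be non-negative", call. = FALSE)
  }
  structure(list(
    quantum_yield = quantum_yield, overlap_integral = overlap_integral,
    refractive_index = refractive_index, donor_lifetime = donor_lifetime,
    forster_radius = forster_radius
  ), class = "photophysics")
}

#' Critical Forster distance
#'
#' `R0^6 = 8.79e-5 * (2/3) * quantum_yield * J / eta^4` with R0 in Angstrom
#' and J in M^-1 cm^-1 nm^4: the textbook constant with the isotropic
#' orientation average baked in, so that the transfer efficiency is 0.5 at
#' `R = R0` under dynamic isotropic averaging.
#'
#' @inheritParams photophysics
#' @return R0 in Angstrom.
#' @export
forster_radius <- function(quantum_yield, overlap_integral, refractive_index) {
  if (!is_number(overlap_integral) || overlap_integral <= 0 ||
      !is_number(refractive_index) || refractive_index <= 0 ||
      !is_number(quantum_yield) || quantum_yield < 0 || quantum_yield > 1) {
    stop("photophysical parameters must be positive (quantum yield in [0, 1])",
         call. = FALSE)
  }
  (8.79e-5 * (2 / 3) * quantum_yield * overlap_integral /
     refractive_index^4)^(1 / 6)
}

#' Orientation factor kappa
#'
#' `kappa = mu_D . mu_A - 3 (mu_D . Rhat)(mu_A . Rhat)`, bounded to
#' \[-2, 2\]; its square enters the transfer rate.
#'
#' @param mu_D,mu_A Donor/acceptor transition-dipole unit vectors.
#' @param r_DA Vector from donor to acceptor dipole center, Angstrom.
#' @return kappa (dimensionless).
#' @export
kappa <- function(mu_D, mu_A, r_DA) {
  mu_D <- vec3(mu_D, "mu_D")
  mu_A <- vec3(mu_A, "mu_A")
  r_DA <- vec3(r_DA, "r_DA")
  rn <- sqrt(sum(r_DA^2))
  if (rn == 0) stop("degenerate geometry: zero donor-acceptor separation",
                    call. = FALSE)
  rh <- r_DA / rn
  sum(mu_D * mu_A) - 3 * sum(mu_D * rh) * sum(mu_A * rh)
}

#' Distance between two dipole centers
#'
#' @param p1,p2 3-vectors, Angstrom.
#' @return Euclidean distance, Angstrom.
#' @export
center_distance <- function(p1, p2) {
  sqrt(sum((vec3(p1) - vec3(p2))^2))
}

#' Energy transfer rate
#'
#' `k_T = (3/2) kappa^2 (1/tau_D) (R0/R)^6` with R0 the isotropic-average
#' critical distance, so `kappa^2 = 2/3` at `R = R0` gives `k_T = 1/tau_D`.
#'
#' @param kappa_sq Orientation factor squared (possibly averaged).
#' @param R Donor-acceptor distance, Angstrom.
#' @param params A [photophysics()] object.
#' @return Transfer rate in 1/ns.
#' @export
transfer_rate <- function(kappa_sq, R, params) {
  if (!is_number(R) || R <= 0) {
    stop("degenerate geometry: R must be positive", call. = FALSE)
  }
  if (!is_number(kappa_sq) || kappa_sq < 0) {
    stop("kappa_sq must be non-negative", call. = FALSE)
  }
  (3 / 2) * kappa_sq * (1 / params$donor_lifetime) *
    (params$forster_radius / R)^6
}

#' FRET efficiency
#'
#' `E = k_T / (k_T + 1/tau_D)` in the dynamic averaging regime.
#'
#' @inheritParams transfer_rate
#' @return Efficiency in \[0, 1\].
#' @export
efficiency <- function(kappa_sq, R, params) {
  kt <- transfer_rate(kappa_sq, R, params)
  kt / (kt + 1 / params$donor_lifetime)
}

#' Mean squared orientation factor over two dipole vector sets
#'
#' The arithmetic mean of `kappa^2` over all `N_D x N_A` ordered pairs of
#' sampled donor and acceptor dipole vectors, computed exactly through the
#' second-moment matrices of the two sets:
#' `tr(S_D S_A) - 6 Rhat' S_D S_A Rhat + 9 (Rhat' S_D Rhat)(Rhat' S_A Rhat)`
#' where `S = (1/N) sum(mu mu')`. This is algebraically identical to the
#' pairwise sum (1e6 pair evaluations at N = 1000 per probe) at O(N) cost.
#'
#' @param donor_set,acceptor_set [dipole_vector_set()] objects or N x 3
#'   matrices of unit vectors.
#' @param r_DA Donor-to-acceptor center vector, Angstrom.
#' @return Mean kappa-squared (dimensionless, in \[0, 4\]).
#' @export
mean_kappa_sq <- function(donor_set, acceptor_set, r_DA) {
  md <- vectors_of(donor_set)
  ma <- vectors_of(acceptor_set)
  if (nrow(md) == 0 || nrow(ma) == 0) {
    stop("dipole vector sets must be nonempty", call. = FALSE)
  }
  r_DA <- vec3(r_DA, "r_DA")
  rn <- sqrt(sum(r_DA^2))
  if (rn == 0) stop("degenerate geometry: zero donor-acceptor separation",
                    call. = FALSE)
  rh <- r_DA / rn
  sd_ <- crossprod(md) / nrow(md)
  sa_ <- crossprod(ma) / nrow(ma)
  sda <- sd_ %*% sa_
  qd <- as.numeric(rh %*% sd_ %*% rh)
  qa <- as.numeric(rh %*% sa_ %*% rh)
  sum(diag(sda)) - 6 * as.numeric(rh %*% sda %*% rh) + 9 * qd * qa
}

vectors_of <- function(x) {
  if (inherits(x, "dipole_vector_set")) return(x$vectors)
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("expected an N x 3 matrix of unit vectors",
                          call. = FALSE)
  x
}

#' Static FRET observables between two placed probes
#'
#' Computes kappa, R and E between a donor and an acceptor probe already
#' placed in a model, using the static (un-averaged) resolved dipoles.
#'
#' @param model An `na_model`.
#' @param donor,acceptor Lists with `position` and `strand` locating the two
#'   probes.
#' @param params A [photophysics()] object.
#' @return A tibble with one row: kappa, kappa_sq, R, E, k_T.
#' @export
fret_observables <- function(model, donor, acceptor, params) {
  d <- resolve_dipole(model, donor$position, donor$strand)
  a <- resolve_dipole(model, acceptor$position, acceptor$strand)
  r_vec <- a$center - d$center
  k <- kappa(d$direction, a$direction, r_vec)
  R <- sqrt(sum(r_vec^2))
  tibble::tibble(
    kappa = k, kappa_sq = k^2, R = R,
    E = efficiency(k^2, R, params),
    k_T = transfer_rate(k^2, R, params)
  )
}

#' Screen donor/acceptor position combinations between two structures
#'
#' Evaluates the static FRET efficiency of every donor x acceptor position
#' combination in two models of the same layout (for example straight versus
#' kinked) and ranks combinations by the absolute efficiency change, the
#' criterion used to pick informative probe placements.
#'
#' @param model_A,model_B `na_model` objects with identical pair counts.
#' @param donor_positions,acceptor_positions Tibbles/data frames with columns
#'   `position` and `strand` (strand defaults to "I" for donors, "II" for
#'   acceptors when absent), or plain integer vectors of positions.
#' @param params A [photophysics()] object.
#' @param donor_probe,acceptor_probe Probe names used at screened positions
#'   (defaults: shipped tCO / tCnitro).
#' @return A tibble sorted by `abs(dE)` descending (index tie-break):
#'   donor_pos, donor_strand, acceptor_pos, acceptor_strand, E_A, E_B, dE.
#' @export
screen_pairs <- function(model_A, model_B, donor_positions, acceptor_positions,
                         params, donor_probe = "tCO",
                         acceptor_probe = "tCnitro") {
  if (n_pairs(model_A) != n_pairs(model_B)) {
    stop("models must have the same number of base pairs", call. = FALSE)
  }
  dp <- normalize_positions(donor_positions, "I")
  ap <- normalize_positions(acceptor_positions, "II")
  grid <- tidyr::crossing(d = seq_len(nrow(dp)), a = seq_len(nrow(ap)))
  rows <- purrr::pmap(grid, function(d, a) {
    don <- dp[d, ]
    acc <- ap[a, ]
    if (don$position == acc$position && don$strand == acc$strand) {
      warning(sprintf("skipping collision at position %d strand %s",
                      don$position, don$strand), call. = FALSE)
      return(NULL)
    }
    ea <- screened_efficiency(model_A, don, acc, params,
                              donor_probe, acceptor_probe)
    eb <- screened_efficiency(model_B, don, acc, params,
                              donor_probe, acceptor_probe)
    tibble::tibble(
      donor_pos = don$position, donor_strand = don$strand,
      acceptor_pos = acc$position, acceptor_strand = acc$strand,
      E_A = ea, E_B = eb, dE = eb - ea
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(donor_pos = integer(), donor_strand = character(),
                          acceptor_pos = integer(),
                          acceptor_strand = character(),
                          E_A = numeric(), E_B = numeric(), dE = numeric()))
  }
  out$.ord <- seq_len(nrow(out))
  out <- out[order(-abs(out$dE), out$.ord), ]
  out$.ord <- NULL
  out
}

normalize_positions <- function(x, default_strand) {
  if (is.numeric(x)) {
    return(tibble::tibble(position = as.integer(x), strand = default_strand))
  }
  x <- tibble::as_tibble(x)
  if (!"strand" %in% names(x)) x$strand <- default_strand
  x[, c("position", "strand")]
}

# efficiency with a probe virtually substituted at the given positions: the
# probes' dipoles are evaluated in the host base frames of the two models
screened_efficiency <- function(model, donor, acceptor, params,
                                donor_probe, acceptor_probe) {
  reg <- probe_registry()
  d <- virtual_dipole(model, donor$position, donor$strand, reg[[donor_probe]])
  a <- virtual_dipole(model, acceptor$position, acceptor$strand,
                      reg[[acceptor_probe]])
  r_vec <- a$center - d$center
  k <- kappa(d$direction, a$direction, r_vec)
  efficiency(k^2, sqrt(sum(r_vec^2)), params)
}

virtual_dipole <- function(model, position, strand, probe) {
  frame <- if (strand == "I") model$base_frames_1[[position]] else
    model$base_frames_2[[position]]
  local_dir <- bent_dipole_local(probe$dipole_direction, probe$bend_angle)
  list(
    center = as.numeric(frame$origin + frame$axes %*% probe$dipole_center),
    direction = unit_vec(as.numeric(frame$axes %*% local_dir))
  )
}
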
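# Dipole directional distributions: 1D Boltzmann densities over the in-plane
# (theta) and out-of-plane (phi) rotation angles of a base probe, sampled and
# mapped onto the unit sphere around the probe's transition dipole.

k_boltzmann_ev <- 8.617333262e-5  # eV / K

#' Specify an angular potential
#'
#' A 1D potential energy function for one rotational mode of a base probe,
#' parameterized by the full width at half maximum of the resulting Boltzmann
#' angular density rather than by a raw stiffness. `"harmonic"` gives a
#' Gaussian density (used for out-of-plane stacking libration);
#' `"lennard_jones"` evaluates a 12-6 potential along a shifted coordinate
#' `r(theta) = r_eq + s * theta`, giving the steep-compression / soft-stretch
#' asymmetry expected of a hydrogen bond, with the length scale `s`
#' calibrated so the density FWHM matches `target_fwhm`.
#'
#' @param kind `"harmonic"` or `"lennard_jones"`.
#' @param target_fwhm Target FWHM of the Boltzmann density, degrees.
#' @param depth Dissociation energy of the Lennard-Jones potential, eV
#'   (default 0.1 eV, an average C-G hydrogen-bond energy).
#' @param temperature Temperature, K (default 295 K).
#' @return A `potential_spec` list.
#' @export
potential_spec <- function(kind = c("harmonic", "lennard_jones"),
                           target_fwhm, depth = 0.1, temperature = 295) {
  kind <- match.arg(kind)
  if (!is_number(target_fwhm) || target_fwhm <= 0) {
    stop("target_fwhm must be positive", call. = FALSE)
  }
  if (!is_number(depth) || depth <= 0) stop("depth must be positive", call. = FALSE)
  if (!is_number(temperature) || temperature <= 0) {
    stop("temperature must be positive", call. = FALSE)
  }
  structure(list(kind = kind, target_fwhm = target_fwhm, depth = depth,
                 temperature = temperature), class = "potential_spec")
}

lj_energy <- function(r, r_eq = 3, depth = 0.1) {
  x <- (r_eq / r)^6
  depth * (x^2 - 2 * x)
}

# Lennard-Jones Boltzmann density over the angular grid for scale s (A/deg).
# Positive theta is the bond-stretch direction. Values where r <= 0 get zero
# density (infinitely repulsive core).
lj_density_raw <- function(theta, s, depth, temperature, r_eq = 3) {
  r <- r_eq + s * theta
  kt <- k_boltzmann_ev * temperature
  v <- rep(Inf, length(theta))
  ok <- r > 0
  v[ok] <- lj_energy(r[ok], r_eq, depth)
  exp(-(v - (-depth)) / kt)
}

# measure the FWHM of a gridded density by interpolated half-max crossings
measure_fwhm <- function(angle, density) {
  i_max <- which.max(density)
  half <- density[i_max] / 2
  cross <- function(idx_range) {
    d <- density[idx_range]
    a <- angle[idx_range]
    below <- which(d < half)
    if (length(below) == 0) return(NA_real_)
    # nearest below-half point to the peak side
    j <- if (a[1] < angle[i_max]) max(below) else min(below)
    k <- if (a[1] < angle[i_max]) j + 1L else j - 1L
    if (k < 1 || k > length(d)) return(NA_real_)
    a[j] + (half - d[j]) * (a[k] - a[j]) / (d[k] - d[j])
  }
  left <- cross(seq_len(i_max))
  right <- cross(i_max:length(angle))
  if (is.na(left) || is.na(right)) return(NA_real_)
  right - left
}

#' Boltzmann angular probability density
#'
#' Builds the normalized Boltzmann density `P(angle) ~ exp(-V(angle)/kT)` on
#' a degree grid for the given potential, calibrated so its measured FWHM
#' equals the spec's target. Harmonic potentials yield a Gaussian density;
#' Lennard-Jones densities are asymmetric with the heavier tail on the
#' bond-stretch (positive-angle) side. The in-plane angular domain is
#' truncated at +/- 60 degrees (the Lennard-Jones density has a
#' dissociation plateau and is only normalizable on a bounded domain).
#'
#' @param spec A [potential_spec()].
#' @param n_grid Number of grid points.
#' @return An `angular_pdf` list: `angle` (degrees), `density` (1/degree,
#'   integrating to 1), `fwhm` (measured, degrees), and the spec.
#' @export
boltzmann_pdf <- function(spec, n_grid = 4001) {
  stopifnot(inherits(spec, "potential_spec"))
  if (spec$kind == "harmonic") {
    sigma <- spec$target_fwhm / (2 * sqrt(2 * log(2)))
    lim <- min(max(6 * sigma, 1), 179)
    angle <- seq(-lim, lim, length.out = n_grid)
    density <- exp(-angle^2 / (2 * sigma^2))
  } else {
    s <- calibrate_width("lennard_jones", spec$depth, spec$temperature,
                         spec$target_fwhm)
    angle <- seq(-60, 60, length.out = n_grid)
    density <- lj_density_raw(angle, s, spec$depth, spec$temperature)
  }
  z <- trapz(angle, density)
  if (!is.finite(z) || z <= 0) {
    stop("density could not be normalized on the grid", call. = FALSE)
  }
  density <- density / z
  fwhm <- measure_fwhm(angle, density)
  if (is.na(fwhm)) {
    stop("target FWHM not resolvable on the angular grid", call. = FALSE)
  }
  structure(list(angle = angle, density = density, fwhm = fwhm, spec = spec),
            class = "angular_pdf")
}

#' Calibrate a potential's length scale to a target angular FWHM
#'
#' Solves (deterministically, by bisection) for the length scale that makes
#' the Boltzmann density's measured FWHM equal the target to 0.5%. For the
#' harmonic potential the closed form `sigma = FWHM / (2 sqrt(2 ln 2))` is
#' returned directly.
#'
#' @param kind `"harmonic"` or `"lennard_jones"`.
#' @param depth LJ dissociation energy, eV.
#' @param temperature Temperature, K.
#' @param target_fwhm Target FWHM, degrees, in (0, 60).
#' @return The length scale: Gaussian sigma in degrees (harmonic) or the
#'   angular-to-radial scale `s` in Angstrom/degree (Lennard-Jones).
#' @export
calibrate_width <- function(kind, depth, temperature, target_fwhm) {
  if (!is_number(target_fwhm) || target_fwhm <= 0 || target_fwhm >= 60) {
    stop("target_fwhm must lie in (0, 60) degrees", call. = FALSE)
  }
  if (kind == "harmonic") {
    return(target_fwhm / (2 * sqrt(2 * log(2))))
  }
  grid <- seq(-60, 60, length.out = 4001)
  fw_of <- function(s) {
    d <- lj_density_raw(grid, s, depth, temperature)
    measure_fwhm(grid, d / trapz(grid, d))
  }
  # the angular FWHM shrinks as the angular-to-radial scale s grows
  lo <- 1e-4
  hi <- 0.5
  f_lo <- fw_of(lo)
  f_hi <- fw_of(hi)
  it <- 0
  while (!is.na(f_hi) && f_hi > target_fwhm && it < 20) {
    hi <- hi * 2
    f_hi <- fw_of(hi)
    it <- it + 1
  }
  # an NA at the wide end means the density is flat on the grid (wider than
  # any measurable FWHM), which still brackets the target from above
  if ((!is.na(f_lo) && f_lo < target_fwhm) ||
      is.na(f_hi) || f_hi > target_fwhm) {
    stop("no bracket for FWHM calibration", call. = FALSE)
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    fm <- fw_of(mid)
    if (is.na(fm)) { lo <- mid; next }
    if (fm > target_fwhm) lo <- mid else hi <- mid
    if (abs(fm - target_fwhm) / target_fwhm < 5e-4) return(mid)
  }
  (lo + hi) / 2
}

#' Sample spherical angles from two marginal densities
#'
#' Draws `n` independent (theta, phi) pairs from the in-plane and
#' out-of-plane densities by inverse-CDF sampling on the grids, implementing
#' the product form of the joint distribution. The out-of-plane density must
#' keep essentially all mass inside |phi| < 85 degrees; wider distributions
#' are refused rather than distorted (samples near phi = +/-90 would pile up
#' at the sphere poles).
#'
#' @param p_in,p_out [boltzmann_pdf()] densities for theta and phi.
#' @param n Number of samples.
#' @param seed Integer seed (draws are reproducible per seed).
#' @return A list with numeric vectors `theta` and `phi` (degrees).
#' @export
sample_orientations <- function(p_in, p_out, n, seed = 1) {
  stopifnot(inherits(p_in, "angular_pdf"), inherits(p_out, "angular_pdf"))
  if (!is_number(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  tail_mass <- pdf_tail_mass(p_out, 85)
  if (tail_mass >= 1e-9) {
    stop("out-of-plane distribution too wide: mass beyond |phi| = 85 degrees",
         call. = FALSE)
  }
  with_seed(seed, function() {
    list(
      theta = inverse_cdf_draw(p_in, stats::runif(n)),
      phi = inverse_cdf_draw(p_out, stats::runif(n))
    )
  })
}

pdf_tail_mass <- function(pdf, limit) {
  out <- abs(pdf$angle) >= limit
  if (!any(out)) return(0)
  trapz_masked(pdf$angle, pdf$density, out)
}

trapz_masked <- function(x, y, mask) {
  y2 <- y
  y2[!mask] <- 0
  trapz(x, y2)
}

inverse_cdf_draw <- function(pdf, u) {
  inverse_cdf_fun(pdf)(u)
}

# interpolating inverse-CDF of a gridded density; built once and reused for
# every uniform draw mapped through the same density
inverse_cdf_fun <- function(pdf) {
  x <- pdf$angle
  d <- pdf$density
  n <- length(x)
  seg <- (d[-1] + d[-n]) * diff(x) / 2
  cdf <- c(0, cumsum(seg))
  cdf <- cdf / cdf[n]
  keep <- c(TRUE, diff(cdf) > 0)
  stats::approxfun(cdf[keep], x[keep], rule = 2)
}

#' Map sampled angles to aligned dipole unit vectors
#'
#' Each (theta, phi) sample becomes the unit vector
#' `cos(phi) cos(theta) e1 + cos(phi) sin(theta) e2 + sin(phi) e3` where `e1`
#' is the probe's resolved dipole direction, `e2` the in-plane perpendicular
#' and `e3` the base-plane normal, so the distribution mode coincides with
#' the dipole and no samples accumulate at the sphere poles.
#'
#' @param samples List with `theta`, `phi` (degrees) from
#'   [sample_orientations()].
#' @param dipole_direction Global unit vector (distribution mode).
#' @param base_frame The probe's base [ref_frame()] supplying the base-plane
#'   normal (its local z axis).
#' @param center Dipole center recorded in the result, Angstrom.
#' @param seed Seed recorded as generation metadata.
#' @return A `dipole_vector_set`: `vectors` (N x 3, unit rows), `center`,
#'   `seed`.
#' @export
to_cartesian_aligned <- function(samples, dipole_direction, base_frame,
                                 center = c(0, 0, 0), seed = NA_integer_) {
  e1 <- unit_vec(vec3(dipole_direction, "dipole_direction"))
  stopifnot(is_ref_frame(base_frame))
  normal <- base_frame$axes[, 3]
  e2 <- c(
    normal[2] * e1[3] - normal[3] * e1[2],
    normal[3] * e1[1] - normal[1] * e1[3],
    normal[1] * e1[2] - normal[2] * e1[1]
  )
  if (sqrt(sum(e2^2)) < 1e-8) {
    stop("degenerate frame: dipole parallel to the base normal", call. = FALSE)
  }
  e2 <- unit_vec(e2)
  e3 <- c(
    e1[2] * e2[3] - e1[3] * e2[2],
    e1[3] * e2[1] - e1[1] * e2[3],
    e1[1] * e2[2] - e1[2] * e2[1]
  )
  th <- deg2rad(samples$theta)
  ph <- deg2rad(samples$phi)
  v <- cbind(cos(ph) * cos(th), cos(ph) * sin(th), sin(ph)) %*%
    rbind(e1, e2, e3)
  dipole_vector_set(v, center = center, seed = seed)
}

#' Dipole vector set
#'
#' N sampled unit vectors (global frame) representing the directional
#' distribution a transition dipole traces during energy transfer, plus the
#' dipole center and generation metadata.
#'
#' @param vectors N x 3 matrix of unit rows.
#' @param center Dipole center, Angstrom.
#' @param seed Seed used to generate the samples.
#' @return A `dipole_vector_set` object.
#' @export
dipole_vector_set <- function(vectors, center = c(0, 0, 0), seed = NA_integer_) {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != 3L || nrow(vectors) < 1L) {
    stop("vectors must be a nonempty N x 3 matrix", call. = FALSE)
  }
  norms <- sqrt(rowSums(vectors^2))
  if (any(abs(norms - 1) > 1e-8)) {
    stop("all vectors must be unit norm", call. = FALSE)
  }
  vectors <- vectors / norms
  structure(list(vectors = unname(vectors), center = vec3(center),
                 seed = seed),
            class = "dipole_vector_set")
}

#' @export
print.dipole_vector_set <- function(x, ...) {
  cat(sprintf("<dipole_vector_set> N = %d, seed = %s\n",
              nrow(x$vectors), as.character(x$seed)))
  invisible(x)
}

# Convenience: build the aligned vector set for a placed probe of a model.
sample_probe_dipoles <- function(model, position, strand, p_in, p_out, n, seed,
                                 bend_angle = NULL) {
  dip <- resolve_dipole(model, position, strand, bend_angle = bend_angle)
  frame <- if (strand == "I") model$base_frames_1[[position]] else
    model$base_frames_2[[position]]
  s <- sample_orientations(p_in, p_out, n, seed)
  to_cartesian_aligned(s, dip$direction, frame, center = dip$center, seed = seed)
}
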
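# Synthetic demonstration-study fixtures: B-form duplexes carrying the
# tCO/tCnitro pair at nine separations (study 1) and two-unit kinked
# constructs with the pair flanking the junction (study 2, 0A and 3A
# bulges), forward-simulated and Poisson-noised at TCSPC acquisition
# settings of 2048 channels / 100 ns / 60 ps IRF / >= 10^4 peak counts.

study1_truth <- function() {
  list(theta_fwhm = 13.1, phi_fwhm = 2, bend_tCO = 8.2, bend_tCnitro = 25)
}

study2_truth <- function(study) {
  dyn <- list(theta_fwhm = 13, phi_fwhm = 2, bend_tCO = 8, bend_tCnitro = 25)
  kink <- if (study == "study2_0A") {
    list(v_x = -0.55, v_y = -1.1, v_z = 3.3, alpha = 15, beta = 1, gamma = 16)
  } else {
    list(v_x = 7.4, v_y = -0.55, v_z = 5.5, alpha = 101, beta = 57, gamma = -43)
  }
  c(dyn, kink)
}

fixture_photophysics <- function() {
  photophysics(donor_lifetime = 4.3, forster_radius = 27)
}

fixture_decay_params <- function() {
  decay_model_params(coupled_fraction = 0.95, donor_fraction = 0.98,
                     other_lifetime = 1)
}

# strand-I motif for study 1: donor host at position 4, guanines at the
# acceptor host positions 10..18 (separations 5..13 base pairs)
study1_motif <- function() "ATCCATCGAGGGGGGGGGCA"

study2_units <- function(kink_position) {
  if (kink_position == 1L) {
    list(u1 = "ATCGAGCCTA", u2 = "AGGGTACGCA")
  } else {
    list(u1 = "ATCGAGCCTAAG", u2 = "AGGGTACG")
  }
}

study2_combos <- function(study) {
  combos <- tidyr::expand_grid(dd = 2:4, da = 2:4)
  if (study == "study2_3A") combos <- combos[!(combos$dd == 4 & combos$da == 4), ]
  combos
}

#' Generate a demonstration-study fixture
#'
#' Builds the study geometry, forward-simulates every donor decay at the
#' study's generating parameters, adds Poisson counting noise, and returns
#' the dataset together with the ground truth and a ready-to-run fit
#' layout. Study 1 is a B-form duplex with nine donor-acceptor separations
#' of 5-13 base pairs (free parameters: the two directional-distribution
#' widths and the two probe bend angles). The study-2 fixtures are two-unit
#' constructs joined by a kink placed at two alternative sequence positions
#' (one kink per sample, one shared parameter set), with 18 (0A) or 16 (3A)
#' donor-acceptor combinations flanking the junction (free parameters: the
#' six kink parameters).
#'
#' @param study `"study1"`, `"study2_0A"` or `"study2_3A"`.
#' @param seed Master seed: sampling and counting noise derive from it.
#' @param n_samples Dipole vectors per distribution used on the analysis
#'   side (default 1000, giving 10^6 orientation combinations per pair).
#' @param n_samples_gen Vectors per distribution used when generating the
#'   synthetic decays (default 20000): measured decays reflect the physical
#'   orientational ensemble, so the generator samples it much more densely
#'   than the analysis does.
#' @param peak_counts Expected top-channel counts (default 10000).
#' @param n_channels,window_ns,irf_fwhm_ps Acquisition settings (defaults
#'   2048 channels, 100 ns, 60 ps).
#' @return A list: `study`, `truth`, `dataset` (list of [fret_curve()]s
#'   carrying the synthetic decays), `geometries`, `free` (suggested
#'   bounds), `fixed` (prior-knowledge values for fitting), `manifest`
#'   (tibble), `donor_reference` ([decay_curve()]), `irf`.
#' @export
study_fixture <- function(study = c("study1", "study2_0A", "study2_3A"),
                          seed = 1, n_samples = 1000, n_samples_gen = 20000,
                          peak_counts = 10000,
                          n_channels = 2048, window_ns = 100,
                          irf_fwhm_ps = 60) {
  study <- match.arg(study)
  times <- tcspc_times(n_channels, window_ns)
  irf <- gaussian_irf(times, fwhm_ps = irf_fwhm_ps, peak_ns = 2)
  ph <- fixture_photophysics()
  dp <- fixture_decay_params()

  if (study == "study1") {
    truth <- study1_truth()
    geoms <- list(geometry_spec("duplex",
                                sequence = sub("^ATC.", "ATCF", study1_motif())))
    seps <- 5:13
    layout <- tibble::tibble(
      curve = seq_along(seps), geometry_id = 1L,
      donor_pos = 4L, donor_strand = "I",
      acceptor_pos = 4L + seps + 1L, acceptor_strand = "II",
      separation = seps
    )
    free <- list(theta_fwhm = c(3, 35), phi_fwhm = c(0.5, 25),
                 bend_tCO = c(-30, 40), bend_tCnitro = c(-30, 40))
    fixed <- list()
  } else {
    truth <- study2_truth(study)
    geoms <- purrr::map(1:2, function(kp) {
      u <- study2_units(kp)
      geometry_spec("kinked", unit1 = list(sequence = u$u1),
                    unit2 = list(sequence = u$u2))
    })
    combos <- study2_combos(study)
    layout <- dplyr::bind_rows(purrr::map(1:2, function(kp) {
      n1 <- nchar(study2_units(kp)$u1)
      tibble::tibble(
        geometry_id = kp,
        donor_pos = n1 - combos$dd + 1L, donor_strand = "I",
        acceptor_pos = n1 + combos$da, acceptor_strand = "II",
        separation = combos$dd + combos$da - 1L
      )
    }))
    layout$curve <- seq_len(nrow(layout))
    free <- list(v_x = c(-10, 10), v_y = c(-10, 10), v_z = c(-2, 12),
                 alpha = c(-180, 180), beta = c(0, 90), gamma = c(-180, 180))
    fixed <- truth[c("theta_fwhm", "phi_fwhm", "bend_tCO", "bend_tCnitro")]
  }

  # forward-simulate at the truth with generation-side sampling seeds
  gen_curves <- purrr::map(seq_len(nrow(layout)), function(i) {
    fret_curve(
      decay = NULL, irf = irf,
      donor = list(position = layout$donor_pos[i],
                   strand = layout$donor_strand[i], probe = "tCO"),
      acceptor = list(position = layout$acceptor_pos[i],
                      strand = layout$acceptor_strand[i], probe = "tCnitro"),
      geometry_id = layout$geometry_id[i], photophysics = ph,
      decay_params = dp, n_samples = n_samples_gen,
      seed = derive_seed(seed, 200L + i)
    )
  })
  gen_spec <- fit_spec(gen_curves, geoms, free = list(), fixed = truth,
                       seed = seed)
  fwd <- forward_model(gen_spec)
  if (isTRUE(fwd$rejected)) {
    stop("fixture truth rejected by constraints: ",
         paste(fwd$violations$detail, collapse = "; "), call. = FALSE)
  }

  dataset <- purrr::map(seq_len(nrow(layout)), function(i) {
    expected <- fwd$model_counts[[i]]
    expected <- expected / max(expected) * peak_counts
    counts <- with_seed(derive_seed(seed, 100L + i),
                        function() stats::rpois(length(expected), expected))
    cv <- gen_curves[[i]]
    cv$decay <- decay_curve(times, counts)
    cv$n_samples <- n_samples                # analysis-side sampling size
    cv$seed <- derive_seed(seed, 300L + i)  # analysis-side sampling seed
    cv
  })

  ref_shape <- convolve_irf(
    total_decay(dp, 0, ph$donor_lifetime, times), irf
  )
  ref_expected <- ref_shape / max(ref_shape) * peak_counts
  donor_reference <- decay_curve(times, with_seed(
    derive_seed(seed, 99L),
    function() stats::rpois(length(ref_expected), ref_expected)
  ))

  manifest <- dplyr::bind_cols(
    layout[, c("curve", "geometry_id", "donor_pos", "donor_strand",
               "acceptor_pos", "acceptor_strand", "separation")],
    fwd$curves[, c("kappa_sq", "R", "E")]
  )
  list(study = study, truth = truth, dataset = dataset, geometries = geoms,
       free = free, fixed = fixed, manifest = manifest,
       donor_reference = donor_reference, irf = irf, seed = seed,
       acquisition = list(n_channels = n_channels, window_ns = window_ns,
                          irf_fwhm_ps = irf_fwhm_ps,
                          peak_counts = peak_counts, n_samples = n_samples))
}

#' Build the ready-to-fit specification of a fixture
#'
#' @param fixture A [study_fixture()] result.
#' @param seed Analysis-side master seed (defaults to the fixture's).
#' @param kink_prior Optional `alpha + gamma` preference window, degrees.
#' @param repetitions Objective sampling repetitions; defaults to 4 for the
#'   study-1 layout (chi-square averaging over repeated samplings, as the
#'   surface analyses do) and 1 (single fixed-seed sampling) for the kink
#'   searches.
#' @return A [fit_spec()] whose free parameters are the study's unknowns.
#' @export
fixture_fit_spec <- function(fixture, seed = NULL, kink_prior = NULL,
                             repetitions = NULL) {
  if (is.null(repetitions)) {
    repetitions <- if (fixture$study == "study1") 4 else 1
  }
  fit_spec(
    dataset = fixture$dataset, geometries = fixture$geometries,
    free = fixture$free, fixed = fixture$fixed,
    seed = if (is.null(seed)) fixture$seed else seed,
    kink_prior = kink_prior, repetitions = repetitions
  )
}

#' Write a fixture to disk
#'
#' Emits one two-column decay file per curve, the IRF, the donor-reference
#' decay and a YAML manifest carrying the ground truth and the curve layout,
#' so the fitting commands can be exercised end to end from files alone.
#'
#' @param fixture A [study_fixture()] result (or a study name, forwarded).
#' @param dir Output directory (created if missing).
#' @param ... Passed to [study_fixture()] when `fixture` is a study name.
#' @return Invisibly, the directory path.
#' @export
generate_fixture <- function(fixture, dir, ...) {
  if (is.character(fixture)) fixture <- study_fixture(fixture, ...)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(fixture$dataset)) {
    write_decay(fixture$dataset[[i]]$decay,
                file.path(dir, sprintf("decay_%02d.txt", i)),
                comment = sprintf("%s curve %d", fixture$study, i))
  }
  write_decay(fixture$irf, file.path(dir, "irf.txt"), comment = "IRF")
  write_decay(fixture$donor_reference, file.path(dir, "donor_reference.txt"),
              comment = "donor-only reference")
  manifest <- list(
    study = fixture$study, seed = fixture$seed,
    truth = fixture$truth, fixed = fixture$fixed,
    acquisition = fixture$acquisition,
    photophysics = list(donor_lifetime = 4.3, forster_radius = 27),
    decay_params = list(coupled_fraction = 0.95, donor_fraction = 0.98,
                        other_lifetime = 1),
    curves = purrr::transpose(as.list(fixture$manifest))
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
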
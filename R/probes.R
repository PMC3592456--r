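#' FRET probe definitions and the probe registry
#'
#' A probe definition places a base-analogue fluorophore in the local base
#' frame: its atoms, the center and in-plane direction of its transition
#' dipole, and the out-of-plane dipole bend angle `phi_b` (degrees, positive
#' toward the 3' side of the host strand). The shipped registry contains the
#' tricyclic cytosine analogues `tCO` (donor, sequence code `F`) and
#' `tCnitro` (acceptor, sequence code `Q`), both pairing with guanine; their
#' atomic coordinates and in-plane dipole direction are documented idealized
#' defaults meant to be overridden when measured values are at hand.
#'
#' @param name Probe identifier (registry key).
#' @param code One-letter sequence code used in [build_duplex()] sequences.
#' @param role `"donor"`, `"acceptor"` or `"either"`.
#' @param atoms Tibble/data.frame with columns name, element, x, y, z
#'   (Angstrom, local base frame).
#' @param dipole_center 3-vector, Angstrom, local base frame.
#' @param dipole_direction Unit 3-vector in the local base plane.
#' @param bend_angle Out-of-plane dipole bend `phi_b`, degrees, in (-90, 90).
#' @param pairs_with One-letter code of the complementary natural base.
#' @return `probe_definition()` returns a `probe_definition` object;
#'   `register_probe()` invisibly returns it after installing it in the
#'   session registry.
#' @export
probe_definition <- function(name, code, role = c("donor", "acceptor", "either"),
                             atoms, dipole_center = c(0, 0, 0),
                             dipole_direction = c(0, 1, 0),
                             bend_angle = 0, pairs_with = "G") {
  role <- match.arg(role)
  dipole_direction <- vec3(dipole_direction, "dipole_direction")
  if (abs(sqrt(sum(dipole_direction^2)) - 1) > 1e-10) {
    stop("dipole_direction must be a unit vector", call. = FALSE)
  }
  if (!is_number(bend_angle) || bend_angle <= -90 || bend_angle >= 90) {
    stop("bend_angle must lie in (-90, 90) degrees", call. = FALSE)
  }
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("name", "element", "x", "y", "z") %in% names(atoms)))
  structure(
    list(name = name, code = code, role = role, atoms = atoms,
         dipole_center = vec3(dipole_center, "dipole_center"),
         dipole_direction = dipole_direction,
         bend_angle = bend_angle, pairs_with = pairs_with),
    class = "probe_definition"
  )
}

load_shipped_probes <- function() {
  dir <- template_dir("probes")
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  reg <- list()
  for (f in files) {
    tpl <- read_template(f)
    p <- probe_definition(
      name = sub("\\.txt$", "", basename(f)),
      code = tpl$code, role = tpl$role, atoms = tpl$atoms,
      dipole_center = tpl$dipole_center,
      dipole_direction = unit_vec(tpl$dipole_direction),
      bend_angle = tpl$bend_angle, pairs_with = tpl$pairs_with
    )
    reg[[p$name]] <- p
  }
  reg
}

#' @rdname probe_definition
#' @param definition A `probe_definition` object.
#' @export
register_probe <- function(definition) {
  stopifnot(inherits(definition, "probe_definition"))
  reg <- probe_registry()
  if (definition$name %in% names(reg)) {
    warning("replacing existing probe definition: ", definition$name,
            call. = FALSE)
  }
  reg[[definition$name]] <- definition
  .basefret_env$probes <- reg
  invisible(definition)
}

#' The session probe registry
#'
#' @return Named list of [probe_definition()] objects currently registered.
#' @export
probe_registry <- function() {
  if (is.null(.basefret_env$probes)) {
    .basefret_env$probes <- load_shipped_probes()
  }
  .basefret_env$probes
}

#' List registered probes
#'
#' @return A tibble with one row per registered probe.
#' @export
list_probes <- function() {
  reg <- probe_registry()
  tibble::tibble(
    name = names(reg),
    code = unname(purrr::map_chr(reg, "code")),
    role = unname(purrr::map_chr(reg, "role")),
    pairs_with = unname(purrr::map_chr(reg, "pairs_with")),
    bend_angle = unname(purrr::map_dbl(reg, "bend_angle")),
    n_atoms = unname(purrr::map_int(reg, ~ nrow(.x$atoms)))
  )
}

# look up a probe by its one-letter sequence code; NULL if no probe uses it
probe_by_code <- function(code) {
  reg <- probe_registry()
  hit <- purrr::detect(reg, ~ .x$code == code)
  hit
}

# Bend the local dipole out of the base plane by phi_b degrees about the
# in-plane axis perpendicular to the dipole. Positive bend points toward the
# local +z, which runs 5'->3' of the host strand in the base's own frame
# (strand-II frames are stored flipped, so the convention carries over).
bent_dipole_local <- function(direction, bend_angle) {
  d <- unit_vec(c(direction[1], direction[2], 0))
  cb <- cos(deg2rad(bend_angle))
  sb <- sin(deg2rad(bend_angle))
  c(cb * d[1], cb * d[2], sb)
}

#' Resolve a placed probe's dipole into global coordinates
#'
#' Applies the out-of-plane bend `phi_b` to the probe's in-plane dipole in
#' the base's own frame (so positive bend points toward the 3' side of the
#' host strand on either strand), then maps center and direction through the
#' base frame into global coordinates.
#'
#' @param model A [build_duplex()] model.
#' @param position Sequence position (1-based).
#' @param strand `"I"` or `"II"`.
#' @param bend_angle Optional override of the registered `phi_b` (degrees).
#' @return List with `center` (global 3-vector, Angstrom) and `direction`
#'   (global unit 3-vector).
#' @export
resolve_dipole <- function(model, position, strand = c("I", "II"),
                           bend_angle = NULL) {
  strand <- match.arg(strand)
  stopifnot(inherits(model, "na_model"))
  hit <- purrr::detect(model$probes, ~ .x$position == position && .x$strand == strand)
  if (is.null(hit)) {
    stop(sprintf("no probe at position %d strand %s", position, strand),
         call. = FALSE)
  }
  probe <- probe_registry()[[hit$probe]]
  if (is.null(bend_angle)) bend_angle <- probe$bend_angle
  frame <- if (strand == "I") model$base_frames_1[[position]] else
    model$base_frames_2[[position]]
  local_dir <- bent_dipole_local(probe$dipole_direction, bend_angle)
  list(
    center = as.numeric(frame$origin + frame$axes %*% probe$dipole_center),
    direction = unit_vec(as.numeric(frame$axes %*% local_dir))
  )
}
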
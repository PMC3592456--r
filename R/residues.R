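# Residue template handling: idealized planar base geometries defined in the
# local base frame, shipped as plain-text files under inst/extdata and loaded
# into a per-session cache. The templates are synthetic idealized rings (see
# the package vignette); the FRET arithmetic depends on dipole positions and
# directions only, with atoms used for output and steric screening.

.basefret_env <- new.env(parent = emptyenv())

#' Read a residue or probe template file
#'
#' Template files are plain text: comment lines start with `#`, atom lines
#' read `atom <name> <element> <x> <y> <z>` (Angstrom, local base frame), and
#' probe files add `code`, `role`, `pairs_with`, `dipole_center`,
#' `dipole_direction` and `bend_angle` entries.
#'
#' @param path Path to a template file.
#' @return A list with `atoms` (tibble: name, element, x, y, z) plus any
#'   probe fields present.
#' @export
read_template <- function(path) {
  if (!file.exists(path)) stop("template file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "\\s+")
  atoms <- purrr::keep(toks, ~ .x[1] == "atom")
  if (length(atoms) == 0) stop("template has no atom lines: ", path, call. = FALSE)
  at <- tibble::tibble(
    name = purrr::map_chr(atoms, 2),
    element = purrr::map_chr(atoms, 3),
    x = purrr::map_dbl(atoms, ~ as.numeric(.x[4])),
    y = purrr::map_dbl(atoms, ~ as.numeric(.x[5])),
    z = purrr::map_dbl(atoms, ~ as.numeric(.x[6]))
  )
  if (any(!is.finite(c(at$x, at$y, at$z)))) {
    stop("non-finite coordinates in template: ", path, call. = FALSE)
  }
  out <- list(atoms = at)
  other <- purrr::discard(toks, ~ .x[1] == "atom")
  for (tk in other) {
    key <- tk[1]
    val <- tk[-1]
    out[[key]] <- switch(key,
      dipole_center = ,
      dipole_direction = as.numeric(val),
      bend_angle = as.numeric(val[1]),
      val[1]
    )
  }
  out
}

template_dir <- function(kind = c("residues", "probes")) {
  kind <- match.arg(kind)
  system.file("extdata", kind, package = "basefret")
}

# Load (and cache) the shipped residue templates keyed by one-letter code.
residue_library <- function() {
  if (!is.null(.basefret_env$residues)) return(.basefret_env$residues)
  dir <- template_dir("residues")
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  lib <- purrr::map(files, read_template)
  names(lib) <- sub("\\.txt$", "", basename(files))
  .basefret_env$residues <- lib
  lib
}

#' Watson-Crick complement of a residue code
#'
#' Natural bases complement as usual; registered probes pair with the base
#' named in their template (`pairs_with`, guanine for the tC family).
#'
#' @param code Character vector of one-letter residue codes.
#' @return Character vector of complementary codes.
#' @export
complement_base <- function(code) {
  map <- c(A = "T", T = "A", G = "C", C = "G", U = "A")
  out <- unname(map[code])
  for (i in seq_along(code)) {
    if (is.na(out[i])) {
      probe <- probe_by_code(code[i])
      if (!is.null(probe)) out[i] <- probe$pairs_with
    }
  }
  if (any(is.na(out))) {
    stop("no complement known for residue code(s): ",
         paste(unique(code[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Standard helix step-parameter presets
#'
#' Fiber-model average base-pair step parameters for regular B-form and
#' A-form helices, shipped as editable defaults (substitutes for
#' experimentally derived per-structure tables, which can be supplied as
#' `.par` files instead).
#'
#' @param form `"B"` or `"A"`.
#' @return A [step_parameters()] vector.
#' @examples
#' helix_step("B")
#' @export
helix_step <- function(form = c("B", "A")) {
  switch(match.arg(form),
    B = step_parameters(shift = 0, slide = 0, rise = 3.38,
                        tilt = 0, roll = 0, twist = 36.0),
    A = step_parameters(shift = 0, slide = -1.48, rise = 2.81,
                        tilt = 0, roll = 8.6, twist = 32.7)
  )
}
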
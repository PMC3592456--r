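#' Geometric constraints for kinked-model screening
#'
#' Two physical plausibility rules applied to candidate kink geometries: no
#' steric clash between atoms of different structural units (atom-atom
#' distance below twice the atomic van der Waals radius), and backbone
#' connectivity (neighboring bases in the same strand no further apart than
#' a covalent sugar-phosphate linker allows).
#'
#' @param vdw_radius Atomic van der Waals radius, Angstrom (default 1.3).
#' @param max_neighbor_distance Maximum distance between neighboring
#'   same-strand base reference points, Angstrom (default 11).
#' @return A `constraint_spec` list.
#' @export
constraint_spec <- function(vdw_radius = 1.3, max_neighbor_distance = 11) {
  if (!is_number(vdw_radius) || vdw_radius <= 0 ||
      !is_number(max_neighbor_distance) || max_neighbor_distance <= 0) {
    stop("constraint parameters must be positive", call. = FALSE)
  }
  structure(list(vdw_radius = vdw_radius,
                 max_neighbor_distance = max_neighbor_distance),
            class = "constraint_spec")
}

#' Check a model against geometric constraints
#'
#' Steric screening evaluates every inter-unit atom pair (a clash anywhere
#' discards the geometry, including between the two junction-flanking
#' residues: a kink that collapses unit 2 onto unit 1 must fail).
#' Connectivity screening uses the base-frame origins of adjacent
#' same-strand bases as reference points.
#'
#' @param model An `na_model` (typically from [join_units()]).
#' @param constraints A [constraint_spec()].
#' @return A list with `pass` (logical) and `violations` (tibble: type,
#'   detail, value).
#' @export
check_constraints <- function(model, constraints = constraint_spec()) {
  stopifnot(inherits(model, "na_model"), inherits(constraints, "constraint_spec"))
  at <- model$atoms
  if (nrow(at) == 0) stop("model has no atoms", call. = FALSE)
  viol <- list()

  units_of_pos <- model$units
  atom_unit <- units_of_pos[at$pos]
  n_units <- max(units_of_pos)
  if (n_units > 1) {
    cutoff <- 2 * constraints$vdw_radius
    xyz <- as.matrix(at[, c("x", "y", "z")])
    for (ua in seq_len(n_units - 1L)) {
      for (ub in (ua + 1L):n_units) {
        ia <- which(atom_unit == ua)
        ib <- which(atom_unit == ub)
        d2 <- outer(rowSums(xyz[ia, , drop = FALSE]^2),
                    rowSums(xyz[ib, , drop = FALSE]^2), "+") -
          2 * tcrossprod(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
        dmin <- sqrt(max(min(d2), 0))
        if (dmin < cutoff) {
          hit <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
          viol <- c(viol, list(tibble::tibble(
            type = "steric",
            detail = sprintf("unit %d %s%d:%s / unit %d %s%d:%s",
                             ua, at$resname[ia[hit[1]]], at$pos[ia[hit[1]]],
                             at$name[ia[hit[1]]],
                             ub, at$resname[ib[hit[2]]], at$pos[ib[hit[2]]],
                             at$name[ib[hit[2]]]),
            value = dmin
          )))
        }
      }
    }
  }

  n <- n_pairs(model)
  for (strand in c("I", "II")) {
    frames <- if (strand == "I") model$base_frames_1 else model$base_frames_2
    for (i in seq_len(n - 1L)) {
      d <- sqrt(sum((frames[[i + 1L]]$origin - frames[[i]]$origin)^2))
      if (d > constraints$max_neighbor_distance) {
        viol <- c(viol, list(tibble::tibble(
          type = "connectivity",
          detail = sprintf("strand %s bases %d-%d", strand, i, i + 1L),
          value = d
        )))
      }
    }
  }

  violations <- if (length(viol)) dplyr::bind_rows(viol) else
    tibble::tibble(type = character(), detail = character(), value = numeric())
  list(pass = nrow(violations) == 0, violations = violations)
}
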
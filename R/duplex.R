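#' Kink parameters between two helical units
#'
#' Three intrinsic ZXZ Euler angles plus a translation vector relating two
#' structural units across a junction. The rotation is applied to unit-2
#' local coordinates as `Rz(alpha) %*% Rx(beta) %*% Rz(gamma)`, so `beta`
#' alone is the bending angle between the two helix axes; the translation
#' `(v_x, v_y, v_z)` is expressed in the frame of the last base pair of the
#' preceding unit.
#'
#' @param v_x,v_y,v_z Translation components, Angstrom.
#' @param alpha,beta,gamma ZXZ Euler angles, degrees; `beta` in \[0, 180\],
#'   `alpha`/`gamma` wrapped to (-180, 180\].
#' @return Named numeric vector of class `kink_parameters`.
#' @export
kink_parameters <- function(v_x = 0, v_y = 0, v_z = 0,
                            alpha = 0, beta = 0, gamma = 0) {
  p <- c(v_x = v_x, v_y = v_y, v_z = v_z,
         alpha = wrap_angle(alpha), beta = beta, gamma = wrap_angle(gamma))
  if (any(!is.finite(p))) stop("kink parameters must be finite", call. = FALSE)
  if (beta < 0 || beta > 180) stop("beta must lie in [0, 180]", call. = FALSE)
  structure(p, class = "kink_parameters")
}

as_kink <- function(x) {
  if (inherits(x, "kink_parameters")) return(x)
  x <- as.numeric(x)
  if (length(x) != 6L) stop("a kink needs six parameters", call. = FALSE)
  kink_parameters(x[1], x[2], x[3], x[4], x[5], x[6])
}

# ZXZ rotation matrix for kink Euler angles (degrees)
kink_rotation <- function(alpha, beta, gamma) {
  rotation_matrix("z", alpha) %*% rotation_matrix("x", beta) %*%
    rotation_matrix("z", gamma)
}

# inverse: ZXZ Euler angles (degrees) from a rotation matrix
rotation_to_euler_zxz <- function(r) {
  beta <- rad2deg(atan2(sqrt(r[1, 3]^2 + r[2, 3]^2), r[3, 3]))
  if (abs(beta) < 1e-9) {
    return(c(alpha = wrap_angle(rad2deg(atan2(r[2, 1], r[1, 1]))),
             beta = 0, gamma = 0))
  }
  c(alpha = wrap_angle(rad2deg(atan2(r[1, 3], -r[2, 3]))),
    beta = beta,
    gamma = wrap_angle(rad2deg(atan2(r[3, 1], r[3, 2]))))
}

#' Express a base-pair step as kink parameters
#'
#' A helper mapping the six step parameters onto the equivalent six kink
#' parameters, so that [join_units()] with the native helix step reproduces a
#' continuous duplex.
#'
#' @param step A [step_parameters()] vector.
#' @return A [kink_parameters()] vector.
#' @export
step_as_kink <- function(step) {
  step <- as_step(step)
  rot <- cehs_rotations(step[["tilt"]], step[["roll"]], step[["twist"]])
  eu <- rotation_to_euler_zxz(rot$full)
  v <- as.numeric(rot$mid %*% step[c("shift", "slide", "rise")])
  kink_parameters(v[1], v[2], v[3], eu[["alpha"]], eu[["beta"]], eu[["gamma"]])
}

natural_codes <- c("A", "C", "G", "T", "U")

split_sequence <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    strsplit(sequence, "")[[1]]
  } else {
    as.character(sequence)
  }
}

resolve_residue <- function(code, position) {
  lib <- residue_library()
  if (code %in% names(lib)) {
    return(list(kind = "base", name = code, atoms = lib[[code]]$atoms))
  }
  probe <- probe_by_code(code)
  if (!is.null(probe)) {
    return(list(kind = "probe", name = probe$name, atoms = probe$atoms,
                probe = probe))
  }
  stop(sprintf("unknown residue code '%s' at position %d", code, position),
       call. = FALSE)
}

place_atoms <- function(atoms, frame, resname, pos, strand) {
  xyz <- apply_rigid_transform(as.matrix(atoms[, c("x", "y", "z")]),
                               frame$axes, frame$origin)
  tibble::tibble(
    name = atoms$name, element = atoms$element, resname = resname,
    pos = pos, strand = strand,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
}

#' Build an all-atom duplex model from a sequence
#'
#' Chains base-pair frames along the sequence with the mid-step (CEHS)
#' construction, places both strands' bases (strand II by the anti-parallel
#' 180-degrees-about-x flip of the pair frame), and resolves any probe
#' dipoles into global coordinates.
#'
#' @param sequence Strand-I sequence, 5'->3': a string of one-letter residue
#'   codes; registered probe codes (`F` = tCO donor, `Q` = tCnitro acceptor
#'   in the shipped registry) may appear anywhere.
#' @param step_table Optional per-step parameters: a [step_parameters()]
#'   vector applied uniformly, or a list/data frame of length
#'   `nchar(sequence) - 1`. Defaults to the regular helix step of `form`.
#' @param pair_table Optional per-pair intra-pair parameters (single
#'   [pair_parameters()] or list/data frame of length `nchar(sequence)`),
#'   defaulting to ideal (all-zero) pairs.
#' @param strand2 Optional strand-II override aligned to strand-I positions:
#'   a string where `"."` keeps the Watson-Crick complement and any probe or
#'   base code substitutes that residue on strand II.
#' @param form Helix preset used when `step_table` is absent, see
#'   [helix_step()].
#' @return An object of class `na_model`: pair frames, per-base frames for
#'   both strands, the atom table (tibble), and the registry of placed
#'   probes with resolved dipole centers and directions.
#' @examples
#' m <- build_duplex("AFGCATGCAQT")
#' m
#' @export
build_duplex <- function(sequence, step_table = NULL, pair_table = NULL,
                         strand2 = NULL, form = "B") {
  seq1 <- split_sequence(sequence)
  n <- length(seq1)
  if (n < 2) stop("sequence must have length >= 2", call. = FALSE)
  if (is.null(step_table)) step_table <- helix_step(form)
  steps <- normalize_param_table(step_table, n - 1L, as_step, "step_table")
  pairs <- if (is.null(pair_table)) {
    rep(list(pair_parameters()), n)
  } else {
    normalize_param_table(pair_table, n, as_pair_params, "pair_table")
  }
  over2 <- if (is.null(strand2)) rep(".", n) else split_sequence(strand2)
  if (length(over2) != n) {
    stop("strand2 must align with the strand-I sequence", call. = FALSE)
  }

  pair_frames <- vector("list", n)
  pair_frames[[1]] <- ref_frame()
  for (i in seq_len(n - 1L)) {
    pair_frames[[i + 1L]] <- step_to_transform(pair_frames[[i]], steps[[i]])
  }

  base1 <- vector("list", n)
  base2 <- vector("list", n)
  atoms <- vector("list", 2L * n)
  probes <- list()
  seq2 <- character(n)
  for (i in seq_len(n)) {
    res1 <- resolve_residue(seq1[i], i)
    code2 <- if (over2[i] == ".") complement_base(seq1[i]) else over2[i]
    res2 <- resolve_residue(code2, i)
    seq2[i] <- code2
    bf <- pair_to_frames(pair_frames[[i]], pairs[[i]])
    base1[[i]] <- bf$strand1
    base2[[i]] <- bf$strand2
    atoms[[2L * i - 1L]] <- place_atoms(res1$atoms, bf$strand1, res1$name, i, "I")
    atoms[[2L * i]] <- place_atoms(res2$atoms, bf$strand2, res2$name, i, "II")
    if (res1$kind == "probe") {
      probes <- c(probes, list(list(probe = res1$name, code = seq1[i],
                                    role = res1$probe$role,
                                    position = i, strand = "I")))
    }
    if (res2$kind == "probe") {
      probes <- c(probes, list(list(probe = res2$name, code = code2,
                                    role = res2$probe$role,
                                    position = i, strand = "II")))
    }
  }

  model <- structure(
    list(
      sequence = seq1, sequence2 = seq2,
      pair_frames = pair_frames,
      base_frames_1 = base1, base_frames_2 = base2,
      atoms = dplyr::bind_rows(atoms),
      probes = probes,
      units = rep(1L, n),
      step_table = steps, pair_table = pairs
    ),
    class = "na_model"
  )
  model
}

normalize_param_table <- function(x, n, caster, what) {
  if (inherits(x, "step_parameters") || inherits(x, "pair_parameters")) {
    return(rep(list(x), n))
  }
  if (is.data.frame(x)) {
    x <- purrr::map(seq_len(nrow(x)), ~ as.numeric(x[.x, , drop = TRUE]))
  }
  if (is.numeric(x) && length(x) == 6L) return(rep(list(caster(x)), n))
  if (!is.list(x) || length(x) != n) {
    stop(sprintf("%s must have %d entries", what, n), call. = FALSE)
  }
  purrr::map(x, caster)
}

#' @export
print.na_model <- function(x, ...) {
  cat(sprintf("<na_model> %d base pairs, %d atoms, %d probe(s), %d unit(s)\n",
              length(x$pair_frames), nrow(x$atoms), length(x$probes),
              max(x$units)))
  cat(" strand I : 5'-", paste(x$sequence, collapse = ""), "-3'\n", sep = "")
  cat(" strand II: 3'-", paste(x$sequence2, collapse = ""), "-5'\n", sep = "")
  for (p in x$probes) {
    cat(sprintf(" probe %s (%s) at position %d strand %s\n",
                p$probe, p$role, p$position, p$strand))
  }
  invisible(x)
}

#' Number of base pairs in a model
#' @param model An `na_model`.
#' @return Integer count.
#' @export
n_pairs <- function(model) length(model$pair_frames)

# rigidly transform every frame and atom of a model (used for invariance
# checks and for mapping a unit through a kink)
transform_model <- function(model, rotation, translation = c(0, 0, 0)) {
  # hot path during kink searches: frames stay orthonormal under a rigid
  # rotation, so skip constructor validation
  tf_frame <- function(f) {
    structure(list(origin = as.numeric(rotation %*% f$origin) + translation,
                   axes = rotation %*% f$axes),
              class = "ref_frame")
  }
  model$pair_frames <- purrr::map(model$pair_frames, tf_frame)
  model$base_frames_1 <- purrr::map(model$base_frames_1, tf_frame)
  model$base_frames_2 <- purrr::map(model$base_frames_2, tf_frame)
  xyz <- apply_rigid_transform(as.matrix(model$atoms[, c("x", "y", "z")]),
                               rotation, translation)
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

#' Join two structural units across a kink
#'
#' Unit 2 is expressed in the frame of its own first base pair, rotated by
#' `Rz(alpha) %*% Rx(beta) %*% Rz(gamma)`, translated by `(v_x, v_y, v_z)`,
#' and finally mapped into global coordinates through the frame of the last
#' base pair of unit 1. Joining is associative, so any number of units can
#' be chained.
#'
#' @param model_1,model_2 `na_model` objects.
#' @param kink A [kink_parameters()] vector.
#' @return A merged `na_model`; `units` records the unit id of every pair
#'   and probe positions are renumbered onto the concatenated sequence.
#' @export
join_units <- function(model_1, model_2, kink) {
  stopifnot(inherits(model_1, "na_model"), inherits(model_2, "na_model"))
  if (n_pairs(model_1) == 0 || n_pairs(model_2) == 0) {
    stop("cannot join an empty model", call. = FALSE)
  }
  kink <- as_kink(kink)
  n1 <- n_pairs(model_1)

  # express unit 2 in its own first-pair frame
  f0 <- model_2$pair_frames[[1]]
  m2 <- transform_model(model_2, t(f0$axes),
                        -as.numeric(crossprod(f0$axes, f0$origin)))
  # kink rotation + translation, then map through unit-1 last pair frame
  rk <- kink_rotation(kink[["alpha"]], kink[["beta"]], kink[["gamma"]])
  fl <- model_1$pair_frames[[n1]]
  rot <- fl$axes %*% rk
  tr <- fl$origin + as.numeric(fl$axes %*% kink[c("v_x", "v_y", "v_z")])
  m2 <- transform_model(m2, rot, tr)

  m2$atoms$pos <- m2$atoms$pos + n1
  probes2 <- purrr::map(m2$probes, function(p) {
    p$position <- p$position + n1
    p
  })
  structure(
    list(
      sequence = c(model_1$sequence, m2$sequence),
      sequence2 = c(model_1$sequence2, m2$sequence2),
      pair_frames = c(model_1$pair_frames, m2$pair_frames),
      base_frames_1 = c(model_1$base_frames_1, m2$base_frames_1),
      base_frames_2 = c(model_1$base_frames_2, m2$base_frames_2),
      atoms = dplyr::bind_rows(model_1$atoms, m2$atoms),
      probes = c(model_1$probes, probes2),
      units = c(model_1$units, m2$units + max(model_1$units)),
      step_table = NULL, pair_table = NULL
    ),
    class = "na_model"
  )
}

#' Extract rebuild parameters from a model
#'
#' Recovers, from the model's frames, the sequence plus per-pair intra-pair
#' parameters and per-step parameters sufficient to rebuild the geometry
#' with [build_duplex()]; the interchange twin of [read_par()]/[write_par()].
#'
#' @param model An `na_model`.
#' @return A list with `sequence`, `step_table` (tibble, n-1 rows) and
#'   `pair_table` (tibble, n rows).
#' @export
model_to_par <- function(model) {
  n <- n_pairs(model)
  pair_rows <- purrr::map(seq_len(n), function(i) {
    pr <- frames_to_pair(model$base_frames_1[[i]], model$base_frames_2[[i]])
    tibble::as_tibble(as.list(unclass(pr$params)))
  })
  step_rows <- purrr::map(seq_len(n - 1L), function(i) {
    st <- transform_to_step(model$pair_frames[[i]], model$pair_frames[[i + 1L]])
    tibble::as_tibble(as.list(unclass(st)))
  })
  list(
    sequence = paste(model$sequence, collapse = ""),
    step_table = dplyr::bind_rows(step_rows),
    pair_table = dplyr::bind_rows(pair_rows)
  )
}
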
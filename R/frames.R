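#' Local reference frames
#'
#' A reference frame locates a base, base pair or helical unit in space: an
#' origin (in Angstrom) plus a right-handed orthonormal axis set. The columns
#' of `axes` are the local x, y and z unit vectors expressed in the global
#' frame. For a base-pair frame the y axis runs along the line connecting the
#' anchor atoms of the two paired bases (pointing from strand II to strand I),
#' the z axis points in the 5'->3' direction of strand I, and x completes a
#' right-handed set; the origin is the midpoint of the anchor-atom line.
#'
#' @param origin Numeric 3-vector, Angstrom.
#' @param axes 3x3 matrix with orthonormal columns and determinant +1.
#' @return An object of class `ref_frame` with elements `origin` and `axes`.
#' @examples
#' f <- ref_frame()                      # the global frame
#' g <- step_to_transform(f, step_parameters(rise = 3.38, twist = 36))
#' transform_to_step(f, g)
#' @export
ref_frame <- function(origin = c(0, 0, 0), axes = diag(3)) {
  origin <- vec3(origin, "origin")
  axes <- as.matrix(axes)
  if (!all(dim(axes) == c(3L, 3L)) || any(!is.finite(axes))) {
    stop("axes must be a finite 3x3 matrix", call. = FALSE)
  }
  dev <- max(abs(crossprod(axes) - diag(3)))
  if (dev > 1e-8) stop("axes must be orthonormal", call. = FALSE)
  if (dev > 1e-12) axes <- orthonormalize(axes)
  if (det(axes) < 0) stop("axes must form a right-handed set", call. = FALSE)
  structure(list(origin = origin, axes = unname(axes)), class = "ref_frame")
}

#' @export
print.ref_frame <- function(x, ...) {
  cat("<ref_frame> origin:", sprintf("%.4f", x$origin), "\n")
  print(round(x$axes, 6))
  invisible(x)
}

is_ref_frame <- function(x) inherits(x, "ref_frame")

# Gram-Schmidt re-orthonormalization guarding against drift in long chains
orthonormalize <- function(m) {
  x <- unit_vec(m[, 1])
  y <- m[, 2] - sum(m[, 2] * x) * x
  y <- unit_vec(y)
  z <- c(
    x[2] * y[3] - x[3] * y[2],
    x[3] * y[1] - x[1] * y[3],
    x[1] * y[2] - x[2] * y[1]
  )
  cbind(x, y, z, deparse.level = 0)
}

#' Elementary rotation matrices
#'
#' The standard right-handed rotation matrix about a named Cartesian axis,
#' acting on column vectors.
#'
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param angle Rotation angle in degrees.
#' @return A 3x3 orthonormal matrix with determinant +1.
#' @examples
#' rotation_matrix("z", 90) %*% c(1, 0, 0)  # -> (0, 1, 0)
#' @export
rotation_matrix <- function(axis, angle) {
  if (!is_number(angle)) stop("angle must be a finite number", call. = FALSE)
  a <- deg2rad(angle)
  c_ <- cos(a)
  s_ <- sin(a)
  switch(match.arg(axis, c("x", "y", "z")),
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
  )
}

#' Apply a rigid-body transform to coordinates
#'
#' Rotates an n x 3 coordinate block and then translates it: each coordinate
#' row is mapped as `row %*% t(rotation) + translation`. Pairwise distances
#' are preserved by the rotation.
#'
#' @param coords Numeric n x 3 matrix (or a 3-vector) of coordinates, Angstrom.
#' @param rotation 3x3 orthonormal matrix.
#' @param translation Numeric 3-vector, Angstrom.
#' @return Transformed coordinates with the same shape as `coords`.
#' @export
apply_rigid_transform <- function(coords, rotation, translation = c(0, 0, 0)) {
  single <- is.null(dim(coords))
  if (single) coords <- matrix(coords, 1L, 3L)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must have 3 columns", call. = FALSE)
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stop("rotation must be orthonormal", call. = FALSE)
  }
  translation <- vec3(translation, "translation")
  out <- coords %*% t(rotation)
  out <- sweep(out, 2L, translation, "+")
  if (single) out[1L, ] else out
}

#' Rigid-body step parameters
#'
#' The six parameters relating two successive base-pair frames: three
#' translations (shift, slide, rise; Angstrom) and three rotations (tilt,
#' roll, twist; degrees).
#'
#' @param shift,slide,rise Translational parameters, Angstrom.
#' @param tilt,roll,twist Rotational parameters, degrees.
#' @return A named numeric vector of class `step_parameters`.
#' @export
step_parameters <- function(shift = 0, slide = 0, rise = 0,
                            tilt = 0, roll = 0, twist = 0) {
  p <- c(shift = shift, slide = slide, rise = rise,
         tilt = tilt, roll = roll, twist = twist)
  if (any(!is.finite(p))) stop("step parameters must be finite", call. = FALSE)
  structure(p, class = "step_parameters")
}

#' Intra-base-pair parameters
#'
#' The six rigid-body parameters describing the two bases within one pair:
#' shear, stretch, stagger (Angstrom) and buckle, propeller, opening
#' (degrees). They are the within-pair analogues of the step parameters.
#'
#' @param shear,stretch,stagger Translations, Angstrom.
#' @param buckle,propeller,opening Rotations, degrees.
#' @return A named numeric vector of class `pair_parameters`.
#' @export
pair_parameters <- function(shear = 0, stretch = 0, stagger = 0,
                            buckle = 0, propeller = 0, opening = 0) {
  p <- c(shear = shear, stretch = stretch, stagger = stagger,
         buckle = buckle, propeller = propeller, opening = opening)
  if (any(!is.finite(p))) stop("pair parameters must be finite", call. = FALSE)
  structure(p, class = "pair_parameters")
}

# Core mid-step construction shared by steps and intra-pair placement.
# Returns the full rotation (frame i -> frame i+1) and the mid-frame rotation,
# both expressed in the local frame i.
cehs_rotations <- function(tilt, roll, twist) {
  gam <- sqrt(tilt^2 + roll^2)
  phi <- if (gam == 0) 0 else rad2deg(atan2(tilt, roll))
  r_full <- rotation_matrix("z", twist / 2 - phi) %*%
    rotation_matrix("y", gam) %*%
    rotation_matrix("z", twist / 2 + phi)
  r_mid <- rotation_matrix("z", twist / 2 - phi) %*%
    rotation_matrix("y", gam / 2) %*%
    rotation_matrix("z", phi)
  list(full = r_full, mid = r_mid)
}

# Inverse of cehs_rotations: ZYZ decomposition of the local rotation matrix.
# Returns (tilt, roll, twist) in degrees, twist in (-180, 180].
cehs_angles <- function(r) {
  g <- rad2deg(atan2(sqrt(r[1, 3]^2 + r[2, 3]^2), r[3, 3]))
  if (abs(g) < 1e-9) {
    tw <- rad2deg(atan2(r[2, 1], r[1, 1]))
    return(c(tilt = 0, roll = 0, twist = wrap_angle(tw)))
  }
  a <- rad2deg(atan2(r[2, 3], r[1, 3]))   # twist/2 - phi
  b <- rad2deg(atan2(r[3, 2], -r[3, 1]))  # twist/2 + phi
  tw <- wrap_angle(a + b)
  phi <- (tw - 2 * a) / 2
  c(tilt = g * sin(deg2rad(phi)), roll = g * cos(deg2rad(phi)), twist = tw)
}

#' Advance a base-pair frame by one step
#'
#' The mid-step (CEHS) construction: the tilt/roll pair acts as a single
#' rotation of magnitude `sqrt(tilt^2 + roll^2)` about a hinge axis in the
#' mid-step frame at phase `atan2(tilt, roll)` from the roll axis, the twist
#' is split symmetrically about the mid-step frame, and the translation
#' (shift, slide, rise) is applied along the mid-step frame axes.
#'
#' @param frame_i A [ref_frame()].
#' @param step A [step_parameters()] vector.
#' @return The `ref_frame` of the next base pair.
#' @export
step_to_transform <- function(frame_i, step) {
  stopifnot(is_ref_frame(frame_i))
  step <- as_step(step)
  rot <- cehs_rotations(step[["tilt"]], step[["roll"]], step[["twist"]])
  axes <- frame_i$axes %*% rot$full
  mid_axes <- frame_i$axes %*% rot$mid
  origin <- frame_i$origin +
    as.numeric(mid_axes %*% step[c("shift", "slide", "rise")])
  ref_frame(origin, orthonormalize(axes))
}

#' Extract step parameters between two frames
#'
#' Exact inverse of [step_to_transform()]: recovers the six rigid-body
#' parameters carrying `frame_i` onto `frame_j`. Angles are returned in
#' (-180, 180].
#'
#' @param frame_i,frame_j [ref_frame()] objects.
#' @return A [step_parameters()] vector.
#' @export
transform_to_step <- function(frame_i, frame_j) {
  stopifnot(is_ref_frame(frame_i), is_ref_frame(frame_j))
  r <- crossprod(frame_i$axes, frame_j$axes)  # local rotation
  ang <- cehs_angles(r)
  rot <- cehs_rotations(ang[["tilt"]], ang[["roll"]], ang[["twist"]])
  mid_axes <- frame_i$axes %*% rot$mid
  tr <- as.numeric(crossprod(mid_axes, frame_j$origin - frame_i$origin))
  step_parameters(shift = tr[1], slide = tr[2], rise = tr[3],
                  tilt = ang[["tilt"]], roll = ang[["roll"]],
                  twist = ang[["twist"]])
}

as_step <- function(x) {
  if (inherits(x, "step_parameters")) return(x)
  x <- as.numeric(x)
  if (length(x) != 6L) stop("a step needs six parameters", call. = FALSE)
  step_parameters(x[1], x[2], x[3], x[4], x[5], x[6])
}

as_pair_params <- function(x) {
  if (inherits(x, "pair_parameters")) return(x)
  x <- as.numeric(x)
  if (length(x) != 6L) stop("a pair needs six parameters", call. = FALSE)
  pair_parameters(x[1], x[2], x[3], x[4], x[5], x[6])
}

# 180 degree flip about the pair x axis: carries a strand-I-style frame onto
# the anti-parallel complementary-strand frame.
flip_x <- function() diag(c(1, -1, -1))

# Place the two base frames of a pair from the pair frame and the intra-pair
# parameters. The pair frame is the mid-frame of the construction; the
# strand-II frame is returned already flipped (its z runs 5'->3' of strand II).
pair_to_frames <- function(pair_frame, pair = pair_parameters()) {
  pair <- as_pair_params(pair)
  rot <- cehs_rotations(pair[["buckle"]], pair[["propeller"]], pair[["opening"]])
  # strand-II (un-flipped) frame A1 and strand-I frame A2 with mid-frame = pair
  a1 <- pair_frame$axes %*% t(rot$mid)
  a2 <- a1 %*% rot$full
  v <- as.numeric(pair_frame$axes %*% pair[c("shear", "stretch", "stagger")])
  o1 <- pair_frame$origin - v / 2
  o2 <- pair_frame$origin + v / 2
  list(
    strand1 = ref_frame(o2, orthonormalize(a2)),
    strand2 = ref_frame(o1, orthonormalize(a1 %*% flip_x()))
  )
}

# Inverse of pair_to_frames: recover pair frame + intra-pair parameters from
# the two base frames (strand2 given in its flipped, physical orientation).
frames_to_pair <- function(strand1, strand2) {
  a1 <- strand2$axes %*% flip_x()
  r <- crossprod(a1, strand1$axes)
  ang <- cehs_angles(r)
  rot <- cehs_rotations(ang[["tilt"]], ang[["roll"]], ang[["twist"]])
  mid <- a1 %*% rot$mid
  tr <- as.numeric(crossprod(mid, strand1$origin - strand2$origin))
  list(
    frame = ref_frame((strand1$origin + strand2$origin) / 2,
                      orthonormalize(mid)),
    params = pair_parameters(shear = tr[1], stretch = tr[2], stagger = tr[3],
                             buckle = ang[["tilt"]], propeller = ang[["roll"]],
                             opening = ang[["twist"]])
  )
}
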
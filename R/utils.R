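# Internal numeric helpers. Angles are degrees at every interface and radians
# only inside trigonometric calls.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap an angle in degrees into (-180, 180]
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# trapezoid integral on a (possibly non-uniform) grid
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

vec3 <- function(x, what = "vector") {
  x <- as.numeric(x)
  if (length(x) != 3L || any(!is.finite(x))) {
    stop(sprintf("%s must be a finite 3-vector", what), call. = FALSE)
  }
  x
}

unit_vec <- function(x) {
  n <- sqrt(sum(x^2))
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  x / n
}

# Evaluate fn() under a local RNG state seeded with `seed`; the caller's
# random stream is left untouched. Used so that repeated objective
# evaluations during fitting see identical draws.
with_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  fn()
}

# deterministic small-integer sub-seed derivation, kept below 2^31
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.double(seed)
  for (o in offs) s <- (s * 69069 + o) %% 2147483647
  as.integer(s)
}
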
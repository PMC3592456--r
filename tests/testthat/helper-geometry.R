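# shared helpers: random rigid bodies, isotropic dipole sets, small decays

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

random_unit_rows <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

random_step <- function() {
  step_parameters(
    shift = stats::runif(1, -5, 5), slide = stats::runif(1, -5, 5),
    rise = stats::runif(1, -5, 5), tilt = stats::runif(1, -60, 60),
    roll = stats::runif(1, -60, 60), twist = stats::runif(1, -60, 60)
  )
}

# small TCSPC layout for fast decay tests: counts stay high enough across
# the whole window that the Poisson weights behave
small_times <- function(n = 512, window = 20) tcspc_times(n, window)

test_photophysics <- function() {
  photophysics(donor_lifetime = 4.3, forster_radius = 27)
}
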
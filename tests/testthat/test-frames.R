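test_that("elementary rotations behave as the standard right-handed set", {
  expect_equal(rotation_matrix("x", 0), diag(3))
  expect_equal(as.numeric(rotation_matrix("z", 90) %*% c(1, 0, 0)),
               c(0, 1, 0), tolerance = 1e-12)
  expect_equal(rotation_matrix("z", 17) %*% rotation_matrix("z", 25),
               rotation_matrix("z", 42), tolerance = 1e-12)
  for (ax in c("x", "y", "z")) {
    r <- rotation_matrix(ax, 37.3)
    expect_equal(crossprod(r), diag(3), tolerance = 1e-12)
    expect_equal(det(r), 1, tolerance = 1e-12)
  }
  expect_error(rotation_matrix("w", 10))
})

test_that("rigid transforms preserve distances and invert exactly", {
  expect_equal(apply_rigid_transform(c(0, 0, 0), diag(3), c(1, 2, 3)),
               c(1, 2, 3))
  expect_equal(apply_rigid_transform(c(1, 0, 0), rotation_matrix("z", 90)),
               c(0, 1, 0), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:20) {
    r <- random_rotation()
    v <- stats::rnorm(3)
    x <- matrix(stats::rnorm(30), 10, 3)
    y <- apply_rigid_transform(x, r, v)
    expect_equal(as.matrix(stats::dist(y)), as.matrix(stats::dist(x)),
                 tolerance = 1e-10)
    back <- apply_rigid_transform(sweep(y, 2, v), t(r))
    expect_equal(back, x, tolerance = 1e-10)
  }
  expect_error(apply_rigid_transform(diag(3), matrix(1:9, 3, 3)),
               "orthonormal")
})

test_that("mid-step construction round-trips its parameters", {
  f <- ref_frame()
  st <- step_parameters(0.1, -1.2, 3.3, 2, 5, 34)
  g <- step_to_transform(f, st)
  expect_equal(unclass(transform_to_step(f, g)), unclass(st),
               tolerance = 1e-10, ignore_attr = TRUE)

  # zero step leaves the frame untouched
  g0 <- step_to_transform(f, step_parameters())
  expect_equal(g0$origin, f$origin)
  expect_equal(g0$axes, f$axes, tolerance = 1e-12)

  # pure rise is a pure translation along z
  gr <- step_to_transform(f, step_parameters(rise = 3.38))
  expect_equal(gr$origin, c(0, 0, 3.38))
  expect_equal(gr$axes, diag(3), tolerance = 1e-12)

  # twist branch convention: 179 degrees stays 179, not -181
  g179 <- step_to_transform(f, step_parameters(rise = 3.38, twist = 179))
  expect_equal(transform_to_step(f, g179)[["twist"]], 179, tolerance = 1e-8)
})

test_that("ten 36-degree steps close a full helical turn", {
  # independent oracle: explicit product of the mid-step rotation matrices
  oracle_axes <- diag(3)
  for (i in 1:10) oracle_axes <- oracle_axes %*% rotation_matrix("z", 36)
  f <- ref_frame()
  for (i in 1:10) f <- step_to_transform(f, step_parameters(rise = 3.38,
                                                            twist = 36))
  expect_equal(f$axes, oracle_axes, tolerance = 1e-10)
  expect_equal(f$axes, diag(3), tolerance = 1e-10)
  expect_equal(f$origin, c(0, 0, 33.8), tolerance = 1e-10)
})

test_that("parameter round-trip holds across the full rigid-body range", {
  set.seed(7)
  f0 <- ref_frame(stats::rnorm(3), random_rotation())
  for (i in 1:1000) {
    st <- random_step()
    g <- step_to_transform(f0, st)
    back <- transform_to_step(f0, g)
    expect_equal(unclass(back), unclass(st), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("frames stay orthonormal through long step chains", {
  set.seed(3)
  f <- ref_frame()
  for (i in 1:1000) f <- step_to_transform(f, random_step())
  expect_lt(max(abs(crossprod(f$axes) - diag(3))), 1e-8)
})

test_that("intra-pair placement round-trips pair parameters", {
  frame <- ref_frame(c(1, -2, 5), random_rotation())
  pp <- pair_parameters(shear = 0.3, stretch = -0.2, stagger = 0.15,
                        buckle = -4, propeller = 10, opening = 3)
  bf <- basefret:::pair_to_frames(frame, pp)
  rec <- basefret:::frames_to_pair(bf$strand1, bf$strand2)
  expect_equal(unclass(rec$params), unclass(pp), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(rec$frame$origin, frame$origin, tolerance = 1e-8)

  # ideal pair: both base frames coincide with the pair frame up to the flip
  bf0 <- basefret:::pair_to_frames(frame, pair_parameters())
  expect_equal(bf0$strand1$axes, frame$axes, tolerance = 1e-10)
  expect_equal(bf0$strand2$axes, frame$axes %*% diag(c(1, -1, -1)),
               tolerance = 1e-10)
  # strand-II local z (its 5'->3') is anti-parallel to the pair z
  expect_equal(sum(bf0$strand2$axes[, 3] * frame$axes[, 3]), -1,
               tolerance = 1e-10)
})
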
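test_that("degree of polarization matches its definition on canonical states", {
  expect_equal(degree_of_polarization(stokes(1, 0, 0, 1)), 1)
  expect_equal(degree_of_polarization(stokes(1, 0, 0, 0)), 0)
  expect_equal(degree_of_polarization(stokes(2, 1, 0, 1)), sqrt(2) / 2)
  expect_error(degree_of_polarization(c(0, 0, 0, 0)), "intensity")
})

test_that("DOP is invariant under positive rescaling", {
  set.seed(101)
  for (s in random_stokes(50)) {
    k <- stats::runif(1, 0.01, 100)
    expect_equal(degree_of_polarization(as.numeric(s) * k),
                 degree_of_polarization(s), tolerance = 1e-12)
  }
})

test_that("depolarization handles identity, halving and full depolarization", {
  s <- stokes(1, 0, 0, 1)
  expect_identical(as.numeric(depolarization(s, s)), 0)
  expect_identical(as.numeric(depolarization(s, stokes(1, 0, 0, 0.5))), 0.5)
  expect_equal(as.numeric(depolarization(s, c(2, 0, 0, 0))), 1)
  expect_error(depolarization(stokes(1, 0, 0, 0), s), "unpolarized")
})

test_that("negative depolarization is flagged, not clipped", {
  d <- depolarization(stokes(1, 0, 0, 0.5), stokes(1, 0, 0, 0.9))
  expect_lt(as.numeric(d), 0)
  expect_true(isTRUE(attr(d, "flagged")))
})

test_that("retardance angle is the Poincare-sphere angle", {
  s <- stokes(1, 0, 0, 1)
  expect_identical(retardance_angle(s, s), 0)
  expect_equal(retardance_angle(s, stokes(1, 1, 0, 0)), pi / 2)
  expect_equal(retardance_angle(s, stokes(1, 0, 0, -1)), pi)
  expect_error(retardance_angle(s, stokes(1, 0, 0, 0)), "zero polarized")
})

test_that("retardance angle is symmetric and scale invariant", {
  set.seed(7)
  ss <- random_stokes(40, dop_min = 0.05)
  for (i in seq(1, 39, by = 2)) {
    a <- ss[[i]]; b <- ss[[i + 1]]
    expect_equal(retardance_angle(a, b), retardance_angle(b, a))
    expect_equal(retardance_angle(as.numeric(a) * 3, b),
                 retardance_angle(a, b), tolerance = 1e-12)
  }
})

test_that("constructor enforces physicality with optional logged clipping", {
  expect_error(stokes(1, 1, 1, 1), "non-physical")
  expect_message(s <- stokes(1, 1, 1, 1, clip = TRUE), "clipping")
  expect_equal(dop_of(s), 1, tolerance = 1e-12)
  # slight violations within tolerance pass silently
  expect_silent(stokes(1, 1 + 1e-12, 0, 0))
})

test_that("Stokes JSON serialization round-trips", {
  s <- stokes(2, 0.3, -0.4, 0.5)
  expect_equal(as.numeric(stokes_from_json(stokes_to_json(s))), as.numeric(s))
  lst <- list(stokes(1, 0, 0, 1), stokes(1, 0.5, 0, 0))
  back <- stokes_from_json(stokes_to_json(lst))
  expect_equal(lapply(back, as.numeric), lapply(lst, as.numeric))
})

test_that("ideal element matrices behave like the textbook forms", {
  # quarter-wave plate at 45 degrees turns horizontal into right-circular
  out <- mueller_apply(mueller_retarder(pi / 2, pi / 4), stokes(1, 1, 0, 0))
  expect_equal(as.numeric(out), c(1, 0, 0, 1), tolerance = 1e-12)
  # rotator composed with its inverse is the identity
  m <- unclass(mueller_rotator(0.7)) %*% unclass(mueller_rotator(-0.7))
  expect_equal(m, diag(4), tolerance = 1e-14)
  # Malus: ideal polarizer halves unpolarized light
  expect_equal(as.numeric(mueller_apply(mueller_linear_polarizer(0),
                                        stokes(1, 0, 0, 0))),
               c(0.5, 0.5, 0, 0))
})

test_that("rotator and retarder blocks are orthogonal with determinant +1", {
  for (m in list(mueller_rotator(0.3), mueller_retarder(1.1, 0.4))) {
    b <- unclass(m)[2:4, 2:4]
    expect_equal(b %*% t(b), diag(3), tolerance = 1e-12)
    expect_equal(det(b), 1, tolerance = 1e-12)
  }
})

test_that("compositions of rotators and retarders never depolarize", {
  set.seed(21)
  for (i in 1:25) {
    m <- diag(4)
    for (k in 1:4) {
      m <- m %*% (if (stats::runif(1) < 0.5)
        unclass(mueller_rotator(stats::runif(1, 0, 2 * pi)))
        else unclass(mueller_retarder(stats::runif(1, 0, pi),
                                      stats::runif(1, 0, pi))))
    }
    s <- random_stokes(1)[[1]]
    out <- as.numeric(m %*% as.numeric(s))
    expect_equal(sqrt(sum(out[2:4]^2)) / out[1], dop_of(s), tolerance = 1e-12)
  }
})
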
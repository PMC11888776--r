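empty_slab <- function() tissue_model(populations = list(
  sphere_population(0.4, 1.4, number_density = 0)))

sphere_slab <- function(mu_s_per_mm, thickness = 20, r = 0.1, n = 1.45,
                        mu_a = 0) {
  tissue_model(slab_thickness_um = thickness, mu_a_per_mm = mu_a,
               populations = list(
                 sphere_population(r, n, mu_s_per_mm = mu_s_per_mm)))
}

test_that("ballistic slab transmits the input state untouched", {
  for (s in list(stokes(1, 0, 0, 1), stokes(1, 1, 0, 0),
                 stokes(1, 0.1, 0.2, 0.3))) {
    r <- run_forward(empty_slab(), s, n_photons = 500, seed = 8)
    expect_lt(abs(as.numeric(r$dep)), 1e-12)
    expect_lt(abs(r$delta), 1e-12)
    expect_equal(r$n_detected, 500)
  }
})

test_that("weight is conserved exactly without absorption or roulette", {
  r <- run_forward(sphere_slab(150), n_photons = 3000, seed = 12,
                   roulette_threshold = 0)
  expect_equal(unname(r$energy["transmitted"] + r$energy["reflected"]),
               r$n_launched)
})

test_that("energy bookkeeping closes with absorption and roulette", {
  r <- run_forward(sphere_slab(300, mu_a = 50), n_photons = 3000, seed = 13)
  total <- sum(r$energy[c("transmitted", "reflected", "absorbed",
                          "terminated", "stuck")])
  expect_equal(total, r$n_launched, tolerance = 1e-6)
  expect_gt(unname(r$energy["absorbed"]), 0)
})

test_that("runs are reproducible by seed and stable across seeds", {
  a <- run_forward(sphere_slab(200), n_photons = 4000, seed = 5)
  b <- run_forward(sphere_slab(200), n_photons = 4000, seed = 5)
  expect_identical(a$mean_out_stokes, b$mean_out_stokes)
  expect_identical(a$energy, b$energy)
  c <- run_forward(sphere_slab(200), n_photons = 4000, seed = 6)
  expect_false(identical(a$mean_out_stokes, c$mean_out_stokes))
  se <- sqrt(a$dep_se^2 + c$dep_se^2)
  expect_lt(abs(a$dep - c$dep), 4 * se + 1e-6)
})

test_that("scatter_event leaves packets untouched in an empty medium", {
  fr <- random_packet_frames(100)
  pk <- photon_packets(100, direction = fr$u, reference = fr$r)
  pk2 <- scatter_event(pk, empty_slab())
  expect_identical(pk2$direction, pk$direction)
  expect_identical(pk2$stokes, pk$stokes)
})

test_that("cylinder scattering preserves the angle to the cylinder axis", {
  ax <- c(0.3, 0.8, 0.52); ax <- ax / sqrt(sum(ax^2))
  mdl <- tissue_model(populations = list(
    cylinder_population(0.5, 1.44, mu_s_per_mm = 100, mean_axis = ax,
                        kappa = Inf)))
  set.seed(31)
  fr <- random_packet_frames(5000)
  pk <- photon_packets(5000, direction = fr$u, reference = fr$r)
  set.seed(32)
  pk2 <- scatter_event(pk, mdl)
  a0 <- acos(pmin(abs(fr$u %*% ax), 1))
  a1 <- acos(pmin(abs(pk2$direction %*% ax), 1))
  expect_lt(max(abs(a0 - a1)), 1e-10)
  # single scattering keeps pure states pure
  dop <- sqrt(rowSums(pk2$stokes[, 2:4]^2)) / pk2$stokes[, 1]
  expect_equal(dop, rep(1, 5000), tolerance = 1e-9)
})

test_that("sphere scattering reproduces the asymmetry parameter", {
  r <- 0.25; n <- 1.45
  mdl <- tissue_model(populations = list(
    sphere_population(r, n, mu_s_per_mm = 100)))
  p <- mdl$populations[[1]]
  # quadrature oracle: the theta marginal of the polarized phase function is
  # proportional to M11(theta) sin(theta) for any input state
  th <- seq(0, pi, length.out = 8001)
  a <- mie_amplitudes(th, p$x, p$m)
  m11 <- (Mod(a$S1)^2 + Mod(a$S2)^2) / 2
  g_oracle <- sum(m11 * cos(th) * sin(th)) / sum(m11 * sin(th))
  set.seed(41)
  nev <- 40000
  pk <- photon_packets(nev, direction = c(0, 0, 1), reference = c(1, 0, 0),
                       stokes = c(1, 0.4, 0.1, 0.6))
  set.seed(42)
  pk2 <- scatter_event(pk, mdl)
  ct <- pk2$direction[, 3]
  expect_lt(abs(mean(ct) - g_oracle), 3 * stats::sd(ct) / sqrt(nev))
})

test_that("depolarization and retardance grow with optical thickness", {
  mfp <- 1 / 0.2  # mu_s = 200/mm = 0.2/um
  deps <- dels <- c()
  for (k in c(1, 2, 5, 10)) {
    r <- run_forward(sphere_slab(200, thickness = k * mfp),
                     n_photons = 5000, seed = 17,
                     acceptance_half_angle = pi / 3)
    deps <- c(deps, r$dep); dels <- c(dels, r$delta)
  }
  expect_true(all(diff(deps) > 0))
  expect_true(all(diff(dels) >= -1e-3))
})

test_that("detected mean Stokes stays physical", {
  r <- run_forward(tissue_preset("normal"), n_photons = 4000, seed = 19)
  expect_lte(dop_of(r$mean_out_stokes), 1 + 1e-9)
  expect_false(r$flagged)
})

test_that("zero detections produce a flagged result", {
  r <- run_forward(sphere_slab(4000, r = 0.05, n = 1.8),
                   n_photons = 30, seed = 20,
                   acceptance_half_angle = 1e-4)
  expect_true(r$flagged || r$n_detected > 0)
  if (r$flagged) expect_true(is.na(r$dep))
})

test_that("Watson orientation sampling covers the limiting cases", {
  mu <- c(0, 0, 1)
  set.seed(50)
  expect_equal(rwatson(5, mu, Inf), matrix(mu, 5, 3, byrow = TRUE))
  iso <- rwatson(20000, mu, 0)
  expect_lt(abs(mean(abs(iso[, 3])) - 0.5), 0.01)   # |cos| uniform
  tight <- rwatson(2000, mu, 100)
  expect_gt(mean(abs(tight %*% mu)), 0.99)
  expect_equal(rowSums(tight^2), rep(1, 2000), tolerance = 1e-12)
})

test_that("scattering patterns from aligned cylinders are anisotropic under linear light", {
  mdl <- function(ax) tissue_model(populations = list(
    cylinder_population(0.5, 1.44, mu_s_per_mm = 100, mean_axis = ax,
                        kappa = Inf)))
  p <- scattering_pattern(mdl(c(1, 0, 0)), stokes(1, 1, 0, 0),
                          n_photons = 8000, seed = 60)
  expect_true(is.finite(p$anisotropy))
  expect_equal(sum(p$grid), unname(p$result$energy["transmitted"]),
               tolerance = 1e-6)
  # single-scattering regime: aligned cylinders perpendicular to the beam
  # scatter into the plane perpendicular to the axis (ux stays ~ 0)
  thin <- tissue_model(slab_thickness_um = 1, populations = list(
    cylinder_population(0.5, 1.44, mu_s_per_mm = 100, mean_axis = c(1, 0, 0),
                        kappa = Inf)))
  ps <- scattering_pattern(thin, stokes(1, 0, 0, 1), n_photons = 4000,
                           seed = 61)
  ex <- ps$result$exit
  expect_lt(max(abs(ex[, 1])), 1e-9)
})
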
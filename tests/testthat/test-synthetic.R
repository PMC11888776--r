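test_that("scan geometries reproduce the published sampling layouts", {
  g1 <- geometry_one_channel()
  expect_equal(g1$n_points, 48)            # 3 x 4 mm at 500 um: 6 x 8
  expect_equal(g1$n_channels, 1)
  g4 <- geometry_four_channel()
  expect_equal(g4$n_points, 64)            # 4 x 4 mm at 500 um: 8 x 8
  expect_equal(nrow(g4$channel_offsets), 4)
  # 2 x 2 channel square with 125 um pitch
  d <- dist(g4$channel_offsets[, c("dx_um", "dy_um")])
  expect_equal(sort(unique(round(as.numeric(d), 9))),
               c(125, 125 * sqrt(2)), tolerance = 1e-9)
  # serpentine: consecutive points are one step apart
  p <- g1$points
  step <- sqrt(diff(p$x_um)^2 + diff(p$y_um)^2)
  expect_true(all(step == 500))
})

test_that("generation is bit-identical by seed and differs across seeds", {
  a <- generate_scan(seed = 3)
  b <- generate_scan(seed = 3)
  expect_identical(a, b)
  c <- generate_scan(seed = 4)
  expect_false(identical(a$dep, c$dep))
  # the generator does not disturb the caller's RNG stream
  set.seed(99); x1 <- stats::rnorm(1)
  set.seed(99); invisible(generate_scan(seed = 5)); x2 <- stats::rnorm(1)
  expect_identical(x1, x2)
})

test_that("the injury field only affects the ipsilateral side", {
  base <- generate_scan(field = injury_field(core_severity = 0), seed = 6)
  hurt <- generate_scan(field = injury_field(core_severity = 1), seed = 6)
  expect_identical(base$dep[base$side == "contra"],
                   hurt$dep[hurt$side == "contra"])
  expect_false(identical(base$dep[base$side == "ipsi"],
                         hurt$dep[hurt$side == "ipsi"]))
})

test_that("severity is monotone in space and in the generated means", {
  f <- injury_field(core_center_mm = c(1, 1), core_severity = 0.8)
  d <- seq(0, 3000, by = 250)
  sev <- severity_at(f, 1000 + d, 1000)
  expect_true(all(diff(sev) <= 0))
  expect_equal(max(sev), 0.8)
  means <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(cs) {
    rec <- generate_scan(field = injury_field(core_severity = cs), seed = 7)
    mean(rec$dep[rec$side == "ipsi"])
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("the noiseless uniform-severity limit hits the target mean", {
  rec <- generate_scan(
    field = injury_field(core_severity = 1, decay_length_mm = 1e9),
    params = generator_params(dep_sd = 1e-9, delta_sd = 1e-9, noise_sd = 0),
    seed = 8)
  ipsi <- rec[rec$side == "ipsi", ]
  expect_equal(ipsi$dep, rep(0.35, nrow(ipsi)), tolerance = 1e-6)
  expect_equal(ipsi$delta, rep(0.33, nrow(ipsi)), tolerance = 1e-6)
})

test_that("inter-channel correlation matches the configured value", {
  set.seed(0)
  cors <- vapply(1:60, function(s) {
    rec <- generate_scan(field = injury_field(core_severity = 0),
                         params = generator_params(noise_sd = 0),
                         seed = 1000 + s)
    d <- matrix(rec$dep[order(rec$side, rec$point_index, rec$channel)],
                ncol = 4, byrow = TRUE)
    mean(stats::cor(d)[upper.tri(diag(4))])
  }, 0)
  se <- stats::sd(cors) / sqrt(length(cors))
  expect_lt(abs(mean(cors) - 0.5), 3 * se)
})

test_that("a null injury field yields calibrated Mann-Whitney false positives", {
  set.seed(1)
  pvals <- vapply(1:100, function(s) {
    rec <- generate_scan(geometry_one_channel(),
                         field = injury_field(core_severity = 0),
                         seed = 2000 + s)
    mann_whitney_two_sided(rec$dep[rec$side == "contra"],
                           rec$dep[rec$side == "ipsi"])$p_value
  }, 0)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.03 + 1e-9)
})

test_that("trace datasets round-trip and handle empty input", {
  set.seed(2)
  ss <- random_stokes(10)
  traces <- generate_trace_dataset(ss)
  for (i in seq_along(ss))
    expect_equal(as.numeric(demodulate(traces[[i]])), as.numeric(ss[[i]]),
                 tolerance = 1e-10)
  expect_identical(generate_trace_dataset(list()), list())
})

test_that("the MC-driven backend produces ordered side contrast", {
  g <- scan_geometry(region_mm = c(1, 1), step_um = 500, n_channels = 1)
  expect_equal(g$n_points, 4)
  rec <- generate_scan(g, injury_field(core_center_mm = c(0.5, 0.5),
                                       decay_length_mm = 10),
                       generator_params(backend = "mc_driven",
                                        mc_photons = 400, noise_sd = 0),
                       seed = 9)
  expect_equal(nrow(rec), 8)
  expect_true(all(is.finite(rec$dep)))
  expect_gt(mean(rec$dep[rec$side == "ipsi"]),
            mean(rec$dep[rec$side == "contra"]))
})

test_that("measurement CSV export keeps all columns", {
  rec <- generate_scan(seed = 10)
  p <- withr::local_tempfile(fileext = ".csv")
  write_scan_csv(rec, p)
  back <- utils::read.csv(p)
  expect_equal(names(back), names(rec))
  expect_equal(back$dep, rec$dep, tolerance = 1e-12)
})
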
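test_that("spherical N-wave matches the closed form and its symmetries", {
  tm <- time_axis()
  ab <- sphere_absorber(c(0, 0, 0), 1.0, 100)
  pos <- c(0, 0, -60)
  sig <- nwave_sphere(ab, pos, tm, c = 1500)

  # independent dense evaluation of the formula at 100x oversampling
  r <- 60; a <- 0.5; c_mm <- 1500 * 1000
  tt_dense <- seq(tm$offset_samples, tm$offset_samples + tm$n_samples - 1,
                  by = 0.01) / tm$fs
  p_dense <- ifelse(abs(r - c_mm * tt_dense) <= a + 1e-9,
                    100 * (r - c_mm * tt_dense) / (2 * r), 0)
  expect_equal(max(abs(sig)), max(abs(p_dense)), tolerance = 0.02)
  expect_equal(max(abs(p_dense)), 100 * a / (2 * r), tolerance = 1e-6)

  # sampled values agree exactly with the formula on the sample grid
  tt <- sample_times(tm)
  expected <- ifelse(abs(r - c_mm * tt) <= a + 1e-9,
                     100 * (r - c_mm * tt) / (2 * r), 0)
  expect_equal(sig, expected, tolerance = 1e-12)

  # compact support and odd symmetry about t = r/c; integral ~ 0
  expect_true(all(sig[tt < (r - a) / c_mm] == 0))
  expect_true(all(sig[tt > (r + a) / c_mm] == 0))
  expect_lt(abs(sum(sig)) / sum(abs(sig)), 0.05)
  sup <- which(sig != 0)
  expect_equal(sig[sup], -rev(sig[sup]), tolerance = 1e-9)

  # sensor inside the absorber is rejected
  expect_error(nwave_sphere(sphere_absorber(c(0, 0, -60), 2, 100), pos, tm),
               "inside absorber")
})

test_that("cylinder sphere-train: degenerate limit, convergence, arrival", {
  tm <- time_axis(fs = 60e6, n_samples = 1024L, offset_samples = 500L)
  # length == diameter with a single packing sphere: equals the N-wave of
  # that sphere scaled by the volume ratio (3/2 for L = d)
  cy <- cylinder_absorber(c(0, 0, 0), 1.0, 1.0, azimuth = 0, elevation = 0,
                          p0 = 100)
  pos <- c(0, 0, -20)
  s_cyl <- signal_cylinder(cy, pos, tm, axial_step = 1.0)
  s_sph <- nwave_sphere(sphere_absorber(c(0, 0, 0), 1.0, 100), pos, tm)
  v_ratio <- (pi * 0.5^2 * 1.0) / (4 / 3 * pi * 0.5^3)
  expect_equal(s_cyl, s_sph * v_ratio, tolerance = 1e-12)

  # self-convergence: halving the axial step changes the band-limited
  # signal by < 1% RMS
  long_cy <- cylinder_absorber(c(0, 0, 0), 1.0, 20, azimuth = 90,
                               elevation = 0, p0 = 100)
  resp <- sensor_response()
  bl <- function(step) {
    raw <- signal_cylinder(long_cy, c(0, 0, -25), tm, axial_step = step)
    s <- signal_set(matrix(raw, 1), "s1", tm, "ideal_broadband")
    as.numeric(apply_sensor_bandwidth(s, resp)$values)
  }
  step0 <- (1500 * 1000) / (2 * tm$fs)
  v1 <- bl(step0); v2 <- bl(step0 / 2)
  expect_lt(sqrt(mean((v1 - v2)^2)) / sqrt(mean(v2^2)), 0.01)

  # y-parallel cylinder at origin, sensor on the z axis: earliest arrival at
  # distance |z| - radius
  sig <- signal_cylinder(long_cy, c(0, 0, -25), tm)
  first <- min(which(sig != 0))
  t_first <- (tm$offset_samples + first - 1) / tm$fs
  expect_equal(t_first * 1500 * 1000, 25 - 0.5, tolerance = 0.05)
})

test_that("simulate_signals is linear and respects geometry", {
  geo <- toy_geo()
  tm <- toy_time()
  # empty phantom -> all zero
  empty <- structure(list(absorbers = list(), seed = NA), class = "phantom")
  s0 <- simulate_signals(empty, geo$coords, tm, sensor_ids = geo$ids)
  expect_true(all(s0$values == 0))
  expect_identical(s0$provenance, "ideal_broadband")

  # doubling p0 doubles the signal exactly
  ph1 <- toy_eval_phantom()
  ph2 <- ph1
  ph2$absorbers <- lapply(ph1$absorbers, function(a) { a$p0 <- 2 * a$p0; a })
  s1 <- simulate_signals(ph1, geo$coords, tm, sensor_ids = geo$ids)
  s2 <- simulate_signals(ph2, geo$coords, tm, sensor_ids = geo$ids)
  expect_equal(s2$values, 2 * s1$values, tolerance = 1e-12)

  # sphere at the origin arrives at the same sample at every real sensor
  orig <- one_sphere_phantom(c(0, 0, 0))
  arr_ids <- paste0("r", geo$array$indices)
  s <- simulate_signals(orig, geo$array$coords, tm, sensor_ids = arr_ids)
  first <- apply(s$values, 1, function(r) min(which(r != 0)))
  expect_lte(diff(range(first)), 1)

  # radial shift by delta moves the arrival by delta/c (cross-correlation)
  delta <- 1.2  # mm
  shifted <- one_sphere_phantom(c(0, 0, -delta))
  pos <- matrix(c(0, 0, -20), 1, dimnames = list("r1"))
  sa <- simulate_signals(orig, pos, tm)$values[1, ]
  sb <- simulate_signals(shifted, pos, tm)$values[1, ]
  cc <- ccf(sb, sa, lag.max = 40, plot = FALSE)
  shift <- cc$lag[which.max(cc$acf)]
  expect_equal(shift, round(-delta / (1500 * 1000) * tm$fs))
})

test_that("bandwidth limitation implements the stated response", {
  resp <- sensor_response()  # 3.5 MHz, 90%
  expect_equal(response_gain(resp, 3.5e6), 1, tolerance = 0.01)
  expect_equal(response_gain(resp, 3.5e6 * 1.45), 0.5, tolerance = 0.01)
  expect_equal(response_gain(resp, 3.5e6 * 0.55), 0.5, tolerance = 0.01)
  expect_lt(abs(response_gain(resp, 0)), 1e-3)

  # a pure tone at fc passes with unit gain (centre of the window, away from
  # edge transients)
  tm <- time_axis(fs = 60e6, n_samples = 2048L, offset_samples = 0L)
  tt <- sample_times(tm)
  tone <- sin(2 * pi * 3.5e6 * tt)
  s <- signal_set(matrix(tone, 1), "s1", tm, "ideal_broadband")
  out <- as.numeric(apply_sensor_bandwidth(s, resp)$values)
  mid <- 500:1500
  expect_equal(max(abs(out[mid])), 1, tolerance = 0.01)

  # independent frequency-domain oracle at 4x zero padding
  ab <- sphere_absorber(c(0, 0, 0), 1.0, 100)
  nw <- nwave_sphere(ab, c(0, 0, -30), tm)
  n4 <- 4 * tm$n_samples
  f <- c(seq(0, n4 / 2), seq(-n4 / 2 + 1, -1)) * tm$fs / n4
  oracle <- Re(fft(fft(c(nw, numeric(n4 - tm$n_samples))) *
                     response_gain(resp, f), inverse = TRUE)) / n4
  ours <- as.numeric(apply_sensor_bandwidth(
    signal_set(matrix(nw, 1), "s1", tm, "ideal_broadband"), resp)$values)
  expect_lt(sqrt(mean((ours - oracle[seq_len(tm$n_samples)])^2)), 1e-6)

  # band-limited energy never exceeds broadband energy
  expect_lte(sum(ours^2), sum(nw^2))

  # provenance is enforced
  s_bl <- apply_sensor_bandwidth(s, resp)
  expect_error(apply_sensor_bandwidth(s_bl, resp), "ideal_broadband")
})

test_that("reference amplitude: equidistance, linearity, exhaustive oracle", {
  tm <- toy_time()
  resp <- sensor_response()
  geo <- toy_geo()
  ref <- reference_amplitude(resp, tm, R = 20)
  expect_equal(reference_amplitude(resp, tm, R = 20, p0 = 50), ref / 2,
               tolerance = 1e-9)

  # brute-force max over all sensors and samples of the band-limited signals
  s <- simulate_signals(one_sphere_phantom(c(0, 0, 0), diameter = 1.0),
                        geo$array$coords, tm,
                        sensor_ids = paste0("r", geo$array$indices))
  bl <- apply_sensor_bandwidth(s, resp)
  expect_equal(ref, max(abs(bl$values)), tolerance = 1e-3)
  # per-sensor peaks agree across sensors to 0.1% (equidistance)
  peaks <- apply(abs(bl$values), 1, max)
  expect_lt(diff(range(peaks)) / mean(peaks), 1e-3)
})

test_that("calibrated noise has the stated statistics and is seeded", {
  tm <- time_axis(fs = 60e6, n_samples = 1792L, offset_samples = 1500L)
  resp <- sensor_response()
  vals <- matrix(0, 600, tm$n_samples)  # > 1e6 samples
  s <- signal_set(vals, paste0("r", 1:600), tm, "ideal_broadband")
  s <- apply_sensor_bandwidth(s, resp)

  spec <- noise_spec(snr_db = 30, rng_seed = 11)
  noisy <- add_noise(s, spec, resp, R = 60)
  ref <- reference_amplitude(resp, tm, R = 60)
  expect_equal(sd(noisy$values), ref * 10^(-30 / 20), tolerance = 0.01)
  expect_identical(noisy$provenance, "band_limited_noisy")

  # same seed -> identical; infinite S/N -> identity
  noisy2 <- add_noise(s, spec, resp, R = 60)
  expect_identical(noisy$values, noisy2$values)
  clean <- add_noise(s, noise_spec(snr_db = Inf), resp, R = 60)
  expect_identical(unname(clean$values), unname(vals))

  expect_error(add_noise(noisy, spec, resp), "band_limited")
})
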
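# Shared fixtures.  Everything is generated in code; heavyweight device-scale
# objects are memoized so the suite builds them once.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 512-channel device geometry (R = 60 mm, omit 7/20, append 513/514)
device_geo <- function() memo("device_geo", build_geometry())

# brute-force residue-class oracle: chain length of residue r modulo k over
# the device index set {1..514} \ {7, 20}
device_indices_oracle <- function() setdiff(1:514, c(7L, 20L))

chain_length_oracle <- function(k) {
  idx <- device_indices_oracle()
  vapply(seq_len(k), function(r) sum(idx %% k == r %% k), integer(1))
}

# toy hemisphere for reduced-scale work: 40 channels, R = 20 mm, a single
# spiral direction at Fibonacci interval 8 (chains of 5 after truncation)
toy_geo <- function(intervals = c(8L)) {
  memo(paste0("toy_geo_", paste(intervals, collapse = "_")), {
    cfg <- array_config(R = 20, n_channels = 40,
                        omitted_indices = integer(0),
                        appended_indices = integer(0))
    build_geometry(cfg, intervals = intervals)
  })
}

toy_time <- function() time_axis(fs = 20e6, n_samples = 256L,
                                 offset_samples = 200L)

# spheres-only training conditions scaled to the toy hemisphere
toy_phantom_spec <- function() {
  phantom_spec(
    placement_radius = 4,
    sphere = list(count = 1:4, diameter = c(0.2, 1.2), p0 = c(50, 100)),
    short_cylinder = list(count = 0:0, diameter = c(0.2, 1.2),
                          length = c(3, 6), p0 = c(50, 100),
                          azimuth = c(-180, 180), elevation = c(-70, 70)),
    long_cylinder = list(count = 0:0, diameter = c(0.2, 1.2),
                         length = c(8, 8), p0 = c(50, 100),
                         azimuth = c(-180, 180), elevation = c(-5, 5)))
}

# fixed three-sphere toy phantom for reconstruction comparisons
toy_eval_phantom <- function() {
  structure(list(absorbers = list(
    sphere_absorber(c(0, -2, -2), 0.8, 100),
    sphere_absorber(c(0, 0, 0), 0.8, 100),
    sphere_absorber(c(0, 2, 2), 0.8, 100)), seed = NA_integer_),
    class = "phantom")
}

one_sphere_phantom <- function(center, diameter = 0.6, p0 = 100) {
  structure(list(absorbers = list(sphere_absorber(center, diameter, p0)),
                 seed = NA_integer_), class = "phantom")
}

# device-scale evaluation-phantom simulation, shared by the acceptance blocks
device_eval_sim <- function() {
  memo("device_eval_sim", {
    geo <- device_geo()
    tm <- time_axis()
    resp <- sensor_response()
    ideal <- simulate_signals(evaluation_phantom(), geo$coords, tm, 1500,
                              sensor_ids = geo$ids)
    ideal_bl <- apply_sensor_bandwidth(ideal, resp)
    real_ids <- geo$ids[seq_along(geo$array$indices)]
    list(geo = geo, time = tm, resp = resp, ideal_bl = ideal_bl,
         ideal_real = subset_signals(ideal_bl, real_ids),
         real_ids = real_ids)
  })
}

device_snr_report <- function() {
  memo("device_snr_report", {
    suppressMessages(run_snr_experiment(pipeline_config(seed = 1),
                                           scale = "ci",
                                           geometry = device_geo()))
  })
}

# random signal set over the device's real sensors (cheap pattern-op input)
random_real_signals <- function(geo, n_samples = 64L, seed = 1L,
                                provenance = "band_limited_noisy") {
  tm <- time_axis(fs = 60e6, n_samples = n_samples, offset_samples = 0L)
  ids <- paste0("r", geo$array$indices)
  vals <- hemipa:::with_seed(seed,
    matrix(rnorm(length(ids) * n_samples), length(ids)))
  signal_set(vals, ids, tm, provenance)
}
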
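#' Acquisition time axis
#'
#' Sample `k` (1-based) is recorded at `t = (offset_samples + k - 1) / fs`
#' after light irradiation.  Defaults are the reference device's values:
#' 60 MHz sampling, 1792 samples, 1500-sample offset (the window is kept as
#' short as possible while covering the reconstruction region).
#'
#' @param fs sampling frequency, Hz.
#' @param n_samples number of recorded samples.
#' @param offset_samples delay from light irradiation to the first sample,
#'   in samples.
#' @return a `time_axis`.
#' @export
time_axis <- function(fs = 60e6, n_samples = 1792L, offset_samples = 1500L) {
  stopifnot(fs > 0, n_samples >= 2, offset_samples >= 0)
  structure(list(fs = fs, n_samples = as.integer(n_samples),
                 offset_samples = as.integer(offset_samples)),
            class = "time_axis")
}

#' Sample times of an axis
#' @param time a [time_axis()].
#' @return numeric vector of sample times in seconds.
#' @export
sample_times <- function(time) {
  (time$offset_samples + seq_len(time$n_samples) - 1) / time$fs
}

#' Transducer frequency response
#'
#' Zero-phase amplitude response with centre frequency `fc` and -6 dB
#' fractional bandwidth `rel_bw`.  The amplitude model is an odd-symmetric
#' (sine-modulated) Gaussian, `H(f) = g(|f| - fc) - g(|f| + fc)` with `g` a
#' Gaussian whose width gives half amplitude at `fc * (1 +/- rel_bw / 2)`;
#' unlike a plain Gaussian this is exactly zero at DC, as a piezoelectric
#' receiver is.
#'
#' @param fc centre frequency, Hz.
#' @param rel_bw -6 dB fractional bandwidth (bandwidth / fc).
#' @return a `sensor_response`.
#' @export
sensor_response <- function(fc = 3.5e6, rel_bw = 0.90) {
  stopifnot(fc > 0, rel_bw > 0)
  structure(list(fc = fc, rel_bw = rel_bw, shape = "gaussian_odd"),
            class = "sensor_response")
}

#' Evaluate the transducer amplitude response
#' @param resp a [sensor_response()].
#' @param f frequencies in Hz (may be negative; the response is even).
#' @return amplitude gain at each frequency.
#' @export
response_gain <- function(resp, f) {
  sigma <- (resp$rel_bw * resp$fc / 2) / sqrt(2 * log(2))
  g <- function(u) exp(-u^2 / (2 * sigma^2))
  g(abs(f) - resp$fc) - g(abs(f) + resp$fc)
}

#' Signal container
#'
#' A set of pressure traces (sensors x samples) with its time axis and a
#' provenance tag recording the pipeline stage.  Provenance may only advance
#' along ideal_broadband -> band_limited -> band_limited_noisy -> cnn_output
#' -> inverse_filtered.
#'
#' @param values numeric matrix, sensors x samples.
#' @param sensor_ids character vector, one id per row.
#' @param time a [time_axis()].
#' @param provenance pipeline stage tag.
#' @return a `signal_set`.
#' @export
signal_set <- function(values, sensor_ids, time,
                       provenance = c("ideal_broadband", "band_limited",
                                      "band_limited_noisy", "cnn_output",
                                      "inverse_filtered")) {
  provenance <- match.arg(provenance)
  values <- as.matrix(values)
  sensor_ids <- as.character(sensor_ids)
  if (nrow(values) != length(sensor_ids))
    stop("row count (", nrow(values), ") must equal number of sensor ids (",
         length(sensor_ids), ")")
  if (ncol(values) != time$n_samples)
    stop("column count must equal time$n_samples")
  rownames(values) <- sensor_ids
  structure(list(values = values, sensor_ids = sensor_ids, time = time,
                 provenance = provenance),
            class = "signal_set")
}

PROVENANCE_ORDER <- c(ideal_broadband = 1, band_limited = 2,
                      band_limited_noisy = 3, cnn_output = 4,
                      inverse_filtered = 5)

#' Subset a signal set by sensor id
#' @param s a `signal_set`.
#' @param ids sensor ids to keep, in the requested order.
#' @return a `signal_set`.
#' @export
subset_signals <- function(s, ids) {
  miss <- setdiff(ids, s$sensor_ids)
  if (length(miss)) stop("missing sensors: ", paste(head(miss, 5),
                                                    collapse = ", "))
  signal_set(s$values[ids, , drop = FALSE], ids, s$time, s$provenance)
}

#' N-wave of a uniform spherical absorber
#'
#' The pressure received at distance `r` from a uniform sphere of radius `a`
#' and initial pressure `p0` is the bipolar N-wave
#' `p(t) = p0 (r - c t) / (2 r)` for `|r - c t| <= a`, zero otherwise; its
#' peak is `p0 a / (2 r)` and its time integral vanishes.
#'
#' @param absorber a [sphere_absorber()].
#' @param sensor_pos 3-vector, mm.
#' @param time a [time_axis()].
#' @param c sound speed, m/s.
#' @return numeric vector of length `time$n_samples`.
#' @export
nwave_sphere <- function(absorber, sensor_pos, time, c = 1500) {
  stopifnot(inherits(absorber, "sphere_absorber"))
  drop(nwave_accumulate_cpp(matrix(sensor_pos, nrow = 1),
                            matrix(absorber$center, nrow = 1),
                            absorber$diameter / 2, absorber$p0,
                            time$fs, time$n_samples, time$offset_samples, c))
}

#' Decompose a cylinder into an equivalent train of spheres
#'
#' The cylinder is discretized as equally spaced spheres along its axis with
#' sphere diameter equal to the cylinder diameter and axial step at most
#' `axial_step` (default `c / (4 fmax)` with `fmax = fs / 2`, i.e. a quarter
#' of the shortest resolvable wavelength); amplitudes are scaled so the total
#' absorbing volume is conserved.
#'
#' @param absorber a [cylinder_absorber()].
#' @param time a [time_axis()] (sets the default step).
#' @param c sound speed, m/s.
#' @param axial_step axial spacing in mm, or `NULL` for the default.
#' @return list with `centers` (n x 3), `radius` (mm) and `p0` (scaled).
#' @export
cylinder_sphere_train <- function(absorber, time, c = 1500,
                                  axial_step = NULL) {
  stopifnot(inherits(absorber, "cylinder_absorber"))
  if (is.null(axial_step)) axial_step <- (c * 1000) / (2 * time$fs)  # mm
  L <- absorber$length
  a <- absorber$diameter / 2
  n <- max(1L, as.integer(ceiling(L / axial_step)))
  axis <- cylinder_axis(absorber)
  s <- ((seq_len(n) - 0.5) / n - 0.5) * L
  centers <- matrix(rep(absorber$center, each = n), ncol = 3) +
    outer(s, axis)
  v_cyl <- pi * a^2 * L
  v_sph <- 4 / 3 * pi * a^3
  list(centers = centers, radius = a,
       p0 = rep(absorber$p0 * v_cyl / (n * v_sph), n))
}

#' Signal of a cylindrical absorber at one sensor
#'
#' Superposition of N-waves from the volume-conserving sphere train of
#' [cylinder_sphere_train()].
#'
#' @inheritParams cylinder_sphere_train
#' @param sensor_pos 3-vector, mm.
#' @return numeric vector of length `time$n_samples`.
#' @export
signal_cylinder <- function(absorber, sensor_pos, time, c = 1500,
                            axial_step = NULL) {
  tr <- cylinder_sphere_train(absorber, time, c, axial_step)
  drop(nwave_accumulate_cpp(matrix(sensor_pos, nrow = 1), tr$centers,
                            rep(tr$radius, nrow(tr$centers)), tr$p0,
                            time$fs, time$n_samples, time$offset_samples, c))
}

# flatten a phantom into one sphere list (cylinders -> sphere trains)
phantom_spheres <- function(phantom, time, c, axial_step = NULL) {
  centers <- list(); radius <- list(); p0 <- list()
  for (ab in phantom$absorbers) {
    if (ab$type == "sphere") {
      centers[[length(centers) + 1L]] <- matrix(ab$center, nrow = 1)
      radius[[length(radius) + 1L]] <- ab$diameter / 2
      p0[[length(p0) + 1L]] <- ab$p0
    } else {
      tr <- cylinder_sphere_train(ab, time, c, axial_step)
      centers[[length(centers) + 1L]] <- tr$centers
      radius[[length(radius) + 1L]] <- rep(tr$radius, nrow(tr$centers))
      p0[[length(p0) + 1L]] <- tr$p0
    }
  }
  list(centers = do.call(rbind, centers), radius = unlist(radius),
       p0 = unlist(p0))
}

#' Simulate ideal broadband received signals
#'
#' Sums the N-wave contributions of every absorber of a phantom at every
#' sensor position.  Linear in the absorbers' `p0`.
#'
#' @param phantom a `phantom`.
#' @param sensor_coords n x 3 matrix of sensor positions, mm.
#' @param time a [time_axis()].
#' @param c sound speed, m/s.
#' @param sensor_ids ids for the rows (default from rownames).
#' @param axial_step cylinder discretization step override (mm).
#' @return a `signal_set` with provenance `ideal_broadband`.
#' @export
simulate_signals <- function(phantom, sensor_coords, time, c = 1500,
                             sensor_ids = rownames(sensor_coords),
                             axial_step = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  sensor_coords <- as.matrix(sensor_coords)
  if (is.null(sensor_ids)) sensor_ids <- as.character(seq_len(nrow(sensor_coords)))
  if (length(phantom$absorbers) == 0) {
    vals <- matrix(0, nrow(sensor_coords), time$n_samples)
  } else {
    sph <- phantom_spheres(phantom, time, c, axial_step)
    vals <- nwave_accumulate_cpp(sensor_coords, sph$centers, sph$radius,
                                 sph$p0, time$fs, time$n_samples,
                                 time$offset_samples, c)
  }
  signal_set(vals, sensor_ids, time, "ideal_broadband")
}

# zero-phase frequency-domain filtering of the rows of a matrix, with
# power-of-two zero padding to suppress circular wrap-around
filter_rows <- function(values, gain_fun, fs) {
  n <- ncol(values)
  nfft <- 2^ceiling(log2(2 * n))
  f <- c(seq(0, nfft / 2), seq(-nfft / 2 + 1, -1)) * fs / nfft
  gain <- gain_fun(f)
  padded <- cbind(values, matrix(0, nrow(values), nfft - n))
  spec <- mvfft(t(padded))
  out <- Re(mvfft(spec * gain, inverse = TRUE)) / nfft
  t(out)[, seq_len(n), drop = FALSE]
}

#' Apply the transducer bandwidth limitation
#'
#' Zero-phase frequency-domain multiplication of each trace by the transducer
#' amplitude response.
#'
#' @param s a `signal_set` with provenance `ideal_broadband`.
#' @param resp a [sensor_response()].
#' @return a `signal_set` with provenance `band_limited`.
#' @export
apply_sensor_bandwidth <- function(s, resp) {
  stopifnot(inherits(s, "signal_set"))
  if (s$provenance != "ideal_broadband")
    stop("bandwidth limitation applies to ideal_broadband signals, got ",
         s$provenance)
  vals <- filter_rows(s$values, function(f) response_gain(resp, f), s$time$fs)
  signal_set(vals, s$sensor_ids, s$time, "band_limited")
}

#' Reference amplitude for noise calibration
#'
#' Peak absolute amplitude of the band-limited signal received from a
#' reference sphere (default diameter 1.0 mm, p0 = 100) at the hemisphere
#' centre, observed at distance `R` (every real sensor is equidistant from
#' the centre, so one evaluation suffices).
#'
#' @param resp a [sensor_response()].
#' @param time a [time_axis()].
#' @param c sound speed, m/s.
#' @param R observation distance (hemisphere radius), mm.
#' @param p0 reference initial pressure.
#' @param diameter reference sphere diameter, mm.
#' @return scalar peak amplitude.
#' @export
reference_amplitude <- function(resp, time, c = 1500, R = 60, p0 = 100,
                                diameter = 1.0) {
  ab <- sphere_absorber(c(0, 0, 0), diameter, p0)
  s <- simulate_signals(structure(list(absorbers = list(ab), seed = NA),
                                  class = "phantom"),
                        matrix(c(0, 0, -R), nrow = 1, dimnames = list("ref")),
                        time, c)
  bl <- apply_sensor_bandwidth(s, resp)
  max(abs(bl$values))
}

#' Calibrated-noise specification
#'
#' Noise is i.i.d. zero-mean Gaussian with standard deviation
#' `reference_amplitude * 10^(-snr_db / 20)`, i.e. `snr_db` below the peak
#' band-limited amplitude of a reference absorber (`p0 = reference_p0`) at
#' the hemisphere centre.
#'
#' @param snr_db signal-to-noise ratio in dB (default 30).
#' @param reference_p0 reference absorber pressure (default 100).
#' @param rng_seed integer seed.
#' @param reference_diameter reference sphere diameter, mm.
#' @return a `noise_spec`.
#' @export
noise_spec <- function(snr_db = 30, reference_p0 = 100, rng_seed = 1L,
                       reference_diameter = 1.0) {
  structure(list(snr_db = snr_db, reference_p0 = reference_p0,
                 rng_seed = as.integer(rng_seed),
                 reference_diameter = reference_diameter),
            class = "noise_spec")
}

#' Add calibrated random noise
#'
#' @param s a `signal_set` with provenance `band_limited`.
#' @param spec a [noise_spec()].
#' @param resp the [sensor_response()] used for calibration.
#' @param R hemisphere radius (reference distance), mm.
#' @param c sound speed, m/s.
#' @return a `signal_set` with provenance `band_limited_noisy`.
#' @export
add_noise <- function(s, spec, resp, R = 60, c = 1500) {
  stopifnot(inherits(s, "signal_set"), inherits(spec, "noise_spec"))
  if (s$provenance != "band_limited")
    stop("noise is added to band_limited signals, got ", s$provenance)
  vals <- s$values
  if (is.finite(spec$snr_db)) {
    ref <- reference_amplitude(resp, s$time, c, R, spec$reference_p0,
                               spec$reference_diameter)
    sd_n <- ref * 10^(-spec$snr_db / 20)
    noise <- with_seed(spec$rng_seed,
                       matrix(rnorm(length(vals), sd = sd_n), nrow(vals)))
    vals <- vals + noise
  }
  signal_set(vals, s$sensor_ids, s$time, "band_limited_noisy")
}
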
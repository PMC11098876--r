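#' Inverse-filter configuration
#'
#' The inverse filter restores (within the usable band) the broadband signal
#' from a band-limited trace: zero-phase frequency-domain gain
#' `LPF(f) / max(H(f), 1 / gain_cap)`, where `H` is the transducer amplitude
#' response and the low-pass guard keeps high-frequency noise from being
#' amplified.  The LPF is a zero-phase Butterworth-style magnitude
#' `1 / sqrt(1 + (f / cutoff)^(2 order))`; the default order 40 gives > 60 dB
#' attenuation at 1.2x the cutoff.
#'
#' @param sensor_response a [sensor_response()].
#' @param lpf_cutoff low-pass cutoff, Hz (default 5 MHz).
#' @param gain_cap maximum amplification of the reciprocal response.
#' @param lpf_order Butterworth-magnitude order.
#' @return an `inverse_filter_config`.
#' @export
inverse_filter_config <- function(sensor_response = hemipa::sensor_response(),
                                  lpf_cutoff = 5e6, gain_cap = 100,
                                  lpf_order = 40L) {
  stopifnot(lpf_cutoff > 0, is.finite(gain_cap), gain_cap > 0)
  structure(list(sensor_response = sensor_response,
                 lpf_cutoff = lpf_cutoff, gain_cap = gain_cap,
                 lpf_order = as.integer(lpf_order)),
            class = "inverse_filter_config")
}

#' Gain of the inverse filter at given frequencies
#' @param cfg an [inverse_filter_config()].
#' @param f frequencies, Hz.
#' @return amplitude gain.
#' @export
inverse_filter_gain <- function(cfg, f) {
  lpf <- 1 / sqrt(1 + (abs(f) / cfg$lpf_cutoff)^(2 * cfg$lpf_order))
  h <- pmax(response_gain(cfg$sensor_response, f), 1 / cfg$gain_cap)
  lpf / h
}

#' Inverse-filter a signal set
#'
#' @param s a `signal_set` (band-limited, noisy, or interpolator output).
#' @param cfg an [inverse_filter_config()].
#' @return a `signal_set` with provenance `inverse_filtered`.
#' @export
inverse_filter <- function(s, cfg = inverse_filter_config()) {
  stopifnot(inherits(s, "signal_set"))
  if (!s$provenance %in% c("band_limited", "band_limited_noisy",
                           "cnn_output"))
    stop("inverse filtering applies to band-limited (or interpolated) ",
         "signals, got ", s$provenance)
  vals <- filter_rows(s$values, function(f) inverse_filter_gain(cfg, f),
                      s$time$fs)
  signal_set(vals, s$sensor_ids, s$time, "inverse_filtered")
}

#' Regular voxel grid
#'
#' @param voxel edge length, mm (device fidelity runs use 0.1 mm; 0.3-0.4 mm
#'   is adequate for scaled-down evaluation).
#' @param extents 3 x 2 matrix or list of per-axis `c(min, max)` in mm;
#'   default covers the absorber placement region, `[-12, 12]^3`.
#' @return a `voxel_grid` with axis vectors `x`, `y`, `z`.
#' @export
voxel_grid <- function(voxel = 0.1,
                       extents = list(c(-12, 12), c(-12, 12), c(-12, 12))) {
  stopifnot(voxel > 0)
  if (is.matrix(extents))
    extents <- lapply(seq_len(nrow(extents)), function(i) extents[i, ])
  stopifnot(length(extents) == 3,
            all(vapply(extents, function(e) e[2] > e[1], logical(1))))
  ax <- lapply(extents, function(e) seq(e[1], e[2], by = voxel))
  structure(list(voxel = voxel, extents = extents,
                 x = ax[[1]], y = ax[[2]], z = ax[[3]]),
            class = "voxel_grid")
}

#' Universal back-projection reconstruction
#'
#' Xu-Wang universal back-projection for a (hemi)spherical aperture: each
#' voxel accumulates the term `b(t) = 2 p(t) - 2 t dp/dt` of every sensor,
#' evaluated at the flight time `|r_voxel - r_sensor| / c` by linear
#' interpolation in sample space (the time axis honors the acquisition
#' offset), weighted by the sensor's share of the total solid angle (uniform
#' by default, element areas being unpublished).  Voxels whose flight time
#' falls outside the recorded window receive zero from that sensor.
#'
#' @param s a `signal_set` (inverse-filtered in the standard pipeline; ideal
#'   broadband in oracle tests).
#' @param sensor_coords n x 3 matrix matching the rows of `s`.
#' @param grid a [voxel_grid()].
#' @param c sound speed, m/s.
#' @param weights per-sensor solid-angle fractions (default uniform `1/n`).
#' @return a `pa_volume`: `values` (3D array, x fastest), `grid`,
#'   `n_outside` (out-of-window lookups).
#' @export
ubp_reconstruct <- function(s, sensor_coords, grid, c = 1500,
                            weights = NULL) {
  stopifnot(inherits(s, "signal_set"), inherits(grid, "voxel_grid"))
  sensor_coords <- as.matrix(sensor_coords)
  if (nrow(sensor_coords) != nrow(s$values))
    stop("sensor_coords rows must match signal rows")
  n <- nrow(s$values)
  if (is.null(weights)) weights <- rep(1 / n, n)
  b <- ubp_term(s)
  res <- ubp_backproject_cpp(b, sensor_coords, weights,
                             grid$x, grid$y, grid$z,
                             s$time$fs, s$time$offset_samples, c)
  if (res$n_outside > 0)
    message(sprintf("ubp_reconstruct: %.0f voxel-sensor flight times outside the recorded window contributed zero",
                    res$n_outside))
  vol <- array(res$values,
               dim = c(length(grid$x), length(grid$y), length(grid$z)))
  structure(list(values = vol, grid = grid, n_outside = res$n_outside),
            class = "pa_volume")
}

#' Back-projection term of a signal set
#'
#' `b(t) = 2 p(t) - 2 t dp/dt`, with the derivative by central differences
#' (one-sided at the window edges) and `t` the absolute time including the
#' acquisition offset.
#'
#' @param s a `signal_set`.
#' @return matrix of the same shape as `s$values`.
#' @export
ubp_term <- function(s) {
  p <- s$values
  n <- ncol(p)
  dp <- matrix(0, nrow(p), n)
  dp[, 2:(n - 1)] <- (p[, 3:n] - p[, 1:(n - 2)]) * (s$time$fs / 2)
  dp[, 1] <- (p[, 2] - p[, 1]) * s$time$fs
  dp[, n] <- (p[, n] - p[, n - 1]) * s$time$fs
  tt <- sample_times(s$time)
  2 * p - 2 * sweep(dp, 2, tt, `*`)
}

#' Maximum intensity projection
#'
#' @param v a `pa_volume`.
#' @param plane projection plane: `"xy"`, `"xz"` or `"yz"` (maximum taken
#'   along the omitted axis).
#' @return 2D matrix; rows follow the first named axis.
#' @export
mip <- function(v, plane = c("xy", "xz", "yz")) {
  plane <- match.arg(plane)
  axis <- switch(plane, xy = 3L, xz = 2L, yz = 1L)
  apply(v$values, setdiff(1:3, axis), max)
}

#' Write a MIP image as plain-text PGM
#'
#' 16-bit ASCII PGM (P2), a text format viewable with standard tools.
#'
#' @param img 2D matrix (e.g. from [mip()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mip_pgm <- function(img, path) {
  lo <- min(img); hi <- max(img)
  scaled <- if (hi > lo) round((img - lo) / (hi - lo) * 65535) else img * 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(nrow(scaled), ncol(scaled)), "65535"), con)
  write(scaled, file = con, ncolumns = nrow(scaled))
  invisible(path)
}
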
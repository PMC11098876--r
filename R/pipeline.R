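#' Derive a per-stage seed from a root seed
#'
#' All randomness in a pipeline run flows from one root seed; each stage gets
#' a distinct deterministic sub-seed (kept below 2^31).
#'
#' @param seed root seed.
#' @param stage small integer stage index.
#' @return integer sub-seed.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + stage * 9973) %% 2147483647)
}

#' Build the linearly interleaved patterns of every chain
#'
#' @param geometry a `pa_geometry`.
#' @param real a `signal_set` of real-sensor signals.
#' @return nested list `[[direction]][[residue]]` of `interleaved_pattern`s.
#' @export
linear_patterns <- function(geometry, real) {
  lapply(seq_along(geometry$chains), function(d) {
    out <- vector("list", geometry$intervals[d])
    for (ch in geometry$chains[[d]])
      out[[ch$residue]] <- interleave_linear(extract_pattern(ch, real))
    out
  })
}

#' Measurement pipeline: real signals to reconstructed volume
#'
#' The full processing chain applied to a measured (or simulated) real-sensor
#' signal set: extract per-chain patterns, linearly interleave, optionally
#' apply the per-direction interpolator networks, scatter into the dense
#' real + virtual signal set (real rows keep the measured signals), inverse
#' filter, and reconstruct by universal back-projection.
#'
#' @param real a `signal_set` of the real sensors (band-limited or noisy).
#' @param geometry a `pa_geometry`.
#' @param models list of per-direction `cnn_model`s, or `NULL`; with no
#'   models and `fallback = "linear"` the linear interleave is used, with
#'   `fallback = "real_only"` the dense stage is skipped entirely (a warning
#'   is issued either way).
#' @param inv_cfg an [inverse_filter_config()].
#' @param grid a [voxel_grid()].
#' @param c sound speed, m/s.
#' @param fallback behaviour without models.
#' @return a `pa_volume`.
#' @export
pipeline_measure <- function(real, geometry, models = NULL,
                             inv_cfg = inverse_filter_config(),
                             grid = voxel_grid(0.4), c = 1500,
                             fallback = c("linear", "real_only")) {
  stopifnot(inherits(real, "signal_set"), inherits(geometry, "pa_geometry"))
  fallback <- match.arg(fallback)
  miss <- setdiff(paste0("r", geometry$array$indices), real$sensor_ids)
  if (length(miss))
    stop("signal set does not cover the array geometry (missing ",
         length(miss), " sensors)")
  if (is.null(models) && fallback == "real_only") {
    warning("no interpolator checkpoints: reconstructing from real sensors only")
    filtered <- inverse_filter(real, inv_cfg)
    return(ubp_reconstruct(filtered,
                           geometry$coords[seq_along(geometry$array$indices), ],
                           grid, c))
  }
  pats <- linear_patterns(geometry, real)
  if (!is.null(models)) {
    for (d in seq_along(pats)) {
      model <- models[[d]]
      if (is.null(model)) stop("missing interpolator model for direction ", d)
      pats[[d]] <- lapply(pats[[d]], function(ip) cnn_predict(model, ip))
    }
  } else {
    warning("no interpolator checkpoints: using linear interleave for virtual sensors")
  }
  dense <- scatter_dense(pats, geometry, real)
  filtered <- inverse_filter(dense, inv_cfg)
  ubp_reconstruct(filtered, geometry$coords, grid, c)
}

#' Scaled-down reproduction of the simulation S/N experiment
#'
#' Simulates the three-cylinder evaluation phantom, reconstructs it from
#' (a) noisy 512-channel real signals, (b) noise-free ideal real signals,
#' (c) noisy real + linearly interpolated virtual signals (dense),
#' (d) noise-free ideal signals at all dense positions, and optionally
#' (e) noisy real + network-interpolated virtual signals; reports the volume
#' S/N of each plus the correlation of the linearly interpolated virtual
#' signals with the ideal ones.  S/N is evaluated on the intensity volume
#' (positive part of the back-projection output, see [volume_intensity()]).
#' `scale = "ci"` coarsens the voxels (0.4 mm) for desk-scale runs;
#' `scale = "full"` uses 0.1 mm voxels.
#'
#' @param pc a [pipeline_config()].
#' @param scale `"ci"` or `"full"`.
#' @param models optional per-direction `cnn_model` list for variant (e).
#' @param geometry optionally a prebuilt `pa_geometry` matching `pc`.
#' @return a `snr_report`: list with `snr` (named dB vector), `corr_linear`
#'   (virtual-signal correlation), `grid`, `seed`.
#' @export
run_snr_experiment <- function(pc = pipeline_config(),
                                  scale = c("ci", "full"), models = NULL,
                                  geometry = NULL) {
  scale <- match.arg(scale)
  stopifnot(inherits(pc, "pipeline_config"))
  voxel <- if (scale == "full") 0.1 else pc$voxel
  grid <- voxel_grid(voxel, pc$extents)
  if (is.null(geometry)) geometry <- build_geometry(pc$config, pc$intervals)
  phantom <- evaluation_phantom()
  inv_cfg <- inverse_filter_config(pc$resp, pc$lpf_cutoff, pc$gain_cap,
                                   pc$lpf_order)
  n_real <- length(geometry$array$indices)
  real_ids <- geometry$ids[seq_len(n_real)]
  real_coords <- geometry$coords[seq_len(n_real), ]

  ideal <- simulate_signals(phantom, geometry$coords, pc$time, pc$c,
                            sensor_ids = geometry$ids)
  ideal_bl <- apply_sensor_bandwidth(ideal, pc$resp)
  ideal_real <- subset_signals(ideal_bl, real_ids)
  noisy_real <- add_noise(ideal_real,
                          noise_spec(pc$snr_db,
                                     rng_seed = stage_seed(pc$seed, 1L)),
                          pc$resp, R = pc$config$R, c = pc$c)

  vids <- geometry$virtuals$ids
  lin <- scatter_dense(linear_patterns(geometry, noisy_real), geometry,
                       noisy_real)
  corr_linear <- pearson_corr(lin, ideal_bl, subset = vids)

  masks <- phantom_masks(phantom, grid, pc$guard)
  recon_snr <- function(s, coords) {
    vol <- ubp_reconstruct(inverse_filter(s, inv_cfg), coords, grid, pc$c)
    snr_db(volume_intensity(vol), masks)
  }
  snr <- c(
    noisy_512 = recon_snr(noisy_real, real_coords),
    ideal_512 = recon_snr(ideal_real, real_coords),
    linear_1897 = recon_snr(lin, geometry$coords),
    ideal_1897 = recon_snr(ideal_bl, geometry$coords))
  if (!is.null(models)) {
    pats <- linear_patterns(geometry, noisy_real)
    for (d in seq_along(pats))
      pats[[d]] <- lapply(pats[[d]], function(ip)
        cnn_predict(models[[d]], ip))
    cnn_dense <- scatter_dense(pats, geometry, noisy_real)
    snr <- c(snr, cnn_1897 = recon_snr(cnn_dense, geometry$coords))
  }
  structure(list(snr = snr, corr_linear = corr_linear, grid = grid,
                 seed = pc$seed, scale = scale),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat("Evaluation-phantom S/N report (", x$scale, " scale, seed ", x$seed,
      ")\n", sep = "")
  for (nm in names(x$snr))
    cat(sprintf("  %-12s %6.2f dB\n", nm, x$snr[nm]))
  cat(sprintf("  linear virtual-signal correlation: %.4f\n", x$corr_linear))
  invisible(x)
}
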
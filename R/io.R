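fmt17 <- function(x) sprintf("%.17g", x)

#' Export / import a geometry as CSV + JSON sidecar
#'
#' CSV columns: `index` (real sensor index, or position within chain for
#' virtual sensors), `kind` (`real` / `virtual`), `direction_or_0`,
#' `residue_or_0`, `x_mm`, `y_mm`, `z_mm`.  Coordinates are written with 17
#' significant digits so the round trip is bit-exact.  The sidecar
#' `<path>.json` holds the array configuration and spiral intervals.
#'
#' @param geometry a `pa_geometry`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_geometry_csv <- function(geometry, path) {
  stopifnot(inherits(geometry, "pa_geometry"))
  arr <- geometry$array
  v <- geometry$virtuals
  df <- data.frame(
    index = c(arr$indices, v$parent$position),
    kind = c(rep("real", length(arr$indices)), rep("virtual", nrow(v$coords))),
    direction_or_0 = c(rep(0L, length(arr$indices)), v$parent$direction),
    residue_or_0 = c(rep(0L, length(arr$indices)), v$parent$residue),
    x_mm = fmt17(c(arr$coords[, 1], v$coords[, 1])),
    y_mm = fmt17(c(arr$coords[, 2], v$coords[, 2])),
    z_mm = fmt17(c(arr$coords[, 3], v$coords[, 3])))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  cfg <- geometry$config
  jsonlite::write_json(
    list(R = cfg$R, n_channels = cfg$n_channels,
         omitted_indices = cfg$omitted_indices,
         appended_indices = cfg$appended_indices,
         z1 = cfg$z1, dz = cfg$dz, intervals = geometry$intervals),
    paste0(path, ".json"), auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_geometry_csv
#' @return for `read_geometry_csv`: the rebuilt `pa_geometry`, with the
#'   stored coordinates verified bit-exactly against the regenerated ones.
#' @export
read_geometry_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- array_config(R = meta$R, n_channels = meta$n_channels,
                      omitted_indices = meta$omitted_indices,
                      appended_indices = meta$appended_indices,
                      z1 = meta$z1, dz = meta$dz)
  geometry <- build_geometry(cfg, intervals = meta$intervals)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stored <- cbind(as.numeric(df$x_mm), as.numeric(df$y_mm),
                  as.numeric(df$z_mm))
  if (!identical(dim(stored), dim(unname(geometry$coords))) ||
      !all(stored == unname(geometry$coords)))
    stop("stored geometry does not match its configuration")
  geometry
}

#' Phantom JSON round trip
#'
#' @param phantom a `phantom`.
#' @param path JSON file.
#' @return `path` invisibly / the `phantom`.
#' @export
write_phantom_json <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom"))
  jsonlite::write_json(
    list(seed = phantom$seed,
         absorbers = lapply(phantom$absorbers, unclass)),
    path, auto_unbox = TRUE, digits = I(17), null = "null", na = "null")
  invisible(path)
}

#' @rdname write_phantom_json
#' @export
read_phantom_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  absorbers <- lapply(obj$absorbers, function(a) {
    if (a$type == "sphere")
      sphere_absorber(unlist(a$center), a$diameter, a$p0)
    else
      cylinder_absorber(unlist(a$center), a$diameter, a$length, a$azimuth,
                        a$elevation, a$p0)
  })
  seed <- if (is.null(obj$seed)) NA_integer_ else as.integer(obj$seed)
  structure(list(absorbers = absorbers, seed = seed), class = "phantom")
}

#' Signal container on disk (TSV + JSON sidecar)
#'
#' Plain-text container for signal sets: a TSV matrix (one row per sensor,
#' 17-significant-digit values, no header) plus a JSON sidecar `<path>.json`
#' holding sensor ids, the time axis (`fs`, `n_samples`, `offset_samples`),
#' provenance and a layout version tag.  Round-trips bit-exactly.
#'
#' @param s a `signal_set`.
#' @param path TSV output path.
#' @return `path` invisibly / the `signal_set`.
#' @export
write_signals <- function(s, path) {
  stopifnot(inherits(s, "signal_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(s$values, 1, function(r) paste(fmt17(r), collapse = "\t")),
             con)
  jsonlite::write_json(
    list(layout_version = 1L, sensor_ids = s$sensor_ids,
         fs = s$time$fs, n_samples = s$time$n_samples,
         offset_samples = s$time$offset_samples, provenance = s$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_signals
#' @export
read_signals <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(path, sep = "\t",
                                      colClasses = "numeric"))
  dimnames(vals) <- NULL
  signal_set(vals, meta$sensor_ids,
             time_axis(meta$fs, meta$n_samples, meta$offset_samples),
             meta$provenance)
}

#' Pipeline configuration round trip
#'
#' A pipeline configuration bundles the array geometry parameters, time axis,
#' transducer response, noise, inverse filter and reconstruction grid into
#' one JSON-serializable object, so a run can be reproduced from its
#' manifest.
#'
#' @param config an `array_config`.
#' @param intervals spiral intervals.
#' @param time a [time_axis()].
#' @param resp a [sensor_response()].
#' @param snr_db noise level, dB.
#' @param c sound speed, m/s.
#' @param voxel,extents reconstruction grid parameters.
#' @param guard background guard distance, mm.
#' @param lpf_cutoff,gain_cap,lpf_order inverse-filter parameters.
#' @param seed root seed; per-stage seeds are derived from it.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(config = device_config(),
                            intervals = DEVICE_INTERVALS,
                            time = time_axis(), resp = sensor_response(),
                            snr_db = 30, c = 1500, voxel = 0.4,
                            extents = list(c(-12, 12), c(-12, 12),
                                           c(-12, 12)),
                            guard = 2, lpf_cutoff = 5e6, gain_cap = 100,
                            lpf_order = 40L, seed = 1L) {
  structure(list(config = config, intervals = as.integer(intervals),
                 time = time, resp = resp, snr_db = snr_db, c = c,
                 voxel = voxel, extents = extents, guard = guard,
                 lpf_cutoff = lpf_cutoff, gain_cap = gain_cap,
                 lpf_order = as.integer(lpf_order), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param pc a `pipeline_config`.
#' @param path JSON file.
#' @export
write_pipeline_config <- function(pc, path) {
  stopifnot(inherits(pc, "pipeline_config"))
  jsonlite::write_json(
    list(array = unclass(pc$config)[c("R", "n_channels", "omitted_indices",
                                      "appended_indices", "z1", "dz")],
         intervals = pc$intervals,
         time = unclass(pc$time), resp = unclass(pc$resp)[c("fc", "rel_bw")],
         snr_db = pc$snr_db, c = pc$c, voxel = pc$voxel,
         extents = pc$extents, guard = pc$guard,
         lpf_cutoff = pc$lpf_cutoff, gain_cap = pc$gain_cap,
         lpf_order = pc$lpf_order, seed = pc$seed),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    config = array_config(R = o$array$R, n_channels = o$array$n_channels,
                          omitted_indices = o$array$omitted_indices,
                          appended_indices = o$array$appended_indices,
                          z1 = o$array$z1, dz = o$array$dz),
    intervals = o$intervals,
    time = time_axis(o$time$fs, o$time$n_samples, o$time$offset_samples),
    resp = sensor_response(o$resp$fc, o$resp$rel_bw),
    snr_db = o$snr_db, c = o$c, voxel = o$voxel,
    extents = lapply(seq_len(nrow(o$extents)), function(i) o$extents[i, ]),
    guard = o$guard, lpf_cutoff = o$lpf_cutoff, gain_cap = o$gain_cap,
    lpf_order = o$lpf_order, seed = o$seed)
}
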
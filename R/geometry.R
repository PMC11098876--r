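#' Hemispherical Fibonacci array configuration
#'
#' Describes a golden-ratio/Fibonacci hemispherical sensor lattice.  Sensor
#' `i` sits at azimuth `2*pi*i/G` (G the golden ratio) and height
#' `z_i = z1 + (i - 1) * dz`, on the sphere of radius `R`
#' (`r_i = sqrt(R^2 - z_i^2)`).  Real devices drill holes for the laser and
#' for water supply, so some nominal indices carry no sensor
#' (`omitted_indices`) and replacement sensors are appended past the nominal
#' count (`appended_indices`).
#'
#' `z1` and `dz` are device calibration values.  The defaults span the
#' hemisphere uniformly from near the pole (`z1 = -0.99 R`, leaving room for
#' the illumination hole) to near the equator (`-0.05 R` at the largest
#' index); all integer chain/count properties are independent of this choice.
#'
#' @param R hemisphere radius in mm.
#' @param n_channels number of physical sensors.
#' @param omitted_indices integer indices with no sensor.
#' @param appended_indices extra indices appended past the nominal count; must
#'   have the same length as `omitted_indices` so the channel count is kept.
#' @param z1 z-coordinate (mm, negative) of the first sensor.
#' @param dz z-spacing in mm (positive).
#' @return an object of class `array_config`.
#' @export
array_config <- function(R = 60, n_channels = 512,
                         omitted_indices = c(7L, 20L),
                         appended_indices = c(513L, 514L),
                         z1 = -0.99 * R, dz = NULL) {
  omitted_indices <- as.integer(omitted_indices)
  appended_indices <- as.integer(appended_indices)
  if (length(omitted_indices) != length(appended_indices))
    stop("omitted_indices and appended_indices must have equal length ",
         "(total sensor count must be preserved)")
  i_max <- if (length(appended_indices)) max(appended_indices) else n_channels
  if (is.null(dz)) dz <- (-0.05 * R - z1) / max(i_max - 1L, 1L)
  if (z1 >= 0) stop("z1 must be negative (array below the equatorial plane)")
  if (dz <= 0) stop("dz must be positive")
  if (z1 + (i_max - 1) * dz >= 0)
    stop("largest-index sensor would sit at or above the equatorial plane")
  if (abs(z1) > R) stop("z1 is below the pole of the hemisphere")
  structure(list(R = R, n_channels = as.integer(n_channels),
                 omitted_indices = omitted_indices,
                 appended_indices = appended_indices,
                 z1 = z1, dz = dz, G = (1 + sqrt(5)) / 2),
            class = "array_config")
}

#' Configuration of the 512-channel reference device
#'
#' The 512-channel hemispherical array (radius ~60 mm) with no sensors at
#' nominal indices 7 and 20 (water-handling hole) and replacements at 513 and
#' 514.
#'
#' @param ... overrides passed to [array_config()].
#' @return an `array_config`.
#' @export
device_config <- function(...) array_config(...)

#' Sensor index set of a configuration
#' @param config an `array_config`.
#' @return increasing integer vector of populated sensor indices.
#' @export
sensor_indices <- function(config) {
  idx <- c(seq_len(config$n_channels), config$appended_indices)
  sort(unique(setdiff(idx, config$omitted_indices)))
}

#' Fibonacci-lattice sensor coordinates
#'
#' Computes the 3D coordinates of every populated sensor index:
#' `x_i = r_i cos(2 pi i / G)`, `y_i = r_i sin(2 pi i / G)`,
#' `z_i = z1 + (i - 1) dz`, `r_i = sqrt(R^2 - z_i^2)`.
#'
#' @param config an [array_config()].
#' @return a `sensor_array`: list with `indices`, `coords` (n x 3 matrix,
#'   mm, columns x/y/z) and `config`.
#' @export
fibonacci_coordinates <- function(config) {
  stopifnot(inherits(config, "array_config"))
  idx <- sensor_indices(config)
  if (length(idx) != config$n_channels)
    stop("index set size ", length(idx), " does not match n_channels ",
         config$n_channels)
  z <- config$z1 + (idx - 1) * config$dz
  if (any(z >= 0)) stop("sensor z-coordinate at or above the equatorial plane")
  if (any(abs(z) > config$R)) stop("sensor z-coordinate beyond the hemisphere")
  r <- sqrt(config$R^2 - z^2)
  phi <- 2 * pi * idx / config$G
  coords <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  rownames(coords) <- idx
  structure(list(indices = idx, coords = coords, config = config),
            class = "sensor_array")
}

#' Default spiral-direction intervals
#'
#' Fibonacci-lattice points form visible spiral families at Fibonacci index
#' intervals.  For the 512-channel device the three usable families are at
#' intervals 34 (direction 1, shortest inter-sensor distance), 21
#' (direction 2) and 13 (direction 3).
#' @export
DEVICE_INTERVALS <- c(34L, 21L, 13L)

#' Extract the spiral chains of one direction
#'
#' A spiral chain is one residue class of sensor indices modulo the
#' direction's Fibonacci interval, ordered by increasing index (hemisphere
#' bottom toward the periphery).  The chains of one direction partition the
#' sensor set.
#'
#' @param array a `sensor_array`.
#' @param direction 1, 2 or 3.
#' @param intervals interval per direction (device default `c(34, 21, 13)`).
#' @return list of `spiral_chain` objects (one per residue class `1..interval`);
#'   each has `direction`, `interval`, `residue`, `member_indices`.
#' @export
extract_spiral_chains <- function(array, direction,
                                  intervals = DEVICE_INTERVALS) {
  stopifnot(inherits(array, "sensor_array"))
  if (!direction %in% seq_along(intervals))
    stop("direction must be one of 1..", length(intervals))
  k <- as.integer(intervals[direction])
  lapply(seq_len(k), function(res) {
    members <- array$indices[(array$indices - res) %% k == 0L]
    structure(list(direction = as.integer(direction), interval = k,
                   residue = as.integer(res),
                   member_indices = sort(members)),
              class = "spiral_chain")
  })
}

#' Truncate chains of one direction to the common minimum length
#'
#' The interpolator input size per direction is fixed by the shortest chain,
#' so every chain is truncated to the direction's minimum length by keeping
#' its lowest-index (innermost) members; the most peripheral sensors of the
#' longer chains lose their virtual neighbours.
#'
#' @param chains list of `spiral_chain` from one direction.
#' @return list of chains, all of equal (minimum) length.
#' @export
truncate_chains <- function(chains) {
  dirs <- vapply(chains, function(ch) ch$direction, integer(1))
  if (length(unique(dirs)) != 1L)
    stop("all chains must come from a single direction")
  m <- min(vapply(chains, function(ch) length(ch$member_indices), integer(1)))
  lapply(chains, function(ch) {
    ch$member_indices <- ch$member_indices[seq_len(m)]
    ch
  })
}

#' Place virtual sensors along truncated chains
#'
#' For each chain a natural cubic spline is fit through the member
#' coordinates parameterized by member ordinal; a virtual sensor is evaluated
#' at each half-ordinal (the centre between adjacent real sensors) and
#' radially renormalized onto the sphere of radius `R` (the spline midpoint
#' falls slightly inside the chord).  Virtual sensors from different
#' directions are kept distinct even where they nearly coincide.
#'
#' @param chains_by_direction list (per direction) of truncated chain lists.
#' @param array the `sensor_array` the chains index into.
#' @return a `virtual_sensor_set`: `coords` (n x 3), `parent` data.frame with
#'   columns direction/residue/position, and `ids` (character).
#' @export
place_virtual_sensors <- function(chains_by_direction, array) {
  stopifnot(inherits(array, "sensor_array"))
  R <- array$config$R
  coords <- list(); parent <- list()
  for (chains in chains_by_direction) {
    for (ch in chains) {
      m <- length(ch$member_indices)
      if (m < 3)
        stop("chain (direction ", ch$direction, ", residue ", ch$residue,
             ") has only ", m, " sensors; cubic spline placement needs >= 3")
      xyz <- array$coords[as.character(ch$member_indices), , drop = FALSE]
      tt <- seq_len(m)
      tv <- tt[-m] + 0.5
      v <- vapply(1:3, function(d) {
        splinefun(tt, xyz[, d], method = "natural")(tv)
      }, numeric(m - 1))
      v <- matrix(v, nrow = m - 1)
      v <- v * (R / sqrt(rowSums(v^2)))
      coords[[length(coords) + 1L]] <- v
      parent[[length(parent) + 1L]] <-
        data.frame(direction = ch$direction, residue = ch$residue,
                   position = seq_len(m - 1))
    }
  }
  coords <- do.call(rbind, coords)
  parent <- do.call(rbind, parent)
  ids <- sprintf("v%d.%d.%d", parent$direction, parent$residue,
                 parent$position)
  if (anyDuplicated(ids)) stop("duplicate virtual sensor identity")
  rownames(coords) <- ids
  colnames(coords) <- c("x", "y", "z")
  structure(list(coords = coords, parent = parent, ids = ids),
            class = "virtual_sensor_set")
}

#' Build the full real + virtual geometry
#'
#' Convenience wrapper: Fibonacci coordinates, spiral chains for every
#' direction, truncation, and virtual sensor placement.  For the 512-channel
#' device this yields 512 real + 1385 virtual = 1897 sensors.
#'
#' @param config an [array_config()].
#' @param intervals spiral intervals per direction.
#' @return a `pa_geometry`: `array`, `chains` (list per direction of truncated
#'   chains), `virtuals`, `coords` (real rows first, then virtual), `ids`
#'   (real ids `"r<i>"`, virtual ids `"v<dir>.<res>.<pos>"`), `intervals`.
#' @export
build_geometry <- function(config = device_config(),
                           intervals = DEVICE_INTERVALS) {
  array <- fibonacci_coordinates(config)
  chains <- lapply(seq_along(intervals), function(d)
    truncate_chains(extract_spiral_chains(array, d, intervals)))
  virtuals <- place_virtual_sensors(chains, array)
  real_ids <- paste0("r", array$indices)
  coords <- rbind(array$coords, virtuals$coords)
  rownames(coords) <- c(real_ids, virtuals$ids)
  structure(list(config = config, intervals = as.integer(intervals),
                 array = array, chains = chains, virtuals = virtuals,
                 coords = coords, ids = c(real_ids, virtuals$ids)),
            class = "pa_geometry")
}

#' @export
print.pa_geometry <- function(x, ...) {
  cat("Hemispherical array geometry\n",
      "  radius: ", x$config$R, " mm\n",
      "  real sensors: ", length(x$array$indices), "\n",
      "  spiral intervals: ", paste(x$intervals, collapse = "/"), "\n",
      "  truncated chain lengths: ",
      paste(vapply(x$chains, function(cs)
        length(cs[[1]]$member_indices), integer(1)), collapse = "/"), "\n",
      "  virtual sensors: ", length(x$virtuals$ids), "\n",
      "  total dense sensors: ", length(x$ids), "\n", sep = "")
  invisible(x)
}
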
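#' Absorber / background voxel masks for a phantom
#'
#' Signal mask: voxels inside any absorber.  Background mask: voxels farther
#' than `guard` from every absorber surface (still inside the grid).  The
#' guard band keeps the blurred absorber rim out of the noise estimate.
#'
#' @param phantom a `phantom`.
#' @param grid a [voxel_grid()].
#' @param guard guard distance, mm (default 2).
#' @return a `mask_pair` of logical 3D arrays `signal_mask`,
#'   `background_mask` (disjoint, both non-empty).
#' @export
phantom_masks <- function(phantom, grid, guard = 2) {
  stopifnot(inherits(phantom, "phantom"), inherits(grid, "voxel_grid"))
  nx <- length(grid$x); ny <- length(grid$y); nz <- length(grid$z)
  gx <- rep(grid$x, times = ny * nz)
  gy <- rep(rep(grid$y, each = nx), times = nz)
  gz <- rep(grid$z, each = nx * ny)
  inside <- logical(nx * ny * nz)
  far <- !logical(nx * ny * nz)
  for (ab in phantom$absorbers) {
    a <- ab$diameter / 2
    if (ab$type == "sphere") {
      d <- sqrt((gx - ab$center[1])^2 + (gy - ab$center[2])^2 +
                  (gz - ab$center[3])^2)
      surf <- d - a                       # signed distance to the surface
    } else {
      u <- cylinder_axis(ab)
      rx <- gx - ab$center[1]; ry <- gy - ab$center[2]; rz <- gz - ab$center[3]
      ax <- rx * u[1] + ry * u[2] + rz * u[3]
      rad2 <- pmax(rx^2 + ry^2 + rz^2 - ax^2, 0)
      dr <- sqrt(rad2) - a                # radial excess
      dax <- abs(ax) - ab$length / 2      # axial excess
      surf <- ifelse(dr <= 0 & dax <= 0, pmax(dr, dax),
                     sqrt(pmax(dr, 0)^2 + pmax(dax, 0)^2))
    }
    inside <- inside | (surf <= 0)
    far <- far & (surf > guard)
  }
  if (!any(inside))
    stop("signal mask is empty: no voxel falls inside an absorber")
  if (!any(far))
    stop("background mask is empty: guard band covers the whole grid")
  dims <- c(nx, ny, nz)
  structure(list(signal_mask = array(inside, dims),
                 background_mask = array(far, dims)),
            class = "mask_pair")
}

#' Volume signal-to-noise ratio
#'
#' `20 log10( mean(v[signal]) / sd(v[background]) )`: mean reconstructed
#' intensity inside the absorbers over the standard deviation of the
#' background (electrical noise plus reconstruction artifacts).  Invariant to
#' positive rescaling of the volume.
#'
#' @param v a `pa_volume`.
#' @param masks a `mask_pair` built on the same grid.
#' @return S/N in dB.
#' @export
snr_db <- function(v, masks) {
  stopifnot(inherits(v, "pa_volume"), inherits(masks, "mask_pair"))
  if (!all(dim(v$values) == dim(masks$signal_mask)))
    stop("masks were built for a different grid")
  noise <- sd(v$values[masks$background_mask])
  if (noise == 0) stop("background standard deviation is zero")
  20 * log10(mean(v$values[masks$signal_mask]) / noise)
}

#' Intensity volume of a reconstruction
#'
#' Reconstructed initial pressure is physically non-negative; universal
#' back-projection nevertheless returns signed values whose negative part is
#' residue of the back-projection kernel.  The intensity volume — what a
#' photoacoustic system displays and what image statistics are computed on —
#' is the positive part (optionally the absolute value).
#'
#' @param v a `pa_volume`.
#' @param mode `"positive"` (clamp negatives to zero) or `"abs"`.
#' @return a `pa_volume` with transformed values.
#' @export
volume_intensity <- function(v, mode = c("positive", "abs")) {
  stopifnot(inherits(v, "pa_volume"))
  mode <- match.arg(mode)
  v$values <- if (mode == "positive") pmax(v$values, 0) else abs(v$values)
  v
}

#' Pearson correlation between two signal sets
#'
#' Flattens the selected rows of both sets into one vector each and returns
#' their Pearson correlation; the global fidelity measure for estimated
#' virtual-sensor signals against the noise-free ideal ones.
#'
#' @param a,b `signal_set`s on the same time axis.
#' @param subset sensor ids to compare (default: all of `a`).
#' @return correlation coefficient.
#' @export
pearson_corr <- function(a, b, subset = a$sensor_ids) {
  stopifnot(inherits(a, "signal_set"), inherits(b, "signal_set"))
  if (a$time$n_samples != b$time$n_samples)
    stop("signal sets have different time axes")
  va <- as.numeric(subset_signals(a, subset)$values)
  vb <- as.numeric(subset_signals(b, subset)$values)
  if (sd(va) == 0 || sd(vb) == 0)
    stop("correlation undefined for a constant signal set")
  cor(va, vb)
}
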
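#' Absorber constructors
#'
#' A phantom is an ordered list of simple optical absorbers: uniform spheres
#' and uniform right cylinders, each carrying an initial sound pressure `p0`
#' (arbitrary units).  Cylinder orientation is given by `azimuth` (angle of
#' the axis projection in the x-y plane, degrees from the x axis) and
#' `elevation` (angle of the axis with the x-y plane, degrees).
#'
#' @param center 3-vector, mm.
#' @param diameter diameter in mm (> 0).
#' @param p0 initial sound pressure, arbitrary units (> 0).
#' @param length cylinder length, mm (> 0).
#' @param azimuth,elevation cylinder axis orientation, degrees.
#' @return an absorber object (class `sphere_absorber` / `cylinder_absorber`).
#' @export
sphere_absorber <- function(center, diameter, p0) {
  stopifnot(length(center) == 3, diameter > 0, p0 > 0)
  structure(list(type = "sphere", center = as.numeric(center),
                 diameter = diameter, p0 = p0),
            class = c("sphere_absorber", "absorber"))
}

#' @rdname sphere_absorber
#' @export
cylinder_absorber <- function(center, diameter, length, azimuth, elevation,
                              p0) {
  stopifnot(length(center) == 3, diameter > 0, length > 0, p0 > 0,
            azimuth >= -180, azimuth <= 180)
  structure(list(type = "cylinder", center = as.numeric(center),
                 diameter = diameter, length = length,
                 azimuth = azimuth, elevation = elevation, p0 = p0),
            class = c("cylinder_absorber", "absorber"))
}

#' Unit axis vector of a cylinder
#' @param ab a `cylinder_absorber`.
#' @return unit 3-vector.
#' @export
cylinder_axis <- function(ab) {
  a <- ab$azimuth * pi / 180
  e <- ab$elevation * pi / 180
  c(cos(e) * cos(a), cos(e) * sin(a), sin(e))
}

#' Training-phantom sampling ranges
#'
#' Ranges of the randomized training phantoms: per class (spheres, short
#' cylinders, long cylinders) a count drawn uniformly from `count`, and
#' uniform draws of diameter, p0, centre (uniform in the ball of
#' `placement_radius`) and, for cylinders, length, azimuth and elevation.
#' Defaults are the reference device's training conditions.  Set a class's
#' `count` to `0:0` to drop it (used by reduced-scale tests).
#'
#' @param placement_radius absorber centres fall within this distance (mm)
#'   of the hemisphere centre.
#' @param sphere,short_cylinder,long_cylinder per-class range lists.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(placement_radius = 10,
                         sphere = list(count = 1:4, diameter = c(0.2, 1.2),
                                       p0 = c(50, 100)),
                         short_cylinder = list(count = 1:4,
                                               diameter = c(0.2, 1.2),
                                               length = c(10, 20),
                                               p0 = c(50, 100),
                                               azimuth = c(-180, 180),
                                               elevation = c(-70, 70)),
                         long_cylinder = list(count = 1:4,
                                              diameter = c(0.2, 1.2),
                                              length = c(50, 50),
                                              p0 = c(50, 100),
                                              azimuth = c(-180, 180),
                                              elevation = c(-5, 5))) {
  structure(list(placement_radius = placement_radius, sphere = sphere,
                 short_cylinder = short_cylinder,
                 long_cylinder = long_cylinder),
            class = "phantom_spec")
}

runif1 <- function(range) runif(1, range[1], range[2])

rand_center <- function(radius) {
  # uniform in the ball of given radius
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2))
  u * radius * runif(1)^(1 / 3)
}

#' Random training phantom
#'
#' Draws one random phantom: independently for each absorber class, a count
#' uniform on its `count` range, then uniform parameters from the class
#' ranges.  Deterministic given `rng_seed` (the phantom records its seed).
#' Absorbers may overlap; pressures superpose.
#'
#' @param rng_seed integer seed.
#' @param spec a [phantom_spec()].
#' @return a `phantom`: list with `absorbers` and `seed`.
#' @export
random_training_phantom <- function(rng_seed, spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  absorbers <- with_seed(rng_seed, {
    out <- list()
    n_sph <- sample_count(spec$sphere$count)
    for (i in seq_len(n_sph)) {
      out[[length(out) + 1L]] <- sphere_absorber(
        center = rand_center(spec$placement_radius),
        diameter = runif1(spec$sphere$diameter),
        p0 = runif1(spec$sphere$p0))
    }
    for (cls in list(spec$short_cylinder, spec$long_cylinder)) {
      n <- sample_count(cls$count)
      for (i in seq_len(n)) {
        out[[length(out) + 1L]] <- cylinder_absorber(
          center = rand_center(spec$placement_radius),
          diameter = runif1(cls$diameter),
          length = runif1(cls$length),
          azimuth = runif1(cls$azimuth),
          elevation = runif1(cls$elevation),
          p0 = runif1(cls$p0))
      }
    }
    out
  })
  structure(list(absorbers = absorbers, seed = as.integer(rng_seed)),
            class = "phantom")
}

sample_count <- function(count_range) {
  if (length(count_range) == 1L) return(as.integer(count_range))
  count_range[sample.int(length(count_range), 1L)]
}

# run code with a local RNG state, restoring the caller's state afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' The fixed three-cylinder evaluation phantom
#'
#' Three cylinders (diameter 1.0 mm, length 50 mm, p0 = 100 arbitrary units)
#' parallel to the y axis, centred at (0, -5, -5), (0, 0, 0) and (0, 5, 5) mm.
#'
#' @return a `phantom`.
#' @export
evaluation_phantom <- function() {
  mk <- function(center) cylinder_absorber(center, diameter = 1.0,
                                           length = 50, azimuth = 90,
                                           elevation = 0, p0 = 100)
  structure(list(absorbers = list(mk(c(0, -5, -5)), mk(c(0, 0, 0)),
                                  mk(c(0, 5, 5))),
                 seed = NA_integer_),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  types <- vapply(x$absorbers, function(a) a$type, character(1))
  cat("Phantom with ", length(types), " absorbers (",
      sum(types == "sphere"), " spheres, ", sum(types == "cylinder"),
      " cylinders), seed ", x$seed, "\n", sep = "")
  invisible(x)
}
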
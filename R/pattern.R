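#' Extract the chain-ordered signal pattern of one spiral chain
#'
#' Gathers the rows of a signal set in chain member order (lowest index,
#' hemisphere bottom, first).  Along a chain the traces vary smoothly, which
#' is what makes per-chain interpolation of virtual-sensor signals possible.
#'
#' @param chain a `spiral_chain`.
#' @param s a `signal_set` containing every chain member (real ids `"r<i>"`).
#' @return a `pattern`: `values` (m x n_samples), `chain_ref`
#'   (direction, residue), `row_kind = "real"`.
#' @export
extract_pattern <- function(chain, s) {
  stopifnot(inherits(chain, "spiral_chain"), inherits(s, "signal_set"))
  ids <- paste0("r", chain$member_indices)
  miss <- setdiff(ids, s$sensor_ids)
  if (length(miss))
    stop("chain (direction ", chain$direction, ", residue ", chain$residue,
         "): sensors missing from signal set: ",
         paste(miss, collapse = ", "))
  structure(list(values = s$values[ids, , drop = FALSE],
                 chain_ref = c(direction = chain$direction,
                               residue = chain$residue),
                 row_kind = "real"),
            class = "pattern")
}

#' Linearly interleave virtual rows into a pattern
#'
#' Between each pair of adjacent real rows inserts their sample-wise
#' arithmetic mean, giving a (2m - 1)-row image whose odd rows (1, 3, ...)
#' are the real rows.  This is the interpolator network's input; on its own
#' it is also the classical linear-interpolation baseline.
#'
#' @param p a `pattern` with at least 2 rows.
#' @return an `interleaved_pattern` with `row_kind = "interleaved"`.
#' @export
interleave_linear <- function(p) {
  stopifnot(inherits(p, "pattern") || inherits(p, "interleaved_pattern"))
  v <- p$values
  m <- nrow(v)
  if (m < 2) stop("interleaving needs at least 2 rows")
  out <- matrix(0, 2 * m - 1, ncol(v))
  out[seq(1, 2 * m - 1, by = 2), ] <- v
  out[seq(2, 2 * m - 2, by = 2), ] <- (v[-m, , drop = FALSE] +
                                         v[-1, , drop = FALSE]) / 2
  structure(list(values = out, chain_ref = p$chain_ref,
                 row_kind = "interleaved"),
            class = "interleaved_pattern")
}

#' Virtual-row indices of an interleaved pattern
#' @param ip an `interleaved_pattern`.
#' @return integer vector of the inserted (virtual) row numbers.
#' @export
virtual_rows <- function(ip) seq(2, nrow(ip$values) - 1, by = 2)

#' Scatter interleaved patterns into a dense real + virtual signal set
#'
#' Routes the virtual rows of every chain's interleaved pattern to their
#' virtual-sensor identities and fills the real-sensor rows from the original
#' measured/simulated signals (the estimated real rows are smoothed copies;
#' by default the measurement itself is kept).  Output rows follow the
#' geometry's dense ordering (all real sensors, then all virtual sensors).
#'
#' @param patterns nested list: `patterns[[direction]][[residue]]` is the
#'   chain's `interleaved_pattern`.
#' @param geometry a `pa_geometry`.
#' @param real a `signal_set` holding the real-sensor signals.
#' @param use_estimated_real if `TRUE`, take real rows from the patterns
#'   (e.g. network-denoised) instead of from `real`; rows covered by several
#'   chains are averaged over directions.
#' @return a `signal_set` over all dense sensors, provenance of `real`.
#' @export
scatter_dense <- function(patterns, geometry, real,
                          use_estimated_real = FALSE) {
  stopifnot(inherits(geometry, "pa_geometry"), inherits(real, "signal_set"))
  n_real <- length(geometry$array$indices)
  nv <- length(geometry$virtuals$ids)
  vals <- matrix(0, n_real + nv, real$time$n_samples)
  ids <- geometry$ids
  real_ids <- ids[seq_len(n_real)]
  vals[seq_len(n_real), ] <- subset_signals(real, real_ids)$values
  seen <- logical(nv)
  vmap <- geometry$virtuals$parent
  vkey <- sprintf("v%d.%d.%d", vmap$direction, vmap$residue, vmap$position)
  row_of <- match(vkey, geometry$virtuals$ids)
  if (use_estimated_real) {
    acc <- matrix(0, n_real, real$time$n_samples)
    cnt <- numeric(n_real)
  }
  for (d in seq_along(geometry$chains)) {
    chains <- geometry$chains[[d]]
    if (length(patterns) < d || is.null(patterns[[d]]))
      stop("missing patterns for direction ", d)
    for (ch in chains) {
      ip <- if (ch$residue <= length(patterns[[d]]))
        patterns[[d]][[ch$residue]] else NULL
      if (is.null(ip))
        stop("missing pattern for direction ", d, ", residue ", ch$residue)
      m <- length(ch$member_indices)
      if (nrow(ip$values) != 2 * m - 1)
        stop("pattern for direction ", d, ", residue ", ch$residue,
             " has ", nrow(ip$values), " rows, expected ", 2 * m - 1)
      vsel <- which(vmap$direction == d & vmap$residue == ch$residue)
      vsel <- vsel[order(vmap$position[vsel])]
      if (length(vsel) != m - 1)
        stop("virtual identity mismatch for direction ", d, ", residue ",
             ch$residue)
      rows <- n_real + row_of[vsel]
      if (any(seen[row_of[vsel]]))
        stop("duplicate virtual identity for direction ", d, ", residue ",
             ch$residue)
      seen[row_of[vsel]] <- TRUE
      vals[rows, ] <- ip$values[virtual_rows(ip), , drop = FALSE]
      if (use_estimated_real) {
        ridx <- match(paste0("r", ch$member_indices), real_ids)
        acc[ridx, ] <- acc[ridx, ] + ip$values[seq(1, 2 * m - 1, 2), ,
                                               drop = FALSE]
        cnt[ridx] <- cnt[ridx] + 1
      }
    }
  }
  if (!all(seen)) stop(sum(!seen), " virtual sensors received no signal")
  if (use_estimated_real) {
    filled <- cnt > 0
    vals[which(filled), ] <- acc[filled, , drop = FALSE] / cnt[filled]
  }
  signal_set(vals, ids, real$time, real$provenance)
}

#' Extract, per chain, the patterns of a whole direction
#'
#' @param geometry a `pa_geometry`.
#' @param s a `signal_set` of real sensors.
#' @param direction direction index.
#' @return list over residues of `pattern` objects.
#' @export
direction_patterns <- function(geometry, s, direction) {
  lapply(geometry$chains[[direction]], function(ch) extract_pattern(ch, s))
}
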
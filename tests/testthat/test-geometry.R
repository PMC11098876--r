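test_that("fibonacci coordinates satisfy the lattice equations", {
  geo <- device_geo()
  arr <- geo$array
  R <- arr$config$R

  expect_length(arr$indices, 512L)
  expect_identical(arr$indices, setdiff(1:514, c(7L, 20L)))

  # every sensor on the sphere of radius R (r_i = sqrt(R^2 - z_i^2) identity)
  expect_lt(max(abs(sqrt(rowSums(arr$coords^2)) - R)), 1e-9 * R)
  # strictly below the equatorial plane, indices strictly increasing
  expect_true(all(arr$coords[, "z"] < 0))
  expect_true(all(diff(arr$indices) > 0))

  # consecutive indices differ in azimuth by exactly 2*pi/G (mod 2*pi)
  G <- arr$config$G
  phi <- atan2(arr$coords[, "y"], arr$coords[, "x"])
  consec <- which(diff(arr$indices) == 1L)
  dphi <- (phi[consec + 1L] - phi[consec]) %% (2 * pi)
  expect_lt(max(abs(dphi - (2 * pi / G) %% (2 * pi))), 1e-8)

  # determinism: identical config -> bit-identical coordinates
  again <- fibonacci_coordinates(device_config())
  expect_identical(again$coords, arr$coords)
})

test_that("invalid array configurations are rejected", {
  expect_error(array_config(omitted_indices = c(7L),
                            appended_indices = c(513L, 514L)),
               "equal length")
  expect_error(array_config(z1 = 0.5 * 60), "negative")
  # sensor pushed to/above the equator
  expect_error(array_config(R = 60, n_channels = 8,
                            omitted_indices = integer(0),
                            appended_indices = integer(0),
                            z1 = -10, dz = 2), "equatorial")
})

test_that("spiral chains partition the array and match the residue oracle", {
  geo <- device_geo()
  arr <- geo$array
  for (d in 1:3) {
    k <- DEVICE_INTERVALS[d]
    chains <- extract_spiral_chains(arr, d)
    expect_length(chains, k)
    lens <- vapply(chains, function(ch) length(ch$member_indices), integer(1))

    # brute-force residue-class counting oracle
    expect_identical(lens, chain_length_oracle(k))
    expect_identical(sum(lens), 512L)

    # disjoint union = index set
    all_members <- sort(unlist(lapply(chains, `[[`, "member_indices")))
    expect_identical(all_members, arr$indices)

    # members congruent to residue; constant stride for the device
    for (ch in chains) {
      expect_true(all(ch$member_indices %% ch$interval ==
                        ch$residue %% ch$interval))
      expect_true(all(diff(ch$member_indices) == ch$interval))
    }
  }
  # direction minima: 14 (interval 34), 23 (21), 38 (13)
  minima <- vapply(1:3, function(d) min(chain_length_oracle(DEVICE_INTERVALS[d])),
                   integer(1))
  expect_identical(minima, c(14L, 23L, 38L))
  expect_error(extract_spiral_chains(arr, 4), "direction")
})

test_that("truncation keeps the innermost members of every chain", {
  arr <- device_geo()$array
  for (d in 1:3) {
    raw <- extract_spiral_chains(arr, d)
    tr <- truncate_chains(raw)
    m <- min(vapply(raw, function(ch) length(ch$member_indices), integer(1)))
    for (i in seq_along(raw)) {
      expect_length(tr[[i]]$member_indices, m)
      # discarded members are exactly the highest-index (peripheral) sensors
      expect_identical(tr[[i]]$member_indices,
                       sort(raw[[i]]$member_indices)[seq_len(m)])
    }
    # chain already at minimum length returned unchanged
    shortest <- which.min(vapply(raw, function(ch)
      length(ch$member_indices), integer(1)))
    expect_identical(tr[[shortest]], raw[[shortest]])
  }
  mixed <- c(extract_spiral_chains(arr, 1)[1], extract_spiral_chains(arr, 2)[1])
  expect_error(truncate_chains(mixed), "single direction")
})

test_that("virtual sensors: counts, sphere membership, midpoint property", {
  geo <- device_geo()
  v <- geo$virtuals
  # 34*13 + 21*22 + 13*37 = 1385 virtual, 512 + 1385 = 1897 total
  expect_identical(nrow(v$coords), 1385L)
  expect_identical(length(geo$ids), 1897L)
  counts <- table(v$parent$direction)
  expect_identical(as.integer(counts), c(34L * 13L, 21L * 22L, 13L * 37L))

  R <- geo$config$R
  expect_lt(max(abs(sqrt(rowSums(v$coords^2)) - R)), 1e-6 * R)

  # each virtual sensor attributed to exactly one chain of one direction
  expect_false(anyDuplicated(v$ids) > 0)

  # midpoint property: virtual closer to each parent than parents are to
  # each other (10% slack for spline curvature)
  arr <- geo$array
  for (d in 1:3) {
    for (ch in geo$chains[[d]][c(1, 7)]) {
      members <- arr$coords[as.character(ch$member_indices), ]
      m <- nrow(members)
      sel <- v$parent$direction == d & v$parent$residue == ch$residue
      vc <- v$coords[sel, , drop = FALSE][order(v$parent$position[sel]), ,
                                          drop = FALSE]
      gap <- sqrt(rowSums((members[-1, ] - members[-m, ])^2))
      d1 <- sqrt(rowSums((vc - members[-m, ])^2))
      d2 <- sqrt(rowSums((vc - members[-1, ])^2))
      expect_true(all(d1 < gap * 1.1) && all(d2 < gap * 1.1))
    }
  }
})

test_that("short chains are rejected by spline placement with a named error", {
  cfg <- array_config(R = 20, n_channels = 6, omitted_indices = integer(0),
                      appended_indices = integer(0))
  arr <- fibonacci_coordinates(cfg)
  chains <- truncate_chains(extract_spiral_chains(arr, 1, intervals = c(3L)))
  expect_error(place_virtual_sensors(list(chains), arr),
               "direction 1, residue 1.*needs >= 3")
})

test_that("geometry CSV + JSON sidecar round-trips bit-exactly", {
  geo <- toy_geo(intervals = c(8L, 5L))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".json"))))
  write_geometry_csv(geo, path)
  back <- read_geometry_csv(path)
  expect_identical(unname(back$coords), unname(geo$coords))
  expect_identical(back$ids, geo$ids)
  expect_identical(back$intervals, geo$intervals)
  expect_equal(back$config$dz, geo$config$dz)
})
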
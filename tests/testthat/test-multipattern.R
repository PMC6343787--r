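test_that("diffraction vectors from spot positions match hand trigonometry", {
  g <- mesh_geometry()
  # spot at the beam centre: q = 0
  q <- spots_to_reciprocal(data.frame(x = g$beam_centre[1],
                                      y = g$beam_centre[2]), g)
  expect_equal(as.numeric(q), c(0, 0, 0), tolerance = 1e-12)

  # spot at 2theta = 30 deg, lambda = 1 A: |q| = 2 sin 15
  r_mm <- g$detector_distance * tan(30 * pi / 180)
  q <- spots_to_reciprocal(
    data.frame(x = g$beam_centre[1] + r_mm / g$pixel_size,
               y = g$beam_centre[2]), g)
  expect_equal(sqrt(sum(q^2)), 2 * sin(15 * pi / 180), tolerance = 1e-10)

  # |q| invariant under rotation of the spot about the beam axis
  for (ang in c(30, 120, 261)) {
    th <- ang * pi / 180
    q2 <- spots_to_reciprocal(
      data.frame(x = g$beam_centre[1] + r_mm * cos(th) / g$pixel_size,
                 y = g$beam_centre[2] + r_mm * sin(th) / g$pixel_size), g)
    expect_equal(sqrt(sum(q2^2)), sqrt(sum(q^2)), tolerance = 1e-12)
  }
})

test_that("DDV histogram matches bin arithmetic and the brute-force oracle", {
  # two vectors 0.0102 apart in 100 bins over [0, 0.04]: one count in the
  # bin of index 26 (1-based; width 4e-4)
  q <- rbind(c(0, 0, 0.01), c(0, 0, 0.0202))
  h <- ddv_histogram(q, 100, 0.04)
  expect_identical(sum(h$counts), 1L)
  expect_identical(which(h$counts == 1L), 26L)

  # N identical vectors: all C(N,2) pairs in bin 1
  q <- matrix(rep(c(0.1, 0.2, 0.3), 8), ncol = 3, byrow = TRUE)
  h <- ddv_histogram(q, 100, 0.04)
  expect_identical(h$counts[1], 28L)
  expect_identical(sum(h$counts[-1]), 0L)

  # 50 random vectors against the explicit double loop
  set.seed(5)
  q <- matrix(stats::rnorm(150, 0, 0.01), ncol = 3)
  h <- ddv_histogram(q, 100, 0.04)
  expect_identical(h$counts, brute_ddv_counts(q, 100, 0.04))
  # conservation: in-range counts plus overflow equal all pairs
  expect_identical(h$n_pairs, 50L * 49L / 2L)
  expect_lte(sum(h$counts), h$n_pairs)
})

test_that("cumulative histogram is the node-wise sum", {
  set.seed(11)
  sim <- simulate_mesh(two_crystal_config(seed = 5, grid = c(6, 6)))
  cfg <- analysis_config()
  cum <- cumulative_histogram(sim$scan, cfg)
  manual <- rep(0L, cfg$hist_bins)
  for (sp in sim$scan$spots) {
    if (nrow(sp) < 2) next
    manual <- manual + ddv_histogram(spots_to_reciprocal(sp, sim$scan$geometry),
                                     cfg$hist_bins, cfg$hist_max)$counts
  }
  expect_identical(cum$counts, manual)

  # single-node mesh: cumulative equals that node's histogram
  g1 <- mesh_geometry(grid_shape = c(1, 1))
  set.seed(2)
  sp <- sim_single_image(g1)
  scan1 <- mesh_scan(g1, matrix(5, 1, 1), list(sp[, 1:3]))
  expect_identical(cumulative_histogram(scan1, cfg)$counts,
                   ddv_histogram(spots_to_reciprocal(sp, g1),
                                 cfg$hist_bins, cfg$hist_max)$counts)
})

test_that("AMPD recovers the minima of a periodic signal", {
  x <- sin(2 * pi * (0:99) / 20)
  found <- ampd_local_minima(x)
  oracle <- brute_local_minima(x)           # 16, 36, 56, 76, 96 (1-based)
  # every detection is a true local minimum, and all interior minima
  # (away from the edge exclusion zone) are found
  expect_true(all(found %in% oracle))
  expect_true(all(oracle[oracle > 5 & oracle < 95] %in% found))

  # small i.i.d. noise does not change the count
  set.seed(3)
  found_noisy <- ampd_local_minima(x + stats::rnorm(100, 0, 0.02))
  expect_identical(length(found_noisy), length(found))

  expect_identical(ampd_local_minima(seq(0, 5, length.out = 60)), integer(0))
  expect_identical(ampd_local_minima(rep(1, 60)), integer(0))
  expect_error(ampd_local_minima(1:3), "length")
})

test_that("baseline slope reproduces ordinary least squares", {
  edges <- seq(0, 0.04, length.out = 101)
  mids <- (edges[-1] + edges[-101]) / 2
  mk <- function(counts) structure(list(counts = counts, bin_edges = edges,
                                        mids = mids, n_pairs = sum(counts)),
                                   class = "ddv_histogram")
  # counts exactly on a line 5 + 1000 x: slope 1000
  h <- mk(5 + 1000 * mids)
  expect_equal(baseline_slope(h, 1:100, c(0, 0.04)), 1000, tolerance = 1e-9)
  # constant counts: slope 0
  expect_equal(baseline_slope(mk(rep(7, 100)), 1:100, c(0, 0.04)), 0,
               tolerance = 1e-9)
  # hand-computed OLS on a 10-bin subset
  bins <- 11:20
  set.seed(8)
  y <- stats::rpois(100, 6)
  xs <- mids[bins]; ys <- y[bins]
  slope_hand <- sum((xs - mean(xs)) * (ys - mean(ys))) /
    sum((xs - mean(xs))^2)
  expect_equal(baseline_slope(mk(y), bins, c(0, 0.04)), slope_hand,
               tolerance = 1e-9)
  # fewer than 3 usable bins is invalid
  expect_true(is.na(baseline_slope(mk(y), c(1, 2), c(0, 0.04))))
  expect_true(is.na(baseline_slope(mk(y), 40:60, c(0, 0.001))))
})

test_that("Ewald cap area matches closed forms and quadrature", {
  # 2theta_max = 90 deg, lambda = 1: S = 2 pi
  q <- rbind(c(0, 0, 1e-9), c(sqrt(2) * sin(pi / 4), 0, -0.2929))
  q[2, ] <- c(sqrt(2), 0, 0) # |q| = sqrt(2) => theta = 45 deg
  expect_equal(ewald_cap_area(q, 1), 2 * pi, tolerance = 1e-10)

  # forward limit: S -> 0
  expect_lt(ewald_cap_area(rbind(c(1e-8, 0, 0)), 1), 1e-12)

  # random inputs against quadrature of the spherical cap
  set.seed(4)
  for (i in 1:5) {
    lam <- stats::runif(1, 0.7, 1.5)
    qmax <- stats::runif(1, 0.1, 0.9) / lam
    q <- matrix(stats::rnorm(30), ncol = 3)
    q <- q / sqrt(rowSums(q^2)) * stats::runif(10, 0.01, qmax)
    tth <- 2 * asin(max(sqrt(rowSums(q^2))) * lam / 2)
    oracle <- stats::integrate(function(p) 2 * pi * (1 / lam)^2 * sin(p),
                               0, tth)$value
    expect_equal(ewald_cap_area(q, lam), oracle, tolerance = 1e-6)
  }
  expect_error(ewald_cap_area(matrix(numeric(0), 0, 3), 1), "at least one")
})

test_that("K combines slope, count and cap area as k0 S / N^2", {
  expect_identical(k_statistic(0, 100, 1), 0)
  expect_equal(k_statistic(2, 200, 0.5), 2.5e-5, tolerance = 1e-12)
  expect_equal(k_statistic(4, 200, 0.5), 2 * k_statistic(2, 200, 0.5))
  # invariance under reordering of the spot list
  set.seed(6)
  g <- mesh_geometry()
  sp <- sim_single_image(g)
  perm <- sp[sample.int(nrow(sp)), ]
  cfg <- analysis_config()
  hb <- 1:100
  for (s in list(sp, perm)) {
    q <- spots_to_reciprocal(s, g)
    h <- ddv_histogram(q, cfg$hist_bins, cfg$hist_max)
    assign(if (identical(s, sp)) "k1" else "k2",
           k_statistic(baseline_slope(h, hb, c(0, 0.04)), nrow(s),
                       ewald_cap_area(q, g$wavelength)))
  }
  expect_identical(k1, k2)
})

test_that("classification flags superposed lattices but not single ones", {
  set.seed(31)
  g <- mesh_geometry(grid_shape = c(4, 5))
  # two crystals: disjoint footprints except one shared column of nodes
  crys <- list(
    crystal_spec(centre = c(1.5, 1), semi_axes = c(2, 1.6),
                 orientation = random_rotation(), peak_score = 10),
    crystal_spec(centre = c(1.5, 3), semi_axes = c(2, 1.6),
                 orientation = random_rotation(), peak_score = 10))
  sim <- simulate_mesh(simulation_config(g, crys, seed = 12))
  mp <- classify_multipattern(sim$scan)
  members <- sim$truth$node_members
  n_lat <- vapply(members, length, 0L)
  idx <- meshcarto:::node_index(g, mp$row, mp$col)
  single <- mp$valid & n_lat[idx] == 1
  double <- mp$valid & n_lat[idx] == 2
  expect_gt(sum(single), 0); expect_gt(sum(double), 0)
  expect_gte(mean(!mp$is_multipattern[single]), 0.95)
  expect_gte(mean(mp$is_multipattern[double]), 0.95)

  # empty or score-free nodes are invalid and unflagged
  empty <- mp$N == 0
  expect_true(all(!mp$valid[empty]))
  expect_true(all(!mp$is_multipattern[empty]))
})
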
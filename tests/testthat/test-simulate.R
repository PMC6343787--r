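test_that("reciprocal basis satisfies the defining dual relations", {
  # cubic: |a*| = 1/a
  B <- reciprocal_basis(c(100, 100, 100, 90, 90, 90))
  expect_equal(unname(sqrt(colSums(B^2))), rep(0.01, 3), tolerance = 1e-12)

  # orthorhombic: direct a is orthogonal to b* and c*
  cell <- c(68, 72, 78, 90, 90, 90)
  B <- reciprocal_basis(cell)
  A <- t(solve(B))      # direct basis implied by duality
  G <- t(A) %*% B
  expect_equal(G, diag(3), tolerance = 1e-12, ignore_attr = TRUE)

  # triclinic volume: det(B) must equal 1/V with V from the brute-force
  # scalar triple product of the direct basis
  cell <- c(55, 63, 71, 80, 95, 104)
  B <- reciprocal_basis(cell)
  A <- t(solve(B))
  V <- abs(sum(A[, 1] * (A[, 2][c(2, 3, 1)] * A[, 3][c(3, 1, 2)] -
                         A[, 2][c(3, 1, 2)] * A[, 3][c(2, 3, 1)])))
  expect_equal(abs(det(B)), 1 / V, tolerance = 1e-10)

  expect_error(reciprocal_basis(c(10, 10, 10, 90, 90, 180)), "degenerate")
})

test_that("orientation is applied rigidly to the reciprocal basis", {
  R <- rotation_about(c(1, 2, 3), 35)
  B0 <- reciprocal_basis(test_cell)
  B1 <- reciprocal_basis(test_cell, R)
  expect_equal(B1, R %*% B0, tolerance = 1e-12)
  expect_equal(sqrt(colSums(B1^2)), sqrt(colSums(B0^2)), tolerance = 1e-12)
})

test_that("still-image spots are self-consistent with the Ewald construction", {
  set.seed(101)
  g <- mesh_geometry()
  R <- random_rotation()
  sp <- sim_single_image(g, jitter = 0, orientation = R)
  expect_gt(nrow(sp), 100)

  # q recomputed from each emitted detector position must fall within twice
  # the excitation window (in reciprocal units) of a lattice node
  q <- spots_to_reciprocal(sp, g)
  B <- reciprocal_basis(test_cell, R)
  hkl <- solve(B, t(q))
  err <- sqrt(colSums((B %*% (hkl - round(hkl)))^2))
  qmax <- 1 / 2.0
  expect_lt(max(err), 2 * 0.1 * pi / 180 * qmax)

  # with a narrow window the projection error vanishes: recovered |q|
  # matches the generating node's |q| to 1e-4
  sp2 <- sim_single_image(g, jitter = 0, halfwidth = 0.02, orientation = R)
  expect_gt(nrow(sp2), 10)
  q2 <- spots_to_reciprocal(sp2, g)
  hkl2 <- round(solve(B, t(q2)))
  qn_node <- sqrt(colSums((B %*% hkl2)^2))
  expect_lt(max(abs(sqrt(rowSums(q2^2)) - qn_node)), 1e-4)

  # ...and every spot must sit within the excitation window of the sphere
  lam <- g$wavelength
  dev <- abs(sqrt(q[, 1]^2 + q[, 2]^2 + (q[, 3] + 1 / lam)^2) - 1 / lam)
  eta <- asin(dev / sqrt(rowSums(q^2))) * 180 / pi
  expect_lt(max(eta), 0.1 + 1e-9)
})

test_that("an empty excitation window yields no spots", {
  g <- mesh_geometry()
  sp <- simulate_still_spots(
    list(list(unit_cell = test_cell, orientation = diag(3))), g, 0,
    excitation_halfwidth = 1e-7, resolution_limit = 2.0)
  expect_identical(nrow(sp), 0L)
})

test_that("multi-lattice spot lists concatenate with provenance", {
  set.seed(7)
  g <- mesh_geometry()
  R1 <- random_rotation(); R2 <- random_rotation()
  lat <- function(R) list(unit_cell = test_cell, orientation = R)
  n1 <- nrow(simulate_still_spots(list(lat(R1)), g, 0))
  n2 <- nrow(simulate_still_spots(list(lat(R2)), g, 0))
  both <- simulate_still_spots(list(lat(R1), lat(R2)), g, 0)
  expect_identical(nrow(both), n1 + n2)
  expect_identical(sum(both$lattice == 1), n1)
  expect_identical(sum(both$lattice == 2), n2)
})

test_that("simulate_mesh is deterministic and scores follow the footprint", {
  set.seed(9); o <- list(random_rotation(), random_rotation())
  cfg <- two_crystal_config(seed = 31, orientations = o)
  s1 <- simulate_mesh(cfg)
  s2 <- simulate_mesh(cfg)
  expect_identical(s1$scan$scores, s2$scan$scores)
  expect_identical(s1$scan$spots, s2$scan$spots)

  # ground-truth score surface equals the semi-ellipsoid sum exactly
  g <- cfg$geometry
  nr <- g$grid_shape[1]; nc <- g$grid_shape[2]
  expected <- matrix(0, nr, nc)
  for (cr in cfg$crystals) {
    p <- list(H = cr$peak_score, x0 = cr$centre[2], y0 = cr$centre[1],
              a = cr$semi_axes[1], b = cr$semi_axes[2], phi = cr$tilt)
    expected <- expected + outer(0:(nr - 1), 0:(nc - 1), function(r, cc)
      semi_ellipsoid(cc, r, p))
  }
  expect_equal(s1$scan$scores, expected, tolerance = 1e-14)

  # node membership: spots present exactly where a footprint covers
  covered <- expected > 0
  has_spots <- matrix(vapply(s1$scan$spots, nrow, 0L) > 0, nr, nc,
                      byrow = TRUE)
  expect_identical(has_spots, covered)
})

test_that("a node under two crystals receives the union of their spots", {
  set.seed(13)
  g <- mesh_geometry(grid_shape = c(5, 5))
  crys <- list(
    crystal_spec(centre = c(2, 2), semi_axes = c(1.8, 1.4),
                 orientation = random_rotation(), peak_score = 5),
    crystal_spec(centre = c(2, 3), semi_axes = c(1.8, 1.4),
                 orientation = random_rotation(), peak_score = 5))
  sim <- simulate_mesh(simulation_config(g, crys, seed = 3))
  overlap <- which(vapply(sim$truth$node_members,
                          function(m) length(m) == 2, TRUE))
  expect_gt(length(overlap), 0)
  lat <- attr(sim$scan$spots[[overlap[1]]], "lattice")
  expect_setequal(unique(lat), c(1L, 2L))
})

test_that("a crystal entirely outside the grid warns but does not error", {
  g <- mesh_geometry(grid_shape = c(4, 4))
  far <- crystal_spec(centre = c(40, 40), semi_axes = c(1, 1),
                      orientation = diag(3))
  expect_warning(simulate_mesh(simulation_config(g, list(far), seed = 1)),
                 "outside")
})

test_that("same-crystal nodes at equal omega are nearly identical images", {
  set.seed(23)
  g <- mesh_geometry(grid_shape = c(6, 3))
  cr <- crystal_spec(centre = c(2.5, 1), semi_axes = c(3, 1.2), tilt = 90,
                     orientation = random_rotation())
  # noise-free centroids: identical orientation and omega give D ~ 0
  sim <- simulate_mesh(simulation_config(g, list(cr), seed = 4,
                                         centroid_sigma_px = 0))
  mask <- sim$scan$scores > 0
  same_col <- which(colSums(mask) >= 2)[1] - 1
  rows <- which(mask[, same_col + 1]) - 1
  d <- distance_score(
    meshcarto:::node_spots(sim$scan, rows[1], same_col),
    meshcarto:::node_spots(sim$scan, rows[2], same_col), g)
  expect_lt(d, 0.01)
})

test_that("calibration curve rises monotonically with the satellite ratio", {
  cal <- calibration_curve_k(c(0, 0.1, 0.25, 0.5, 1), replicates = 12,
                             seed = 17)
  expect_true(all(diff(cal$mean_K) > 0))
  # single-lattice K statistically indistinguishable from 0 at 3 sigma
  # (it can be exactly 0 when every baseline bin is empty)
  expect_lte(cal$mean_K[1], 3 * cal$sd_K[1] / sqrt(cal$n[1]))
  cal2 <- calibration_curve_k(c(0, 0.1, 0.25, 0.5, 1), replicates = 12,
                              seed = 17)
  expect_identical(cal$mean_K, cal2$mean_K)
  expect_error(calibration_curve_k(c(0.5, 1.5)), "ratios")
})
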
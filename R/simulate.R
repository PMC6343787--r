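#' Specification of one simulated crystal
#'
#' A crystal occupies an elliptical footprint on the mesh; its score surface
#' is a semi-ellipsoid of peak height `peak_score` over that footprint
#' (score proportional to illuminated crystal thickness). All nodes inside
#' the footprint diffract with the crystal's lattice orientation, optionally
#' drifting linearly along the major axis (`orientation_gradient`, degrees
#' per grid unit, emulating a gradually bent crystal).
#'
#' @param centre length-2 numeric, footprint centre as (row, col) grid
#'   units, continuous.
#' @param semi_axes length-2 numeric (a, b) in grid units, a along the tilt
#'   direction.
#' @param tilt in-plane rotation of the major axis, degrees. 0 means the
#'   major axis runs along the columns (the fast scan direction).
#' @param unit_cell length-6 numeric (a, b, c, alpha, beta, gamma) in
#'   Angstrom and degrees.
#' @param orientation 3x3 rotation matrix applied to the reciprocal basis.
#' @param peak_score semi-ellipsoid peak height H (dimensionless, > 0).
#' @param orientation_gradient lattice rotation per grid unit along the
#'   major axis, degrees (about the goniometer axis).
#' @return an object of class `crystal_spec`.
#' @export
crystal_spec <- function(centre, semi_axes, tilt = 0,
                         unit_cell = c(68, 72, 78, 90, 90, 90),
                         orientation = diag(3),
                         peak_score = 10,
                         orientation_gradient = 0) {
  if (any(semi_axes <= 0)) stop("semi_axes must be > 0")
  if (peak_score <= 0) stop("peak_score must be > 0")
  structure(list(centre = as.numeric(centre),
                 semi_axes = as.numeric(semi_axes),
                 tilt = as.numeric(tilt),
                 unit_cell = as.numeric(unit_cell),
                 orientation = orientation,
                 peak_score = as.numeric(peak_score),
                 orientation_gradient = as.numeric(orientation_gradient)),
            class = "crystal_spec")
}

#' Simulation configuration
#'
#' @param geometry a [mesh_geometry()].
#' @param crystals list of [crystal_spec()] objects.
#' @param excitation_halfwidth effective reflection half-width for a still
#'   image (mosaicity plus bandwidth plus divergence), degrees. A
#'   reciprocal-lattice node diffracts when its angular offset from the
#'   Ewald sphere is below this value.
#' @param resolution_limit diffraction limit of the lattices, Angstrom.
#' @param noise_spots_per_image expected number of spurious uniform spots
#'   added per image (Poisson).
#' @param centroid_sigma_px Gaussian spot-centroid measurement error,
#'   detector pixels.
#' @param seed integer seed; [simulate_mesh()] is deterministic given it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(geometry = mesh_geometry(),
                              crystals = list(),
                              excitation_halfwidth = 0.1,
                              resolution_limit = 2.0,
                              noise_spots_per_image = 0,
                              centroid_sigma_px = 0.3,
                              seed = 1L) {
  if (excitation_halfwidth <= 0) stop("excitation_halfwidth must be > 0")
  if (resolution_limit <= geometry$wavelength / 2)
    stop("resolution_limit must exceed wavelength/2")
  structure(list(geometry = geometry, crystals = crystals,
                 excitation_halfwidth = excitation_halfwidth,
                 resolution_limit = resolution_limit,
                 noise_spots_per_image = noise_spots_per_image,
                 centroid_sigma_px = centroid_sigma_px,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Read a simulation configuration from YAML
#'
#' The file holds a `geometry` mapping (fields of [mesh_geometry()]), a
#' `crystals` sequence (fields of [crystal_spec()]; `orientation` may be
#' given as `axis` + `angle_deg`, or omitted for `random`), and the
#' top-level simulation fields of [simulation_config()]. Crystals with
#' `orientation: random` draw from the RNG seeded by `seed`.
#'
#' @param path YAML file.
#' @param seed overrides the file's `seed` when not `NULL`.
#' @return a [simulation_config()].
#' @export
read_simulation_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  geom <- do.call(mesh_geometry, raw$geometry)
  seed <- if (!is.null(seed)) as.integer(seed)
          else if (!is.null(raw$seed)) as.integer(raw$seed) else 1L
  crystals <- withr_seed(seed + 1L, lapply(raw$crystals, function(cr) {
    orientation <- if (is.null(cr$orientation) ||
                       identical(cr$orientation, "random")) random_rotation()
      else rotation_about(unlist(cr$orientation$axis),
                          cr$orientation$angle_deg)
    crystal_spec(
      centre = unlist(cr$centre), semi_axes = unlist(cr$semi_axes),
      tilt = cr$tilt %||% 0,
      unit_cell = unlist(cr$unit_cell %||% c(68, 72, 78, 90, 90, 90)),
      orientation = orientation,
      peak_score = cr$peak_score %||% 10,
      orientation_gradient = cr$orientation_gradient %||% 0)
  }))
  simulation_config(
    geometry = geom, crystals = crystals,
    excitation_halfwidth = raw$excitation_halfwidth %||% 0.1,
    resolution_limit = raw$resolution_limit %||% 2.0,
    noise_spots_per_image = raw$noise_spots_per_image %||% 0,
    centroid_sigma_px = raw$centroid_sigma_px %||% 0.3,
    seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reciprocal basis of a unit cell
#'
#' Builds the direct basis in a standard setting (a along x, b in the xy
#' plane), inverts it, and applies `orientation`. Columns of the result are
#' the reciprocal vectors a*, b*, c* in 1/Angstrom, satisfying
#' a_i . a*_j = delta_ij.
#'
#' @param unit_cell length-6 numeric (a, b, c, alpha, beta, gamma),
#'   Angstrom / degrees.
#' @param orientation 3x3 rotation matrix.
#' @return 3x3 matrix with reciprocal vectors as columns.
#' @export
reciprocal_basis <- function(unit_cell, orientation = diag(3)) {
  a <- unit_cell[1]; b <- unit_cell[2]; cc <- unit_cell[3]
  al <- unit_cell[4] * pi / 180; be <- unit_cell[5] * pi / 180
  ga <- unit_cell[6] * pi / 180
  av <- c(a, 0, 0)
  bv <- c(b * cos(ga), b * sin(ga), 0)
  cx <- cc * cos(be)
  cy <- cc * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz2 <- cc^2 - cx^2 - cy^2
  if (!is.finite(cz2) || cz2 <= 0) stop("degenerate unit cell")
  A <- cbind(av, bv, c(cx, cy, sqrt(cz2)))
  if (abs(det(A)) < 1e-9) stop("degenerate unit cell")
  orientation %*% t(solve(A))
}

# cache of candidate reciprocal nodes (crystal frame) per (cell, resolution)
.lattice_cache <- new.env(parent = emptyenv())

# all reciprocal-lattice vectors with 0 < |q| <= 1/resolution, columns of a
# 3 x n matrix, enumerated in the unrotated crystal frame
lattice_candidates <- function(unit_cell, resolution_limit) {
  key <- paste(c(format(unit_cell, digits = 10), format(resolution_limit)),
               collapse = "|")
  hit <- .lattice_cache[[key]]
  if (!is.null(hit)) return(hit)
  qmax <- 1 / resolution_limit
  B <- reciprocal_basis(unit_cell)
  lens <- unit_cell[1:3]
  hm <- ceiling(qmax * lens) + 1
  H <- as.matrix(expand.grid(-hm[1]:hm[1], -hm[2]:hm[2], -hm[3]:hm[3]))
  Q <- B %*% t(H)
  qn2 <- colSums(Q^2)
  keep <- qn2 > 1e-18 & qn2 <= qmax^2
  out <- Q[, keep, drop = FALSE]
  .lattice_cache[[key]] <- out
  out
}

#' Simulate spots of one still image
#'
#' For each reciprocal-lattice node within the resolution sphere, the node
#' is rotated by the lattice orientation and the goniometer angle; it
#' diffracts when its angular offset from the Ewald sphere (radius
#' 1/wavelength, centred at -z/wavelength) is below
#' `excitation_halfwidth`. The scattered ray through the node is
#' intersected with the detector plane; spots falling off the detector are
#' dropped. Spot lists of multiple lattices are concatenated, with a
#' `lattice` provenance column.
#'
#' Randomness (centroid jitter, intensities, noise spots) uses the current
#' RNG state.
#'
#' @param lattices list of descriptors, each a list with `unit_cell` and
#'   `orientation` (or a bare 3x3 reciprocal basis obtained from
#'   [reciprocal_basis()]; then `resolution_limit` enumeration uses the
#'   basis directly).
#' @param geometry a [mesh_geometry()].
#' @param omega goniometer angle of the image, degrees.
#' @param excitation_halfwidth degrees, see [simulation_config()].
#' @param resolution_limit Angstrom.
#' @param centroid_sigma_px spot-centroid jitter, pixels (0 for exact
#'   positions).
#' @param noise_spots expected number of spurious uniform spots (Poisson;
#'   0 disables).
#' @return data frame with columns `x`, `y`, `intensity`, `lattice`
#'   (0 = noise).
#' @export
simulate_still_spots <- function(lattices, geometry, omega,
                                 excitation_halfwidth = 0.1,
                                 resolution_limit = 2.0,
                                 centroid_sigma_px = 0,
                                 noise_spots = 0) {
  if (!length(lattices)) stop("need at least one lattice")
  lam <- geometry$wavelength
  Rw <- rotation_omega(omega)
  out <- vector("list", length(lattices))
  for (li in seq_along(lattices)) {
    lat <- lattices[[li]]
    Q0 <- lattice_candidates(lat$unit_cell, resolution_limit)
    Q <- (Rw %*% lat$orientation) %*% Q0
    dev <- abs(sqrt(Q[1, ]^2 + Q[2, ]^2 + (Q[3, ] + 1 / lam)^2) - 1 / lam)
    qn <- sqrt(colSums(Q^2))
    eta <- asin(pmin(1, dev / qn)) * 180 / pi
    Q <- Q[, eta < excitation_halfwidth, drop = FALSE]
    if (!ncol(Q)) { out[[li]] <- NULL; next }
    d <- rbind(Q[1, ], Q[2, ], Q[3, ] + 1 / lam)
    d <- d / rep(sqrt(colSums(d^2)), each = 3)
    d <- d[, d[3, ] > 1e-6, drop = FALSE]
    if (!ncol(d)) { out[[li]] <- NULL; next }
    tt <- geometry$detector_distance / d[3, ]
    px <- geometry$beam_centre[1] + d[1, ] * tt / geometry$pixel_size
    py <- geometry$beam_centre[2] + d[2, ] * tt / geometry$pixel_size
    if (centroid_sigma_px > 0) {
      px <- px + stats::rnorm(length(px), 0, centroid_sigma_px)
      py <- py + stats::rnorm(length(py), 0, centroid_sigma_px)
    }
    on <- px >= 0 & px < geometry$detector_shape[1] &
          py >= 0 & py < geometry$detector_shape[2]
    n <- sum(on)
    out[[li]] <- data.frame(x = px[on], y = py[on],
                            intensity = stats::rlnorm(n, 0, 1),
                            lattice = rep(li, n))
  }
  spots <- do.call(rbind, out)
  if (is.null(spots))
    spots <- cbind(empty_spots(), lattice = integer(0))
  if (noise_spots > 0) {
    k <- stats::rpois(1, noise_spots)
    if (k > 0)
      spots <- rbind(spots, data.frame(
        x = stats::runif(k, 0, geometry$detector_shape[1]),
        y = stats::runif(k, 0, geometry$detector_shape[2]),
        intensity = stats::rlnorm(k, -1, 0.5),
        lattice = rep(0L, k)))
  }
  rownames(spots) <- NULL
  spots
}

# semi-ellipsoid footprint value of crystal `cr` at grid point (row, col);
# also returns the signed position along the major axis (grid units)
footprint_eval <- function(cr, row, col) {
  phi <- cr$tilt * pi / 180
  dx <- col - cr$centre[2]; dy <- row - cr$centre[1]
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  s2 <- 1 - u^2 / cr$semi_axes[1]^2 - v^2 / cr$semi_axes[2]^2
  list(value = cr$peak_score * sqrt(pmax(0, s2)), u = u, inside = s2 > 0)
}

#' Simulate a full mesh scan with ground truth
#'
#' Every node covered by a crystal's elliptical footprint receives that
#' crystal's still-image spots (at the node's omega and, if the crystal has
#' a nonzero `orientation_gradient`, an orientation rotated in proportion
#' to the node's position along the major axis). Nodes covered by several
#' crystals receive the concatenation of their spot lists. The node score
#' is the sum of the crystals' semi-ellipsoid surface values at the node
#' (exactly; scores carry no noise). Deterministic given `config$seed`;
#' the caller's RNG state is preserved.
#'
#' @param config a [simulation_config()].
#' @return list with elements `scan` (a [mesh_scan()]) and `truth` (list:
#'   per-crystal true parameters, per-node contributing crystal ids and the
#'   true score grid).
#' @export
simulate_mesh <- function(config) {
  withr_seed(config$seed, simulate_mesh_impl(config))
}

simulate_mesh_impl <- function(config) {
  g <- config$geometry
  nr <- g$grid_shape[1]; nc <- g$grid_shape[2]
  for (ci in seq_along(config$crystals)) {
    cr <- config$crystals[[ci]]
    fp <- footprint_eval(cr, rep(0:(nr - 1), each = nc),
                         rep(0:(nc - 1), times = nr))
    if (!any(fp$inside))
      warning(sprintf("crystal %d lies entirely outside the grid", ci))
  }
  scores <- matrix(0, nr, nc)
  spots <- vector("list", nr * nc)
  members <- vector("list", nr * nc)
  for (r in 0:(nr - 1)) for (cc in 0:(nc - 1)) {
    om <- node_omega(g, r, cc)
    contrib <- integer(0)
    lattices <- list()
    sc <- 0
    for (ci in seq_along(config$crystals)) {
      cr <- config$crystals[[ci]]
      fp <- footprint_eval(cr, r, cc)
      if (!fp$inside) next
      contrib <- c(contrib, ci)
      sc <- sc + fp$value
      orient <- cr$orientation
      if (cr$orientation_gradient != 0)
        orient <- rotation_omega(cr$orientation_gradient * fp$u) %*% orient
      lattices[[length(lattices) + 1]] <-
        list(unit_cell = cr$unit_cell, orientation = orient)
    }
    idx <- node_index(g, r, cc)
    scores[r + 1, cc + 1] <- sc
    members[[idx]] <- contrib
    if (length(lattices) || config$noise_spots_per_image > 0) {
      if (length(lattices)) {
        sp <- simulate_still_spots(
          lattices, g, om,
          excitation_halfwidth = config$excitation_halfwidth,
          resolution_limit = config$resolution_limit,
          centroid_sigma_px = config$centroid_sigma_px,
          noise_spots = config$noise_spots_per_image)
        sp$lattice <- ifelse(sp$lattice > 0, contrib[sp$lattice], 0L)
      } else {
        k <- stats::rpois(1, config$noise_spots_per_image)
        sp <- data.frame(x = stats::runif(k, 0, g$detector_shape[1]),
                         y = stats::runif(k, 0, g$detector_shape[2]),
                         intensity = stats::rlnorm(k, -1, 0.5),
                         lattice = rep(0L, k))
      }
      spots[[idx]] <- sp[, c("x", "y", "intensity")]
      attr(spots[[idx]], "lattice") <- sp$lattice
    } else {
      spots[[idx]] <- empty_spots()
    }
  }
  truth <- list(
    crystals = lapply(config$crystals, function(cr)
      list(centre = cr$centre, semi_axes = cr$semi_axes, tilt = cr$tilt,
           peak_score = cr$peak_score,
           orientation_gradient = cr$orientation_gradient)),
    node_members = members,
    scores = scores)
  list(scan = mesh_scan(g, scores, spots), truth = truth)
}

#' K-statistic calibration curve against satellite spot ratio
#'
#' Replicates the threshold-calibration simulation: a main lattice is
#' superposed with a satellite lattice whose spot list is randomly
#' subsampled so that it contributes `ratio` times the main lattice's spot
#' count. The multi-pattern statistic K is computed for each replicate
#' image; baseline regions are derived once from the cumulative DDV
#' histogram of all simulated images, mirroring the mesh analysis.
#'
#' @param spot_ratio_grid numeric vector of satellite/main spot-count
#'   ratios in \[0, 1\] (0 = single lattice).
#' @param replicates images per ratio.
#' @param config a [simulation_config()] providing geometry, cell (taken
#'   from the first crystal, or the default cell), excitation width and
#'   noise settings.
#' @param seed integer seed.
#' @param analysis an [analysis_config()].
#' @return data frame with columns `ratio`, `mean_K`, `sd_K`, `n` plus an
#'   attribute `"K"` holding the per-replicate matrix.
#' @export
calibration_curve_k <- function(spot_ratio_grid = c(0, 0.1, 0.25, 0.5, 1),
                                replicates = 20,
                                config = simulation_config(),
                                seed = 1L,
                                analysis = analysis_config()) {
  if (any(spot_ratio_grid < 0 | spot_ratio_grid > 1))
    stop("ratios must lie in [0, 1]")
  g <- config$geometry
  cell <- if (length(config$crystals)) config$crystals[[1]]$unit_cell
          else crystal_spec(c(0, 0), c(1, 1))$unit_cell
  withr_seed(seed, calibration_curve_impl(spot_ratio_grid, replicates,
                                          config, analysis, cell))
}

calibration_curve_impl <- function(spot_ratio_grid, replicates, config,
                                   analysis, cell) {
  g <- config$geometry
  sim1 <- function() {
    simulate_still_spots(
      list(list(unit_cell = cell, orientation = random_rotation())), g, 0,
      excitation_halfwidth = config$excitation_halfwidth,
      resolution_limit = config$resolution_limit,
      centroid_sigma_px = config$centroid_sigma_px,
      noise_spots = config$noise_spots_per_image)
  }
  # one pair of independent lattices per replicate, reused across ratios so
  # the curve is paired (lower variance between ratio levels)
  pairs <- replicate(replicates, list(main = sim1(), sat = sim1()),
                     simplify = FALSE)
  cum <- rep(0, analysis$hist_bins)
  for (p in pairs) {
    q <- spots_to_reciprocal(p$main, g)
    cum <- cum + ddv_histogram(q, analysis$hist_bins, analysis$hist_max)$counts
  }
  bl <- baseline_regions(cum, analysis)
  K <- matrix(NA_real_, replicates, length(spot_ratio_grid))
  skipped <- 0L
  for (j in seq_along(spot_ratio_grid)) {
    ratio <- spot_ratio_grid[j]
    for (i in seq_len(replicates)) {
      p <- pairs[[i]]
      sp <- p$main
      if (ratio > 0) {
        k <- min(round(nrow(p$main) * ratio), nrow(p$sat))
        sp <- rbind(sp, p$sat[sample.int(nrow(p$sat), k), ])
      }
      if (nrow(sp) < analysis$min_spots_for_k) { skipped <- skipped + 1L; next }
      q <- spots_to_reciprocal(sp, g)
      hist <- ddv_histogram(q, analysis$hist_bins, analysis$hist_max)
      k0 <- baseline_slope(hist, bl, analysis$fit_range)
      if (is.na(k0)) { skipped <- skipped + 1L; next }
      S <- ewald_cap_area(q, g$wavelength)
      K[i, j] <- k_statistic(k0, nrow(sp), S)
    }
  }
  if (skipped) message(skipped, " replicate image(s) skipped (too few spots)")
  out <- data.frame(ratio = spot_ratio_grid,
                    mean_K = colMeans(K, na.rm = TRUE),
                    sd_K = apply(K, 2, stats::sd, na.rm = TRUE),
                    n = colSums(!is.na(K)))
  attr(out, "K") <- K
  out
}
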
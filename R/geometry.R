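#' Experiment geometry of a mesh scan
#'
#' Bundles the beamline parameters needed to interpret detector-pixel spot
#' coordinates and to assign a goniometer angle to every grid node.
#'
#' Conventions used throughout the package: the direct beam travels along
#' +z and hits the flat detector (normal to the beam) at `beam_centre`,
#' `detector_distance` millimetres from the sample. Detector pixels are
#' 0-based and continuous, with x along the fast axis and y along the slow
#' axis. Grid nodes are addressed as (row, col), 0-based. Each row of the
#' mesh is collected during a small rotation of the goniometer: node
#' (row, col) is exposed at `omega = omega_start + col * omega_per_image`
#' degrees, and omega resets at the start of every row.
#'
#' @param wavelength X-ray wavelength in Angstrom.
#' @param detector_distance sample-to-detector distance in mm.
#' @param pixel_size detector pixel edge in mm (square pixels).
#' @param beam_centre length-2 numeric, direct-beam position in pixels
#'   (fast, slow).
#' @param detector_shape length-2 integer, detector size in pixels
#'   (n_fast, n_slow).
#' @param grid_shape length-2 integer, mesh dimensions (n_rows, n_cols).
#' @param omega_per_image rotation increment per image within a row, degrees.
#' @param omega_start omega of the first image of every row, degrees.
#'
#' @return an object of class `mesh_geometry`.
#' @export
mesh_geometry <- function(wavelength = 1.0,
                          detector_distance = 250,
                          pixel_size = 0.172,
                          beam_centre = c(737.5, 839.5),
                          detector_shape = c(1475L, 1679L),
                          grid_shape = c(10L, 10L),
                          omega_per_image = 0.05,
                          omega_start = 0) {
  g <- list(
    wavelength = as.numeric(wavelength),
    detector_distance = as.numeric(detector_distance),
    pixel_size = as.numeric(pixel_size),
    beam_centre = as.numeric(beam_centre),
    detector_shape = as.integer(detector_shape),
    grid_shape = as.integer(grid_shape),
    omega_per_image = as.numeric(omega_per_image),
    omega_start = as.numeric(omega_start)
  )
  class(g) <- "mesh_geometry"
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  stopifnot(inherits(g, "mesh_geometry"))
  if (!(g$wavelength > 0)) stop("wavelength must be > 0")
  if (!(g$detector_distance > 0)) stop("detector_distance must be > 0")
  if (!(g$pixel_size > 0)) stop("pixel_size must be > 0")
  if (length(g$beam_centre) != 2 || length(g$detector_shape) != 2)
    stop("beam_centre and detector_shape must have length 2")
  if (any(g$grid_shape < 1)) stop("grid_shape components must be >= 1")
  if (g$beam_centre[1] < 0 || g$beam_centre[1] >= g$detector_shape[1] ||
      g$beam_centre[2] < 0 || g$beam_centre[2] >= g$detector_shape[2])
    stop("beam_centre must lie inside the detector bounds")
  invisible(g)
}

#' @export
print.mesh_geometry <- function(x, ...) {
  cat(sprintf(
    "<mesh_geometry> lambda %.4g A, distance %.4g mm, pixel %.4g mm\n",
    x$wavelength, x$detector_distance, x$pixel_size))
  cat(sprintf("  detector %d x %d px, beam centre (%.1f, %.1f)\n",
              x$detector_shape[1], x$detector_shape[2],
              x$beam_centre[1], x$beam_centre[2]))
  cat(sprintf("  grid %d x %d nodes, omega %g + col * %g deg (per-row reset)\n",
              x$grid_shape[1], x$grid_shape[2],
              x$omega_start, x$omega_per_image))
  invisible(x)
}

#' Omega angle of a grid node
#'
#' @param geometry a [mesh_geometry()].
#' @param row,col 0-based grid indices (vectorised).
#' @return omega in degrees.
#' @export
node_omega <- function(geometry, row, col) {
  geometry$omega_start + col * geometry$omega_per_image
}

#' Analysis configuration
#'
#' Tunable parameters of the mesh-scan analysis. Defaults follow the
#' published method where it states a value and documented package choices
#' elsewhere (see the methods vignette).
#'
#' @param k_threshold multi-pattern threshold on the K statistic, 1/Angstrom.
#' @param ray_gate matching gate and cap for per-spot angular deviations,
#'   degrees.
#' @param d_cutoff dendrogram cut distance separating crystals, degrees.
#' @param omega_gate pairs of images further apart than this in omega get
#'   zero weight in the average linkage, degrees.
#' @param hist_bins number of DDV histogram bins.
#' @param hist_max upper DDV length bound of the histogram, 1/Angstrom.
#' @param fit_range length-2 numeric, DDV length range used in the baseline
#'   fit, 1/Angstrom.
#' @param min_spots_for_k below this spot count the K test is skipped and
#'   the node treated as single-pattern.
#' @param score_floor scores strictly above this count as "diffraction
#'   present".
#' @param penalty_weight weight of no-diffraction nodes in the shape-fit
#'   objective.
#' @param de_seed integer seed for the differential-evolution shape fit.
#' @param connectivity 8 (default) or 4; grid adjacency used when building
#'   connected regions.
#'
#' @return an object of class `analysis_config` (a list).
#' @export
analysis_config <- function(k_threshold = 1.4e-4,
                            ray_gate = 0.1,
                            d_cutoff = 0.093,
                            omega_gate = 0.5,
                            hist_bins = 100L,
                            hist_max = 1 / 25,
                            fit_range = c(1e-3, 40e-3),
                            min_spots_for_k = 10L,
                            score_floor = 0,
                            penalty_weight = 10,
                            de_seed = 42L,
                            connectivity = 8L) {
  cfg <- list(
    k_threshold = k_threshold, ray_gate = ray_gate, d_cutoff = d_cutoff,
    omega_gate = omega_gate, hist_bins = as.integer(hist_bins),
    hist_max = hist_max, fit_range = as.numeric(fit_range),
    min_spots_for_k = as.integer(min_spots_for_k),
    score_floor = score_floor, penalty_weight = penalty_weight,
    de_seed = as.integer(de_seed), connectivity = as.integer(connectivity)
  )
  if (!(cfg$d_cutoff > 0 && cfg$d_cutoff <= cfg$ray_gate))
    stop("need 0 < d_cutoff <= ray_gate")
  if (cfg$hist_bins < 10) stop("hist_bins must be >= 10")
  if (cfg$fit_range[1] < 0 || cfg$fit_range[2] > cfg$hist_max)
    stop("fit_range must lie within [0, hist_max]")
  if (!cfg$connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  class(cfg) <- "analysis_config"
  cfg
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis length-3 numeric, rotation axis (any norm).
#' @param angle_deg rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  co <- cos(th); si <- sin(th); C <- 1 - co
  matrix(c(
    co + u[1]^2 * C,        u[1] * u[2] * C - u[3] * si, u[1] * u[3] * C + u[2] * si,
    u[2] * u[1] * C + u[3] * si, co + u[2]^2 * C,        u[2] * u[3] * C - u[1] * si,
    u[3] * u[1] * C - u[2] * si, u[3] * u[2] * C + u[1] * si, co + u[3]^2 * C
  ), nrow = 3, byrow = TRUE)
}

# goniometer omega axis: vertical (lab y), beam along +z
rotation_omega <- function(angle_deg) rotation_about(c(0, 1, 0), angle_deg)

#' Uniform random 3D rotation
#'
#' Random axis on the unit sphere and uniform angle; adequate for drawing
#' unrelated lattice orientations.
#'
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  z <- stats::rnorm(3)
  rotation_about(z, stats::runif(1, 0, 360))
}

#' Construct a mesh scan container
#'
#' A mesh scan is the pipeline input: geometry, a dense score grid, and one
#' spot table per node. Spot tables are data frames with columns `x`, `y`
#' (detector pixels) and `intensity`, stored in row-major node order
#' (index = row * n_cols + col + 1).
#'
#' @param geometry a [mesh_geometry()].
#' @param scores numeric matrix n_rows x n_cols of diffraction scores.
#' @param spots list of spot data frames, row-major, length n_rows * n_cols.
#' @return an object of class `mesh_scan`.
#' @export
mesh_scan <- function(geometry, scores, spots) {
  validate_geometry(geometry)
  nr <- geometry$grid_shape[1]; nc <- geometry$grid_shape[2]
  scores <- as.matrix(scores)
  if (!all(dim(scores) == c(nr, nc)))
    stop(sprintf("score grid is %d x %d but geometry says %d x %d",
                 nrow(scores), ncol(scores), nr, nc))
  if (any(scores < 0)) stop("scores must be >= 0")
  if (length(spots) != nr * nc)
    stop(sprintf("expected %d spot tables, got %d", nr * nc, length(spots)))
  for (i in seq_along(spots)) {
    s <- spots[[i]]
    if (!is.data.frame(s) || !all(c("x", "y", "intensity") %in% names(s)))
      stop("each spot table needs columns x, y, intensity")
    if (nrow(s) && (any(s$x < 0) || any(s$x >= geometry$detector_shape[1]) ||
                    any(s$y < 0) || any(s$y >= geometry$detector_shape[2])))
      stop(sprintf("spot table %d has coordinates outside the detector", i))
  }
  structure(list(geometry = geometry, scores = scores, spots = spots),
            class = "mesh_scan")
}

#' @export
print.mesh_scan <- function(x, ...) {
  nd <- sum(x$scores > 0)
  cat(sprintf("<mesh_scan> %d x %d nodes, %d with score > 0, %d spots total\n",
              nrow(x$scores), ncol(x$scores), nd,
              sum(vapply(x$spots, nrow, 0L))))
  invisible(x)
}

# row-major node index (1-based) from 0-based (row, col)
node_index <- function(geometry, row, col) {
  row * geometry$grid_shape[2] + col + 1L
}

# spots of node (row, col), 0-based
node_spots <- function(scan, row, col) {
  scan$spots[[node_index(scan$geometry, row, col)]]
}

empty_spots <- function() {
  data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0))
}
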
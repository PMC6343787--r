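#' Read a mesh-scan bundle from disk
#'
#' A bundle is a directory holding `geometry.json` (or `geometry.yaml`),
#' `scores.csv` (n_rows x n_cols, row-major, no header) and a `spots/`
#' subdirectory with one tab-separated table `r{row}_c{col}.tsv` per node
#' (columns `x`, `y`, `intensity`; 0-based node indices in the file name).
#'
#' @param path bundle directory.
#' @return a [mesh_scan()].
#' @export
read_scan_bundle <- function(path) {
  if (!dir.exists(path)) stop("bundle directory not found: ", path)
  gfile <- file.path(path, "geometry.json")
  if (file.exists(gfile)) {
    raw <- jsonlite::read_json(gfile, simplifyVector = TRUE)
  } else {
    gfile <- file.path(path, "geometry.yaml")
    if (!file.exists(gfile)) stop("no geometry.json or geometry.yaml in ", path)
    raw <- yaml::read_yaml(gfile)
  }
  req <- c("wavelength", "detector_distance", "pixel_size", "beam_centre",
           "detector_shape", "grid_shape", "omega_per_image", "omega_start")
  missing <- setdiff(req, names(raw))
  if (length(missing))
    stop("malformed geometry file, missing fields: ",
         paste(missing, collapse = ", "))
  geometry <- mesh_geometry(
    wavelength = raw$wavelength, detector_distance = raw$detector_distance,
    pixel_size = raw$pixel_size, beam_centre = unlist(raw$beam_centre),
    detector_shape = unlist(raw$detector_shape),
    grid_shape = unlist(raw$grid_shape),
    omega_per_image = raw$omega_per_image, omega_start = raw$omega_start)

  sfile <- file.path(path, "scores.csv")
  if (!file.exists(sfile)) stop("no scores.csv in ", path)
  scores <- as.matrix(utils::read.csv(sfile, header = FALSE))
  dimnames(scores) <- NULL
  nr <- geometry$grid_shape[1]; nc <- geometry$grid_shape[2]
  if (!all(dim(scores) == c(nr, nc)))
    stop(sprintf("score grid is %d x %d but geometry says %d x %d",
                 nrow(scores), ncol(scores), nr, nc))

  spots <- vector("list", nr * nc)
  for (r in 0:(nr - 1)) for (cc in 0:(nc - 1)) {
    f <- file.path(path, "spots", sprintf("r%d_c%d.tsv", r, cc))
    if (!file.exists(f)) stop("missing spot table: ", f)
    tab <- utils::read.delim(f, colClasses = "numeric")
    if (!all(c("x", "y", "intensity") %in% names(tab)))
      stop("spot table lacks x/y/intensity columns: ", f)
    spots[[node_index(geometry, r, cc)]] <-
      tab[, c("x", "y", "intensity"), drop = FALSE]
  }
  mesh_scan(geometry, scores, spots)
}

# full-precision ASCII for doubles (round-trips exactly)
fmt_num <- function(x) {
  out <- vapply(x, function(v) formatC(v, digits = 17, format = "g"), "")
  sub("^\\s+", "", out)
}

#' Write a mesh scan as a bundle directory
#'
#' Inverse of [read_scan_bundle()]; numeric values are serialized at full
#' double precision so that a read/write round trip is exact.
#'
#' @param scan a [mesh_scan()].
#' @param path target directory (created if absent).
#' @param ground_truth optional list written as `ground_truth.json`.
#' @return `path`, invisibly.
#' @export
write_scan_bundle <- function(scan, path, ground_truth = NULL) {
  dir.create(file.path(path, "spots"), recursive = TRUE, showWarnings = FALSE)
  g <- scan$geometry
  jsonlite::write_json(
    list(wavelength = g$wavelength, detector_distance = g$detector_distance,
         pixel_size = g$pixel_size, beam_centre = g$beam_centre,
         detector_shape = g$detector_shape, grid_shape = g$grid_shape,
         omega_per_image = g$omega_per_image, omega_start = g$omega_start),
    file.path(path, "geometry.json"), auto_unbox = TRUE, digits = NA)
  writeLines(apply(scan$scores, 1, function(r) paste(fmt_num(r), collapse = ",")),
             file.path(path, "scores.csv"))
  nr <- g$grid_shape[1]; nc <- g$grid_shape[2]
  for (r in 0:(nr - 1)) for (cc in 0:(nc - 1)) {
    s <- node_spots(scan, r, cc)
    lines <- c("x\ty\tintensity",
               if (nrow(s)) paste(fmt_num(s$x), fmt_num(s$y),
                                  fmt_num(s$intensity), sep = "\t"))
    writeLines(lines, file.path(path, "spots", sprintf("r%d_c%d.tsv", r, cc)))
  }
  if (!is.null(ground_truth))
    jsonlite::write_json(ground_truth, file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write the crystal report
#'
#' Emits `crystals.json` (ranked crystal table with fit parameters and the
#' integral signal), `labels.csv` (per-node label grid: -2 multi-pattern,
#' 0 no signal, k >= 1 crystal id) and `meta.json` (analysis configuration
#' and seed).
#'
#' @param result a pipeline result as returned by [run_pipeline()], i.e. a
#'   list with elements `crystals` (data frame) and `labels` (integer
#'   matrix).
#' @param path target directory (created if absent).
#' @param config the [analysis_config()] used (stored in `meta.json`).
#' @return `path`, invisibly.
#' @export
write_crystal_report <- function(result, path, config = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(result$crystals, file.path(path, "crystals.json"),
                       dataframe = "rows", digits = NA)
  writeLines(apply(result$labels, 1, paste, collapse = ","),
             file.path(path, "labels.csv"))
  meta <- list(n_crystals = nrow(result$crystals),
               grid_shape = dim(result$labels))
  if (!is.null(config)) meta$config <- unclass(config)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload a crystal report
#'
#' @param path report directory written by [write_crystal_report()].
#' @return list with `crystals` (data frame) and `labels` (integer matrix).
#' @export
read_crystal_report <- function(path) {
  crystals <- jsonlite::read_json(file.path(path, "crystals.json"),
                                  simplifyVector = TRUE)
  if (length(crystals) == 0) crystals <- empty_crystal_table()
  lines <- readLines(file.path(path, "labels.csv"))
  labels <- do.call(rbind, lapply(strsplit(lines, ","), as.integer))
  list(crystals = as.data.frame(crystals), labels = labels)
}

empty_crystal_table <- function() {
  data.frame(id = integer(0), x0 = numeric(0), y0 = numeric(0),
             a = numeric(0), b = numeric(0), phi = numeric(0),
             H = numeric(0), I = numeric(0), rank = integer(0),
             node_count = integer(0), fit_residual = numeric(0),
             colour = integer(0))
}
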
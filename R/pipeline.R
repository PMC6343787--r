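#' Run the full mesh-scan analysis
#'
#' Orchestrates the workflow: multi-pattern classification, connected
#' diffracting regions, per-region distance matrices, omega-gated average
#' linkage, dendrogram cut, global crystal ids, semi-ellipsoid fits and
#' ranking. Deterministic given the scan and configuration.
#'
#' @param scan a [mesh_scan()] or a bundle directory path (read with
#'   [read_scan_bundle()]).
#' @param config an [analysis_config()].
#' @return list of class `mesh_result`:
#'   \describe{
#'     \item{crystals}{ranked crystal table (id, x0, y0, a, b, phi, H, I,
#'       rank, node_count, colour).}
#'     \item{labels}{integer label grid: -2 multi-pattern, 0 no signal,
#'       k >= 1 crystal id.}
#'     \item{multipattern}{per-node classification table.}
#'     \item{regions}{regions with filled distance matrices.}
#'     \item{dendrograms}{per-region `mesh_dendrogram`.}
#'     \item{log}{per-stage counts.}
#'   }
#' @export
run_pipeline <- function(scan, config = analysis_config()) {
  if (is.character(scan)) scan <- read_scan_bundle(scan)
  stopifnot(inherits(scan, "mesh_scan"))
  log <- list()
  t0 <- proc.time()[3]
  stage <- function(name, value) {
    log[[name]] <<- c(value, elapsed_s = round(proc.time()[3] - t0, 2))
  }

  mp <- classify_multipattern(scan, config)
  stage("multipattern", c(n_nodes = nrow(mp),
                          n_diffracting = sum(mp$score > config$score_floor),
                          n_flagged = sum(mp$is_multipattern)))

  regions <- connected_regions(scan, mp, config)
  stage("regions", c(n_regions = length(regions),
                     n_nodes = sum(vapply(regions, function(r) nrow(r$nodes), 0L))))

  dendros <- vector("list", length(regions))
  assignments <- vector("list", length(regions))
  for (k in seq_along(regions)) {
    regions[[k]] <- region_distance_matrix(regions[[k]], scan, config)
    dend <- weighted_average_linkage(regions[[k]]$D,
                                     regions[[k]]$nodes$omega,
                                     config$omega_gate, config$ray_gate)
    dendros[[k]] <- dend
    assignments[[k]] <- if (dend$n < 2) rep(1L, dend$n)
                        else cut_dendrogram(dend, config$d_cutoff)
  }
  ids <- assign_crystal_ids(regions, assignments)
  n_crystals <- length(ids$crystal_regions)
  stage("clustering", c(n_crystals = n_crystals))

  nr <- scan$geometry$grid_shape[1]; nc <- scan$geometry$grid_shape[2]
  labels <- matrix(0L, nr, nc)
  labels[cbind(mp$row + 1, mp$col + 1)] <-
    ifelse(mp$is_multipattern, -2L, 0L)
  if (n_crystals > 0)
    labels[cbind(ids$nodes$row + 1, ids$nodes$col + 1)] <- ids$nodes$crystal

  fits <- empty_crystal_table()
  if (n_crystals > 0) {
    flagged <- mp[mp$is_multipattern, c("row", "col")]
    fit_rows <- vector("list", n_crystals)
    for (cid in seq_len(n_crystals)) {
      own <- ids$nodes[ids$nodes$crystal == cid, c("row", "col")]
      own$score <- scan$scores[cbind(own$row + 1, own$col + 1)]
      other <- ids$nodes[ids$nodes$crystal != cid, c("row", "col")]
      fit_rows[[cid]] <- fit_crystal_shape(
        own, exclude = rbind(other, flagged),
        grid_shape = scan$geometry$grid_shape,
        config = config, crystal_id = cid)
    }
    fits <- do.call(rbind, fit_rows)
    fits <- rank_crystals(fits)
    fits$colour <- (fits$rank - 1L) %% 9L + 1L
  } else {
    fits$rank <- integer(0)
  }
  stage("shapefit", c(n_fits = nrow(fits),
                      n_fallback = sum(fits$fallback %in% TRUE)))

  structure(list(crystals = fits, labels = labels, multipattern = mp,
                 regions = regions, dendrograms = dendros, log = log),
            class = "mesh_result")
}

#' @export
print.mesh_result <- function(x, ...) {
  cat(sprintf("<mesh_result> %d crystal(s), %d multi-pattern node(s)\n",
              nrow(x$crystals), sum(x$labels == -2L)))
  if (nrow(x$crystals)) {
    top <- utils::head(x$crystals, 5)
    cat("  top crystals (rank, id, I, a, b, H):\n")
    for (i in seq_len(nrow(top)))
      cat(sprintf("   #%d id %d  I=%.2f  a=%.2f b=%.2f H=%.2f\n",
                  top$rank[i], top$id[i], top$I[i], top$a[i], top$b[i],
                  top$H[i]))
  }
  invisible(x)
}

# fixed 9-colour palette for the crystal map; colour index cycles
crystal_palette <- function() {
  c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00",
    "#A65628", "#F781BF", "#00CED1", "#FFD700")
}

#' Render the crystal map
#'
#' Always writes the label grid as `labels.csv` under `path`. With
#' `png = TRUE` also writes `map.png`: crystal regions in a cycling
#' 9-colour palette tinted by diffraction score, multi-pattern zones grey,
#' fitted ellipse outlines overlaid.
#'
#' @param result a `mesh_result` from [run_pipeline()].
#' @param path output directory.
#' @param scan the analysed [mesh_scan()] (needed for score tinting; may
#'   be `NULL` for CSV-only output).
#' @param png write the raster image as well.
#' @return `path`, invisibly.
#' @export
render_map <- function(result, path, scan = NULL, png = FALSE) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  writeLines(apply(result$labels, 1, paste, collapse = ","),
             file.path(path, "labels.csv"))
  if (!png) return(invisible(path))
  lab <- result$labels
  nr <- nrow(lab); nc <- ncol(lab)
  pal <- crystal_palette()
  colour_of <- integer(max(0, nrow(result$crystals)))
  if (nrow(result$crystals))
    colour_of[result$crystals$id] <- result$crystals$colour
  img <- matrix("#FFFFFF", nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    l <- lab[r, cc]
    if (l == -2L) img[r, cc] <- "#808080"
    else if (l >= 1L) {
      base <- pal[colour_of[l]]
      tint <- 1
      if (!is.null(scan)) {
        smax <- max(scan$scores)
        if (smax > 0) tint <- 0.35 + 0.65 * scan$scores[r, cc] / smax
      }
      rgb <- grDevices::col2rgb(base) / 255 * tint
      img[r, cc] <- grDevices::rgb(rgb[1], rgb[2], rgb[3])
    }
  }
  grDevices::png(file.path(path, "map.png"), width = 120 * nc / max(nr, nc) * 6,
                 height = 120 * nr / max(nr, nc) * 6, res = 120)
  op <- graphics::par(mar = c(2, 2, 1, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::plot(NA, xlim = c(-0.5, nc - 0.5), ylim = c(nr - 0.5, -0.5),
                 xlab = "col", ylab = "row", asp = 1)
  graphics::rect(rep(0:(nc - 1), each = nr) - 0.5,
                 rep(0:(nr - 1), times = nc) - 0.5,
                 rep(0:(nc - 1), each = nr) + 0.5,
                 rep(0:(nr - 1), times = nc) + 0.5,
                 col = as.vector(img), border = NA)
  th <- seq(0, 2 * pi, length.out = 120)
  for (i in seq_len(nrow(result$crystals))) {
    cr <- result$crystals[i, ]
    phi <- cr$phi * pi / 180
    ex <- cr$x0 + cr$a * cos(th) * cos(phi) - cr$b * sin(th) * sin(phi)
    ey <- cr$y0 + cr$a * cos(th) * sin(phi) + cr$b * sin(th) * cos(phi)
    graphics::lines(ex, ey, col = "black", lwd = 1.5)
  }
  invisible(path)
}
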
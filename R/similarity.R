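#' Scattered-ray directions of an image's spots
#'
#' Unit vectors from the sample (origin) to each spot's lab-frame position
#' on the detector. Instrument-independent angular comparisons between
#' images are made on these rays.
#'
#' @param spots data frame with columns `x`, `y` (detector pixels).
#' @param geometry a [mesh_geometry()].
#' @return n x 3 matrix of unit vectors.
#' @export
scattered_rays <- function(spots, geometry) {
  xm <- (spots$x - geometry$beam_centre[1]) * geometry$pixel_size
  ym <- (spots$y - geometry$beam_centre[2]) * geometry$pixel_size
  nrm <- sqrt(xm^2 + ym^2 + geometry$detector_distance^2)
  cbind(xm / nrm, ym / nrm, geometry$detector_distance / nrm)
}

#' Angular distance score D between two images
#'
#' The image with fewer spots is the reference (ties: the first argument).
#' For every reference spot the nearest compared-image ray is found; the
#' deviation Delta_i is the angle between the two rays if below `ray_gate`
#' and `ray_gate` otherwise (spots further apart than the gate are not the
#' same spot). D is the root mean square of the Delta_i, so D lies in
#' \[0, ray_gate\] and does not depend on the sizes of the two spot lists.
#'
#' @param spots_a,spots_b spot data frames.
#' @param geometry a [mesh_geometry()].
#' @param ray_gate matching gate, degrees.
#' @return D in degrees, or `NA` ("no comparison") when either list is
#'   empty.
#' @export
distance_score <- function(spots_a, spots_b, geometry, ray_gate = 0.1) {
  if (!nrow(spots_a) || !nrow(spots_b)) return(NA_real_)
  if (nrow(spots_b) < nrow(spots_a)) { tmp <- spots_a; spots_a <- spots_b; spots_b <- tmp }
  ra <- scattered_rays(spots_a, geometry)
  rb <- scattered_rays(spots_b, geometry)
  # nearest ray by maximum cosine; the dense Gram matrix is fast at mesh
  # spot counts (hundreds) and exact
  best <- apply(ra %*% t(rb), 1, max)
  ang <- acos(pmin(1, pmax(-1, best))) * 180 / pi
  sqrt(mean(pmin(ang, ray_gate)^2))
}

#' Geometrically connected diffracting regions
#'
#' Nodes with score above `score_floor` that are not flagged multi-pattern
#' are partitioned into connected components of the grid (8-connectivity by
#' default, so diagonal neighbours connect; set `config$connectivity = 4`
#' to require edge adjacency).
#'
#' @param scan a [mesh_scan()].
#' @param multipattern result of [classify_multipattern()] (or `NULL` for
#'   no flags).
#' @param config an [analysis_config()].
#' @return list of regions; each region is a list with `nodes` (data frame
#'   `row`, `col`, `omega`, 0-based indices) and `D` (`NULL` until filled
#'   by [region_distance_matrix()]).
#' @export
connected_regions <- function(scan, multipattern = NULL,
                              config = analysis_config()) {
  nr <- scan$geometry$grid_shape[1]; nc <- scan$geometry$grid_shape[2]
  mask <- scan$scores > config$score_floor
  if (!is.null(multipattern)) {
    flag <- matrix(FALSE, nr, nc)
    flag[cbind(multipattern$row + 1, multipattern$col + 1)] <-
      multipattern$is_multipattern
    mask <- mask & !flag
  }
  if (config$connectivity == 8L) {
    nb <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(r0, c0), 1)
    lab[r0, c0] <- cur
    while (nrow(queue)) {
      p <- queue[1, , drop = TRUE]
      queue <- queue[-1, , drop = FALSE]
      for (j in seq_len(nrow(nb))) {
        rr <- p[1] + nb[j, 1]; cc <- p[2] + nb[j, 2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
  }
  out <- vector("list", cur)
  for (k in seq_len(cur)) {
    w <- which(lab == k, arr.ind = TRUE)
    w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
    nodes <- data.frame(row = w[, 1] - 1L, col = w[, 2] - 1L)
    nodes$omega <- node_omega(scan$geometry, nodes$row, nodes$col)
    out[[k]] <- list(nodes = nodes, D = NULL)
  }
  out
}

#' Fill a region's condensed distance matrix
#'
#' Computes [distance_score()] for every pair of the region's nodes, in the
#' standard condensed order (pairs (i, j), i < j, j varying fastest as in
#' [stats::dist()]). Pairs involving a node without spots get the maximal
#' score `ray_gate`.
#'
#' @param region one element of [connected_regions()].
#' @param scan the [mesh_scan()].
#' @param config an [analysis_config()].
#' @return the region with `D` set (numeric, length n(n-1)/2).
#' @export
region_distance_matrix <- function(region, scan, config = analysis_config()) {
  nodes <- region$nodes
  n <- nrow(nodes)
  sp <- lapply(seq_len(n), function(i)
    node_spots(scan, nodes$row[i], nodes$col[i]))
  rays <- lapply(sp, function(s)
    if (nrow(s)) scattered_rays(s, scan$geometry) else NULL)
  D <- numeric(if (n > 1) n * (n - 1) / 2 else 0)
  pos <- 0L
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in (i + 1):n) {
      pos <- pos + 1L
      ra <- rays[[i]]; rb <- rays[[j]]
      if (is.null(ra) || is.null(rb)) { D[pos] <- config$ray_gate; next }
      if (nrow(rb) < nrow(ra)) { tmp <- ra; ra <- rb; rb <- tmp }
      best <- apply(ra %*% t(rb), 1, max)
      ang <- acos(pmin(1, pmax(-1, best))) * 180 / pi
      D[pos] <- sqrt(mean(pmin(ang, config$ray_gate)^2))
    }
  }
  region$D <- D
  region
}
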
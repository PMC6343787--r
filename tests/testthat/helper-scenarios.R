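# shared builders and independent oracles for the test suite

test_cell <- c(68, 72, 78, 90, 90, 90)

# one still image of a single randomly oriented lattice at default MX-like
# geometry; uses the current RNG state
sim_single_image <- function(geometry = mesh_geometry(), omega = 0,
                             halfwidth = 0.1, resolution = 2.0,
                             jitter = 0.3, noise = 0,
                             orientation = random_rotation()) {
  simulate_still_spots(
    list(list(unit_cell = test_cell, orientation = orientation)),
    geometry, omega,
    excitation_halfwidth = halfwidth, resolution_limit = resolution,
    centroid_sigma_px = jitter, noise_spots = noise)
}

# a compact two-crystal mesh with known ground truth
two_crystal_config <- function(seed, grid = c(10, 10),
                               orientations = list(random_rotation(),
                                                   random_rotation())) {
  g <- mesh_geometry(grid_shape = grid)
  far <- grid - 3
  crys <- list(
    crystal_spec(centre = c(2, 2), semi_axes = c(2.2, 1.4), tilt = 20,
                 orientation = orientations[[1]], peak_score = 12),
    crystal_spec(centre = far, semi_axes = c(2, 1.2), tilt = 100,
                 orientation = orientations[[2]], peak_score = 8))
  simulation_config(g, crys, seed = seed)
}

# --- independent oracles -------------------------------------------------

# brute-force DDV histogram via an explicit double loop
brute_ddv_counts <- function(q, bins, hist_max) {
  counts <- integer(bins)
  w <- hist_max / bins
  n <- nrow(q)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((q[i, ] - q[j, ])^2))
    if (d < hist_max) {
      b <- 1L + floor(d / w)
      counts[b] <- counts[b] + 1L
    }
  }
  counts
}

# strict local minima by direct comparison of immediate neighbours
brute_local_minima <- function(x) {
  n <- length(x)
  which(vapply(seq_len(n), function(i)
    i > 1 && i < n && x[i] < x[i - 1] && x[i] < x[i + 1], TRUE))
}

# recursive flood fill, independent of the package's BFS labelling
flood_fill_count <- function(mask, eight = TRUE) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  nb <- if (eight) cbind(c(-1,-1,-1,0,0,1,1,1), c(-1,0,1,-1,1,-1,0,1))
        else cbind(c(-1,1,0,0), c(0,0,-1,1))
  fill <- function(r, c) {
    stack <- list(c(r, c))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (p[1] < 1 || p[1] > nr || p[2] < 1 || p[2] > nc) next
      if (!mask[p[1], p[2]] || seen[p[1], p[2]]) next
      seen[p[1], p[2]] <<- TRUE
      for (j in seq_len(nrow(nb)))
        stack[[length(stack) + 1]] <- c(p[1] + nb[j, 1], p[2] + nb[j, 2])
    }
  }
  count <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc))
    if (mask[r, c] && !seen[r, c]) { count <- count + 1L; fill(r, c) }
  count
}

# cophenetic distance matrix implied by a mesh_dendrogram
dendrogram_cophenetic <- function(dend) {
  n <- dend$n
  members <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  for (s in seq_len(nrow(dend$merge))) {
    get <- function(v) if (v < 0) members[[-v]] else members[[n + v]]
    a <- get(dend$merge[s, 1]); b <- get(dend$merge[s, 2])
    coph[a, b] <- coph[b, a] <- dend$height[s]
    members[[n + s]] <- c(a, b)
  }
  coph
}
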
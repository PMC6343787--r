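#' Diffraction vectors from spot positions
#'
#' Converts detector spot centroids to reciprocal-space diffraction vectors
#' q = (s_hat - z_hat) / lambda, where s_hat is the unit vector from the
#' sample to the spot's lab position (detector plane normal to the beam at
#' `detector_distance`, beam along +z). |q| = 2 sin(theta) / lambda.
#'
#' @param spots data frame with columns `x`, `y` (detector pixels).
#' @param geometry a [mesh_geometry()].
#' @return n x 3 matrix of q vectors in 1/Angstrom.
#' @export
spots_to_reciprocal <- function(spots, geometry) {
  xm <- (spots$x - geometry$beam_centre[1]) * geometry$pixel_size
  ym <- (spots$y - geometry$beam_centre[2]) * geometry$pixel_size
  nrm <- sqrt(xm^2 + ym^2 + geometry$detector_distance^2)
  cbind(xm / nrm, ym / nrm, geometry$detector_distance / nrm - 1) /
    geometry$wavelength
}

#' Histogram of difference-diffraction-vector lengths
#'
#' Counts |q_i - q_j| over all unordered pairs i < j into `bins` equal bins
#' spanning \[0, hist_max) with half-open intervals; pair distances at or
#' beyond `hist_max` are discarded (the analysis only uses the short range).
#'
#' @param q_vectors n x 3 matrix from [spots_to_reciprocal()].
#' @param bins number of bins.
#' @param hist_max upper bound, 1/Angstrom.
#' @return list of class `ddv_histogram`: `counts` (length `bins`),
#'   `bin_edges` (length `bins + 1`), `mids`, `n_pairs` (total pairs
#'   including overflow).
#' @export
ddv_histogram <- function(q_vectors, bins = 100L, hist_max = 1 / 25) {
  n <- nrow(q_vectors)
  edges <- seq(0, hist_max, length.out = bins + 1)
  if (n < 2) {
    counts <- integer(bins)
  } else {
    d <- stats::dist(q_vectors)
    counts <- tabulate(1L + floor(d[d < hist_max] / (hist_max / bins)),
                       nbins = bins)
  }
  structure(list(counts = counts, bin_edges = edges,
                 mids = (edges[-1] + edges[-(bins + 1)]) / 2,
                 n_pairs = if (n < 2) 0L else n * (n - 1) / 2),
            class = "ddv_histogram")
}

#' Cumulative DDV histogram over a mesh scan
#'
#' Element-wise sum of the per-node DDV histograms over all nodes with at
#' least two spots. Its local minima locate the baseline regions shared by
#' every image of the scan.
#'
#' @param scan a [mesh_scan()].
#' @param config an [analysis_config()].
#' @return a `ddv_histogram` (counts summed over nodes).
#' @export
cumulative_histogram <- function(scan, config = analysis_config()) {
  acc <- NULL
  for (sp in scan$spots) {
    if (nrow(sp) < 2) next
    h <- ddv_histogram(spots_to_reciprocal(sp, scan$geometry),
                       config$hist_bins, config$hist_max)
    if (is.null(acc)) acc <- h
    else { acc$counts <- acc$counts + h$counts
           acc$n_pairs <- acc$n_pairs + h$n_pairs }
  }
  if (is.null(acc))
    acc <- ddv_histogram(matrix(numeric(0), 0, 3),
                         config$hist_bins, config$hist_max)
  acc
}

#' AMPD local minima of a signal
#'
#' Automatic multiscale-based peak detection applied to the negated signal:
#' the signal is linearly detrended, a local-extremum scalogram is built
#' over window scales k = 1..ceiling(n/2)-1 (entry 0 where the point
#' exceeds both neighbours at lag k, penalty 1 elsewhere, including points
#' too close to either end), the scale lambda minimising the scalogram
#' row sum is selected (smallest scale on ties), and indices that are
#' extrema at every scale up to lambda are returned.
#'
#' @param signal numeric vector, length >= 5.
#' @param max_scale optional cap on the largest window scale considered.
#' @return integer vector of minima positions (ascending); empty for flat
#'   or monotone signals.
#' @export
ampd_local_minima <- function(signal, max_scale = NULL) {
  n <- length(signal)
  if (n < 5) stop("signal must have length >= 5")
  x <- -as.numeric(signal)
  i <- seq_len(n)
  x <- x - stats::lm.fit(cbind(1, i), x)$fitted.values
  L <- ceiling(n / 2) - 1
  if (!is.null(max_scale)) L <- min(L, as.integer(max_scale))
  # tolerance keeps detrending round-off from fabricating extrema on flat
  # or exactly linear signals
  eps <- sqrt(.Machine$double.eps) * max(abs(x), 1)
  M <- matrix(1L, L, n)
  for (k in seq_len(L)) {
    idx <- (k + 1):(n - k)
    hit <- x[idx] > x[idx - k] + eps & x[idx] > x[idx + k] + eps
    M[k, idx[hit]] <- 0L
  }
  lambda <- which.min(rowSums(M))
  which(colSums(M[seq_len(lambda), , drop = FALSE]) == 0)
}

#' Baseline regions of a cumulative DDV histogram
#'
#' Locates AMPD minima of the cumulative histogram, keeps those whose
#' count is low (at most the lower quartile plus 1% of the dynamic range
#' — higher minima are dips inside the forest of closely spaced
#' intra-lattice peaks and still carry lattice counts), expands each into
#' its surrounding low-count plateau, and adds every bin with zero
#' cumulative count (a bin empty over the whole mesh provably contains no
#' intra-lattice distance of any of its crystals). One guard bin is then
#' trimmed from each side of every region longer than two bins: peak
#' positions are fixed lengths shared by all images, but their measured
#' tails bleed into the adjacent bin and would otherwise bias per-image
#' slopes for strongly diffracting orientations. The returned bin set is
#' computed once per mesh and reused for every per-image baseline fit.
#'
#' @param cum_counts numeric vector of cumulative histogram counts.
#' @param config an [analysis_config()].
#' @return integer vector of baseline bin indices.
#' @export
baseline_regions <- function(cum_counts, config = analysis_config()) {
  mins <- ampd_local_minima(cum_counts)
  n <- length(cum_counts)
  depth <- stats::quantile(cum_counts, 0.25) +
    0.01 * (max(cum_counts) - min(cum_counts))
  keep <- mins[cum_counts[mins] <= depth]
  out <- which(cum_counts == 0)
  for (m in keep) {
    j <- m; while (j > 1 && cum_counts[j - 1] <= depth) j <- j - 1
    k <- m; while (k < n && cum_counts[k + 1] <= depth) k <- k + 1
    out <- c(out, j:k)
  }
  out <- sort(unique(out))
  if (!length(out)) return(out)
  runs <- split(out, cumsum(c(1, diff(out) != 1)))
  trimmed <- lapply(runs, function(run)
    if (length(run) > 2) run[-c(1, length(run))] else run)
  sort(unname(unlist(trimmed)))
}

#' Baseline slope of a DDV histogram
#'
#' Ordinary least-squares slope of counts versus bin centre (1/Angstrom),
#' restricted to the baseline bins that fall inside `fit_range`. The slope
#' k0 carries units of Angstrom (counts per 1/Angstrom).
#'
#' @param histogram a `ddv_histogram`.
#' @param baseline_bins integer bin indices (from [baseline_regions()]).
#' @param fit_range length-2 numeric, 1/Angstrom.
#' @return slope k0, or `NA` when fewer than 3 usable bins remain.
#' @export
baseline_slope <- function(histogram, baseline_bins,
                           fit_range = c(1e-3, 40e-3)) {
  mids <- histogram$mids[baseline_bins]
  use <- mids >= fit_range[1] & mids <= fit_range[2]
  if (sum(use) < 3) return(NA_real_)
  xx <- mids[use]; yy <- histogram$counts[baseline_bins][use]
  unname(stats::lm.fit(cbind(1, xx), yy)$coefficients[2])
}

#' Area of the Ewald-sphere cap containing the spots
#'
#' S = 2 pi (1/lambda)^2 (1 - cos 2theta_max), with 2theta_max the largest
#' scattering angle among the spots.
#'
#' @param q_vectors n x 3 matrix of diffraction vectors (n >= 1).
#' @param wavelength Angstrom.
#' @return cap area in 1/Angstrom^2.
#' @export
ewald_cap_area <- function(q_vectors, wavelength) {
  if (!nrow(q_vectors)) stop("ewald_cap_area needs at least one spot")
  qn <- sqrt(rowSums(q_vectors^2))
  theta_max <- asin(min(1, max(qn) * wavelength / 2))
  2 * pi * (1 / wavelength)^2 * (1 - cos(2 * theta_max))
}

#' Multi-pattern statistic K
#'
#' K = k0 * S / N^2: the baseline slope normalised by the spot density N/S
#' and the spot count N. Expressed in 1/Angstrom.
#'
#' @param k0 baseline slope (Angstrom).
#' @param N spot count.
#' @param S Ewald cap area (1/Angstrom^2).
#' @return K in 1/Angstrom.
#' @export
k_statistic <- function(k0, N, S) {
  stopifnot(N > 0, S > 0)
  k0 * S / N^2
}

#' Classify every node of a mesh scan for multi-pattern diffraction
#'
#' Baseline regions are determined once from the mesh-wide cumulative DDV
#' histogram, then each node's histogram is fitted and its K computed.
#' Nodes whose score is at or below `score_floor`, or with fewer than
#' `min_spots_for_k` spots, or with an unusable baseline fit are marked
#' invalid and treated as single-pattern.
#'
#' @param scan a [mesh_scan()].
#' @param config an [analysis_config()].
#' @return data frame with one row per node (row-major): `row`, `col`,
#'   `score`, `N`, `k0`, `S`, `K`, `valid`, `is_multipattern`; the baseline
#'   bin indices are attached as attribute `"baseline_bins"`.
#' @export
classify_multipattern <- function(scan, config = analysis_config()) {
  g <- scan$geometry
  nr <- g$grid_shape[1]; nc <- g$grid_shape[2]
  cum <- cumulative_histogram(scan, config)
  bl <- baseline_regions(cum$counts, config)
  n <- nr * nc
  res <- data.frame(row = rep(0:(nr - 1), each = nc),
                    col = rep(0:(nc - 1), times = nr),
                    score = as.vector(t(scan$scores)),
                    N = vapply(scan$spots, nrow, 0L),
                    k0 = NA_real_, S = NA_real_, K = NA_real_,
                    valid = FALSE, is_multipattern = FALSE)
  for (i in seq_len(n)) {
    if (res$score[i] <= config$score_floor) next
    if (res$N[i] < config$min_spots_for_k) next
    q <- spots_to_reciprocal(scan$spots[[i]], g)
    h <- ddv_histogram(q, config$hist_bins, config$hist_max)
    k0 <- baseline_slope(h, bl, config$fit_range)
    if (is.na(k0)) next
    S <- ewald_cap_area(q, g$wavelength)
    res$k0[i] <- k0
    res$S[i] <- S
    res$K[i] <- k_statistic(k0, res$N[i], S)
    res$valid[i] <- TRUE
    res$is_multipattern[i] <- res$K[i] > config$k_threshold
  }
  attr(res, "baseline_bins") <- bl
  res
}
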
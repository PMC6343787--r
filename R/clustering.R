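#' Omega-gated weighted average linkage
#'
#' Agglomerative hierarchical clustering of a region's nodes from the
#' condensed distance matrix. The distance between two clusters is the
#' weighted mean of the cross-pair distances, with weight 0 for pairs of
#' images taken more than `omega_gate` degrees apart in omega and weight 1
#' otherwise: pairs of stills at distant goniometer angles cannot share
#' spots, so their (saturated) distance carries no information. When every
#' cross pair is gated out, the cluster distance falls back to `ray_gate`
#' (maximally dissimilar), so such clusters never merge below the cutoff.
#' With all weights equal to 1 the procedure reduces to textbook
#' (unweighted) average linkage. The closest pair merges first; ties break
#' towards the smallest pair of cluster indices, for reproducibility.
#'
#' @param D condensed distance vector (order as in [stats::dist()]) over n
#'   nodes.
#' @param omegas per-node omega angles, degrees (length n).
#' @param omega_gate degrees.
#' @param ray_gate fallback distance for fully gated cluster pairs,
#'   degrees.
#' @return object of class `mesh_dendrogram`: list with `merge` (hclust
#'   convention: negative entries are leaves), `height`, `n`. Empty (`n`
#'   merges = 0) for a single node.
#' @export
weighted_average_linkage <- function(D, omegas, omega_gate = 0.5,
                                     ray_gate = 0.1) {
  n <- length(omegas)
  if (n * (n - 1) / 2 != length(D))
    stop("condensed matrix length does not match number of nodes")
  if (n < 2)
    return(structure(list(merge = matrix(0L, 0, 2), height = numeric(0),
                          n = n), class = "mesh_dendrogram"))
  Dm <- matrix(0, n, n)
  Dm[lower.tri(Dm)] <- D
  Dm <- Dm + t(Dm)
  W <- outer(omegas, omegas, function(a, b) as.numeric(abs(a - b) <= omega_gate))
  SW <- W            # pairwise weight sums between current clusters
  SD <- W * Dm       # pairwise weighted distance sums
  active <- seq_len(n)          # active cluster ids in index order
  id <- -seq_len(n)             # hclust-style id of each active cluster
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  cluster_dist <- function(a, b) {
    if (SW[a, b] > 0) SD[a, b] / SW[a, b] else ray_gate
  }
  for (step in seq_len(n - 1)) {
    m <- length(active)
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      d <- cluster_dist(active[i], active[j])
      if (d < best - 1e-15) { best <- d; bi <- i; bj <- j }
    }
    a <- active[bi]; b <- active[bj]
    merge[step, ] <- c(id[bi], id[bj])
    height[step] <- best
    # merged cluster stored in slot a; weighted sums are additive
    others <- active[-c(bi, bj)]
    SW[a, others] <- SW[others, a] <- SW[a, others] + SW[b, others]
    SD[a, others] <- SD[others, a] <- SD[a, others] + SD[b, others]
    active <- c(active[-c(bi, bj)], a)
    id <- c(id[-c(bi, bj)], step)
    # keep active list in stable order of first formation for tie-breaking
    ord <- order(match(active, seq_len(n)))
    active <- active[ord]; id <- id[ord]
  }
  structure(list(merge = merge, height = height, n = n),
            class = "mesh_dendrogram")
}

#' @export
print.mesh_dendrogram <- function(x, ...) {
  cat(sprintf("<mesh_dendrogram> %d leaves, %d merges, height range [%g, %g]\n",
              x$n, nrow(x$merge),
              if (length(x$height)) min(x$height) else NA,
              if (length(x$height)) max(x$height) else NA))
  invisible(x)
}

#' Linkage table of a dendrogram
#'
#' Standard linkage-matrix layout for export and plotting: one row per
#' merge with the two child cluster ids (leaves are 1..n, merges continue
#' at n+1), the linkage distance, and the merged cluster size.
#'
#' @param dendrogram a `mesh_dendrogram`.
#' @return data frame with columns `cluster_i`, `cluster_j`, `distance`,
#'   `size`.
#' @export
linkage_table <- function(dendrogram) {
  n <- dendrogram$n
  m <- nrow(dendrogram$merge)
  sizes <- numeric(m)
  conv <- function(v) ifelse(v < 0, -v, n + v)
  size_of <- function(v) ifelse(v < 0, 1, sizes[pmax(v, 1)])
  for (i in seq_len(m))
    sizes[i] <- sum(size_of(dendrogram$merge[i, ]))
  data.frame(cluster_i = conv(dendrogram$merge[, 1]),
             cluster_j = conv(dendrogram$merge[, 2]),
             distance = dendrogram$height,
             size = sizes)
}

#' Cut a dendrogram at a fixed linkage distance
#'
#' Flat clusters are the maximal groups formed by applying every merge
#' whose linkage distance is strictly below `d_cutoff`. Labels are
#' contiguous, numbered by first node appearance.
#'
#' @param dendrogram a `mesh_dendrogram`.
#' @param d_cutoff degrees.
#' @return integer vector of cluster labels (length n).
#' @export
cut_dendrogram <- function(dendrogram, d_cutoff = 0.093) {
  n <- dendrogram$n
  if (n == 0) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  reps <- integer(nrow(dendrogram$merge))  # representative leaf per merge
  for (s in seq_len(nrow(dendrogram$merge))) {
    ch <- dendrogram$merge[s, ]
    leaf <- function(v) if (v < 0) -v else reps[v]
    la <- leaf(ch[1]); lb <- leaf(ch[2])
    reps[s] <- la
    if (dendrogram$height[s] < d_cutoff) {
      ra <- find(la); rb <- find(lb)
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  as.integer(factor(roots, levels = unique(roots)))
}

#' Combine per-region cluster assignments into a global crystal list
#'
#' Assigns globally unique crystal ids across regions (region order, then
#' local label order); singleton clusters are retained as crystals.
#'
#' @param regions list of regions (with `nodes`).
#' @param assignments list of per-region label vectors from
#'   [cut_dendrogram()] (a single-node region may have an empty dendrogram;
#'   pass `1L` or leave as produced by [run_pipeline()]).
#' @return list with `nodes` (data frame `row`, `col`, `crystal`) and
#'   `crystal_regions` (integer vector: region index of each crystal id).
#' @export
assign_crystal_ids <- function(regions, assignments) {
  stopifnot(length(regions) == length(assignments))
  nodes <- list(); region_of <- integer(0)
  offset <- 0L
  for (k in seq_along(regions)) {
    lab <- assignments[[k]]
    if (!length(lab)) lab <- rep(1L, nrow(regions[[k]]$nodes))
    nk <- max(lab)
    nodes[[k]] <- data.frame(row = regions[[k]]$nodes$row,
                             col = regions[[k]]$nodes$col,
                             crystal = offset + lab)
    region_of <- c(region_of, rep(k, nk))
    offset <- offset + nk
  }
  list(nodes = do.call(rbind, nodes), crystal_regions = region_of)
}
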
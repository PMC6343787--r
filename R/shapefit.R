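#' Semi-ellipsoid surface
#'
#' E(x, y) = H * sqrt(max(0, 1 - u^2/a^2 - v^2/b^2)) with
#' u = (x - x0) cos(phi) + (y - y0) sin(phi),
#' v = -(x - x0) sin(phi) + (y - y0) cos(phi).
#' Mesh coordinates are x = column, y = row (grid units, continuous).
#'
#' @param x,y numeric vectors of mesh coordinates.
#' @param params named list or vector with `H`, `x0`, `y0`, `a`, `b`,
#'   `phi` (phi in degrees).
#' @return surface values (0 outside the ellipse).
#' @export
semi_ellipsoid <- function(x, y, params) {
  p <- as.list(params)
  phi <- p$phi * pi / 180
  u <- (x - p$x0) * cos(phi) + (y - p$y0) * sin(phi)
  v <- -(x - p$x0) * sin(phi) + (y - p$y0) * cos(phi)
  p$H * sqrt(pmax(0, 1 - u^2 / p$a^2 - v^2 / p$b^2))
}

# classic differential evolution (rand/1/bin) over box bounds, minimising
# fn(vector). Deterministic given the RNG state. Returns the best member,
# its value, and the best-so-far trace per generation.
diff_evolution <- function(fn, lower, upper, np = 45L, maxiter = 150L,
                           F = 0.7, CR = 0.9) {
  d <- length(lower)
  pop <- matrix(stats::runif(np * d), np, d)
  pop <- sweep(sweep(pop, 2, upper - lower, `*`), 2, lower, `+`)
  val <- apply(pop, 1, fn)
  trace <- numeric(maxiter)
  for (gen in seq_len(maxiter)) {
    for (i in seq_len(np)) {
      idx <- sample.int(np, 3)
      while (any(idx == i)) idx <- sample.int(np, 3)
      mut <- pop[idx[1], ] + F * (pop[idx[2], ] - pop[idx[3], ])
      mut <- pmin(pmax(mut, lower), upper)
      cross <- stats::runif(d) < CR
      cross[sample.int(d, 1)] <- TRUE
      cand <- ifelse(cross, mut, pop[i, ])
      cv <- fn(cand)
      if (cv <= val[i]) { pop[i, ] <- cand; val[i] <- cv }
    }
    trace[gen] <- min(val)
  }
  best <- which.min(val)
  list(par = pop[best, ], value = val[best], trace = trace)
}

#' Fit a semi-ellipsoid to one crystal's score diagram
#'
#' Minimises the weighted least-squares objective
#' F(theta) = sum_i alpha_i (E(x_i, y_i; theta) - s_i)^2 over an evaluation
#' neighbourhood: the crystal's own nodes contribute their scores with
#' weight 1; no-diffraction nodes inside the crystal's bounding box dilated
#' by 2 nodes contribute target 0 with weight `penalty_weight` (penalising
#' fitted volume hanging over empty mesh area); nodes belonging to other
#' crystals or flagged multi-pattern are excluded. Global optimisation by
#' differential evolution with a fixed seed, followed by a bounded
#' local polish of the best member; the reported fit is canonicalised to
#' a >= b with phi in \[0, 180).
#'
#' Bounds: x0, y0 within the dilated bounding box; a, b in (0.3, max grid
#' dimension); H in (0, 2 max score]; phi in \[0, 180).
#'
#' @param nodes data frame with columns `row`, `col`, `score` for the
#'   crystal's own nodes (scores > 0).
#' @param exclude optional data frame `row`, `col` of nodes to leave out of
#'   the evaluation neighbourhood (other crystals, multi-pattern zones).
#' @param grid_shape length-2 integer (n_rows, n_cols).
#' @param config an [analysis_config()] (penalty weight, DE seed).
#' @param crystal_id id recorded in the result and mixed into the DE seed
#'   so fits are independent yet reproducible.
#' @return one-row data frame of class columns: `id`, `x0`, `y0`, `a`,
#'   `b`, `phi`, `H`, `I`, `fit_residual`, `node_count`, `fallback`.
#' @export
fit_crystal_shape <- function(nodes, exclude = NULL, grid_shape,
                              config = analysis_config(), crystal_id = 1L) {
  stopifnot(nrow(nodes) >= 1, any(nodes$score > 0))
  dil <- 2L
  r_rng <- pmin(pmax(range(nodes$row) + c(-dil, dil), 0), grid_shape[1] - 1)
  c_rng <- pmin(pmax(range(nodes$col) + c(-dil, dil), 0), grid_shape[2] - 1)
  hood <- expand.grid(row = r_rng[1]:r_rng[2], col = c_rng[1]:c_rng[2])
  key <- function(d) d$row * grid_shape[2] + d$col
  own <- key(nodes)
  hood <- hood[!(key(hood) %in% own), ]
  if (!is.null(exclude) && nrow(exclude))
    hood <- hood[!(key(hood) %in% key(exclude)), ]
  xx <- c(nodes$col, hood$col)
  yy <- c(nodes$row, hood$row)
  ss <- c(nodes$score, rep(0, nrow(hood)))
  ww <- c(rep(1, nrow(nodes)), rep(config$penalty_weight, nrow(hood)))
  smax <- max(nodes$score)
  lower <- c(H = 1e-6, x0 = c_rng[1], y0 = r_rng[1], a = 0.3, b = 0.3, phi = 0)
  upper <- c(H = 2 * smax, x0 = c_rng[2], y0 = r_rng[2],
             a = max(grid_shape), b = max(grid_shape), phi = 180)
  obj <- function(p) {
    e <- semi_ellipsoid(xx, yy, list(H = p[1], x0 = p[2], y0 = p[3],
                                     a = p[4], b = p[5], phi = p[6]))
    sum(ww * (e - ss)^2)
  }
  fit <- withr_seed(config$de_seed + crystal_id, {
    de <- diff_evolution(obj, lower, upper)
    pol <- tryCatch(
      stats::optim(de$par, obj, method = "L-BFGS-B",
                   lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(pol) && pol$value <= de$value)
      list(par = pol$par, value = pol$value, trace = de$trace)
    else de
  })
  fallback <- FALSE
  p <- fit$par
  if (!all(is.finite(p)) || p[1] <= 0) {
    # optimiser failure: report bounding-box dimensions
    fallback <- TRUE
    p <- c(smax, mean(range(nodes$col)), mean(range(nodes$row)),
           max(0.5, diff(range(nodes$col)) / 2 + 0.5),
           max(0.5, diff(range(nodes$row)) / 2 + 0.5), 0)
  }
  names(p) <- c("H", "x0", "y0", "a", "b", "phi")
  if (p["b"] > p["a"]) {   # canonical form: a >= b
    p[c("a", "b")] <- p[c("b", "a")]
    p["phi"] <- p["phi"] + 90
  }
  p["phi"] <- p["phi"] %% 180
  out <- data.frame(id = crystal_id, x0 = unname(p["x0"]), y0 = unname(p["y0"]),
                    a = unname(p["a"]), b = unname(p["b"]),
                    phi = unname(p["phi"]), H = unname(p["H"]),
                    I = 2 / 3 * pi * unname(p["a"] * p["b"] * p["H"]),
                    fit_residual = fit$value, node_count = nrow(nodes),
                    fallback = fallback)
  attr(out, "trace") <- fit$trace
  out
}

# evaluate expr under a temporary RNG state (restores the caller's state)
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  expr
}

#' Rank crystals by integral diffraction signal
#'
#' Descending by I = (2/3) pi a b H, with a stable tie-break on crystal
#' id. Adds a `rank` column.
#'
#' @param fits data frame of crystal fits (rows from
#'   [fit_crystal_shape()]).
#' @return the fits reordered, with `rank`.
#' @export
rank_crystals <- function(fits) {
  if (!nrow(fits)) { fits$rank <- integer(0); return(fits) }
  ord <- order(-fits$I, fits$id)
  fits <- fits[ord, , drop = FALSE]
  fits$rank <- seq_len(nrow(fits))
  rownames(fits) <- NULL
  fits
}
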
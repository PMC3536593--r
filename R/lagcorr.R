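#' Characteristic response time of a species
#'
#' Estimates the per-species timescale (the "rate limitingness") as the mean
#' over samples of |X(t_k) - X(t_{k-1})| / |dX/dt at t_k|, with the
#' derivative taken from the Stineman interpolant of the series. This bounds
#' the lag grid of the correlation analysis.
#'
#' @details The derivative in the denominator is meant to be the slope of
#' the underlying concentration curve. For series that carry measurement
#' errors the slope is therefore taken from a cross-validated smoothing
#' spline of the series — an interpolant through noisy points tracks the
#' noise, its slopes scale like increment/step, and the estimator would
#' collapse to the sampling step regardless of the dynamics. Error-free
#' series use the Stineman interpolant slopes directly.
#'
#' @param ts a [timeseries_set()].
#' @param i species name or column index.
#' @return The estimated timescale in hours.
#' @export
species_lag <- function(ts, i) {
  stopifnot(inherits(ts, "tlc_timeseries"))
  x <- ts$values[, i]
  noisy <- !is.null(ts$errors) && any(ts$errors[, i] > 0) &&
    length(ts$times) >= 10L
  dx <- if (noisy) {
    fit <- tryCatch(
      stats::smooth.spline(ts$times, x, cv = FALSE),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      derivative(ts$times, x)
    } else {
      stats::predict(fit, ts$times, deriv = 1L)$y
    }
  } else {
    derivative(ts$times, x)
  }
  m <- length(x)
  inc <- abs(x[-1L] - x[-m])
  slope <- abs(dx[-1L])
  keep <- slope > 0
  if (any(!keep)) {
    warning(sum(!keep), " term(s) with zero derivative skipped in lag ",
            "estimation", call. = FALSE)
  }
  if (!any(keep)) {
    stop("series uninformative for lag estimation", call. = FALSE)
  }
  mean(inc[keep] / slope[keep])
}

#' Lag grid for the correlation tensor
#'
#' Builds the discrete set of candidate lags: multiples of the sampling step
#' from 0 up to the minimum over species of the characteristic timescale
#' ([species_lag()]). Lags are additionally capped so that at least
#' `cfg$lags$min_pairs` overlapping sample pairs remain.
#'
#' @param ts a uniformly sampled [timeseries_set()].
#' @param cfg configuration list from [tlc_config()].
#' @return An object of class `lag_grid` with fields `step`, `lags`,
#'   `tau_species`, `tau_min`.
#' @export
lag_grid <- function(ts, cfg = tlc_config()) {
  stopifnot(inherits(ts, "tlc_timeseries"))
  dt <- diff(ts$times)
  if (diff(range(dt)) > 1e-8 * mean(dt)) {
    stop("lag_grid requires uniform sampling; resample first", call. = FALSE)
  }
  step <- mean(dt) * cfg$lags$stride
  taus <- vapply(ts$species, function(sp) species_lag(ts, sp), numeric(1L))
  tau_min <- min(taus)
  lmax_pairs <- length(ts$times) - cfg$lags$min_pairs
  lmax <- min(floor(tau_min / step + 1e-12), lmax_pairs)
  if (lmax < 1L) {
    if (tau_min < step) {
      warning("minimum species timescale below one sampling step; ",
              "lag grid reduced to {0}", call. = FALSE)
    }
    lmax <- 0L
  }
  structure(
    list(step = step, lags = step * (0:lmax), tau_species = taus,
         tau_min = tau_min),
    class = "lag_grid"
  )
}

#' @export
print.lag_grid <- function(x, ...) {
  cat(sprintf("Lag grid: %d lags, step %.4g h, bound tau_min = %.4g h\n",
              length(x$lags), x$step, x$tau_min))
  invisible(x)
}

#' Voronoi pair-density estimate on a 2-D scatter
#'
#' Tessellates the scatter into Voronoi cells, clips unbounded hull cells to
#' the data bounding box expanded by half the median nearest-neighbour
#' distance, and returns per-point densities 1/(n Area) so that the density
#' integrates to one over the clipped region. Degenerate scatters (< 4
#' points, collinear, or coincident) fall back to uniform density.
#'
#' @param points numeric matrix with two columns.
#' @return List with `density`, `area`, `weight` (densities renormalised to
#'   sum to one, the weights used by [lagged_covariance()]), and `degenerate`.
#' @export
voronoi_density <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L)
  n <- nrow(points)
  uniform <- function(msg = NULL) {
    if (!is.null(msg)) warning(msg, call. = FALSE)
    list(density = rep(1 / max(n, 1L), n), area = rep(1, n),
         weight = rep(1 / max(n, 1L), n), degenerate = TRUE)
  }
  if (n < 4L) return(uniform())
  ctr <- sweep(points, 2L, colMeans(points))
  sv <- svd(ctr)$d
  if (sv[1L] <= 0) {
    return(uniform("all scatter points coincide; uniform density used"))
  }
  if (sv[2L] / sv[1L] < 1e-10) return(uniform())  # collinear scatter
  d <- as.matrix(dist(points))
  diag(d) <- Inf
  nn <- apply(d, 1L, min)
  pad <- median(nn[is.finite(nn)]) / 2
  if (!is.finite(pad) || pad <= 0) pad <- 1e-8 * max(abs(points), 1)
  xr <- range(points[, 1L]) + c(-pad, pad)
  yr <- range(points[, 2L]) + c(-pad, pad)
  areas <- voronoi_cell_areas_cpp(points, xr[1L], xr[2L], yr[1L], yr[2L])
  # coincident sites share one cell: split its area evenly among them
  zero <- areas <= 0
  if (any(zero)) {
    for (k in which(zero)) {
      twin <- which(d[k, ] == 0)
      twin <- twin[areas[twin] > 0]
      if (length(twin) > 0L) areas[k] <- areas[twin[1L]]
    }
    grp <- apply(points, 1L, paste, collapse = ",")
    mult <- as.numeric(table(grp)[grp])
    areas <- areas / mult
  }
  density <- 1 / (n * areas)
  list(density = density, area = areas, weight = density / sum(density),
       degenerate = FALSE)
}

# covariance, variances and weights of one ordered (i, j, lag) slice
cov_pair <- function(ts, i, j, lag_steps, cfg) {
  m <- length(ts$times)
  npair <- m - lag_steps
  if (npair < cfg$lags$min_pairs) {
    return(NULL)
  }
  xi <- ts$values[, i]
  xj <- ts$values[, j]
  si <- xi[seq_len(npair)] - mean(xi)
  sj <- xj[seq_len(npair) + lag_steps] - mean(xj)
  w <- if (identical(cfg$lags$weighting, "density")) {
    voronoi_density(cbind(xi[seq_len(npair)],
                          xj[seq_len(npair) + lag_steps]))$weight
  } else {
    # quadrature: density times cell area is the measure element of the
    # covariance integral; with one point per Voronoi cell the product is
    # exactly 1/n, so the weights are uniform without tessellating
    rep(1 / npair, npair)
  }
  list(
    Cij = sum(w * si * sj),
    Vi = sum(w * si^2),
    Vj = sum(w * sj^2),
    si = si, sj = sj, w = w, npair = npair
  )
}

#' Density-weighted lagged covariance of two species
#'
#' Centres each series on its own plain time average, weights every point of
#' the lagged scatter (X_i(t_k), X_j(t_k + tau)) by its Voronoi density, and
#' returns the weighted time average of the product of deviations.
#'
#' @param ts a uniformly sampled [timeseries_set()].
#' @param i,j species names or indices (i observed at t, j at t + tau).
#' @param tau lag in hours; must be a multiple of the sampling step.
#' @param cfg configuration list.
#' @return The covariance value, or `NA` when fewer than
#'   `cfg$lags$min_pairs` sample pairs overlap.
#' @export
lagged_covariance <- function(ts, i, j, tau, cfg = tlc_config()) {
  stopifnot(inherits(ts, "tlc_timeseries"))
  dt <- mean(diff(ts$times))
  ls <- as.integer(round(tau / dt))
  if (abs(ls * dt - tau) > 1e-6 * dt) {
    stop("tau must be a multiple of the sampling step", call. = FALSE)
  }
  cp <- cov_pair(ts, i, j, ls, cfg)
  if (is.null(cp)) {
    warning("fewer than ", cfg$lags$min_pairs,
            " overlapping pairs; covariance undefined", call. = FALSE)
    return(NA_real_)
  }
  cp$Cij
}

#' Time-lagged correlation tensor
#'
#' For every ordered species pair and every lag on the grid, computes the
#' Voronoi-weighted covariance C_ij(tau) and the correlation
#' r_ij(tau) = C_ij / sqrt|C_ii C_jj|, where the variance terms are computed
#' with the same pair weights (which bounds |r| by one). Zero-variance
#' species yield undefined rows/columns.
#'
#' @param ts a uniformly sampled [timeseries_set()].
#' @param grid a [lag_grid()]; computed from `ts` when missing.
#' @param cfg configuration list.
#' @return Object of class `lagged_correlation` with `species`, `lags`,
#'   `C`, `Vi`, `Vj`, `r` (each an N x N x n_lags array).
#' @export
correlation_tensor <- function(ts, grid = NULL, cfg = tlc_config()) {
  stopifnot(inherits(ts, "tlc_timeseries"))
  if (is.null(grid)) grid <- lag_grid(ts, cfg)
  sp <- ts$species
  N <- length(sp)
  L <- length(grid$lags)
  dt <- mean(diff(ts$times))
  dimn <- list(sp, sp, signif(grid$lags, 8))
  C <- array(NA_real_, c(N, N, L), dimnames = dimn)
  Vi <- array(NA_real_, c(N, N, L), dimnames = dimn)
  Vj <- array(NA_real_, c(N, N, L), dimnames = dimn)
  novar <- vapply(sp, function(s) sd(ts$values[, s]) == 0, logical(1L))
  if (any(novar)) {
    warning("zero-variance species excluded from correlations: ",
            paste(sp[novar], collapse = ", "), call. = FALSE)
  }
  for (l in seq_len(L)) {
    ls <- as.integer(round(grid$lags[l] / dt))
    for (a in seq_len(N)) {
      if (novar[a]) next
      for (b in seq_len(N)) {
        if (novar[b]) next
        cp <- cov_pair(ts, a, b, ls, cfg)
        if (is.null(cp)) next
        C[a, b, l] <- cp$Cij
        Vi[a, b, l] <- cp$Vi
        Vj[a, b, l] <- cp$Vj
      }
    }
  }
  denom <- sqrt(abs(Vi * Vj))
  r <- C / ifelse(denom > 0, denom, NA_real_)
  structure(
    list(species = sp, lags = grid$lags, step = grid$step, C = C,
         Vi = Vi, Vj = Vj, r = r),
    class = "lagged_correlation"
  )
}

#' @export
print.lagged_correlation <- function(x, ...) {
  cat(sprintf("Lagged correlation tensor: %d species x %d lags (0..%.4g h)\n",
              length(x$species), length(x$lags), max(x$lags)))
  invisible(x)
}

#' Interspecies distance matrix from a correlation tensor
#'
#' c_ij is the maximum over lags of |r_ij(tau)| (the two orderings are
#' symmetrised by their maximum; the ordered values and argmax lags are kept
#' for edge orientation). Distances default to
#' d_ij = sqrt|c_ii - 2 c_ij + c_jj|; setting
#' `cfg$distance$square_root = FALSE` gives the plain absolute-value form.
#'
#' @param corr a [correlation_tensor()] result.
#' @param cfg configuration list.
#' @return Object of class `tlc_distance` with symmetrised `c`, ordered
#'   `c_ordered`, argmax lags `tau_star`, distances `d`, and a slot `dd` for
#'   propagated errors (filled by [distance_error()]).
#' @export
distance_matrix <- function(corr, cfg = tlc_config()) {
  stopifnot(inherits(corr, "lagged_correlation"))
  sp <- corr$species
  N <- length(sp)
  c_ord <- matrix(NA_real_, N, N, dimnames = list(sp, sp))
  tau_star <- matrix(NA_real_, N, N, dimnames = list(sp, sp))
  for (a in seq_len(N)) {
    for (b in seq_len(N)) {
      prof <- abs(corr$r[a, b, ])
      if (all(is.na(prof))) next
      l <- which.max(prof)
      c_ord[a, b] <- prof[l]
      tau_star[a, b] <- corr$lags[l]
    }
  }
  c_sym <- pmax(c_ord, t(c_ord))
  d <- matrix(NA_real_, N, N, dimnames = list(sp, sp))
  for (a in seq_len(N)) {
    for (b in seq_len(N)) {
      cii <- c_sym[a, a]
      cjj <- c_sym[b, b]
      cij <- c_sym[a, b]
      if (is.na(cii) || is.na(cjj) || is.na(cij)) next
      v <- abs(cii - 2 * cij + cjj)
      d[a, b] <- if (isTRUE(cfg$distance$square_root)) sqrt(v) else v
    }
  }
  structure(
    list(species = sp, c = c_sym, c_ordered = c_ord, tau_star = tau_star,
         d = d, dd = NULL, square_root = isTRUE(cfg$distance$square_root)),
    class = "tlc_distance"
  )
}

#' @export
print.tlc_distance <- function(x, ...) {
  cat(sprintf("Distance matrix over %d species (%s form)%s\n",
              length(x$species),
              if (x$square_root) "square-root" else "absolute-value",
              if (is.null(x$dd)) "" else ", with propagated errors"))
  print(round(x$d, 3))
  invisible(x)
}

#' Export the correlation tensor as a long table
#'
#' Writes columns `i`, `j`, `tau`, `r` (one row per ordered pair and lag),
#' the format consumed by external heat-mapping tools.
#'
#' @param corr a [correlation_tensor()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_correlation <- function(corr, path) {
  stopifnot(inherits(corr, "lagged_correlation"))
  sp <- corr$species
  grid <- expand.grid(i = sp, j = sp, tau = corr$lags,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$r <- as.vector(corr$r)
  write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export distances (and errors, when available) as a long table
#'
#' @param dist a [distance_matrix()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_distances <- function(dist, path) {
  stopifnot(inherits(dist, "tlc_distance"))
  sp <- dist$species
  idx <- which(upper.tri(dist$d), arr.ind = TRUE)
  out <- data.frame(
    i = sp[idx[, 1L]], j = sp[idx[, 2L]],
    d = dist$d[idx],
    dd = if (is.null(dist$dd)) NA_real_ else dist$dd[idx],
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
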
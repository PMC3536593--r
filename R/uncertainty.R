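#' Measurement-error matrix of a time series
#'
#' Returns the stored per-value absolute errors, or, when the series carries
#' none, the configured default relative error times |X|.
#'
#' @param ts a [timeseries_set()].
#' @param cfg configuration list.
#' @return Numeric matrix of absolute errors, same shape as `ts$values`.
#' @export
measurement_errors <- function(ts, cfg = tlc_config()) {
  stopifnot(inherits(ts, "tlc_timeseries"))
  if (!is.null(ts$errors)) return(ts$errors)
  cfg$errors$default_rel * abs(ts$values)
}

# error propagation through one (i, j, lag) covariance slice; returns the
# absolute errors on C_ij, V_i, V_j computed with the slice's own weights
cov_error_pair <- function(ts, dX, a, b, lag_steps, cfg) {
  cp <- cov_pair(ts, a, b, lag_steps, cfg)
  if (is.null(cp)) return(NULL)
  npair <- cp$npair
  dXbar_i <- mean(dX[, a])
  dXbar_j <- mean(dX[, b])
  dSi <- dX[seq_len(npair), a] + dXbar_i
  dSj <- dX[seq_len(npair) + lag_steps, b] + dXbar_j
  # |S_i S_j| * rss of relative errors, written in its cancelled stable form
  per_time <- sqrt((dSi * cp$sj)^2 + (cp$si * dSj)^2)
  list(
    dC = sum(cp$w * per_time),
    dVi = sum(cp$w * sqrt(2) * abs(cp$si) * dSi),
    dVj = sum(cp$w * sqrt(2) * abs(cp$sj) * dSj),
    cp = cp
  )
}

#' Propagated error of the lagged covariance
#'
#' First-order propagation of the per-value measurement errors through the
#' density-weighted covariance: the centred-value error is
#' deltaS(t) = deltaX(t) + mean(deltaX), each scatter point contributes the
#' root-sum-square of the two relative errors (the density-error term is
#' neglected), and the per-time absolute errors are averaged with the same
#' Voronoi weights as the covariance itself.
#'
#' @param ts a uniformly sampled [timeseries_set()].
#' @param corr a [correlation_tensor()] result (provides the lag grid).
#' @param tau lag in hours, on the grid of `corr`.
#' @param cfg configuration list.
#' @return N x N matrix of absolute covariance errors at lag `tau`.
#' @export
covariance_error <- function(ts, corr, tau, cfg = tlc_config()) {
  full <- covariance_errors(ts, corr, cfg)
  l <- which(abs(corr$lags - tau) < 1e-9 + 1e-6 * corr$step)
  if (length(l) != 1L) stop("tau is not on the lag grid", call. = FALSE)
  full$dC[, , l]
}

#' Full covariance error budget over the lag grid
#'
#' @inheritParams covariance_error
#' @return List of arrays `dC`, `dVi`, `dVj` matching the shape of `corr$C`.
#' @export
covariance_errors <- function(ts, corr, cfg = tlc_config()) {
  stopifnot(inherits(ts, "tlc_timeseries"),
            inherits(corr, "lagged_correlation"))
  dX <- measurement_errors(ts, cfg)
  sp <- corr$species
  N <- length(sp)
  L <- length(corr$lags)
  dt <- corr$step
  dimn <- dimnames(corr$C)
  dC <- array(NA_real_, c(N, N, L), dimnames = dimn)
  dVi <- array(NA_real_, c(N, N, L), dimnames = dimn)
  dVj <- array(NA_real_, c(N, N, L), dimnames = dimn)
  for (l in seq_len(L)) {
    ls <- as.integer(round(corr$lags[l] / dt))
    for (a in seq_len(N)) {
      for (b in seq_len(N)) {
        if (is.na(corr$C[a, b, l])) next
        ce <- cov_error_pair(ts, dX, a, b, ls, cfg)
        if (is.null(ce)) next
        dC[a, b, l] <- ce$dC
        dVi[a, b, l] <- ce$dVi
        dVj[a, b, l] <- ce$dVj
      }
    }
  }
  list(dC = dC, dVi = dVi, dVj = dVj)
}

#' Propagated error of the correlation coefficient
#'
#' delta r = |r| sqrt((dC/C)^2 + ((dVi/Vi)^2 + (dVj/Vj)^2)/4), evaluated in
#' the algebraically equivalent form sqrt((dC/sqrt(Vi Vj))^2 +
#' r^2((dVi/Vi)^2 + (dVj/Vj)^2)/4), which stays defined where C = 0 (there
#' only the covariance term survives, and a warning is logged).
#'
#' @param corr a [correlation_tensor()] result.
#' @param err covariance error budget from [covariance_errors()].
#' @return Array of absolute correlation errors, same shape as `corr$r`.
#' @export
correlation_error <- function(corr, err) {
  stopifnot(inherits(corr, "lagged_correlation"))
  denom <- sqrt(abs(corr$Vi * corr$Vj))
  if (any(corr$C == 0 & err$dC > 0, na.rm = TRUE)) {
    warning("zero covariance encountered; correlation error from the ",
            "remaining terms", call. = FALSE)
  }
  sqrt((err$dC / denom)^2 +
         corr$r^2 / 4 * ((err$dVi / corr$Vi)^2 + (err$dVj / corr$Vj)^2))
}

#' Propagated error of the interspecies distances
#'
#' Uses the per-pair maximum over lags of |delta r(tau)| as the correlation
#' error (symmetrised conservatively by the larger ordered direction), then
#' delta d = (dc_ii + 2 dc_ij + dc_jj) / (2 d) for the square-root distance
#' form, or the bare sum for the absolute-value form. Distances of zero with
#' nonzero correlation error receive the limiting value sqrt(dc-sum).
#'
#' @param dist a [distance_matrix()] result.
#' @param dr array of correlation errors from [correlation_error()].
#' @param cfg configuration list.
#' @return `dist` with the error matrix filled into `$dd`.
#' @export
distance_error <- function(dist, dr, cfg = tlc_config()) {
  stopifnot(inherits(dist, "tlc_distance"))
  N <- length(dist$species)
  dc_ord <- apply(abs(dr), c(1L, 2L), function(v) {
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  })
  dc <- pmax(dc_ord, t(dc_ord))
  dd <- matrix(NA_real_, N, N, dimnames = dimnames(dist$d))
  for (a in seq_len(N)) {
    for (b in seq_len(N)) {
      s <- dc[a, a] + 2 * dc[a, b] + dc[b, b]
      if (is.na(s)) next
      if (!dist$square_root) {
        dd[a, b] <- s
      } else if (a == b) {
        dd[a, b] <- 0
      } else if (dist$d[a, b] <= cfg$numeric$floor) {
        dd[a, b] <- sqrt(s)
        warning("zero distance with nonzero correlation error for pair (",
                dist$species[a], ", ", dist$species[b],
                "); limiting error used", call. = FALSE)
      } else {
        dd[a, b] <- s / (2 * dist$d[a, b])
      }
    }
  }
  dist$dd <- dd
  dist$dc <- dc
  dist
}

#' Propagated error of the embedding stress
#'
#' First-order propagation of the distance errors through the
#' residual-sum-of-squares stress:
#' delta S = (1/S) sum over pairs |d_ij - e_ij| delta d_ij, where e_ij is
#' the embedded distance. Zero at a perfect embedding.
#'
#' @param embedding an [fit_embedding()] result.
#' @param dd matrix of distance errors (`$dd` of [distance_error()]).
#' @return The absolute stress error.
#' @export
stress_error <- function(embedding, dd) {
  stopifnot(inherits(embedding, "tlc_embedding"))
  if (embedding$stress <= 0) return(0)
  e <- as.matrix(stats::dist(embedding$coords))
  d <- embedding$dmat
  idx <- which(upper.tri(d) & is.finite(d) & is.finite(dd), arr.ind = TRUE)
  sum(abs(d[idx] - e[idx]) * dd[idx]) / embedding$stress
}
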
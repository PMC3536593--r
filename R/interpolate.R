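#' Stineman monotone interpolation
#'
#' Rational interpolation after Stineman: within each interval the interpolant
#' is the chord plus a rational correction built from the deviations of the
#' endpoint slopes from the chord slope. The curve passes through every data
#' point, never overshoots local extrema, and is exact on straight lines.
#'
#' @param x strictly increasing abscissae (length >= 2).
#' @param y ordinates, same length as `x`.
#' @param xout points at which to evaluate the interpolant.
#' @return Numeric vector of interpolated values at `xout`.
#' @seealso [stineman_slopes()] for the knot derivatives.
#' @export
#' @examples
#' stineman_interp(0:4, (0:4)^2, c(0.5, 2.5))
stineman_interp <- function(x, y, xout) {
  stopifnot(length(x) == length(y), length(x) >= 2L, all(diff(x) > 0))
  yp <- stineman_slopes(x, y)
  n <- length(x)
  idx <- findInterval(xout, x, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx >= n] <- n - 1L
  s <- (y[idx + 1L] - y[idx]) / (x[idx + 1L] - x[idx])
  dxo <- xout - x[idx]
  dxo1 <- xout - x[idx + 1L]
  yo <- y[idx] + s * dxo
  dy1 <- (yp[idx] - s) * dxo
  dy2 <- (yp[idx + 1L] - s) * dxo1
  prod <- dy1 * dy2
  corr <- numeric(length(xout))
  pos <- prod > 0
  neg <- prod < 0
  corr[pos] <- prod[pos] / (dy1[pos] + dy2[pos])
  corr[neg] <- prod[neg] * (dxo[neg] + dxo1[neg]) /
    ((dy1[neg] - dy2[neg]) * (x[idx + 1L][neg] - x[idx][neg]))
  yo + corr
}

#' Knot slopes of the Stineman interpolant
#'
#' Interior slopes are chord-length-weighted averages of the two adjacent
#' secant slopes; endpoint slopes extrapolate linearly. These are the
#' derivatives of the interpolant at the data points.
#'
#' @inheritParams stineman_interp
#' @return Numeric vector of slopes, one per data point.
#' @export
stineman_slopes <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 2L, all(diff(x) > 0))
  dx <- diff(x)
  dy <- diff(y)
  s <- dy / dx
  if (n == 2L) {
    return(rep(s, 2L))
  }
  yp <- numeric(n)
  w <- dx^2 + dy^2  # squared chord lengths
  # interior slope: secants mixed with the opposite interval's chord weight
  yp[2:(n - 1L)] <- (s[-1L] * w[-(n - 1L)] + s[-(n - 1L)] * w[-1L]) /
    (w[-(n - 1L)] + w[-1L])
  yp[1L] <- 2 * s[1L] - yp[2L]
  yp[n] <- 2 * s[n - 1L] - yp[n - 1L]
  yp
}

#' Derivative of a series at its sampling points
#'
#' Evaluates dX/dt at each sampling time as the knot derivative of the
#' Stineman interpolant through the series.
#'
#' @param times strictly increasing sampling times (>= 3 points).
#' @param values series values at `times`.
#' @return Numeric vector of derivative estimates, one per sample.
#' @export
#' @examples
#' derivative(0:10, 3 * (0:10) + 1)  # exactly 3 everywhere
derivative <- function(times, values) {
  if (length(times) < 3L) {
    stop("derivative estimation needs at least 3 samples", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  stineman_slopes(times, values)
}
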
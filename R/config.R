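#' Default configuration for the inference pipeline
#'
#' Returns the full list of tunable settings used across the topology and
#' calibration stages. Any subset can be overridden by passing a named list;
#' unknown keys are rejected to catch typos.
#'
#' @param ... named overrides, either top-level groups or scalar settings
#'   inside a group, e.g. `tlc_config(prune = list(relative_error = 0.5))`.
#'
#' @return A nested named list of settings.
#'
#' @details Groups and their members:
#' \describe{
#'   \item{numeric}{`eps` numerical tolerance (default 1e-9); `floor` the
#'     division-by-zero guard applied to centred values and distances before
#'     relative errors are formed (default 1e-12).}
#'   \item{lags}{`min_pairs` minimum number of overlapping (t, t+tau) pairs
#'     for a lag to be usable (default 4); `stride` lag-grid stride in units
#'     of the sampling step (default 1); `weighting` how the Voronoi pair
#'     density enters the covariance: `"quadrature"` (default) multiplies
#'     the density by its cell area, the Riemann discretisation of the
#'     covariance integral; `"density"` weights each point by the bare
#'     density, which over-weights dense regions of the scatter.}
#'   \item{errors}{`default_rel` relative measurement error assumed when no
#'     error columns are present (default 0.07).}
#'   \item{distance}{`square_root` use d = sqrt|c_ii - 2 c_ij + c_jj| (default
#'     TRUE); FALSE gives the plain absolute-value form.}
#'   \item{embedding}{`restarts` random restarts of the downhill simplex
#'     (default 20); `maxit_factor` iteration cap per restart as a multiple of
#'     N*D (default 1e4); `reltol` convergence tolerance (default 1e-10);
#'     `normalized_stress` divide the residual stress by sqrt(sum d^2)
#'     (default FALSE); `threshold_on` "embedded" or "raw" distances for edge
#'     thresholding when MDS ran (default "embedded"); `bins` histogram bin
#'     rule, NULL for max(10, ceiling(sqrt(P))) (default NULL); `threshold`
#'     fixed edge threshold overriding the histogram rule (default NULL).}
#'   \item{orientation}{`tail_tol` tolerance on the tail-decay comparison used
#'     at zero-lag ties (default 0.02); `weak_r` |r| level below which an edge
#'     is annotated weak (default 0.05).}
#'   \item{fit}{`quad_nodes` Gauss-Hermite nodes for non-integer exponents
#'     (default 11); `sigma_floor_rel` variance floor relative to median |X|
#'     (default 1e-8); `bound_factor` upper parameter bound as a multiple of
#'     the initial guess (default 10); `maxit` optimizer iteration cap
#'     (default 500).}
#'   \item{prune}{`relative_error` pruning threshold rho on Delta k / k
#'     (default 1.0; 0.5 gives the stricter 50% variant).}
#' }
#' @export
#' @examples
#' cfg <- tlc_config(prune = list(relative_error = 0.5))
#' cfg$prune$relative_error
tlc_config <- function(...) {
  cfg <- list(
    numeric = list(eps = 1e-9, floor = 1e-12),
    lags = list(min_pairs = 4L, stride = 1L, weighting = "quadrature"),
    errors = list(default_rel = 0.07),
    distance = list(square_root = TRUE),
    embedding = list(
      restarts = 20L, maxit_factor = 1e4, reltol = 1e-10,
      normalized_stress = FALSE, threshold_on = "embedded",
      bins = NULL, threshold = NULL
    ),
    orientation = list(tail_tol = 0.02, weak_r = 0.05),
    fit = list(
      quad_nodes = 11L, sigma_floor_rel = 1e-8,
      bound_factor = 10, maxit = 500L
    ),
    prune = list(relative_error = 1.0)
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1L]])) {
    overrides <- overrides[[1L]]
  }
  for (grp in names(overrides)) {
    if (!grp %in% names(cfg)) {
      stop("unknown config group: ", grp, call. = FALSE)
    }
    for (key in names(overrides[[grp]])) {
      if (!key %in% names(cfg[[grp]])) {
        stop("unknown config key: ", grp, "$", key, call. = FALSE)
      }
      cfg[[grp]][[key]] <- overrides[[grp]][[key]]
    }
  }
  cfg
}
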
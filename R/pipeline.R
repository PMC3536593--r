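#' Infer reaction hypotheses from a concentration time series
#'
#' Runs the full topology stage: uniform resampling (when needed), lag-grid
#' estimation, the Voronoi-weighted lagged correlation tensor, error
#' propagation, the distance matrix, dimension selection with
#' Kruskal-Shepard scaling, histogram thresholding, undirected graph
#' construction and lag-based orientation. Every intermediate artifact is
#' kept on the returned object.
#'
#' @param ts a [timeseries_set()].
#' @param cfg configuration list.
#' @param seed seed for the embedding restarts.
#' @return Object of class `tlc_inference` with fields `ts`, `grid`,
#'   `corr`, `errors`, `dr`, `dist`, `selection`, `threshold`, `network`
#'   (undirected), and `hypotheses` (a [orient()] result).
#' @export
infer_network <- function(ts, cfg = tlc_config(), seed = 1L) {
  stopifnot(inherits(ts, "tlc_timeseries"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  if (length(ts$species) < 2L) {
    hyp <- structure(
      list(species = ts$species,
           hypotheses = data.frame(
             id = character(), from = character(), to = character(),
             leader = character(), tau_star = numeric(),
             r_star = numeric(), sign = numeric(), reversible = logical(),
             weak = logical(), stringsAsFactors = FALSE)),
      class = "directed_hypotheses"
    )
    return(structure(list(ts = ts, hypotheses = hyp),
                     class = "tlc_inference"))
  }
  dt <- diff(ts$times)
  if (diff(range(dt)) > 1e-8 * mean(dt)) {
    ts <- stage("resample", resample_uniform(ts))
  }
  grid <- stage("lag_grid", lag_grid(ts, cfg))
  corr <- stage("correlation", correlation_tensor(ts, grid, cfg))
  errs <- stage("covariance_errors", covariance_errors(ts, corr, cfg))
  dr <- stage("correlation_error", correlation_error(corr, errs))
  dmat <- stage("distance", distance_matrix(corr, cfg))
  dmat <- stage("distance_error", distance_error(dmat, dr, cfg))
  sel <- stage("select_dimension", select_dimension(dmat, seed, cfg))
  use_embedded <- !identical(sel$D, "skip-MDS") &&
    identical(cfg$embedding$threshold_on, "embedded")
  thr_src <- if (use_embedded) {
    sel$embeddings[[as.character(sel$D)]]
  } else {
    dmat
  }
  if (length(ts$species) < 3L) {
    # a single interspecies distance carries no contrast to threshold on
    warning("fewer than 3 species: no edges can be thresholded",
            call. = FALSE)
    thr <- structure(list(threshold = 0, breaks = NULL, counts = NULL,
                          centers = NULL), class = "edge_threshold")
    net <- structure(
      list(species = ts$species,
           edges = data.frame(i = character(), j = character(),
                              distance = numeric(),
                              stringsAsFactors = FALSE),
           threshold = 0, histogram = NULL,
           source = if (use_embedded) "embedded" else "raw"),
      class = "undirected_network"
    )
  } else {
    thr <- stage("threshold", edge_threshold(thr_src, cfg))
    net <- stage("build_undirected", build_undirected(thr_src, thr))
  }
  hyp <- stage("orient", orient(corr, net, cfg))
  structure(
    list(ts = ts, grid = grid, corr = corr, errors = errs, dr = dr,
         dist = dmat, selection = sel, threshold = thr, network = net,
         hypotheses = hyp),
    class = "tlc_inference"
  )
}

#' @export
print.tlc_inference <- function(x, ...) {
  cat("Network inference result\n")
  if (!is.null(x$grid)) print(x$grid)
  if (!is.null(x$selection)) {
    cat("  chosen dimension:", as.character(x$selection$D), "\n")
  }
  if (!is.null(x$network)) print(x$network)
  cat(sprintf("  %d directed hypotheses\n", nrow(x$hypotheses$hypotheses)))
  invisible(x)
}

#' Calibrate hypothesised reactions against the time series
#'
#' Fits the generalized mass action model induced by the hypotheses by
#' maximum likelihood ([fit_gma()]) and prunes null-kinetics reactions
#' ([prune()]).
#'
#' @param ts a [timeseries_set()].
#' @param hypotheses a [orient()] result, a `tlc_inference`, or a
#'   [reaction_network()].
#' @param cfg configuration list.
#' @return The retained [reaction_network()] (attribute `"report"` holds
#'   the pruning table, `"fit"` the [fit_gma()] object).
#' @export
calibrate <- function(ts, hypotheses, cfg = tlc_config()) {
  if (inherits(hypotheses, "tlc_inference")) {
    hypotheses <- hypotheses$hypotheses
  }
  net <- if (inherits(hypotheses, "directed_hypotheses")) {
    hypotheses_network(hypotheses)
  } else {
    hypotheses
  }
  stopifnot(inherits(net, "reaction_network"))
  if (nrow(net$reactions) == 0L) {
    out <- reaction_network(net$reactions, species = net$species)
    attr(out, "report") <- data.frame()
    return(out)
  }
  model <- build_gma(net)
  fit <- fit_gma(model, ts, cfg)
  out <- prune(fit, net, cfg)
  attr(out, "fit") <- fit
  out
}

#' Score an inferred network against a reference
#'
#' Tags every inferred reaction: `E` (expected) when the same directed
#' reaction exists in the reference; `P` (plausible) when it does not but a
#' directed reference path of length >= 2 leads from its reactant to its
#' product (the apparent interaction is mediated by intermediate
#' biotransformations); `U` (unexpected) otherwise. Sensitivity is the
#' fraction of expected reactions detected (with and without plausibles
#' counted as detections); accuracy is the fraction of E among the E+P
#' detections. A conventional precision E/(E+P+U) is reported alongside.
#'
#' @param inferred a [reaction_network()] (duplicated directed reactions
#'   are counted once).
#' @param reference the reference [reaction_network()].
#' @return Object of class `evaluation_report`: `tags` (per-reaction data
#'   frame), `counts`, and the percentage metrics
#'   `sensitivity_with_plausibles`, `sensitivity_without_plausibles`,
#'   `accuracy`, `precision`.
#' @export
evaluate <- function(inferred, reference) {
  stopifnot(inherits(inferred, "reaction_network"),
            inherits(reference, "reaction_network"))
  ref <- reference$reactions
  inf <- inferred$reactions
  inf <- inf[!duplicated(inf[, c("from", "to")]), , drop = FALSE]
  species <- union(reference$species, inferred$species)
  g <- igraph::graph_from_data_frame(
    ref[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = species)
  )
  pl <- igraph::distances(g, mode = "out")
  ref_key <- paste(ref$from, ref$to)
  tag <- character(nrow(inf))
  for (r in seq_len(nrow(inf))) {
    key <- paste(inf$from[r], inf$to[r])
    if (key %in% ref_key) {
      tag[r] <- "E"
    } else {
      len <- pl[inf$from[r], inf$to[r]]
      tag[r] <- if (is.finite(len) && len >= 2) "P" else "U"
    }
  }
  Ec <- sum(tag == "E")
  Pc <- sum(tag == "P")
  Uc <- sum(tag == "U")
  expected <- nrow(ref)
  counts <- c(expected = expected, detected = Ec + Pc + Uc,
              E = Ec, P = Pc, U = Uc,
              correctly_detected = Ec, missed = expected - Ec)
  structure(
    list(
      tags = cbind(inf[, c("id", "from", "to")], tag = tag),
      counts = counts,
      sensitivity_with_plausibles = 100 * (Ec + Pc) / expected,
      sensitivity_without_plausibles = 100 * Ec / expected,
      accuracy = if (Ec + Pc > 0) 100 * Ec / (Ec + Pc) else NA_real_,
      precision = if (Ec + Pc + Uc > 0) {
        100 * Ec / (Ec + Pc + Uc)
      } else {
        NA_real_
      }
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  c <- x$counts
  cat(sprintf(
    "Evaluation: %d inferred (%d E, %d P, %d U) vs %d expected\n",
    c[["detected"]], c[["E"]], c[["P"]], c[["U"]], c[["expected"]]
  ))
  cat(sprintf("  sensitivity (plausibles included): %.1f%%\n",
              x$sensitivity_with_plausibles))
  cat(sprintf("  sensitivity (plausibles excluded): %.1f%%\n",
              x$sensitivity_without_plausibles))
  cat(sprintf("  accuracy E/(E+P): %.1f%%   precision E/(E+P+U): %.1f%%\n",
              x$accuracy, x$precision))
  invisible(x)
}

#' Run the full benchmark pipeline once
#'
#' Simulates the reference pathway, infers the topology, calibrates and
#' prunes, and scores against the reference network.
#'
#' @param seed seed driving the noise realisation and all stochastic
#'   stages.
#' @param cfg configuration list.
#' @param ... passed to [simulate_pathway()] (e.g. `noise`, `times`).
#' @return List with `ts`, `inference`, `calibrated`, `report`.
#' @export
run_benchmark <- function(seed = 1L, cfg = tlc_config(), ...) {
  ref <- reference_network()
  ts <- simulate_pathway(network = ref, seed = seed, ...)
  inf <- infer_network(ts, cfg, seed = seed)
  cal <- calibrate(ts, inf, cfg)
  rep <- evaluate(cal, ref)
  list(ts = ts, inference = inf, calibrated = cal, report = rep)
}
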
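#' Residual-sum-of-squares stress of a configuration
#'
#' S_D = sqrt(sum over unordered pairs (d_ij - ||z_i - z_j||)^2). Pairs with
#' undefined target distance are excluded (with a warning). Setting
#' `cfg$embedding$normalized_stress = TRUE` divides by sqrt(sum d_ij^2),
#' giving the classical normalised variant.
#'
#' @param coords N x D coordinate matrix.
#' @param dmat N x N target distance matrix (or a [distance_matrix()]
#'   object).
#' @param cfg configuration list.
#' @return The stress value.
#' @export
stress <- function(coords, dmat, cfg = tlc_config()) {
  if (inherits(dmat, "tlc_distance")) dmat <- dmat$d
  coords <- as.matrix(coords)
  dmat <- as.matrix(dmat)
  stopifnot(nrow(coords) == nrow(dmat), nrow(dmat) == ncol(dmat))
  if (any(!is.finite(dmat[upper.tri(dmat)]))) {
    warning("undefined distances excluded from stress", call. = FALSE)
  }
  s <- stress_cpp(as.numeric(coords), dmat, ncol(coords))
  if (isTRUE(cfg$embedding$normalized_stress)) {
    tot <- sqrt(sum(dmat[upper.tri(dmat)]^2, na.rm = TRUE))
    if (tot > 0) s <- s / tot
  }
  s
}

#' Kruskal-Shepard embedding by downhill simplex
#'
#' Minimises the residual stress over N*D coordinates with Nelder-Mead
#' restarts: the first restart starts from the classical-scaling
#' configuration, the rest from seeded uniform draws on a box scaled to the
#' largest distance. The best restart is returned, centred at the origin.
#'
#' @param dmat target distances: an N x N matrix or a [distance_matrix()].
#' @param D embedding dimension (1, 2 or 3).
#' @param restarts number of simplex restarts.
#' @param seed RNG seed for the random initialisations.
#' @param cfg configuration list.
#' @return Object of class `tlc_embedding`: `dimension`, `coords`, `stress`,
#'   `best_restart`, `converged`, `dmat`.
#' @export
fit_embedding <- function(dmat, D, restarts = NULL, seed = 1L,
                          cfg = tlc_config()) {
  if (inherits(dmat, "tlc_distance")) dmat <- dmat$d
  dmat <- as.matrix(dmat)
  N <- nrow(dmat)
  stopifnot(D %in% 1:3, N >= 2L)
  if (is.null(restarts)) restarts <- cfg$embedding$restarts
  dwork <- dmat
  dwork[!is.finite(dwork)] <- 0  # only used to seed initialisations
  maxd <- max(dwork)
  if (maxd <= 0) maxd <- 1
  maxit <- ceiling(cfg$embedding$maxit_factor * N * D)
  obj <- function(par) stress_cpp(par, dmat, D)

  inits <- vector("list", restarts)
  cm <- tryCatch(
    suppressWarnings(cmdscale(dwork, k = D)),
    error = function(e) NULL
  )
  set.seed(seed)
  for (rI in seq_len(restarts)) {
    if (rI == 1L && !is.null(cm) && ncol(cm) >= 1L) {
      z <- matrix(0, N, D)
      z[, seq_len(ncol(cm))] <- cm
      inits[[rI]] <- as.numeric(z)
    } else {
      inits[[rI]] <- runif(N * D, -maxd / 2, maxd / 2)
    }
  }
  best <- NULL
  for (rI in seq_len(restarts)) {
    fit <- optim(inits[[rI]], obj, method = "Nelder-Mead",
                 control = list(reltol = cfg$embedding$reltol,
                                maxit = maxit))
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      best$restart <- rI
    }
  }
  coords <- matrix(best$par, N, D)
  coords <- sweep(coords, 2L, colMeans(coords))  # translation gauge
  rownames(coords) <- rownames(dmat)
  s <- stress(coords, dmat, cfg)
  structure(
    list(dimension = D, coords = coords, stress = s,
         best_restart = best$restart, converged = best$convergence == 0L,
         restarts = restarts, seed = seed, dmat = dmat),
    class = "tlc_embedding"
  )
}

#' @export
print.tlc_embedding <- function(x, ...) {
  cat(sprintf("%d-D embedding of %d species: stress %.4g (%d restarts%s)\n",
              x$dimension, nrow(x$coords), x$stress, x$restarts,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Choose the embedding dimension from the error budget
#'
#' Fits 2-D and 3-D embeddings. A dimension is admissible when every
#' embedded distance lies inside the error band \[d - delta d, d + delta d\].
#' Three dimensions are preferred over two when S3 + deltaS3 <= S2 + deltaS2.
#' When neither dimension is admissible, the scaling step is skipped and
#' downstream thresholding uses the raw distance matrix.
#'
#' @param dist a [distance_matrix()] with errors filled by
#'   [distance_error()].
#' @param seed RNG seed passed to [fit_embedding()].
#' @param cfg configuration list.
#' @return Object of class `dimension_selection`: `D` (2, 3, or the string
#'   "skip-MDS"), per-dimension embeddings, stresses, stress errors and
#'   admissibility flags.
#' @export
select_dimension <- function(dist, seed = 1L, cfg = tlc_config()) {
  stopifnot(inherits(dist, "tlc_distance"))
  if (is.null(dist$dd)) {
    stop("distance errors missing; run distance_error() first", call. = FALSE)
  }
  fits <- list()
  admissible <- c(`2` = FALSE, `3` = FALSE)
  stresses <- c(`2` = NA_real_, `3` = NA_real_)
  dstresses <- c(`2` = NA_real_, `3` = NA_real_)
  for (D in c(2L, 3L)) {
    emb <- fit_embedding(dist$d, D, seed = seed + D, cfg = cfg)
    emb$dstress <- stress_error(emb, dist$dd)
    fits[[as.character(D)]] <- emb
    e <- as.matrix(stats::dist(emb$coords))
    idx <- upper.tri(dist$d) & is.finite(dist$d) & is.finite(dist$dd)
    admissible[as.character(D)] <-
      all(e[idx] >= dist$d[idx] - dist$dd[idx] &
            e[idx] <= dist$d[idx] + dist$dd[idx])
    stresses[as.character(D)] <- emb$stress
    dstresses[as.character(D)] <- emb$dstress
  }
  eps <- cfg$numeric$eps
  D <- if (!any(admissible)) {
    "skip-MDS"
  } else if (all(admissible)) {
    # a third dimension must buy a real stress reduction: when the planar
    # fit is already essentially perfect there is nothing to reduce
    if (stresses["2"] > eps &&
        stresses["3"] + dstresses["3"] <= stresses["2"] + dstresses["2"]) {
      3L
    } else {
      2L
    }
  } else if (admissible["3"]) 3L else 2L
  structure(
    list(D = D, embeddings = fits, stress = stresses, dstress = dstresses,
         admissible = admissible),
    class = "dimension_selection"
  )
}

#' @export
print.dimension_selection <- function(x, ...) {
  cat("Dimension selection:", as.character(x$D), "\n")
  for (D in c("2", "3")) {
    cat(sprintf("  D=%s: stress %.4g +- %.4g, %sadmissible\n", D,
                x$stress[D], x$dstress[D],
                if (x$admissible[D]) "" else "not "))
  }
  invisible(x)
}

#' Edge threshold from the histogram of distances
#'
#' Histograms all off-diagonal distances and returns the mean of the centres
#' of the bins attaining the maximum count. The bin count defaults to
#' max(10, ceiling(sqrt(P))) for P distances.
#'
#' @param distances numeric vector of off-diagonal distances, or a
#'   [distance_matrix()] / [fit_embedding()] object.
#' @param cfg configuration list (`cfg$embedding$bins` overrides the bin
#'   rule; `cfg$embedding$threshold` bypasses the histogram entirely).
#' @return Object of class `edge_threshold`: `threshold`, `breaks`, `counts`,
#'   `centers`.
#' @export
edge_threshold <- function(distances, cfg = tlc_config()) {
  if (inherits(distances, "tlc_distance")) {
    distances <- distances$d[upper.tri(distances$d)]
  } else if (inherits(distances, "tlc_embedding")) {
    e <- as.matrix(stats::dist(distances$coords))
    distances <- e[upper.tri(e)]
  }
  distances <- distances[is.finite(distances)]
  if (!is.null(cfg$embedding$threshold)) {
    return(structure(list(threshold = cfg$embedding$threshold,
                          breaks = NULL, counts = NULL, centers = NULL),
                     class = "edge_threshold"))
  }
  if (length(distances) < 3L) {
    stop("need at least 3 off-diagonal distances", call. = FALSE)
  }
  if (diff(range(distances)) == 0) {
    warning("all distances identical; threshold set to that value",
            call. = FALSE)
    return(structure(list(threshold = distances[1L], breaks = NULL,
                          counts = NULL, centers = NULL),
                     class = "edge_threshold"))
  }
  P <- length(distances)
  bins <- cfg$embedding$bins
  if (is.null(bins)) bins <- max(10L, ceiling(sqrt(P)))
  breaks <- seq(min(distances), max(distances), length.out = bins + 1L)
  counts <- tabulate(
    findInterval(distances, breaks, rightmost.closed = TRUE),
    nbins = bins
  )
  centers <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  thr <- mean(centers[counts == max(counts)])
  structure(list(threshold = thr, breaks = breaks, counts = counts,
                 centers = centers),
            class = "edge_threshold")
}

#' Undirected interaction graph by distance thresholding
#'
#' Two species are linked when their (embedded, when scaling ran; raw
#' otherwise) distance does not exceed the threshold: proximity in
#' correlation distance is read as evidence of a biochemical interaction.
#'
#' @param x distances to threshold: a [fit_embedding()] or
#'   [distance_matrix()] object.
#' @param threshold numeric threshold or an [edge_threshold()] result.
#' @return Object of class `undirected_network`: `species`, `edges` (data
#'   frame `i`, `j`, `distance`), `threshold`, `histogram`, `source`.
#' @export
build_undirected <- function(x, threshold) {
  hist_meta <- NULL
  if (inherits(threshold, "edge_threshold")) {
    hist_meta <- threshold[c("breaks", "counts", "centers")]
    threshold <- threshold$threshold
  }
  stopifnot(is.numeric(threshold), threshold > 0)
  if (inherits(x, "tlc_embedding")) {
    dmat <- as.matrix(stats::dist(x$coords))
    rownames(dmat) <- colnames(dmat) <- rownames(x$coords)
    src <- "embedded"
  } else if (inherits(x, "tlc_distance")) {
    dmat <- x$d
    src <- "raw"
  } else {
    dmat <- as.matrix(x)
    src <- "raw"
  }
  sp <- rownames(dmat)
  if (is.null(sp)) sp <- paste0("X", seq_len(nrow(dmat)))
  idx <- which(upper.tri(dmat) & dmat <= threshold, arr.ind = TRUE)
  edges <- data.frame(
    i = sp[idx[, 1L]], j = sp[idx[, 2L]],
    distance = dmat[idx], stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(species = sp, edges = edges, threshold = threshold,
         histogram = hist_meta, source = src),
    class = "undirected_network"
  )
}

#' @export
print.undirected_network <- function(x, ...) {
  cat(sprintf(
    "Undirected network: %d species, %d edges (threshold %.4g on %s distances)\n",
    length(x$species), nrow(x$edges), x$threshold, x$source
  ))
  invisible(x)
}

#' Export an undirected network as an edge list
#'
#' @param net an [build_undirected()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_edges <- function(net, path) {
  stopifnot(inherits(net, "undirected_network"))
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
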
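#' Orient an undirected network from the lag structure
#'
#' Converts every undirected edge into a pair of opposed unimolecular
#' reaction hypotheses (pruning is the calibration stage's job) annotated
#' with temporal precedence. For an edge (i, j), the lag at which
#' |r_ij(tau)| peaks with i as the leading series is compared with the
#' corresponding lag for j leading: a strictly positive argmax lag in
#' exactly one ordering marks that ordering's reference species as the
#' leader. When both orderings peak at zero lag, the ordering whose |r|
#' decays more slowly over the upper half of the lag grid marks the leader;
#' below the tail tolerance the edge is annotated reversible with no leader.
#'
#' @param corr a [correlation_tensor()] covering the full lag grid.
#' @param net an [build_undirected()] result.
#' @param cfg configuration list (`orientation$tail_tol`,
#'   `orientation$weak_r`).
#' @return Object of class `directed_hypotheses`: `species` and a data frame
#'   `hypotheses` with columns `id`, `from`, `to`, `leader`, `tau_star`,
#'   `r_star`, `sign`, `reversible`, `weak`.
#' @export
orient <- function(corr, net, cfg = tlc_config()) {
  stopifnot(inherits(corr, "lagged_correlation"),
            inherits(net, "undirected_network"))
  lags <- corr$lags
  sp <- corr$species
  rows <- list()
  for (e in seq_len(nrow(net$edges))) {
    i <- net$edges$i[e]
    j <- net$edges$j[e]
    prof_ij <- abs(corr$r[i, j, ])  # i leading (i at t, j at t + tau)
    prof_ji <- abs(corr$r[j, i, ])
    l_ij <- which.max(prof_ij)
    l_ji <- which.max(prof_ji)
    peak <- max(prof_ij[l_ij], prof_ji[l_ji], na.rm = TRUE)
    weak <- is.finite(peak) && peak < cfg$orientation$weak_r
    leader <- NA_character_
    tau_star <- NA_real_
    reversible <- FALSE
    if (lags[l_ij] > 0 && lags[l_ji] == 0) {
      leader <- i
      tau_star <- lags[l_ij]
    } else if (lags[l_ji] > 0 && lags[l_ij] == 0) {
      leader <- j
      tau_star <- lags[l_ji]
    } else if (lags[l_ij] > 0 && lags[l_ji] > 0) {
      # both orderings peak late: the larger peak decides the leader
      if (prof_ij[l_ij] >= prof_ji[l_ji]) {
        leader <- i
        tau_star <- lags[l_ij]
      } else {
        leader <- j
        tau_star <- lags[l_ji]
      }
    } else {
      # both maxima at zero lag: compare the decay of the positive-lag tails
      upper <- lags >= max(lags) / 2 & lags > 0
      if (any(upper)) {
        tail_ij <- mean(prof_ij[upper], na.rm = TRUE)
        tail_ji <- mean(prof_ji[upper], na.rm = TRUE)
        if (is.finite(tail_ij) && is.finite(tail_ji) &&
            abs(tail_ij - tail_ji) > cfg$orientation$tail_tol) {
          if (tail_ij > tail_ji) {
            leader <- i
            tau_star <- 0
          } else {
            leader <- j
            tau_star <- 0
          }
        } else {
          reversible <- TRUE
          tau_star <- 0
        }
      } else {
        reversible <- TRUE
        tau_star <- 0
      }
    }
    sgn_ij <- sign(corr$r[i, j, l_ij])
    sgn_ji <- sign(corr$r[j, i, l_ji])
    rows[[length(rows) + 1L]] <- data.frame(
      from = i, to = j, leader = leader, tau_star = tau_star,
      r_star = corr$r[i, j, l_ij], sign = sgn_ij,
      reversible = reversible, weak = weak, stringsAsFactors = FALSE
    )
    rows[[length(rows) + 1L]] <- data.frame(
      from = j, to = i, leader = leader, tau_star = tau_star,
      r_star = corr$r[j, i, l_ji], sign = sgn_ji,
      reversible = reversible, weak = weak, stringsAsFactors = FALSE
    )
  }
  hyps <- if (length(rows) > 0L) {
    do.call(rbind, rows)
  } else {
    data.frame(from = character(), to = character(), leader = character(),
               tau_star = numeric(), r_star = numeric(), sign = numeric(),
               reversible = logical(), weak = logical(),
               stringsAsFactors = FALSE)
  }
  # leader-first ordering within each pair, as reaction hypotheses are read
  if (nrow(hyps) > 0L) {
    hyps$id <- paste0("R", seq_len(nrow(hyps)))
    hyps <- hyps[, c("id", "from", "to", "leader", "tau_star", "r_star",
                     "sign", "reversible", "weak")]
  } else {
    hyps$id <- character()
  }
  structure(list(species = sp, hypotheses = hyps),
            class = "directed_hypotheses")
}

#' @export
print.directed_hypotheses <- function(x, ...) {
  h <- x$hypotheses
  cat(sprintf("Directed hypotheses: %d reactions (%d edges)\n",
              nrow(h), nrow(h) / 2L))
  if (nrow(h) > 0L) {
    for (k in seq_len(nrow(h))) {
      cat(sprintf("  %-4s %s -> %s  (leader %s, tau* = %.3g%s%s)\n",
                  h$id[k], h$from[k], h$to[k],
                  ifelse(is.na(h$leader[k]), "-", h$leader[k]),
                  h$tau_star[k],
                  ifelse(h$reversible[k], ", reversible", ""),
                  ifelse(h$weak[k], ", weak", "")))
    }
  }
  invisible(x)
}

#' Convert directed hypotheses into a reaction network
#'
#' Emits one first-order conversion per hypothesis row, ready for the
#' calibration stage or for [write_reactions()].
#'
#' @param hyp a [orient()] result.
#' @return A [reaction_network()].
#' @export
hypotheses_network <- function(hyp) {
  stopifnot(inherits(hyp, "directed_hypotheses"))
  h <- hyp$hypotheses
  reaction_network(
    data.frame(id = h$id, from = h$from, to = h$to,
               stringsAsFactors = FALSE),
    species = hyp$species
  )
}
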
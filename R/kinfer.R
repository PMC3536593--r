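#' Build a generalized mass action model from a reaction list
#'
#' Each first-order conversion A -> B with rate constant k contributes the
#' monomial -k X_A to dA/dt and +k X_A to dB/dt. Every reaction keeps its
#' own parameter, also when reactions share structure.
#'
#' @param net a [reaction_network()].
#' @return Object of class `gma_model`: `species`, `params` (reaction ids,
#'   one parameter per reaction) and `terms`, a per-species list of monomial
#'   terms `(par, sign, species, alpha)`.
#' @export
build_gma <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  sp <- net$species
  terms <- setNames(vector("list", length(sp)), sp)
  for (s in sp) terms[[s]] <- list()
  rx <- net$reactions
  for (p in seq_len(nrow(rx))) {
    from <- rx$from[p]
    to <- rx$to[p]
    term <- list(par = p, species = from, alpha = 1)
    terms[[from]] <- c(terms[[from]], list(c(term, sign = -1)))
    terms[[to]] <- c(terms[[to]], list(c(term, sign = +1)))
  }
  structure(
    list(species = sp, params = rx$id, reactions = rx, terms = terms),
    class = "gma_model"
  )
}

#' @export
print.gma_model <- function(x, ...) {
  cat(sprintf("GMA model: %d species, %d parameters\n",
              length(x$species), length(x$params)))
  invisible(x)
}

#' Concentration increments of a time series
#'
#' First differences D_i(t_k) = X_i(t_k) - X_i(t_{k-1}) per species, with
#' the time steps the rate model needs to predict them.
#'
#' @param ts a [timeseries_set()] (or any object with `times` and `values`).
#' @return Object of class `increment_data`: `species`, `D` (M x N matrix),
#'   `dt` (length M), `times`, `M`.
#' @export
increments <- function(ts) {
  stopifnot(inherits(ts, "tlc_timeseries"))
  m <- length(ts$times)
  if (m < 2L) stop("need at least 2 samples", call. = FALSE)
  D <- ts$values[-1L, , drop = FALSE] - ts$values[-m, , drop = FALSE]
  structure(
    list(species = ts$species, D = D, dt = diff(ts$times),
         times = ts$times, M = m - 1L),
    class = "increment_data"
  )
}

# Gauss-Hermite nodes/weights by Golub-Welsch (physicists' convention)
gauss_hermite <- function(n) {
  if (n == 1L) return(list(x = 0, w = sqrt(pi)))
  off <- sqrt(seq_len(n - 1L) / 2)
  J <- diag(0, n)
  J[cbind(1:(n - 1L), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1L, ]^2)
}

# E[X^a] for X ~ N(mu, sd^2); closed-form moments for integer a,
# Gauss-Hermite with clipping at zero otherwise
power_moment <- function(mu, sd, alpha, nodes = 11L) {
  if (sd <= 0) return(pmax(mu, if (alpha %% 1 == 0) -Inf else 0)^alpha)
  if (alpha %% 1 == 0 && alpha >= 0) {
    a <- as.integer(alpha)
    if (a == 0L) return(rep(1, length(mu)))
    m_prev <- rep(1, length(mu))  # E[X^0]
    m_cur <- mu                   # E[X^1]
    if (a == 1L) return(m_cur)
    for (k in 2:a) {
      m_next <- mu * m_cur + (k - 1) * sd^2 * m_prev
      m_prev <- m_cur
      m_cur <- m_next
    }
    return(m_cur)
  }
  gh <- gauss_hermite(nodes)
  if (any(mu - 4 * sd < 0)) {
    warning("quadrature near zero concentration; integrand clipped at 0",
            call. = FALSE)
  }
  vapply(mu, function(m) {
    x <- m + sqrt(2) * sd * gh$x
    sum(gh$w * pmax(x, 0)^alpha) / sqrt(pi)
  }, numeric(1L))
}

#' Expected reaction rate under observation noise
#'
#' E\[f_i(X)\] where each concentration is independently normal around its
#' observed value with standard deviation `sigma`. Integer exponents use
#' closed-form Gaussian moments (E\[X\] = Xhat, E\[X^2\] = Xhat^2 + sigma^2,
#' ...); non-integer exponents use Gauss-Hermite quadrature with the
#' integrand clipped at zero concentration.
#'
#' @param model a [build_gma()] model.
#' @param state named vector of observed concentrations.
#' @param theta parameter vector (one entry per model parameter).
#' @param sigma observation noise standard deviation (>= 0).
#' @param cfg configuration list (`fit$quad_nodes`).
#' @return Named vector of expected rates, one per species.
#' @export
expected_rate <- function(model, state, theta, sigma, cfg = tlc_config()) {
  stopifnot(inherits(model, "gma_model"), sigma >= 0)
  vapply(model$species, function(s) {
    val <- 0
    for (term in model$terms[[s]]) {
      mono <- prod(vapply(seq_along(term$species), function(w) {
        power_moment(state[[term$species[w]]], sigma, term$alpha[w],
                     cfg$fit$quad_nodes)
      }, numeric(1L)))
      val <- val + term$sign * theta[term$par] * mono
    }
    val
  }, numeric(1L))
}

#' Tridiagonal covariance of the increment vector
#'
#' Shared measurement noise at consecutive observation times makes adjacent
#' increments anticorrelated: Cov(D) has diagonal 2 sigma^2 and first
#' off-diagonals -sigma^2. Determinant and linear solves use the closed
#' forms of this matrix (det = sigma^(2M) (M+1); solve by the discrete
#' Green's function), which are stable for any M.
#'
#' @param sigma noise standard deviation (> 0).
#' @param M number of increments (>= 1).
#' @return Object of class `banded_covariance`: `sigma`, `M`, `matrix`,
#'   `logdet`, `det`, and `solve(v)` / `quad(v)` operators.
#' @export
banded_covariance <- function(sigma, M) {
  stopifnot(M >= 1L)
  if (sigma <= 0) {
    stop("sigma must be positive (singular covariance otherwise)",
         call. = FALSE)
  }
  mat <- diag(2 * sigma^2, M)
  if (M > 1L) {
    idx <- cbind(1:(M - 1L), 2:M)
    mat[idx] <- -sigma^2
    mat[idx[, 2:1, drop = FALSE]] <- -sigma^2
  }
  logdet <- 2 * M * log(sigma) + log(M + 1)
  solve_fn <- function(v) tridiag_green_solve(v) / sigma^2
  structure(
    list(sigma = sigma, M = M, matrix = mat, logdet = logdet,
         det = exp(logdet), solve = solve_fn,
         quad = function(v) sum(v * solve_fn(v))),
    class = "banded_covariance"
  )
}

# solve K y = v for K = tridiag(-1, 2, -1) via its Green's function
# G_kl = min(k,l) (M+1-max(k,l)) / (M+1), in O(M) with cumulative sums
tridiag_green_solve <- function(v) {
  M <- length(v)
  k <- seq_len(M)
  c1 <- cumsum(k * v)                       # sum_{l<=k} l v_l
  c2 <- rev(cumsum(rev((M + 1 - k) * v)))   # sum_{l>=k} (M+1-l) v_l
  c2next <- c(c2[-1L], 0)                   # sum_{l>k}
  ((M + 1 - k) * c1 + k * c2next) / (M + 1)
}

# per-species design matrices Phi_i (M x P): column p holds the signed,
# time-step-scaled expected monomial of parameter p in f_i at t_{k-1}
gma_design <- function(model, ts, sigma, cfg) {
  inc <- increments(ts)
  M <- inc$M
  P <- length(model$params)
  X <- ts$values[seq_len(M), , drop = FALSE]
  lapply(model$species, function(s) {
    Phi <- matrix(0, M, P)
    for (term in model$terms[[s]]) {
      mono <- rep(1, M)
      for (w in seq_along(term$species)) {
        mono <- mono * power_moment(X[, term$species[w]], sigma,
                                    term$alpha[w], cfg$fit$quad_nodes)
      }
      Phi[, term$par] <- Phi[, term$par] + term$sign * inc$dt * mono
    }
    Phi
  })
}

gma_is_linear <- function(model) {
  all(vapply(model$terms, function(tl) {
    all(vapply(tl, function(term) all(term$alpha == 1), logical(1L)))
  }, logical(1L)))
}

#' Negative log-likelihood of the observed increments
#'
#' Minus the log of the increment likelihood: for each species,
#' (1/2) (D_i - m_i)' C^{-1} (D_i - m_i), plus (N/2) log det C and the
#' Gaussian constant, with the model prediction
#' m_i(t_k) = (t_k - t_{k-1}) E\[f_i(X(t_{k-1}))\] and C the tridiagonal
#' increment covariance of [banded_covariance()].
#'
#' @param model a [build_gma()] model.
#' @param ts a [timeseries_set()] of the observed concentrations.
#' @param theta nonnegative parameter vector.
#' @param sigma noise level (> 0).
#' @param cfg configuration list.
#' @return The scalar negative log-likelihood (`Inf` when the model
#'   prediction is non-finite).
#' @export
neg_log_likelihood <- function(model, ts, theta, sigma,
                               cfg = tlc_config()) {
  design <- gma_design(model, ts, sigma, cfg)
  inc <- increments(ts)
  nll_from_design(design, inc$D[, model$species, drop = FALSE],
                  inc$M, theta, sigma)
}

nll_from_design <- function(design, D, M, theta, sigma) {
  N <- length(design)
  total <- 0
  for (i in seq_len(N)) {
    m_i <- design[[i]] %*% theta
    r <- D[, i] - as.numeric(m_i)
    if (any(!is.finite(r))) return(Inf)
    total <- total + 0.5 * sum(r * tridiag_green_solve(r)) / sigma^2
  }
  total + N * (M * log(sigma) + 0.5 * log(M + 1)) +
    N * M / 2 * log(2 * pi)
}
# (D must be column-aligned with the design list, i.e. model-species order)

#' Maximum-likelihood estimation of GMA rate constants
#'
#' Jointly maximises the increment likelihood over the nonnegative rate
#' constants and the noise level. Initial guesses come from a nonnegative
#' least-squares regression of the increments on the monomial predictors;
#' the optimiser is bounded quasi-Newton (L-BFGS-B) with upper bounds a
#' fixed multiple of the initial guesses. Standard errors are taken from
#' the inverse observed information at the optimum; parameters whose
#' information is singular get infinite standard errors (and are therefore
#' pruned downstream).
#'
#' @param model a [build_gma()] model.
#' @param ts a [timeseries_set()] covering all model species.
#' @param cfg configuration list (`fit$...` group).
#' @return Object of class `gma_fit`: `theta` (named), `se`, `sigma`,
#'   `nll`, `nll_init`, `converged`, `theta0`.
#' @export
fit_gma <- function(model, ts, cfg = tlc_config()) {
  stopifnot(inherits(model, "gma_model"), inherits(ts, "tlc_timeseries"))
  missing_sp <- setdiff(model$species, ts$species)
  if (length(missing_sp) > 0L) {
    stop("model references unmeasured species: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  inc <- increments(ts)
  P <- length(model$params)
  N <- length(model$species)
  if (inc$M * N <= P + 1L) {
    stop("too few increments to identify the parameters", call. = FALSE)
  }
  linear <- gma_is_linear(model)
  design0 <- gma_design(model, ts, 0, cfg)
  Dmat <- inc$D[, model$species, drop = FALSE]

  A <- do.call(rbind, design0)
  d <- as.numeric(Dmat)
  theta0 <- tryCatch(pracma::lsqnonneg(A, d)$x,
                     error = function(e) rep(0, P))
  resid0 <- d - as.numeric(A %*% theta0)
  sigma_floor <- cfg$fit$sigma_floor_rel * max(median(abs(ts$values)), 1e-8)
  sigma0 <- max(sd(resid0) / sqrt(2), sigma_floor * 10, 1e-8)

  if (linear) {
    # exact maximum likelihood: theta minimises the K^-1-metric residual
    # independently of sigma (the quadratic form merely scales with it),
    # so a generalised-least-squares NNLS gives the global optimum, and
    # sigma has the closed form quad / (N M)
    R <- chol(banded_covariance(1, inc$M)$matrix)  # K = R'R
    Aw <- do.call(rbind, lapply(design0, function(Phi) {
      backsolve(R, Phi, transpose = TRUE)
    }))
    bw <- as.numeric(vapply(seq_len(N), function(i) {
      backsolve(R, Dmat[, i], transpose = TRUE)
    }, numeric(inc$M)))
    theta_hat <- tryCatch(pracma::lsqnonneg(Aw, bw)$x,
                          error = function(e) theta0)
    quad <- sum((bw - as.numeric(Aw %*% theta_hat))^2)
    sigma_hat <- max(sqrt(quad / (N * inc$M)), sigma_floor)
    nll_opt <- nll_from_design(design0, Dmat, inc$M, theta_hat, sigma_hat)
    nll_init <- nll_from_design(design0, Dmat, inc$M, theta0, sigma0)
    if (!is.finite(nll_opt) || nll_opt > nll_init) {
      theta_hat <- theta0
      sigma_hat <- sigma0
      nll_opt <- nll_init
    }
    opt <- list(par = c(theta_hat, sigma_hat), value = nll_opt,
                convergence = 0L)
  } else {
    # nonlinear monomials: bounded quasi-Newton over (theta, sigma) from
    # the NNLS warm start, bounds a fixed multiple of the initial guesses
    ref <- max(theta0, sigma0, 1e-3)
    upper <- c(pmax(theta0, ref) * cfg$fit$bound_factor, Inf)
    lower <- c(rep(0, P), sigma_floor)
    obj <- function(par) {
      theta <- par[seq_len(P)]
      sigma <- par[P + 1L]
      design <- gma_design(model, ts, sigma, cfg)
      val <- nll_from_design(design, Dmat, inc$M, theta, sigma)
      if (!is.finite(val)) val <- 1e12
      val
    }
    par0 <- c(theta0, sigma0)
    nll_init <- obj(par0)
    opt <- optim(par0, obj, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = cfg$fit$maxit))
    if (opt$value > nll_init) {  # never worse than the warm start
      opt$par <- par0
      opt$value <- nll_init
      opt$convergence <- 1L
    }
  }
  theta_hat <- setNames(opt$par[seq_len(P)], model$params)
  sigma_hat <- opt$par[P + 1L]

  se <- rep(Inf, P)
  H <- if (linear) {
    # observed information in closed form for the linear-in-X case
    sg <- sigma_hat
    Hth <- matrix(0, P, P)
    hts <- numeric(P)
    quad <- 0
    for (i in seq_along(design0)) {
      Phi <- design0[[i]]
      r <- Dmat[, i] - as.numeric(Phi %*% theta_hat)
      Kr <- tridiag_green_solve(r)
      KPhi <- apply(Phi, 2L, tridiag_green_solve)
      Hth <- Hth + crossprod(Phi, KPhi) / sg^2
      hts <- hts + 2 * as.numeric(crossprod(Phi, Kr)) / sg^3
      quad <- quad + sum(r * Kr)
    }
    rbind(cbind(Hth, hts),
          c(hts, 3 * quad / sg^4 - N * inc$M / sg^2))
  } else {
    obj_h <- function(par) {
      design <- gma_design(model, ts, par[P + 1L], cfg)
      nll_from_design(design, Dmat, inc$M, par[seq_len(P)], par[P + 1L])
    }
    tryCatch(optimHess(opt$par, obj_h), error = function(e) NULL)
  }
  if (!is.null(H)) {
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(cov)) {
      cov <- tryCatch(MASS_ginv(H), error = function(e) NULL)
    }
    if (!is.null(cov)) {
      v <- diag(cov)[seq_len(P)]
      se <- ifelse(is.finite(v) & v > 0, sqrt(v), Inf)
    }
  }
  structure(
    list(theta = theta_hat, se = setNames(se, model$params),
         sigma = sigma_hat, nll = opt$value, nll_init = nll_init,
         converged = opt$convergence == 0L, theta0 = theta0,
         model = model),
    class = "gma_fit"
  )
}

# Moore-Penrose pseudoinverse via SVD (used when the information matrix is
# numerically singular; affected parameters surface as huge variances)
MASS_ginv <- function(H, tol = sqrt(.Machine$double.eps)) {
  s <- svd(H)
  pos <- s$d > tol * s$d[1L]
  if (!any(pos)) return(NULL)
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.gma_fit <- function(x, ...) {
  cat(sprintf(
    "GMA maximum-likelihood fit: %d parameters, sigma = %.4g, NLL = %.6g%s\n",
    length(x$theta), x$sigma, x$nll,
    if (x$converged) "" else " (not converged)"
  ))
  invisible(x)
}

#' @export
summary.gma_fit <- function(object, ...) {
  out <- data.frame(
    id = names(object$theta), k = unname(object$theta),
    dk = unname(object$se),
    ratio = unname(ifelse(object$theta > 0, object$se / object$theta, Inf)),
    stringsAsFactors = FALSE
  )
  cat(sprintf("sigma = %.6g; NLL = %.6g\n", object$sigma, object$nll))
  print(out, digits = 4)
  invisible(out)
}

#' @export
coef.gma_fit <- function(object, ...) object$theta

#' Prune null-kinetics reactions
#'
#' Removes every reaction whose estimated rate constant is nonpositive or
#' whose relative standard error Delta k / k reaches the threshold rho:
#' such kinetics are read as noise, not as a biochemical process. Surviving
#' reactions carry their estimates.
#'
#' @param est a [fit_gma()] result whose parameter names match the reaction
#'   ids of `net`, or `NULL` to use the `k`/`dk` columns already stored in
#'   `net` (e.g. a printed table of estimates).
#' @param net a [reaction_network()] of the fitted hypotheses.
#' @param cfg configuration list (`prune$relative_error` is rho; the default
#'   1.0 cuts at "error equal to the estimate", 0.5 gives the stricter 50%
#'   rule).
#' @return The retained [reaction_network()], with a data-frame attribute
#'   `"report"` tabulating every reaction's `k`, `dk`, `ratio` and `kept`.
#' @export
prune <- function(est, net, cfg = tlc_config()) {
  stopifnot(inherits(net, "reaction_network"))
  rx <- net$reactions
  if (!is.null(est)) {
    stopifnot(inherits(est, "gma_fit"))
    idx <- match(rx$id, names(est$theta))
    if (any(is.na(idx))) {
      stop("fit does not cover all reactions of the network", call. = FALSE)
    }
    rx$k <- unname(est$theta[idx])
    rx$dk <- unname(est$se[idx])
  }
  if (any(is.na(rx$k)) || any(is.na(rx$dk))) {
    stop("reactions without (k, dk) estimates cannot be pruned",
         call. = FALSE)
  }
  rho <- cfg$prune$relative_error
  ratio <- ifelse(rx$k > 0, rx$dk / rx$k, Inf)
  kept <- rx$k > 0 & ratio < rho
  report <- data.frame(id = rx$id, from = rx$from, to = rx$to, k = rx$k,
                       dk = rx$dk, ratio = ratio, kept = kept,
                       stringsAsFactors = FALSE)
  out <- reaction_network(rx[kept, , drop = FALSE], species = net$species)
  attr(out, "report") <- report
  out
}
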
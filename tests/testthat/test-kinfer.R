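test_that("a single conversion induces the expected rate functions", {
  net <- reaction_network(
    data.frame(id = "R1", from = "A", to = "B", k = 1,
               stringsAsFactors = FALSE)
  )
  model <- build_gma(net)
  r <- expected_rate(model, c(A = 2, B = 0), theta = 1, sigma = 0)
  expect_equal(unname(r["A"]), -2)
  expect_equal(unname(r["B"]), 2)
})

test_that("the reference network induces ten balanced rate functions", {
  model <- build_gma(reference_network())
  expect_equal(length(model$species), 10L)
  expect_equal(length(model$params), 19L)
  # the monophosphate balance collects five conversions
  expect_equal(length(model$terms[["dFdCMP"]]), 5L)
  touching <- sort(model$reactions$id[
    model$reactions$from == "dFdCMP" | model$reactions$to == "dFdCMP"
  ])
  expect_equal(touching, c("E10", "E13", "E7", "E8", "E9"))
})

test_that("an empty network yields all-zero rates", {
  net <- reaction_network(
    data.frame(id = character(), from = character(), to = character(),
               stringsAsFactors = FALSE),
    species = c("A", "B")
  )
  model <- build_gma(net)
  r <- expected_rate(model, c(A = 1, B = 2), theta = numeric(0), sigma = 0)
  expect_equal(unname(r), c(0, 0))
})

test_that("increments telescope to the endpoint difference", {
  ts <- timeseries_set(0:2, cbind(A = c(1, 3, 2)))
  inc <- increments(ts)
  expect_equal(unname(inc$D[, 1]), c(2, -1))
  set.seed(12)
  ts2 <- timeseries_set(seq(0, 5, by = 0.5),
                        cbind(A = rnorm(11), B = rnorm(11)))
  inc2 <- increments(ts2)
  expect_equal(colSums(inc2$D),
               ts2$values[11, ] - ts2$values[1, ], tolerance = 1e-12)
  ts3 <- timeseries_set(0:4, cbind(A = rep(2, 5)))
  expect_true(all(increments(ts3)$D == 0))
})

test_that("expected monomials follow Gaussian moments and quadrature", {
  net <- reaction_network(
    data.frame(id = "R1", from = "A", to = "B", stringsAsFactors = FALSE)
  )
  model <- build_gma(net)
  # quadratic monomial: E[X^2] = Xhat^2 + sigma^2
  model$terms[["B"]][[1]]$alpha <- 2
  r <- expected_rate(model, c(A = 2, B = 0), theta = 1, sigma = 1)
  expect_equal(unname(r["B"]), 5)
  # linear case is exact for any sigma
  model$terms[["B"]][[1]]$alpha <- 1
  r1 <- expected_rate(model, c(A = 2, B = 0), theta = 1, sigma = 3)
  expect_equal(unname(r1["B"]), 2)
  # fractional exponent against a Monte-Carlo oracle
  model$terms[["B"]][[1]]$alpha <- 1.5
  r15 <- suppressWarnings(
    expected_rate(model, c(A = 4, B = 0), theta = 1, sigma = 1)
  )
  set.seed(77)
  mc <- mean(pmax(rnorm(1e6, 4, 1), 0)^1.5)
  expect_lt(abs(r15[["B"]] - mc) / mc, 0.005)
})

test_that("the banded covariance has its closed-form determinant", {
  C2 <- banded_covariance(1, 2)
  expect_equal(C2$matrix, matrix(c(2, -1, -1, 2), 2, 2))
  expect_equal(C2$det, 3, tolerance = 1e-12)
  C3 <- banded_covariance(1, 3)
  expect_equal(C3$det, 4, tolerance = 1e-12)  # det_M = M + 1 recurrence
  for (M in c(1, 5, 20)) {
    Cs <- banded_covariance(0.7, M)
    expect_equal(Cs$logdet, as.numeric(determinant(Cs$matrix)$modulus),
                 tolerance = 1e-9)
    expect_true(all(eigen(Cs$matrix, only.values = TRUE)$values > 0))
    v <- rnorm(M)
    expect_equal(as.numeric(Cs$matrix %*% Cs$solve(v)), v, tolerance = 1e-9)
  }
  expect_error(banded_covariance(0, 5), "positive")
})

test_that("the likelihood matches a dense-matrix evaluation", {
  set.seed(21)
  for (case in 1:4) {
    k <- runif(2, 0.2, 1)
    ts <- make_chain_series(k, m = 9, dt = 0.3)
    ts$values <- ts$values + matrix(rnorm(length(ts$values), 0, 0.05),
                                    nrow(ts$values))
    net <- chain_network(k)
    model <- build_gma(net)
    theta <- runif(2, 0.1, 1)
    sigma <- runif(1, 0.05, 0.5)
    got <- neg_log_likelihood(model, ts, theta, sigma)
    # dense oracle
    inc <- increments(ts)
    M <- inc$M
    Cd <- banded_covariance(sigma, M)$matrix
    dense <- 0
    for (i in seq_along(model$species)) {
      sp <- model$species[i]
      pred <- inc$dt * vapply(seq_len(M), function(r) {
        expected_rate(model, ts$values[r, ], theta, sigma)[[sp]]
      }, numeric(1))
      r_ <- inc$D[, sp] - pred
      dense <- dense + 0.5 * t(r_) %*% solve(Cd) %*% r_
    }
    dense <- dense + length(model$species) *
      (0.5 * determinant(Cd)$modulus[1] + M / 2 * log(2 * pi))
    expect_equal(got, as.numeric(dense), tolerance = 1e-10)
  }
})

test_that("a perfect prediction leaves only the determinant term", {
  k <- 0.5
  ts <- make_chain_series(k, m = 20, dt = 0.1)
  net <- chain_network(k)
  model <- build_gma(net)
  sigma <- 0.3
  M <- increments(ts)$M
  got <- neg_log_likelihood(model, ts, theta = k, sigma = sigma)
  const <- 2 * (M * log(sigma) + 0.5 * log(M + 1)) + 2 * M / 2 * log(2 * pi)
  expect_equal(got, const, tolerance = 1e-9)
})

test_that("noiseless rate constants are recovered to high precision", {
  k <- 0.5
  ts <- make_chain_series(k, m = 51, dt = 0.2)
  fit <- fit_gma(build_gma(chain_network(k)), ts)
  expect_equal(unname(fit$theta[["R1"]]), 0.5, tolerance = 1e-3)
  expect_lte(fit$nll, fit$nll_init)

  # grid-search oracle over k confirms the optimum location
  nll_of <- function(kk) neg_log_likelihood(build_gma(chain_network(k)),
                                            ts, kk, fit$sigma)
  grid <- seq(0.4, 0.6, by = 0.005)
  expect_equal(grid[which.min(vapply(grid, nll_of, numeric(1)))], 0.5,
               tolerance = 0.01)
})

test_that("a five-reaction chain is recovered from exact finite differences", {
  k <- c(0.8, 0.5, 0.3, 0.6, 0.4)
  ts <- make_chain_series(k, m = 80, dt = 0.1)
  fit <- fit_gma(build_gma(chain_network(k)), ts)
  expect_equal(unname(fit$theta), k, tolerance = 1e-3)
})

test_that("noisy estimates stay near truth with positive standard errors", {
  k <- 0.5
  hits <- 0
  ks <- numeric(20)
  for (s in 1:20) {
    set.seed(100 + s)
    ts <- make_chain_series(k, m = 51, dt = 0.2)
    ts$values <- pmax(ts$values * (1 + 0.05 * rnorm(length(ts$values))), 0)
    ts <- timeseries_set(ts$times, ts$values,
                         errors = 0.05 * abs(ts$values))
    fit <- fit_gma(build_gma(chain_network(k)), ts)
    ks[s] <- fit$theta[["R1"]]
    if (fit$se[["R1"]] > 0) hits <- hits + 1
  }
  expect_lt(abs(median(ks) - k) / k, 0.10)
  expect_equal(hits, 20L)
})

test_that("spurious zero-rate reactions earn pruning-grade errors", {
  # a reverse reaction absent from the generating model, at benchmark scale
  flagged <- sum(vapply(1:10, spurious_pruned, logical(1)))
  expect_gte(flagged, 9L)
})

test_that("pruning applies the relative-error rule at its boundary", {
  net <- reaction_network(
    data.frame(id = c("R1", "R11", "RB"),
               from = c("dFdCout", "dFdC", "A"),
               to = c("dFdC", "dFdU", "B"),
               k = c(7.10898534, 0.05303525, 1.0),
               dk = c(0.08340605, 0.11826494, 1.0),
               stringsAsFactors = FALSE)
  )
  kept <- prune(NULL, net)
  expect_true("R1" %in% kept$reactions$id)
  expect_false("R11" %in% kept$reactions$id)
  expect_false("RB" %in% kept$reactions$id)  # ratio exactly 1 is cut
  report <- attr(kept, "report")
  expect_equal(report$ratio[report$id == "R11"],
               0.11826494 / 0.05303525, tolerance = 1e-9)
  # the softer 50% variant is stricter still
  kept50 <- prune(NULL, net, tlc_config(prune = list(relative_error = 0.5)))
  expect_equal(kept50$reactions$id, "R1")
})
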
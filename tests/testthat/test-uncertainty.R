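# small helper: correlation object plus error budget on a toy series
toy_budget <- function(seed = 2, m = 30, rel = 0.07) {
  set.seed(seed)
  x <- cumsum(rnorm(m))
  y <- cumsum(rnorm(m))
  z <- x + 0.5 * y + rnorm(m, sd = 0.2)
  vals <- cbind(A = x, B = y, C = z)
  ts <- timeseries_set(seq_len(m), vals, errors = rel * abs(vals))
  grid <- lag_grid(ts)
  corr <- correlation_tensor(ts, grid)
  list(ts = ts, corr = corr, err = covariance_errors(ts, corr))
}

test_that("zero measurement error produces an identically zero budget", {
  set.seed(4)
  m <- 25
  vals <- cbind(A = cumsum(rnorm(m)), B = cumsum(rnorm(m)))
  ts <- timeseries_set(seq_len(m), vals, errors = matrix(0, m, 2))
  corr <- correlation_tensor(ts, lag_grid(ts))
  err <- covariance_errors(ts, corr)
  expect_true(all(err$dC == 0, na.rm = TRUE))
  dr <- correlation_error(corr, err)
  expect_true(all(dr == 0, na.rm = TRUE))
  dm <- distance_error(distance_matrix(corr), dr)
  expect_true(all(dm$dd == 0, na.rm = TRUE))
})

test_that("the error budget is homogeneous of degree one in the input error", {
  b1 <- toy_budget(rel = 0.05)
  b2 <- toy_budget(rel = 0.10)
  expect_equal(b2$err$dC, 2 * b1$err$dC, tolerance = 1e-9)
  dr1 <- correlation_error(b1$corr, b1$err)
  dr2 <- correlation_error(b2$corr, b2$err)
  expect_equal(dr2, 2 * dr1, tolerance = 1e-9)
  dm1 <- distance_error(distance_matrix(b1$corr), dr1)
  dm2 <- distance_error(distance_matrix(b2$corr), dr2)
  expect_equal(dm2$dd, 2 * dm1$dd, tolerance = 1e-9)
})

test_that("covariance error matches a term-by-term spreadsheet evaluation", {
  vals <- cbind(A = c(1, 3, 2, 5, 4), B = c(2, 2.5, 4, 3, 6))
  errs <- cbind(A = c(0.1, 0.2, 0.1, 0.3, 0.2),
                B = c(0.2, 0.1, 0.2, 0.1, 0.3))
  ts <- timeseries_set(0:4, vals, errors = errs)
  grid <- structure(list(step = 1, lags = 0, tau_species = NULL,
                         tau_min = 0), class = "lag_grid")
  corr <- correlation_tensor(ts, grid)
  got <- covariance_error(ts, corr, 0)
  # independent evaluation with uniform weights over the 5 scatter points
  si <- vals[, 1] - mean(vals[, 1])
  sj <- vals[, 2] - mean(vals[, 2])
  dSi <- errs[, 1] + mean(errs[, 1])
  dSj <- errs[, 2] + mean(errs[, 2])
  # |S_i S_j| rss(dS_i/S_i, dS_j/S_j), written in its cancelled form so a
  # centred value of zero stays finite
  per_time <- sqrt((dSi * sj)^2 + (si * dSj)^2)
  expect_equal(got["A", "B"], mean(per_time), tolerance = 1e-10)
})

test_that("correlation error reproduces the textbook substitution case", {
  # r = 0.5 with a 10% relative covariance error and exact variances
  corr <- structure(
    list(species = c("A", "B"), lags = 0, step = 1,
         C = array(c(1, 0.5, 0.5, 1), c(2, 2, 1)),
         Vi = array(1, c(2, 2, 1)), Vj = array(1, c(2, 2, 1)),
         r = array(c(1, 0.5, 0.5, 1), c(2, 2, 1))),
    class = "lagged_correlation"
  )
  err <- list(dC = array(c(0, 0.05, 0.05, 0), c(2, 2, 1)),
              dVi = array(0, c(2, 2, 1)), dVj = array(0, c(2, 2, 1)))
  dr <- correlation_error(corr, err)
  expect_equal(dr[1, 2, 1], 0.05, tolerance = 1e-12)
})

test_that("correlation error equals the gradient-based oracle", {
  b <- toy_budget()
  dr <- correlation_error(b$corr, b$err)
  # finite-difference sensitivities of r = C / sqrt(Vi Vj)
  h <- 1e-6
  for (idx in list(c(1, 2, 1), c(2, 3, 1), c(1, 3, 2))) {
    a <- idx[1]; bb <- idx[2]; l <- idx[3]
    if (l > length(b$corr$lags)) next
    C <- b$corr$C[a, bb, l]; Vi <- b$corr$Vi[a, bb, l]
    Vj <- b$corr$Vj[a, bb, l]
    r_of <- function(C, Vi, Vj) C / sqrt(abs(Vi * Vj))
    gC <- (r_of(C + h, Vi, Vj) - r_of(C - h, Vi, Vj)) / (2 * h)
    gVi <- (r_of(C, Vi + h, Vj) - r_of(C, Vi - h, Vj)) / (2 * h)
    gVj <- (r_of(C, Vi, Vj + h) - r_of(C, Vi, Vj - h)) / (2 * h)
    oracle <- sqrt((gC * b$err$dC[a, bb, l])^2 +
                     (gVi * b$err$dVi[a, bb, l])^2 +
                     (gVj * b$err$dVj[a, bb, l])^2)
    expect_equal(dr[a, bb, l], oracle, tolerance = 0.05)
  }
})

test_that("distance error reproduces the substitution case and the oracle", {
  # d = 0.8 with dc_ij = 0.08 and exact diagonals: delta d = 0.1
  dm <- structure(
    list(species = c("A", "B"),
         c = matrix(c(1, 0.68, 0.68, 1), 2, 2,
                    dimnames = list(c("A", "B"), c("A", "B"))),
         d = matrix(c(0, 0.8, 0.8, 0), 2, 2,
                    dimnames = list(c("A", "B"), c("A", "B"))),
         dd = NULL, square_root = TRUE),
    class = "tlc_distance"
  )
  dr <- array(c(0, 0.08, 0.08, 0), c(2, 2, 1))
  out <- distance_error(dm, dr)
  expect_equal(out$dd["A", "B"], 2 * 0.08 / (2 * 0.8), tolerance = 1e-12)

  # three-species toy against coordinate-wise finite differences
  b <- toy_budget()
  dmat <- distance_matrix(b$corr)
  drr <- correlation_error(b$corr, b$err)
  out3 <- distance_error(dmat, drr)
  h <- 1e-7
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    a <- pair[1]; bb <- pair[2]
    d_of <- function(cii, cij, cjj) sqrt(abs(cii - 2 * cij + cjj))
    cii <- dmat$c[a, a]; cjj <- dmat$c[bb, bb]; cij <- dmat$c[a, bb]
    g_ii <- abs((d_of(cii + h, cij, cjj) - d_of(cii - h, cij, cjj)) / (2 * h))
    g_ij <- abs((d_of(cii, cij + h, cjj) - d_of(cii, cij - h, cjj)) / (2 * h))
    g_jj <- abs((d_of(cii, cij, cjj + h) - d_of(cii, cij, cjj - h)) / (2 * h))
    oracle <- g_ii * out3$dc[a, a] + g_ij * out3$dc[a, bb] +
      g_jj * out3$dc[bb, bb]
    expect_equal(out3$dd[a, bb], oracle, tolerance = 0.05)
  }
})

test_that("stress error matches its substitution case and a numeric Jacobian", {
  # single residual of 0.5 at S = 1 with delta d = 0.2 gives delta S = 0.1
  emb <- structure(
    list(dimension = 1, coords = matrix(c(0, 0.5), 2, 1),
         stress = 1, dmat = matrix(c(0, 1, 1, 0), 2, 2)),
    class = "tlc_embedding"
  )
  dd <- matrix(c(0, 0.2, 0.2, 0), 2, 2)
  expect_equal(stress_error(emb, dd), 0.5 * 0.2 / 1, tolerance = 1e-12)
  emb0 <- emb
  emb0$stress <- 0
  expect_equal(stress_error(emb0, dd), 0)

  set.seed(8)
  pts <- matrix(rnorm(8), 4, 2)
  dmat <- config_distances(pts)
  dmat[upper.tri(dmat)] <- dmat[upper.tri(dmat)] + runif(6, 0.05, 0.2)
  dmat[lower.tri(dmat)] <- t(dmat)[lower.tri(dmat)]
  emb2 <- fit_embedding(dmat, 2, restarts = 5, seed = 1)
  dd2 <- matrix(0.03, 4, 4); diag(dd2) <- 0
  got <- stress_error(emb2, dd2)
  h <- 1e-6
  oracle <- 0
  for (a in 1:3) for (bb in (a + 1):4) {
    dp <- dmat; dm_ <- dmat
    dp[a, bb] <- dp[bb, a] <- dp[a, bb] + h
    dm_[a, bb] <- dm_[bb, a] <- dm_[a, bb] - h
    g <- (stress(emb2$coords, dp) - stress(emb2$coords, dm_)) / (2 * h)
    oracle <- oracle + abs(g) * dd2[a, bb]
  }
  expect_equal(got, oracle, tolerance = 0.05)
})
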
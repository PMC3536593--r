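# small fixtures built in code, shared across test files

# uniformly sampled sine/cosine pair with a known phase shift
make_shifted_pair <- function(shift_steps, m = 120, step = 0.5,
                              noise = 0, seed = 1) {
  set.seed(seed)
  t <- seq(0, by = step, length.out = m + shift_steps)
  base <- sin(t / 3) + 0.5 * cos(t / 7)
  xi <- base[seq_len(m) + shift_steps]   # i runs ahead of j
  xj <- base[seq_len(m)] + rnorm(m, 0, noise)
  timeseries_set(t[seq_len(m)], cbind(A = xi, B = xj))
}

# linear chain A1 -> A2 -> ... over Euler-exact finite differences, so the
# increment model holds exactly
make_chain_series <- function(k, m = 60, dt = 0.1, x0 = NULL) {
  n <- length(k) + 1L
  sp <- paste0("S", seq_len(n))
  if (is.null(x0)) x0 <- c(10, rep(0, n - 1L))
  X <- matrix(0, m, n, dimnames = list(NULL, sp))
  X[1L, ] <- x0
  for (r in 2:m) {
    x <- X[r - 1L, ]
    f <- numeric(n)
    for (p in seq_along(k)) {
      f[p] <- f[p] - k[p] * x[p]
      f[p + 1L] <- f[p + 1L] + k[p] * x[p]
    }
    X[r, ] <- x + dt * f
  }
  timeseries_set(seq(0, by = dt, length.out = m), X)
}

chain_network <- function(k) {
  n <- length(k) + 1L
  sp <- paste0("S", seq_len(n))
  reaction_network(
    data.frame(id = paste0("R", seq_along(k)),
               from = sp[-n], to = sp[-1L], k = k,
               stringsAsFactors = FALSE),
    species = sp
  )
}

# distance matrix of a point configuration
config_distances <- function(pts) {
  as.matrix(stats::dist(pts))
}

# fraction of interior fixed-grid cells whose aggregated Voronoi density is
# within a factor two of the histogram density (the independent oracle)
voronoi_hist_frac <- function(seed, n = 500, bins = 10L) {
  set.seed(seed)
  pts <- matrix(rnorm(2L * n), ncol = 2)
  v <- voronoi_density(pts)
  bx <- seq(min(pts[, 1]), max(pts[, 1]), length.out = bins + 1L)
  by <- seq(min(pts[, 2]), max(pts[, 2]), length.out = bins + 1L)
  ix <- findInterval(pts[, 1], bx, rightmost.closed = TRUE)
  iy <- findInterval(pts[, 2], by, rightmost.closed = TRUE)
  counts <- table(factor(ix, seq_len(bins)), factor(iy, seq_len(bins)))
  hist_density <- counts / (n * diff(bx)[1L] * diff(by)[1L])
  cell <- paste(ix, iy)
  vmean <- tapply(v$density, cell, mean)
  inner <- 2:(bins - 1L)
  keys <- as.vector(outer(inner, inner, paste))
  keys <- keys[keys %in% names(vmean)]
  ids <- do.call(rbind, strsplit(keys, " "))
  ratio <- vmean[keys] /
    hist_density[cbind(as.integer(ids[, 1]), as.integer(ids[, 2]))]
  mean(ratio > 0.5 & ratio < 2, na.rm = TRUE)
}

# Euler-exact two-species conversion with a spurious reverse hypothesis,
# at the benchmark scale; returns TRUE when the spurious reaction is pruned
spurious_pruned <- function(seed, k = 0.5, n = 200, dt = 0.1) {
  set.seed(seed)
  X <- matrix(0, n, 2, dimnames = list(NULL, c("S1", "S2")))
  X[1, ] <- c(10, 0)
  for (r in 2:n) {
    x <- X[r - 1, ]
    X[r, ] <- x + dt * c(-k * x[1], k * x[1])
  }
  Xn <- pmax(X * (1 + 0.07 * matrix(rnorm(2 * n), n, 2)), 0)
  ts <- timeseries_set(seq(0, by = dt, length.out = n), Xn,
                       errors = 0.07 * abs(Xn))
  net <- reaction_network(
    data.frame(id = c("R1", "Z"), from = c("S1", "S2"),
               to = c("S2", "S1"), stringsAsFactors = FALSE)
  )
  kept <- prune(fit_gma(build_gma(net), ts), net)$reactions$id
  !"Z" %in% kept
}
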
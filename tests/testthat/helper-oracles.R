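# Independent oracles used across tests. These re-derive expected values by
# brute force or textbook formulas and must stay independent of the package
# implementation.

# textbook Welch statistic and two-sided p
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# step-up BH by explicit enumeration over ranks
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(o == i)  # rank of p[i]
    q[i] <- min(1, min(m * p[o][j:m] / (j:m)))
  }
  q
}

# two-sided Fisher p by full hypergeometric enumeration
# (minimum-likelihood convention)
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# restricted-percentile median by explicit sorting and linear interpolation
# (type-7 quantile formula written out)
oracle_restricted_median <- function(x, lo = 0.4, hi = 0.8) {
  x <- sort(x)
  n <- length(x)
  q7 <- function(p) {
    h <- (n - 1) * p + 1
    fl <- floor(h)
    x[fl] + (h - fl) * (x[min(fl + 1, n)] - x[fl])
  }
  band <- x[x >= q7(lo) & x <= q7(hi)]
  stats::median(band)
}

# events for a synthetic two-population mixture with known labels
make_labelled_events <- function(n_pos, n_neg, pos_median = 1e4,
                                 neg_median = 10, cv = 0.3) {
  sdlog <- sqrt(log(1 + cv^2))
  data.frame(
    mng = c(pos_median * exp(rnorm(n_pos, 0, sdlog)),
            neg_median * exp(rnorm(n_neg, 0, sdlog))),
    mcherry = neg_median * exp(rnorm(n_pos + n_neg, 0, sdlog)),
    label = rep(c("mng", "wt"), c(n_pos, n_neg)))
}

# brute-force least-squares slope by iterated grid refinement
oracle_slope_grid <- function(y, t, lo = -5, hi = 5, iters = 8L) {
  for (i in seq_len(iters)) {
    grid <- seq(lo, hi, length.out = 201L)
    sse <- vapply(grid, function(a) sum((y - a * t)^2), numeric(1))
    k <- which.min(sse)
    step <- grid[2] - grid[1]
    lo <- grid[k] - step
    hi <- grid[k] + step
  }
  (lo + hi) / 2
}
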
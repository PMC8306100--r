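# Independent oracles used across the suite.  These deliberately avoid the
# package's own cumulative-mass machinery: marginals are computed by direct
# summation over the weight array, cdfs by Riemann sums on fine grids.

# brute-force marginal masses of the first k axes of a weight array
oracle_marginal <- function(weights, k) {
  w <- if (is.null(dim(weights))) array(weights, length(weights)) else weights
  w <- w / sum(w)
  d <- length(dim(w))
  if (k == d) return(w)
  apply(w, seq_len(k), sum)
}

# brute-force 1D cdf of a piecewise-constant density by Riemann sum
oracle_grid_cdf <- function(weights, x, n_sub = 4000L) {
  m <- weights / sum(weights)
  n <- length(m)
  grid <- (seq_len(n_sub) - 0.5) / n_sub
  pdfv <- m[pmin(floor(grid * n) + 1, n)] * n
  vapply(x, function(xx) sum(pdfv[grid <= xx]) / n_sub, numeric(1))
}

# independent samplers for the analytic families (known closed identities,
# none of which use the package's idf machinery)
oracle_sample <- function(family, n) {
  switch(family,
    uniform = runif(n),
    arcsine = rbeta(n, 0.5, 0.5),
    triangular = (runif(n) + runif(n)) / 2,
    ramp = pmax(runif(n), runif(n)),
    stop("no oracle sampler for ", family))
}

# total-variation distance between an iid target sample and the target's
# bin masses (calibrates the sampling-noise scale of TV diagnostics)
oracle_iid_tv <- function(density, n, bins = 100L, seed = 1) {
  set.seed(seed)
  x <- oracle_sample(density$family, n)
  counts <- tabulate(pmin(floor(x * bins) + 1, bins), bins)
  target <- diff(c(0, density$cdf(seq_len(bins) / bins)))
  0.5 * sum(abs(counts / n - target))
}

expect_close <- function(actual, expected, tol) {
  expect_true(max(abs(actual - expected)) <= tol,
              label = sprintf("max|diff| = %.3g (tol %.3g)",
                              max(abs(actual - expected)), tol))
}
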
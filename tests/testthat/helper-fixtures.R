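# Small fixtures built in code, shared across test files.

# several acceptance checks are expected to accumulate failures without
# aborting the remainder of the suite
options(testthat.max_fails = Inf, testthat.progress.max_fails = Inf)

# a deterministic correlated region with a couple of genuine signals
make_test_region <- function(m = 8, rho = 0.6, h2_r = 0.02, n = 5e4,
                             causal = c(2, 5), effects = c(0.04, -0.03),
                             seed = 3) {
  set.seed(seed)
  f <- ld_factorize(make_ld(list(type = "ar1", rho = rho), m))
  beta <- numeric(m)
  beta[causal] <- effects
  bh <- simulate_sumstats(beta, f, h2_r, n)
  whiten(bh, f, n, h2_r)
}

# random positive semi-definite correlation matrix with unit diagonal
random_corr <- function(m, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(4 * m * m), 4 * m, m)
  v <- stats::cov2cor(crossprod(x))
  (v + t(v)) / 2
}

expect_close <- function(a, b, tol) {
  expect_lt(max(abs(a - b)), tol)
}
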
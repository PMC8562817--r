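#' Exact posterior by enumeration (small-region oracle)
#'
#' For regions with at most `max_m` SNPs, computes the posterior over
#' (causal configuration, p) exactly: for each of the 2^M configurations the
#' slab effects are integrated analytically, giving the Gaussian marginal
#' likelihood N(beta_tilde; 0, sigma_e^2 I + sigma_g^2(p) A_C A_C'), and the
#' p dimension is handled by quadrature on a grid that is uniform in the
#' Beta(alpha, alpha) prior CDF (so the prior is absorbed into the measure
#' and the integrable endpoint singularities of the Beta(0.2, 0.2) density
#' cause no trouble).
#'
#' The slab variance uses the same clamped sigma_g^2(p) = h2 / (M clamp(p))
#' convention as the sampler, so both target exactly the same distribution.
#'
#' @param region a `transformed_region`.
#' @param alpha symmetric Beta prior hyper-parameter.
#' @param n_grid number of quadrature nodes in (0, 1).
#' @param max_m refuse enumeration beyond this region size (default 12).
#' @return list with `p_grid`, `p_weights` (posterior masses on the grid,
#'   summing to 1), `p_mean`, `p_sd`, `k_mean`, and `pip` (exact per-SNP
#'   posterior inclusion probabilities).
#' @export
enumerate_posterior <- function(region, alpha = 0.2, n_grid = 2000L,
                                max_m = 12L) {
  stopifnot(inherits(region, "transformed_region"))
  m <- region$m_r
  if (m > max_m) stop("region too large for 2^M enumeration: M = ", m)
  q <- region$ld$rank
  G <- region$ld$gram
  b <- region$b
  btb <- sum(region$beta_tilde^2)
  se2 <- (1 - region$h2_r) / region$n

  u <- (seq_len(n_grid) - 0.5) / n_grid
  # extreme prior-CDF nodes can round to exactly 0 or 1 in doubles, where
  # log p / log(1-p) degenerate; nudge them to the nearest interior point
  p_grid <- pmin(pmax(stats::qbeta(u, alpha, alpha), 1e-300), 1 - 1e-12)
  sg2 <- region$h2_r / (m * .clamp_p(p_grid, m))   # length n_grid

  n_cfg <- 2^m
  # log-likelihood matrix: configs x grid
  loglik <- matrix(0, n_cfg, n_grid)
  kvec <- integer(n_cfg)
  base <- -0.5 * q * log(2 * pi)
  for (cfg in seq_len(n_cfg) - 1L) {
    idx <- which(bitwAnd(cfg, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
    k <- length(idx)
    kvec[cfg + 1L] <- k
    if (k == 0) {
      loglik[cfg + 1L, ] <- base - 0.5 * q * log(se2) - 0.5 * btb / se2
    } else {
      eg <- eigen(G[idx, idx, drop = FALSE], symmetric = TRUE)
      ev <- pmax(eg$values, 0)
      w2 <- drop(crossprod(eg$vectors, b[idx]))^2
      # det(se2 I_q + sg2 A_C A_C') = se2^(q-k) prod_j (se2 + sg2 ev_j)
      logdet <- (q - k) * log(se2) +
        colSums(log(outer(ev, sg2) + se2))
      # Woodbury quadratic form using only G_CC and b_C
      quad <- btb / se2 -
        colSums(w2 / (outer(ev, rep(1, n_grid)) / se2 + rep(1, k) %o% (1 / sg2))) / se2^2
      loglik[cfg + 1L, ] <- base - 0.5 * logdet - 0.5 * quad
    }
  }
  logw <- loglik + kvec %o% log(p_grid) + (m - kvec) %o% log1p(-p_grid)
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  p_weights <- colSums(w)
  p_mean <- sum(p_weights * p_grid)
  p_sd <- sqrt(max(sum(p_weights * p_grid^2) - p_mean^2, 0))
  k_mean <- sum(rowSums(w) * kvec)
  pip <- vapply(seq_len(m), function(j) {
    has <- bitwAnd(seq_len(n_cfg) - 1L, bitwShiftL(1L, j - 1L)) != 0L
    sum(w[has, ])
  }, numeric(1))
  list(p_grid = p_grid, p_weights = p_weights, p_mean = p_mean,
       p_sd = p_sd, k_mean = k_mean, pip = pip)
}

#' Grid-normalized conditional density of p (quadrature oracle)
#'
#' Normalizes [log_conditional_p()] for fixed (c, gamma) on the same
#' prior-CDF grid used by [enumerate_posterior()], returning the grid, the
#' normalized masses, and the CDF evaluated at the grid points. Used to
#' validate the Metropolis-Hastings p-chain.
#'
#' @inheritParams log_conditional_p
#' @param n_grid quadrature nodes.
#' @return list with `p_grid`, `weights`, `cdf`, and `cdf_at` (a function
#'   evaluating the CDF at arbitrary points by interpolation).
#' @export
conditional_p_quadrature <- function(k, m_r, gamma_causal, h2_r, alpha,
                                     n_grid = 4000L) {
  u <- (seq_len(n_grid) - 0.5) / n_grid
  p_grid <- stats::qbeta(u, alpha, alpha)
  # the Beta(alpha, alpha) prior is the grid measure; drop it from the density
  logf <- vapply(p_grid, function(p) {
    log_conditional_p(p, k, m_r, gamma_causal, h2_r, alpha) -
      stats::dbeta(p, alpha, alpha, log = TRUE)
  }, numeric(1))
  w <- exp(logf - max(logf))
  w <- w / sum(w)
  cdf <- cumsum(w)
  cdf_at <- stats::approxfun(p_grid, cdf, yleft = 0, yright = 1, rule = 2)
  list(p_grid = p_grid, weights = w, cdf = cdf, cdf_at = cdf_at)
}
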
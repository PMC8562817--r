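#' MCMC sampler for regional polygenicity
#'
#' A collapsed Gibbs sampler over per-SNP causal statuses c and slab effects
#' gamma, with a Metropolis-Hastings step for the regional polygenicity p.
#' The target is the joint posterior
#'   P(p, gamma, c | beta_hat, alpha, h2_r)
#'     propto P(p | alpha) P(c | p) P(gamma_causal | h2_r, p)
#'            P(beta_tilde | gamma, c, h2_r)
#' on the whitened scale, with non-causal gamma entries collapsed out of the
#' state (they contribute nothing to the likelihood and are re-integrated
#' analytically in the inclusion probability).
#'
#' @name sampler
NULL

# p is clamped away from {0, 1} wherever it parametrizes the slab variance
# sigma_g^2 = h2 / (M p) or the Beta proposal, since both degenerate at the
# boundary. The clamp is part of the model definition used everywhere
# (sampler, conditional density, enumeration oracle), so all routes target
# the same distribution.
.clamp_p <- function(p, m) {
  lo <- 1 / (10 * m)
  pmin(pmax(p, lo), 1 - lo)
}

.logistic <- function(x) {
  # mirrors the C++ engine branch-for-branch so R and C++ chains agree bitwise
  if (x >= 0) 1 / (1 + exp(-x)) else {
    e <- exp(x)
    e / (1 + e)
  }
}

#' Model variance constants
#'
#' sigma_g^2 = h2_r / (M_r p) is the slab (causal effect) variance, recomputed
#' whenever p changes; sigma_e^2 = (1 - h2_r) / N is the noise variance of
#' the whitened marginal effects.
#'
#' @param p current polygenicity in (0, 1) (clamped internally).
#' @param h2_r regional heritability in (0, 1).
#' @param m_r number of SNPs in the region.
#' @param n GWAS sample size.
#' @return list with `sigma_g2` and `sigma_e2`, both strictly positive.
#' @export
model_constants <- function(p, h2_r, m_r, n) {
  if (!is.finite(h2_r) || h2_r <= 0 || h2_r >= 1) {
    stop("h2_r must lie strictly in (0, 1)")
  }
  if (!is.finite(n) || n <= 0) stop("n must be positive")
  sg2 <- h2_r / (m_r * .clamp_p(p, m_r))
  se2 <- (1 - h2_r) / n
  if (sg2 <= 0 || se2 <= 0) stop("non-positive variance constant")
  list(sigma_g2 = sg2, sigma_e2 = se2)
}

#' Sampler configuration
#'
#' @param n_iter total MCMC iterations (default 1000).
#' @param burn_in discarded iterations (default 250).
#' @param alpha symmetric Beta prior hyper-parameter on p (default 0.2,
#'   putting weight on the tails).
#' @param proposal_c concentration C of the Beta(alpha + C p, alpha + C(1-p))
#'   Metropolis-Hastings proposal (default 10).
#' @param init_z_threshold |z| cutoff above which a SNP starts causal
#'   (default 3.5).
#' @param seed optional RNG seed applied by [run_gibbs()].
#' @param update_order `"fixed-ascending"` (default) or
#'   `"random-permutation"`.
#' @param engine `"sparse"` (default, O(K M) per iteration) or `"naive"`
#'   (O(M^2) per iteration); both produce bit-identical chains under the
#'   same seed.
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(n_iter = 1000L, burn_in = 250L, alpha = 0.2,
                           proposal_c = 10, init_z_threshold = 3.5,
                           seed = NULL, update_order = "fixed-ascending",
                           engine = "sparse") {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  if (!(n_iter > burn_in && burn_in >= 0)) stop("need n_iter > burn_in >= 0")
  if (!(alpha > 0)) stop("alpha must be positive")
  if (!(proposal_c > 0)) stop("proposal_c must be positive")
  update_order <- match.arg(update_order,
                            c("fixed-ascending", "random-permutation"))
  engine <- match.arg(engine, c("sparse", "naive"))
  structure(list(n_iter = n_iter, burn_in = burn_in, alpha = alpha,
                 proposal_c = proposal_c,
                 init_z_threshold = init_z_threshold, seed = seed,
                 update_order = update_order, engine = engine),
            class = "sampler_config")
}

#' Initialize the sampler state
#'
#' SNPs with |z| at or above the threshold start causal; their slab effects
#' are drawn from the prior N(0, sigma_g^2) evaluated at the initial p,
#' which is the causal fraction floored at 1/M_r and capped at 1 - 1/M_r.
#'
#' @param z_scores finite numeric vector of GWAS z-scores.
#' @param config a [sampler_config()].
#' @param h2_r regional heritability.
#' @param n GWAS sample size.
#' @param ld_factor optional [ld_factorize()] result; when supplied together
#'   with `beta_tilde` the rank-length residual beta_tilde - A (gamma * c)
#'   is built and cached on the state.
#' @param beta_tilde optional whitened effects for residual construction.
#' @return object of class `sampler_state` with fields `c`, `gamma`, `p`,
#'   `k` and (optionally) `residual`.
#' @export
init_state <- function(z_scores, config, h2_r, n,
                       ld_factor = NULL, beta_tilde = NULL) {
  if (!all(is.finite(z_scores))) stop("z-scores must be finite")
  m <- length(z_scores)
  cvec <- as.integer(abs(z_scores) >= config$init_z_threshold)
  k <- sum(cvec)
  p0 <- min(max(k / m, 1 / m), 1 - 1 / m)
  const <- model_constants(p0, h2_r, m, n)
  gamma <- numeric(m)
  if (k > 0) gamma[cvec == 1L] <- stats::rnorm(k, 0, sqrt(const$sigma_g2))
  st <- list(c = cvec, gamma = gamma, p = p0, k = k, residual = NULL)
  if (!is.null(ld_factor) && !is.null(beta_tilde)) {
    st$residual <- compute_residual(st, ld_factor, beta_tilde)
  }
  structure(st, class = "sampler_state")
}

#' From-scratch residual beta_tilde - A (gamma * c)
#'
#' @param state a `sampler_state`.
#' @param ld_factor the region's LD factor.
#' @param beta_tilde the region's whitened effects.
#' @return rank-length numeric vector.
#' @export
compute_residual <- function(state, ld_factor, beta_tilde) {
  beta_tilde - drop(ld_factor$sqrt_rows %*% (state$gamma * state$c))
}

#' Full conditional of a causal effect (slab posterior)
#'
#' Mean and variance of gamma_m given c_m = 1 and the rest of the state:
#' 1/sigma_m^2 = 1/sigma_g^2 + G_mm / sigma_e^2 and
#' mu_m = (sigma_m^2 / sigma_e^2) * r_m' A[, m], with the inner product
#' computed sparsely as b_m - sum over the other causal SNPs l of
#' G_lm gamma_l (cost O(K)).
#'
#' @param m SNP index (1-based).
#' @param state a `sampler_state`.
#' @param region a `transformed_region`.
#' @return list with `mu` and `sigma2`.
#' @export
slab_conditional <- function(m, state, region) {
  const <- model_constants(state$p, region$h2_r, region$m_r, region$n)
  G <- region$ld$gram
  dot <- region$b[m]
  causal <- which(state$c == 1L)
  for (l in causal) {
    if (l == m) next
    dot <- dot - G[l, m] * state$gamma[l]
  }
  sig2 <- 1 / (1 / const$sigma_g2 + G[m, m] / const$sigma_e2)
  mu <- sig2 * dot / const$sigma_e2
  list(mu = mu, sigma2 = sig2)
}

#' Posterior inclusion probability for one SNP
#'
#' d_m = logistic(log(p/(1-p)) + 0.5 log(sigma_m^2/sigma_g^2)
#'                + mu_m^2 / (2 sigma_m^2)),
#' the log-space form of p s e / (p s e + 1 - p) with
#' s = sqrt(sigma_m^2/sigma_g^2) and e = exp(mu_m^2/(2 sigma_m^2)), which
#' never overflows.
#'
#' @param mu,sigma2 slab-conditional mean and variance for the SNP.
#' @param sigma_g2 slab prior variance at the current p.
#' @param p current polygenicity.
#' @return inclusion probability in [0, 1].
#' @export
inclusion_prob <- function(mu, sigma2, sigma_g2, p) {
  x <- log(p / (1 - p)) + 0.5 * log(sigma2 / sigma_g2) + mu^2 / (2 * sigma2)
  .logistic(x)
}

#' Block update of (gamma_m, c_m) for one SNP
#'
#' Draws c_m ~ Bernoulli(d_m); if causal, draws gamma_m from its slab
#' conditional, otherwise sets it to zero. The cached residual (when
#' present) is updated incrementally by -A[, m] * delta(gamma_m c_m).
#'
#' @inheritParams slab_conditional
#' @return the updated `sampler_state`.
#' @export
update_snp <- function(m, state, region) {
  const <- model_constants(state$p, region$h2_r, region$m_r, region$n)
  sc <- slab_conditional(m, state, region)
  d <- inclusion_prob(sc$mu, sc$sigma2, const$sigma_g2, state$p)
  u <- stats::runif(1)
  newc <- if (u < d) 1L else 0L
  newg <- 0
  if (newc == 1L) newg <- stats::rnorm(1, sc$mu, sqrt(sc$sigma2))
  delta <- newg * newc - state$gamma[m] * state$c[m]
  if (!is.null(state$residual) && delta != 0) {
    state$residual <- state$residual - region$ld$sqrt_rows[, m] * delta
  }
  state$k <- state$k + (newc - state$c[m])
  state$c[m] <- newc
  state$gamma[m] <- newg
  state
}

#' Unnormalized log conditional density of p
#'
#' (alpha-1) log p + (alpha-1) log(1-p) + k log p + (M_r - k) log(1-p)
#' plus the Gaussian slab log-densities of the causal gammas evaluated at
#' variance h2_r / (M_r p). Only causal gamma terms enter; non-causal gammas
#' are not part of the collapsed state.
#'
#' @param p evaluation point; returns -Inf outside (0, 1).
#' @param k number of causal SNPs.
#' @param m_r number of SNPs in the region.
#' @param gamma_causal numeric vector of slab effects at the causal SNPs.
#' @param h2_r regional heritability.
#' @param alpha Beta prior hyper-parameter.
#' @return unnormalized log density.
#' @export
log_conditional_p <- function(p, k, m_r, gamma_causal, h2_r, alpha) {
  if (!(p > 0 && p < 1)) return(-Inf)
  lp <- (alpha - 1) * (log(p) + log1p(-p))
  lp <- lp + k * log(p) + (m_r - k) * log1p(-p)
  sdg <- sqrt(h2_r / (m_r * .clamp_p(p, m_r)))
  for (g in gamma_causal) {           # sequential accumulation mirrors C++
    lp <- lp + stats::dnorm(g, 0, sdg, log = TRUE)
  }
  lp
}

#' Metropolis-Hastings update of p
#'
#' Proposes p* ~ Beta(alpha + C p, alpha + C (1 - p)) and accepts with
#' probability min(1, exp(log pi(p*) - log pi(p) + log q(p | p*)
#' - log q(p* | p))), i.e. with the Hastings correction for the asymmetric
#' proposal.
#'
#' @param state a `sampler_state`.
#' @param region a `transformed_region`.
#' @param config a [sampler_config()].
#' @return the state, with attribute `accepted` (logical).
#' @export
mh_update_p <- function(state, region, config) {
  m <- region$m_r
  pc <- .clamp_p(state$p, m)
  a1 <- config$alpha + config$proposal_c * pc
  b1 <- config$alpha + config$proposal_c * (1 - pc)
  ps <- stats::rbeta(1, a1, b1)
  gamma_causal <- state$gamma[state$c == 1L]
  if (ps > 0 && ps < 1) {
    psc <- .clamp_p(ps, m)
    a2 <- config$alpha + config$proposal_c * psc
    b2 <- config$alpha + config$proposal_c * (1 - psc)
    logr <- log_conditional_p(ps, state$k, m, gamma_causal,
                              region$h2_r, config$alpha) -
      log_conditional_p(state$p, state$k, m, gamma_causal,
                        region$h2_r, config$alpha) +
      stats::dbeta(state$p, a2, b2, log = TRUE) -
      stats::dbeta(ps, a1, b1, log = TRUE)
  } else {
    logr <- -Inf
  }
  u <- stats::runif(1)
  accepted <- log(u) < logr
  if (accepted) state$p <- ps
  attr(state, "accepted") <- accepted
  state
}

.validate_region_for_sampling <- function(region) {
  stopifnot(inherits(region, "transformed_region"))
  if (!(region$h2_r > 0 && region$h2_r < 1)) {
    stop("h2_r must lie strictly in (0, 1)")
  }
  if (!(region$n > 0)) stop("n must be positive")
}

.draws_object <- function(raw, config, region) {
  structure(list(p_samples = as.numeric(raw$p_samples),
                 k_samples = as.numeric(raw$k_samples),
                 pip = as.numeric(raw$pip),
                 accept_rate = raw$accept_rate,
                 inner_ops = raw$inner_ops,
                 n_iter = config$n_iter, burn_in = config$burn_in,
                 m_r = region$m_r, h2_r = region$h2_r,
                 snp_ids = region$snp_ids),
            class = "posterior_draws")
}

#' Run the Gibbs sampler on a region
#'
#' Each iteration performs one blocked (gamma, c) sweep over all SNPs in the
#' configured order followed by one Metropolis-Hastings update of p.
#' Post-burn-in draws of p and of the causal count K are retained, along
#' with per-SNP inclusion frequencies. With the sparse engine the total cost
#' is O(n_iter * K * M); the naive engine performs the identical arithmetic
#' in O(n_iter * M^2).
#'
#' @param region a `transformed_region` from [whiten()].
#' @param config a [sampler_config()].
#' @param count_ops if `TRUE`, also record the number of inner-loop terms
#'   scanned (for complexity diagnostics).
#' @return a `posterior_draws` object: `p_samples`, `k_samples`, `pip`,
#'   `accept_rate`.
#' @export
run_gibbs <- function(region, config = sampler_config(), count_ops = FALSE) {
  .validate_region_for_sampling(region)
  if (!is.null(config$seed)) set.seed(config$seed)
  z <- region$beta_hat * sqrt(region$n)
  st <- init_state(z, config, region$h2_r, region$n)
  raw <- .gibbs_engine(region$b, region$ld$gram, region$h2_r, region$n,
                       st$c, st$gamma, st$p,
                       config$n_iter, config$burn_in, config$alpha,
                       config$proposal_c,
                       sparse = (config$engine == "sparse"),
                       random_order = (config$update_order ==
                                         "random-permutation"),
                       count_ops = count_ops)
  .draws_object(raw, config, region)
}

#' Pure-R reference implementation of [run_gibbs()]
#'
#' Consumes the RNG in exactly the same order as the compiled engine, so
#' chains agree bitwise under a shared seed. Intended for small regions
#' (validation and the residual-integrity check); cost is O(n_iter * M^2)
#' plus the residual bookkeeping.
#'
#' @inheritParams run_gibbs
#' @param check_every recompute the cached residual from scratch every this
#'   many iterations and stop if it drifts beyond 1e-8 (0 disables).
#' @return a `posterior_draws` object.
#' @export
run_gibbs_r <- function(region, config = sampler_config(),
                        check_every = 100L) {
  .validate_region_for_sampling(region)
  if (!is.null(config$seed)) set.seed(config$seed)
  m <- region$m_r
  z <- region$beta_hat * sqrt(region$n)
  st <- init_state(z, config, region$h2_r, region$n,
                   ld_factor = region$ld, beta_tilde = region$beta_tilde)
  n_keep <- config$n_iter - config$burn_in
  p_samples <- numeric(n_keep)
  k_samples <- numeric(n_keep)
  pip <- numeric(m)
  accept <- 0L
  for (it in seq_len(config$n_iter)) {
    ord <- if (config$update_order == "random-permutation") {
      sample.int(m)
    } else {
      seq_len(m)
    }
    for (mm in ord) st <- update_snp(mm, st, region)
    st <- mh_update_p(st, region, config)
    if (isTRUE(attr(st, "accepted"))) accept <- accept + 1L
    if (check_every > 0 && it %% check_every == 0) {
      fresh <- compute_residual(st, region$ld, region$beta_tilde)
      if (max(abs(fresh - st$residual)) > 1e-8) {
        stop("residual integrity violated at iteration ", it)
      }
    }
    if (it > config$burn_in) {
      idx <- it - config$burn_in
      p_samples[idx] <- st$p
      k_samples[idx] <- st$k
      pip <- pip + st$c
    }
  }
  raw <- list(p_samples = p_samples, k_samples = k_samples,
              pip = pip / n_keep, accept_rate = accept / config$n_iter,
              inner_ops = NULL)
  .draws_object(raw, config, region)
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf(
    "posterior draws: %d retained (of %d, burn-in %d), M_r = %d\n",
    length(x$p_samples), x$n_iter, x$burn_in, x$m_r))
  cat(sprintf("  E[p | data] = %.4g  (sd %.3g), accept rate %.2f\n",
              mean(x$p_samples), stats::sd(x$p_samples), x$accept_rate))
  invisible(x)
}
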
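#' Synthetic GWAS generator
#'
#' Generates inputs with exactly the statistical structure the model
#' assumes: LD matrices (identity / AR1 / constant-correlation blocks /
#' empirical from simulated genotypes), spike-and-slab causal architectures
#' (single Gaussian or Gaussian mixtures), marginal effects drawn at the
#' summary-statistic level from N(V beta, V sigma_e^2), and genotype-level
#' phenotype simulation with OLS marginal effects beta_hat = X'y / N.
#'
#' @name simulator
NULL

#' Simulation specification
#'
#' @param p_r true regional polygenicity in [0, 1].
#' @param h2_gw genome-wide heritability in (0, 1).
#' @param n GWAS sample size.
#' @param m_r SNPs per region.
#' @param m_total total SNP count used to scale genome-wide to regional
#'   heritability, h2_r = h2_gw * m_r / m_total (default 5e5, an array-scale
#'   SNP count).
#' @param n_regions number of regions (genotype-level pipeline).
#' @param effect_dist `list(type = "single")` or `list(type = "mixture",
#'   variances = c(...), weights = c(...))`; mixture variances are absolute
#'   per-SNP effect variances and causal SNPs are spread equally among the
#'   components (equal assignment probabilities, expected not exact counts).
#' @param ld_spec `list(type = "identity")`, `list(type = "ar1", rho = )`,
#'   `list(type = "block", sizes = , rho = )`, or `list(type =
#'   "from-genotypes", n = , base = <ld_spec>)`.
#' @param seed optional RNG seed recorded with the spec.
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(p_r, h2_gw = 0.5, n = 5e5, m_r = 1000L,
                     m_total = 5e5, n_regions = 1L,
                     effect_dist = list(type = "single"),
                     ld_spec = list(type = "ar1", rho = 0.9),
                     seed = NULL) {
  if (!(p_r >= 0 && p_r <= 1)) stop("p_r must lie in [0, 1]")
  if (!(h2_gw > 0 && h2_gw < 1)) stop("h2_gw must lie in (0, 1)")
  if (identical(effect_dist$type, "mixture")) {
    if (is.null(effect_dist$weights)) {
      effect_dist$weights <- rep(1, length(effect_dist$variances))
    }
    effect_dist$weights <- effect_dist$weights / sum(effect_dist$weights)
    if (any(effect_dist$variances <= 0)) stop("mixture variances must be positive")
    if (abs(sum(effect_dist$weights) - 1) > 1e-12) stop("weights must sum to 1")
  }
  structure(list(p_r = p_r, h2_gw = h2_gw, n = n, m_r = as.integer(m_r),
                 m_total = m_total, n_regions = as.integer(n_regions),
                 effect_dist = effect_dist, ld_spec = ld_spec, seed = seed),
            class = "sim_spec")
}

#' Regional heritability from genome-wide heritability
#'
#' h2_r = h2_gw * m_r / m_total: the genome-wide heritability scaled by the
#' share of SNPs falling in the region.
#'
#' @param h2_gw genome-wide heritability.
#' @param m_r SNPs in the region.
#' @param m_total total SNPs.
#' @return regional heritability.
#' @export
regional_h2 <- function(h2_gw, m_r, m_total) {
  if (m_r > m_total) stop("m_r must not exceed m_total")
  h2_gw * m_r / m_total
}

#' Construct a synthetic LD matrix
#'
#' @param ld_spec see [sim_spec()].
#' @param m_r region size.
#' @param seed optional seed (only consulted for `"from-genotypes"`).
#' @return an [ld_matrix()].
#' @export
make_ld <- function(ld_spec, m_r, seed = NULL) {
  type <- ld_spec$type
  if (type == "identity") {
    return(ld_matrix(diag(m_r)))
  }
  if (type == "ar1") {
    rho <- ld_spec$rho
    if (abs(rho) >= 1) stop("ar1 requires |rho| < 1")
    i <- seq_len(m_r)
    return(ld_matrix(rho^abs(outer(i, i, "-"))))
  }
  if (type == "block") {
    sizes <- ld_spec$sizes
    rho <- ld_spec$rho
    if (abs(rho) >= 1) stop("block requires |rho| < 1")
    if (sum(sizes) != m_r) stop("block sizes must sum to m_r")
    v <- matrix(0, m_r, m_r)
    at <- 0L
    for (s in sizes) {
      idx <- at + seq_len(s)
      v[idx, idx] <- rho
      at <- at + s
    }
    diag(v) <- 1
    return(ld_matrix(v))
  }
  if (type == "from-genotypes") {
    if (!is.null(seed)) set.seed(seed)
    base <- make_ld(ld_spec$base, m_r)
    x <- simulate_genotypes(ld_spec$n, ld_factorize(base))
    return(compute_ld(x))
  }
  stop("unknown ld_spec type: ", type)
}

#' Draw a causal architecture
#'
#' c_m ~ Bernoulli(p_r) i.i.d.; for the single-Gaussian architecture,
#' beta_m | c_m = 1 ~ N(0, h2_r / (m_r p_r)); for mixtures, each causal SNP
#' is assigned one mixture component (equal probabilities by default) and
#' draws its effect from N(0, variance of that component).
#'
#' @param spec a [sim_spec()].
#' @param seed optional seed.
#' @return list with `c_true` (integer), `beta_true`, `component` (0 for
#'   non-causal), and `h2_r` (the design regional heritability for the
#'   single-Gaussian case, NA for mixtures whose variance is absolute).
#' @export
draw_architecture <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- spec$m_r
  c_true <- stats::rbinom(m, 1L, spec$p_r)
  beta <- numeric(m)
  comp <- integer(m)
  k <- sum(c_true)
  h2_r <- regional_h2(spec$h2_gw, spec$m_r, spec$m_total)
  if (k > 0) {
    if (identical(spec$effect_dist$type, "mixture")) {
      vars <- spec$effect_dist$variances
      comp[c_true == 1L] <- sample(length(vars), k, replace = TRUE,
                                   prob = spec$effect_dist$weights)
      beta[c_true == 1L] <- stats::rnorm(k, 0, sqrt(vars[comp[c_true == 1L]]))
      h2_r <- NA_real_
    } else {
      if (spec$p_r <= 0) stop("p_r = 0 cannot have causal SNPs")
      beta[c_true == 1L] <- stats::rnorm(k, 0, sqrt(h2_r / (m * spec$p_r)))
    }
  }
  list(c_true = c_true, beta_true = beta, component = comp, h2_r = h2_r)
}

#' Realized regional genetic variance
#'
#' beta' V beta on the retained subspace: the genetic variance contributed
#' by the region under standardized genotypes, i.e. the realized regional
#' heritability for a unit-variance trait.
#'
#' @param beta_true effect vector.
#' @param ld_factor the region's LD factor.
#' @return scalar.
#' @export
realized_regional_h2 <- function(beta_true, ld_factor) {
  ab <- drop(ld_factor$sqrt_rows %*% beta_true)
  sum(ab^2)
}

#' Simulate GWAS marginal effects at the summary-statistic level
#'
#' One draw from beta_hat | beta ~ N(V beta, V sigma_e^2) with
#' sigma_e^2 = (1 - h2_r) / n, realized through the LD factor as
#' V beta + A' z sqrt(sigma_e^2), z ~ N(0, I_rank), which handles singular
#' V through the rank truncation.
#'
#' @param beta_true true effect vector.
#' @param ld an [ld_factorize()] result (or an [ld_matrix()], factorized on
#'   the fly).
#' @param h2_r regional heritability used for the noise scale.
#' @param n GWAS sample size.
#' @param seed optional seed.
#' @return numeric vector of marginal effects.
#' @export
simulate_sumstats <- function(beta_true, ld, h2_r, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(ld, "ld_matrix")) ld <- ld_factorize(ld)
  stopifnot(inherits(ld, "ld_factor"))
  se2 <- (1 - h2_r) / n
  if (se2 <= 0) stop("sigma_e^2 must be positive: need h2_r < 1 and n > 0")
  mean_part <- drop(ld$gram %*% beta_true)
  z <- stats::rnorm(ld$rank)
  mean_part + drop(crossprod(ld$sqrt_rows, z)) * sqrt(se2)
}

#' Simulate standardized genotypes with a target LD structure
#'
#' Rows are drawn from N(0, V) via the LD factor and the columns are then
#' standardized, so `compute_ld` of the result converges to V as n grows.
#' A Gaussian copula stands in for allele counts: the model consumes only
#' standardized genotypes and their correlation, which this construction
#' controls exactly.
#'
#' @param n number of individuals (>= 2).
#' @param ld an [ld_factorize()] result or [ld_matrix()].
#' @param seed optional seed.
#' @return n x M standardized genotype matrix.
#' @export
simulate_genotypes <- function(n, ld, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 2) stop("need n >= 2")
  if (inherits(ld, "ld_matrix")) ld <- ld_factorize(ld)
  stopifnot(inherits(ld, "ld_factor"))
  z <- matrix(stats::rnorm(n * ld$rank), n, ld$rank)
  standardize_genotypes(z %*% ld$sqrt_rows)
}

#' Simulate a phenotype and compute OLS marginal effects
#'
#' y | beta ~ N(X beta, (1 - h2_gw) I_N), then beta_hat = X'y / N, the OLS
#' marginal association estimate per SNP under standardized genotypes.
#'
#' @param genotypes standardized genotype matrix.
#' @param beta_true effect vector (length = ncol(genotypes)).
#' @param h2_gw genome-wide heritability controlling the noise variance.
#' @param seed optional seed.
#' @return numeric vector of marginal effects.
#' @export
simulate_phenotype_and_ols <- function(genotypes, beta_true, h2_gw,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!(h2_gw > 0 && h2_gw < 1)) stop("h2_gw must lie in (0, 1)")
  n <- nrow(genotypes)
  g <- drop(genotypes %*% beta_true)
  y <- g + stats::rnorm(n, 0, sqrt(1 - h2_gw))
  drop(crossprod(genotypes, y)) / n
}

#' HESS-type regional heritability estimate from summary statistics
#'
#' h2_r is estimated as (N beta_hat' V^+ beta_hat - q) / (N - q) where q is
#' the retained rank of the LD factor; beta_hat' V^+ beta_hat equals the
#' squared norm of the whitened effects.
#'
#' @param beta_hat marginal effects on the standardized scale.
#' @param ld_factor the region's LD factor.
#' @param n GWAS sample size.
#' @return scalar estimate (can be negative in null regions; callers floor
#'   it before use as a model input).
#' @export
estimate_h2 <- function(beta_hat, ld_factor, n) {
  bt <- drop(ld_factor$inv_sqrt %*% beta_hat)
  q <- ld_factor$rank
  (n * sum(bt^2) - q) / (n - q)
}

#' Relative bias of replicate estimates
#'
#' (mean(estimates) - truth) / truth. For truth = 0 the ratio is undefined
#' and the absolute bias mean(estimates) is returned with a warning.
#'
#' @param estimates numeric vector of replicate estimates.
#' @param truth true value.
#' @return scalar fraction (not percent).
#' @export
relative_bias <- function(estimates, truth) {
  if (truth == 0) {
    warning("truth is zero; returning absolute bias")
    return(mean(estimates))
  }
  (mean(estimates) - truth) / truth
}

#' Summary-statistic-level simulation + inference experiment
#'
#' For each requested polygenicity, repeatedly draws an architecture,
#' simulates marginal effects with the simulation LD, whitens with the
#' inference LD (the same factor unless `ld_infer` is supplied), runs the
#' Gibbs sampler with the design regional heritability as input, and
#' records the posterior mean.
#'
#' @param p_values vector of true regional polygenicities.
#' @param spec a [sim_spec()] providing h2_gw, n, m_r, m_total, ld_spec and
#'   effect distribution (its `p_r` is ignored in favor of `p_values`).
#' @param n_reps replicates per polygenicity.
#' @param config a [sampler_config()].
#' @param ld_infer optional second LD (factor or matrix) used for inference
#'   (LD-mismatch experiments); default: the simulation LD.
#' @param h2_input `"design"` (default: h2_gw m_r / m_total), `"realized"`
#'   (beta' V beta of each draw) or `"estimate"` (HESS-type from the
#'   simulated effects, floored at 1e-6).
#' @param seed RNG seed for the whole experiment.
#' @return data.frame with columns `p_r`, `rep`, `p_hat` (posterior mean),
#'   `p_sd`, `k_true`.
#' @export
grid_experiment <- function(p_values, spec, n_reps = 30L,
                            config = sampler_config(), ld_infer = NULL,
                            h2_input = c("design", "realized", "estimate"),
                            seed = 1L) {
  h2_input <- match.arg(h2_input)
  set.seed(seed)
  ld_sim <- make_ld(spec$ld_spec, spec$m_r)
  f_sim <- ld_factorize(ld_sim)
  f_inf <- if (is.null(ld_infer)) {
    f_sim
  } else if (inherits(ld_infer, "ld_factor")) {
    ld_infer
  } else {
    ld_factorize(ld_infer)
  }
  out <- vector("list", length(p_values) * n_reps)
  i <- 0L
  for (p_r in p_values) {
    spec_p <- spec
    spec_p$p_r <- p_r
    for (rep in seq_len(n_reps)) {
      arch <- draw_architecture(spec_p)
      bh <- simulate_sumstats(arch$beta_true, f_sim,
                              regional_h2(spec$h2_gw, spec$m_r, spec$m_total),
                              spec$n)
      h2_r <- switch(h2_input,
        design = regional_h2(spec$h2_gw, spec$m_r, spec$m_total),
        realized = max(realized_regional_h2(arch$beta_true, f_sim), 1e-6),
        estimate = max(estimate_h2(bh, f_inf, spec$n), 1e-6))
      region <- whiten(bh, f_inf, spec$n, h2_r)
      draws <- run_gibbs(region, config)
      i <- i + 1L
      out[[i]] <- data.frame(p_r = p_r, rep = rep,
                             p_hat = mean(draws$p_samples),
                             p_sd = stats::sd(draws$p_samples),
                             k_true = sum(arch$c_true))
    }
  }
  do.call(rbind, out)
}

#' Per-setting relative bias (percent) of a grid experiment
#'
#' @param df output of [grid_experiment()].
#' @return data.frame with `p_r`, `mean_p_hat`, `rel_bias_pct`, `se_p_hat`.
#' @export
bias_summary <- function(df) {
  sp <- split(df, df$p_r)
  out <- lapply(sp, function(d) {
    data.frame(p_r = d$p_r[1], mean_p_hat = mean(d$p_hat),
               rel_bias_pct = 100 * relative_bias(d$p_hat, d$p_r[1]),
               se_p_hat = stats::sd(d$p_hat) / sqrt(nrow(d)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' LD-mismatch experiment
#'
#' Simulates marginal effects with `ld_sim` and performs inference with
#' `ld_infer`, reporting the relative bias of the posterior mean over
#' replicates; with `ld_infer = NULL` this reduces to the matched-LD
#' experiment.
#'
#' @param spec a [sim_spec()] (uses its `p_r`).
#' @param ld_sim LD used for simulation (matrix or factor).
#' @param ld_infer LD used for inference (matrix or factor), or NULL.
#' @param n_reps replicates.
#' @param config a [sampler_config()].
#' @param seed RNG seed.
#' @return list with `estimates`, `rel_bias`, `mc_se` (Monte-Carlo standard
#'   error of the mean estimate divided by truth).
#' @export
ld_mismatch_experiment <- function(spec, ld_sim, ld_infer = NULL,
                                   n_reps = 30L, config = sampler_config(),
                                   seed = 1L) {
  set.seed(seed)
  f_sim <- if (inherits(ld_sim, "ld_factor")) ld_sim else ld_factorize(ld_sim)
  f_inf <- if (is.null(ld_infer)) {
    f_sim
  } else if (inherits(ld_infer, "ld_factor")) {
    ld_infer
  } else {
    ld_factorize(ld_infer)
  }
  if (f_sim$m != f_inf$m) stop("simulation and inference LD dimensions differ")
  h2_r <- regional_h2(spec$h2_gw, spec$m_r, spec$m_total)
  est <- numeric(n_reps)
  # per-replicate seeds decouple the data stream from the chains, so runs
  # with different inference LD but the same seed see identical data and
  # their estimates are paired replicate by replicate
  for (rep in seq_len(n_reps)) {
    set.seed(seed + 7919L * rep)
    arch <- draw_architecture(spec)
    bh <- simulate_sumstats(arch$beta_true, f_sim, h2_r, spec$n)
    region <- whiten(bh, f_inf, spec$n, h2_r)
    cfg <- config
    cfg$seed <- seed + 104729L * rep
    est[rep] <- mean(run_gibbs(region, cfg)$p_samples)
  }
  list(estimates = est, rel_bias = relative_bias(est, spec$p_r),
       mc_se = stats::sd(est) / sqrt(n_reps) / spec$p_r)
}

#' Multi-region genotype-level simulation + inference experiment
#'
#' Emulates the chromosome-style pipeline: standardized genotypes are
#' simulated once under a block LD structure spanning `n_regions`
#' consecutive regions; each replicate draws a genome-wide architecture at
#' polygenicity `p`, simulates a phenotype, computes OLS marginal effects
#' beta_hat = X'y/N, windows them into regions, and runs the sampler per
#' region with in-sample LD (computed from the simulated genotypes) and a
#' regional heritability input.
#'
#' @param spec a [sim_spec()]; `m_r` is the per-region SNP count,
#'   `n_regions` the region count, `p_r` the genome-wide causal proportion,
#'   `ld_spec` the within-region LD model.
#' @param n_reps phenotype replicates.
#' @param config a [sampler_config()].
#' @param h2_input `"estimate"` (default, HESS-type per region per
#'   replicate), `"realized"`, or `"design"`.
#' @param seed RNG seed.
#' @return data.frame with columns `region`, `rep`, `p_hat`, `p_sd`,
#'   `h2_r_input`, `k_true`.
#' @export
genotype_experiment <- function(spec, n_reps = 30L,
                                config = sampler_config(),
                                h2_input = c("estimate", "realized", "design"),
                                seed = 1L) {
  h2_input <- match.arg(h2_input)
  set.seed(seed)
  n_reg <- spec$n_regions
  m_r <- spec$m_r
  m <- n_reg * m_r
  # simulate genotypes region by region (independent blocks), holding each
  # region's matrix separately so the full N x M genome never has to be
  # materialized; one design factor serves all regions and in-sample LD is
  # recomputed from the realized genotypes
  f_design <- ld_factorize(make_ld(spec$ld_spec, m_r))
  x_regions <- vector("list", n_reg)
  factors <- vector("list", n_reg)
  for (r in seq_len(n_reg)) {
    x_regions[[r]] <- simulate_genotypes(spec$n, f_design)
    factors[[r]] <- ld_factorize(compute_ld(x_regions[[r]]))
  }
  gw_spec <- spec
  gw_spec$m_r <- m
  gw_spec$m_total <- m
  out <- vector("list", n_reg * n_reps)
  i <- 0L
  for (rep in seq_len(n_reps)) {
    arch <- draw_architecture(gw_spec)
    # y = sum_r X_r beta_r + noise, accumulated region-wise
    g <- numeric(spec$n)
    for (r in seq_len(n_reg)) {
      cols <- (r - 1L) * m_r + seq_len(m_r)
      if (any(arch$beta_true[cols] != 0)) {
        g <- g + drop(x_regions[[r]] %*% arch$beta_true[cols])
      }
    }
    y <- g + stats::rnorm(spec$n, 0, sqrt(1 - spec$h2_gw))
    for (r in seq_len(n_reg)) {
      cols <- (r - 1L) * m_r + seq_len(m_r)
      bh <- drop(crossprod(x_regions[[r]], y)) / spec$n
      h2_r <- switch(h2_input,
        estimate = max(estimate_h2(bh, factors[[r]], spec$n), 1e-6),
        realized = max(realized_regional_h2(arch$beta_true[cols],
                                            factors[[r]]), 1e-6),
        design = regional_h2(spec$h2_gw, m_r, m))
      region <- whiten(bh, factors[[r]], spec$n, h2_r)
      draws <- run_gibbs(region, config)
      i <- i + 1L
      out[[i]] <- data.frame(region = r, rep = rep,
                             p_hat = mean(draws$p_samples),
                             p_sd = stats::sd(draws$p_samples),
                             h2_r_input = h2_r,
                             k_true = sum(arch$c_true[cols]))
    }
  }
  do.call(rbind, out)
}
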
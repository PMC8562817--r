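#' Posterior reporting
#'
#' Turns per-region posterior draws into regional summaries, the
#' nonzero-region call, genome-wide polygenicity and causal-SNP counts with
#' credible intervals, threshold proportions, and the regression of
#' regional heritability on causal-SNP counts with outlier flagging.
#'
#' @name summarize
NULL

#' Summarize one region's posterior draws
#'
#' Posterior mean, SD and equal-tailed 95% credible interval of p; the
#' causal count M_c is reported per draw as M_r * p, so its summaries are
#' the p summaries scaled by M_r. A region is called nonzero when
#' p_mean - 2 p_sd > 0.
#'
#' @param draws a `posterior_draws` object (or list with `p_samples`).
#' @param m_r region SNP count (defaults to the value carried by `draws`).
#' @param h2_r regional heritability (optional, carried into the report).
#' @param region_id identifier (default "region1").
#' @return one-row data.frame of class `region_report` with columns
#'   `region_id`, `m_r`, `h2_r`, `p_mean`, `p_sd`, `p_lo95`, `p_hi95`,
#'   `mc_mean`, `mc_sd`, `mc_lo95`, `mc_hi95`, `nonzero`.
#' @export
summarize_region <- function(draws, m_r = NULL, h2_r = NULL,
                             region_id = "region1") {
  p <- draws$p_samples
  if (length(p) == 0) stop("no retained draws")
  if (is.null(m_r)) m_r <- draws$m_r
  if (is.null(h2_r)) h2_r <- if (!is.null(draws$h2_r)) draws$h2_r else NA_real_
  ci <- unname(stats::quantile(p, c(0.025, 0.975)))
  p_mean <- mean(p)
  p_sd <- stats::sd(p)
  if (is.na(p_sd)) p_sd <- 0
  out <- data.frame(region_id = region_id, m_r = m_r, h2_r = h2_r,
                    p_mean = p_mean, p_sd = p_sd,
                    p_lo95 = ci[1], p_hi95 = ci[2],
                    mc_mean = m_r * p_mean, mc_sd = m_r * p_sd,
                    mc_lo95 = m_r * ci[1], mc_hi95 = m_r * ci[2],
                    nonzero = (p_mean - 2 * p_sd) > 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("region_report", class(out))
  out
}

#' Aggregate regional posteriors to a genome-wide report
#'
#' Genome-wide causal count = sum over regions of M_r E[p_r]; genome-wide
#' polygenicity = that sum divided by the total SNP count (the SNP-weighted
#' mean of regional polygenicities, which is the set of semantics under
#' which p and M_c = p * M agree). Credible intervals come from summing
#' independently resampled per-region draws (regions are modeled as
#' posterior-independent; each resample picks one retained draw per region
#' with replacement).
#'
#' @param reports data.frame of stacked [summarize_region()] rows.
#' @param draws_list list of `posterior_draws`, parallel to `reports`.
#' @param n_resample number of resamples for the intervals (default 1e4).
#' @return list of class `genome_report`: `percent_regions_nonzero` (0-100),
#'   `p_gw_mean`, `p_gw_ci95`, `mc_gw_mean`, `mc_gw_ci95`,
#'   `threshold_props` (proportions in [0, 1] for k = 1, 5, 50),
#'   `m_total`.
#' @export
aggregate_genome <- function(reports, draws_list, n_resample = 10000L) {
  stopifnot(nrow(reports) == length(draws_list))
  if (anyDuplicated(reports$region_id)) stop("overlapping regions: duplicate ids")
  m <- reports$m_r
  m_total <- sum(m)
  mc_gw_mean <- sum(m * reports$p_mean)
  sums <- numeric(n_resample)
  for (r in seq_along(draws_list)) {
    p <- draws_list[[r]]$p_samples
    sums <- sums + m[r] * p[sample.int(length(p), n_resample, replace = TRUE)]
  }
  mc_ci <- unname(stats::quantile(sums, c(0.025, 0.975)))
  structure(list(
    percent_regions_nonzero = 100 * mean(reports$nonzero),
    p_gw_mean = mc_gw_mean / m_total,
    p_gw_ci95 = mc_ci / m_total,
    mc_gw_mean = mc_gw_mean,
    mc_gw_ci95 = mc_ci,
    threshold_props = threshold_proportions(reports, c(1, 5, 50)),
    m_total = m_total), class = "genome_report")
}

#' Proportion of regions with at least k causal SNPs
#'
#' For k = 1 the nonzero call (p_mean - 2 p_sd > 0) is used; for k > 1 the
#' mirrored criterion mc_mean - 2 mc_sd >= k. Alternatively
#' `rule = "posterior"` calls a region when the posterior probability of
#' K_r >= k (from the retained causal-count draws) is at least 0.95.
#'
#' @param reports stacked [summarize_region()] rows.
#' @param k_list thresholds (default c(1, 5, 50)).
#' @param rule `"mean2sd"` (default) or `"posterior"`.
#' @param draws_list required for `rule = "posterior"`.
#' @return named numeric vector of proportions in [0, 1].
#' @export
threshold_proportions <- function(reports, k_list = c(1, 5, 50),
                                  rule = c("mean2sd", "posterior"),
                                  draws_list = NULL) {
  rule <- match.arg(rule)
  if (nrow(reports) == 0) stop("no region reports")
  out <- vapply(k_list, function(k) {
    if (rule == "posterior") {
      if (is.null(draws_list)) stop("rule = 'posterior' needs draws_list")
      mean(vapply(draws_list,
                  function(d) mean(d$k_samples >= k) >= 0.95, logical(1)))
    } else if (k <= 1) {
      mean(reports$nonzero)
    } else {
      mean(reports$mc_mean - 2 * reports$mc_sd >= k)
    }
  }, numeric(1))
  names(out) <- paste0("ge", k_list)
  out
}

#' Regress regional heritability on SNP counts
#'
#' Ordinary least squares of h2_r on the region SNP count M_r alone, on the
#' causal count Mc_r alone, and on both; flags outlier regions with
#' |studentized residual| > 3 (from the Mc_r-alone fit, whose residuals
#' identify regions with disproportionate heritability given their causal
#' count).
#'
#' @param h2_by_region regional heritability estimates (>= 10 regions).
#' @param m_by_region SNP counts per region.
#' @param mc_by_region causal-count estimates per region.
#' @return list with elements `m`, `mc`, `both` (each: `slopes`,
#'   `r_squared`, `p_value`), and `outliers` (logical per region).
#' @export
regress_h2_on_counts <- function(h2_by_region, m_by_region, mc_by_region) {
  n <- length(h2_by_region)
  if (n < 10) stop("need at least 10 regions")
  stopifnot(length(m_by_region) == n, length(mc_by_region) == n)
  for (nm in c("m_by_region", "mc_by_region")) {
    v <- get(nm)
    if (stats::sd(v) == 0) stop("constant predictor: ", nm)
  }
  if (abs(stats::cor(m_by_region, mc_by_region)) > 1 - 1e-12) {
    stop("collinear predictors")
  }
  df <- data.frame(h2 = h2_by_region, m = m_by_region, mc = mc_by_region)
  fit_m <- stats::lm(h2 ~ m, data = df)
  fit_mc <- stats::lm(h2 ~ mc, data = df)
  fit_both <- stats::lm(h2 ~ m + mc, data = df)
  pick <- function(fit) {
    s <- summary(fit)
    list(slopes = stats::coef(fit)[-1],
         r_squared = s$r.squared,
         p_value = stats::pf(s$fstatistic[1], s$fstatistic[2],
                             s$fstatistic[3], lower.tail = FALSE))
  }
  list(m = pick(fit_m), mc = pick(fit_mc), both = pick(fit_both),
       outliers = abs(stats::rstudent(fit_mc)) > 3)
}

#' @export
print.genome_report <- function(x, ...) {
  cat(sprintf("genome-wide polygenicity: %.4g (95%% CI %.4g-%.4g)\n",
              x$p_gw_mean, x$p_gw_ci95[1], x$p_gw_ci95[2]))
  cat(sprintf("causal SNPs: %.1f (95%% CI %.1f-%.1f) of %d\n",
              x$mc_gw_mean, x$mc_gw_ci95[1], x$mc_gw_ci95[2], x$m_total))
  cat(sprintf("regions nonzero: %.1f%%; >=1/>=5/>=50 causal: %s\n",
              x$percent_regions_nonzero,
              paste(sprintf("%.3f", x$threshold_props), collapse = "/")))
  invisible(x)
}
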
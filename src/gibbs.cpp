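#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Collapsed spike-and-slab Gibbs sweep with a Metropolis-Hastings update for
// the polygenicity parameter p. Two engines share the identical arithmetic:
//   sparse : inner products over the maintained (sorted) causal set, O(K M)
//   naive  : inner products scanning every SNP, O(M^2)
// Both consume R's RNG in the same order, so chains are bit-identical to
// each other and to the pure-R reference sweep.

static inline double clamp_p(double p, int m) {
  double lo = 1.0 / (10.0 * (double)m);
  if (p < lo) return lo;
  if (p > 1.0 - lo) return 1.0 - lo;
  return p;
}

static inline double logistic_stable(double x) {
  if (x >= 0.0) {
    return 1.0 / (1.0 + std::exp(-x));
  } else {
    double e = std::exp(x);
    return e / (1.0 + e);
  }
}

// Unnormalized log conditional density of p given (c, gamma): Beta(alpha,
// alpha) prior + Bernoulli likelihood of c + Gaussian slab terms for the
// causal gammas, whose variance h2/(M p) is where p enters nonlinearly.
static double log_cond_p(double p, int k, int m, double h2, double alpha,
                         const std::vector<int>& causal,
                         const std::vector<double>& gamma) {
  if (!(p > 0.0) || !(p < 1.0)) return R_NegInf;
  double lp = (alpha - 1.0) * (std::log(p) + std::log1p(-p));
  lp += (double)k * std::log(p) + (double)(m - k) * std::log1p(-p);
  double sdg = std::sqrt(h2 / ((double)m * clamp_p(p, m)));
  for (size_t i = 0; i < causal.size(); ++i) {
    lp += R::dnorm(gamma[causal[i]], 0.0, sdg, 1);
  }
  return lp;
}

// [[Rcpp::export(name = ".gibbs_engine")]]
List gibbs_engine(NumericVector b, NumericMatrix G, double h2, double n_gwas,
                  IntegerVector c0, NumericVector gamma0, double p0,
                  int n_iter, int burn_in, double alpha, double proposal_c,
                  bool sparse, bool random_order, bool count_ops) {
  const int m = b.size();
  if (G.nrow() != m || G.ncol() != m) stop("G dimension mismatch");
  if (c0.size() != m || gamma0.size() != m) stop("state dimension mismatch");

  std::vector<int> c(m);
  std::vector<double> gamma(m);
  std::vector<int> causal; causal.reserve(m);
  for (int i = 0; i < m; ++i) {
    c[i] = c0[i];
    gamma[i] = gamma0[i];
    if (c[i]) causal.push_back(i);
  }
  int k = (int)causal.size();
  double p = p0;
  double se2 = (1.0 - h2) / n_gwas;
  double sg2 = h2 / ((double)m * clamp_p(p, m));

  const int n_keep = n_iter - burn_in;
  NumericVector p_samples(n_keep), k_samples(n_keep);
  NumericVector pip(m);
  int accept = 0;
  double ops = 0.0;

  IntegerVector order(m);
  for (int i = 0; i < m; ++i) order[i] = i;

  for (int it = 0; it < n_iter; ++it) {
    if (random_order) {
      order = Rcpp::sample(m, m, false) - 1;
    }
    for (int j = 0; j < m; ++j) {
      int mm = order[j];
      // r_m' A_{.m} computed sparsely: b_m - sum_{l != m, c_l = 1} G_lm g_l
      double dot = b[mm];
      const double* col = &G(0, mm);
      if (sparse) {
        for (size_t q = 0; q < causal.size(); ++q) {
          int l = causal[q];
          ops += 1.0;
          if (l == mm) continue;
          dot -= col[l] * gamma[l];
        }
      } else {
        for (int l = 0; l < m; ++l) {
          ops += 1.0;
          if (l == mm || !c[l]) continue;
          dot -= col[l] * gamma[l];
        }
      }
      double sig2 = 1.0 / (1.0 / sg2 + col[mm] / se2);
      double mu = sig2 * dot / se2;
      double x = std::log(p / (1.0 - p)) + 0.5 * std::log(sig2 / sg2) +
                 mu * mu / (2.0 * sig2);
      double d = logistic_stable(x);
      double u = R::unif_rand();
      int newc = (u < d) ? 1 : 0;
      double newg = 0.0;
      if (newc) newg = R::rnorm(mu, std::sqrt(sig2));
      if (newc != c[mm]) {
        if (newc) {
          causal.insert(std::lower_bound(causal.begin(), causal.end(), mm), mm);
          ++k;
        } else {
          causal.erase(std::lower_bound(causal.begin(), causal.end(), mm));
          --k;
        }
      }
      c[mm] = newc;
      gamma[mm] = newg;
    }

    // Metropolis-Hastings update for p with Beta(alpha + C p, alpha + C(1-p))
    // proposal and the Hastings correction for its asymmetry.
    double pc = clamp_p(p, m);
    double a1 = alpha + proposal_c * pc;
    double b1 = alpha + proposal_c * (1.0 - pc);
    double ps = R::rbeta(a1, b1);
    double logr;
    if (ps > 0.0 && ps < 1.0) {
      double psc = clamp_p(ps, m);
      double a2 = alpha + proposal_c * psc;
      double b2 = alpha + proposal_c * (1.0 - psc);
      logr = log_cond_p(ps, k, m, h2, alpha, causal, gamma) -
             log_cond_p(p, k, m, h2, alpha, causal, gamma) +
             R::dbeta(p, a2, b2, 1) - R::dbeta(ps, a1, b1, 1);
    } else {
      logr = R_NegInf;
    }
    double u2 = R::unif_rand();
    if (std::log(u2) < logr) {
      p = ps;
      sg2 = h2 / ((double)m * clamp_p(p, m));
      ++accept;
    }

    if (it >= burn_in) {
      int idx = it - burn_in;
      p_samples[idx] = p;
      k_samples[idx] = (double)k;
      for (size_t q = 0; q < causal.size(); ++q) pip[causal[q]] += 1.0;
    }
  }

  for (int i = 0; i < m; ++i) pip[i] /= (double)n_keep;
  IntegerVector c_final(m);
  NumericVector gamma_final(m);
  for (int i = 0; i < m; ++i) { c_final[i] = c[i]; gamma_final[i] = gamma[i]; }

  List out = List::create(
    _["p_samples"] = p_samples,
    _["k_samples"] = k_samples,
    _["pip"] = pip,
    _["accept_rate"] = (double)accept / (double)n_iter,
    _["c_final"] = c_final,
    _["gamma_final"] = gamma_final,
    _["p_final"] = p);
  if (count_ops) out["inner_ops"] = ops;
  return out;
}
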
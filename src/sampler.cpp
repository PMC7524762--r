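// Gibbs sampler for the joint hierarchical linearized Ricker model.
//
// Likelihood per growth observation i of herd j:
//   r_{i,j} ~ Normal(rmax_j + gamma_{i,j} + b_{i,j} * N_{i,j}, sigma_eps)
// where gamma is present under the r-varying variants and b is either the
// herd's fixed slope beta_j or a per-year slope betad_{i,j}.
// Hierarchy: rmax_j ~ N(mu_rmax, sigma_rmax);
//   gamma_{i,j} ~ N(0, sigma_gamma_j); betad_{i,j} ~ N(mu_betad_j, sigma_betad_j).
// Priors: means ~ N(0, prior_var_mean); SDs ~ Uniform(0, sd_upper).
// All location updates are conjugate; SDs use univariate slice sampling.
// Uses R's RNG so set.seed() on the R side makes chains reproducible.

#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline double log_sigma_target(double s, double m, double SS,
                                      double upper) {
  if (s <= 0.0 || s >= upper)
    return -std::numeric_limits<double>::infinity();
  return -m * std::log(s) - SS / (2.0 * s * s);
}

// slice sampler with stepping-out and shrinkage on (0, upper)
static double slice_sigma(double cur, double m, double SS, double upper) {
  if (cur <= 0.0 || cur >= upper) cur = std::min(upper * 0.5, 1.0);
  double y = log_sigma_target(cur, m, SS, upper) + std::log(R::unif_rand());
  double w = 0.5 * cur + 0.05;
  double L = cur - w * R::unif_rand();
  double U = L + w;
  if (L < 0.0) L = 0.0;
  for (int k = 0; k < 50 && L > 0.0 &&
       log_sigma_target(L, m, SS, upper) > y; ++k) {
    L -= w;
    if (L < 0.0) { L = 0.0; break; }
  }
  for (int k = 0; k < 50 && U < upper &&
       log_sigma_target(U, m, SS, upper) > y; ++k) {
    U += w;
    if (U > upper) { U = upper; break; }
  }
  for (int it = 0; it < 200; ++it) {
    double x = L + (U - L) * R::unif_rand();
    if (log_sigma_target(x, m, SS, upper) > y) return x;
    if (x < cur) L = x; else U = x;
  }
  return cur;
}

static inline double rnorm_post(double prec, double prec_times_mean) {
  double v = 1.0 / prec;
  return R::norm_rand() * std::sqrt(v) + prec_times_mean * v;
}

// variant codes: 0 = none, 1 = r_var, 2 = beta_var, 3 = both
// [[Rcpp::export(name = ".ricker_gibbs_chain")]]
NumericMatrix ricker_gibbs_chain(List herd_N, List herd_r,
                                 IntegerVector variant,
                                 double prior_var_mean, double sd_upper,
                                 int n_warmup, int n_iter, int thin,
                                 NumericVector init) {
  const int J = herd_N.size();
  std::vector<NumericVector> N(J), r(J);
  std::vector<int> nobs(J);
  int n_tot = 0;
  for (int j = 0; j < J; ++j) {
    N[j] = as<NumericVector>(herd_N[j]);
    r[j] = as<NumericVector>(herd_r[j]);
    nobs[j] = N[j].size();
    n_tot += nobs[j];
  }

  // state, unpacked from the flat init vector (layout mirrors the output
  // columns, minus the trailing deviance)
  double mu_rmax, sigma_rmax, sigma_eps;
  std::vector<double> rmax(J), beta(J, 0.0), sigma_gamma(J, 0.0);
  std::vector<double> mu_betad(J, 0.0), sigma_betad(J, 0.0);
  std::vector< std::vector<double> > gamma(J), betad(J);
  int pos = 0;
  mu_rmax = init[pos++]; sigma_rmax = init[pos++]; sigma_eps = init[pos++];
  int ncol = 4;  // globals + deviance
  for (int j = 0; j < J; ++j) {
    rmax[j] = init[pos++]; ++ncol;
    const bool rv = variant[j] == 1 || variant[j] == 3;
    const bool bv = variant[j] == 2 || variant[j] == 3;
    if (rv) {
      sigma_gamma[j] = init[pos++]; ++ncol;
      gamma[j].resize(nobs[j]);
      for (int i = 0; i < nobs[j]; ++i) { gamma[j][i] = init[pos++]; ++ncol; }
    }
    if (bv) {
      mu_betad[j] = init[pos++]; ++ncol;
      sigma_betad[j] = init[pos++]; ++ncol;
      betad[j].resize(nobs[j]);
      for (int i = 0; i < nobs[j]; ++i) { betad[j][i] = init[pos++]; ++ncol; }
    } else {
      beta[j] = init[pos++]; ++ncol;
    }
  }
  if (pos != init.size())
    stop("init vector length does not match the model layout");

  const int n_keep = n_iter / thin;
  NumericMatrix out(n_keep, ncol);
  const double inv_pv = 1.0 / prior_var_mean;
  int kept = 0;

  for (int sweep = 0; sweep < n_warmup + n_iter; ++sweep) {
    const double inv_ve = 1.0 / (sigma_eps * sigma_eps);

    for (int j = 0; j < J; ++j) {
      const bool rv = variant[j] == 1 || variant[j] == 3;
      const bool bv = variant[j] == 2 || variant[j] == 3;
      const int n = nobs[j];

      // rmax_j | .  (conjugate; prior N(mu_rmax, sigma_rmax))
      double sum_y = 0.0;
      for (int i = 0; i < n; ++i) {
        double b = bv ? betad[j][i] : beta[j];
        double g = rv ? gamma[j][i] : 0.0;
        sum_y += r[j][i] - g - b * N[j][i];
      }
      double inv_vr = 1.0 / (sigma_rmax * sigma_rmax);
      rmax[j] = rnorm_post(n * inv_ve + inv_vr,
                           sum_y * inv_ve + mu_rmax * inv_vr);

      // gamma_{i,j} | .  and sigma_gamma_j
      if (rv) {
        double inv_vg = 1.0 / (sigma_gamma[j] * sigma_gamma[j]);
        double SSg = 0.0;
        for (int i = 0; i < n; ++i) {
          double b = bv ? betad[j][i] : beta[j];
          double y = r[j][i] - rmax[j] - b * N[j][i];
          gamma[j][i] = rnorm_post(inv_ve + inv_vg, y * inv_ve);
          SSg += gamma[j][i] * gamma[j][i];
        }
        sigma_gamma[j] = slice_sigma(sigma_gamma[j], n, SSg, sd_upper);
      }

      // slope structure
      if (!bv) {
        double sNN = 0.0, sNy = 0.0;
        for (int i = 0; i < n; ++i) {
          double g = rv ? gamma[j][i] : 0.0;
          double y = r[j][i] - rmax[j] - g;
          sNN += N[j][i] * N[j][i];
          sNy += N[j][i] * y;
        }
        beta[j] = rnorm_post(sNN * inv_ve + inv_pv, sNy * inv_ve);
      } else {
        double inv_vb = 1.0 / (sigma_betad[j] * sigma_betad[j]);
        double sum_b = 0.0;
        for (int i = 0; i < n; ++i) {
          double g = rv ? gamma[j][i] : 0.0;
          double y = r[j][i] - rmax[j] - g;
          betad[j][i] = rnorm_post(N[j][i] * N[j][i] * inv_ve + inv_vb,
                                   N[j][i] * y * inv_ve + mu_betad[j] * inv_vb);
          sum_b += betad[j][i];
        }
        mu_betad[j] = rnorm_post(n * inv_vb + inv_pv, sum_b * inv_vb);
        double SSb = 0.0;
        for (int i = 0; i < n; ++i) {
          double d = betad[j][i] - mu_betad[j];
          SSb += d * d;
        }
        sigma_betad[j] = slice_sigma(sigma_betad[j], n, SSb, sd_upper);
      }
    }

    // hyper-parameters of rmax
    double inv_vr = 1.0 / (sigma_rmax * sigma_rmax);
    double sum_rmax = 0.0;
    for (int j = 0; j < J; ++j) sum_rmax += rmax[j];
    mu_rmax = rnorm_post(J * inv_vr + inv_pv, sum_rmax * inv_vr);
    double SSr = 0.0;
    for (int j = 0; j < J; ++j) {
      double d = rmax[j] - mu_rmax;
      SSr += d * d;
    }
    sigma_rmax = slice_sigma(sigma_rmax, J, SSr, sd_upper);

    // shared residual SD and joint deviance
    double SSe = 0.0;
    for (int j = 0; j < J; ++j) {
      const bool rv = variant[j] == 1 || variant[j] == 3;
      const bool bv = variant[j] == 2 || variant[j] == 3;
      for (int i = 0; i < nobs[j]; ++i) {
        double b = bv ? betad[j][i] : beta[j];
        double g = rv ? gamma[j][i] : 0.0;
        double e = r[j][i] - rmax[j] - g - b * N[j][i];
        SSe += e * e;
      }
    }
    sigma_eps = slice_sigma(sigma_eps, n_tot, SSe, sd_upper);

    if (sweep >= n_warmup && (sweep - n_warmup) % thin == thin - 1) {
      double dev = n_tot * std::log(2.0 * M_PI) +
        2.0 * n_tot * std::log(sigma_eps) + SSe / (sigma_eps * sigma_eps);
      int c = 0;
      out(kept, c++) = mu_rmax;
      out(kept, c++) = sigma_rmax;
      out(kept, c++) = sigma_eps;
      for (int j = 0; j < J; ++j) {
        const bool rv = variant[j] == 1 || variant[j] == 3;
        const bool bv = variant[j] == 2 || variant[j] == 3;
        out(kept, c++) = rmax[j];
        if (rv) {
          out(kept, c++) = sigma_gamma[j];
          for (int i = 0; i < nobs[j]; ++i) out(kept, c++) = gamma[j][i];
        }
        if (bv) {
          out(kept, c++) = mu_betad[j];
          out(kept, c++) = sigma_betad[j];
          for (int i = 0; i < nobs[j]; ++i) out(kept, c++) = betad[j][i];
        } else {
          out(kept, c++) = beta[j];
        }
      }
      out(kept, c++) = dev;
      ++kept;
    }
  }
  return out;
}
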
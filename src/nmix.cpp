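// Marginalized binomial-Poisson mixture likelihood and the
// Metropolis-within-Gibbs sampler operating on it. The latent site
// abundance N_i is summed out over max(y_i.) .. K, so the sampler moves
// only in the continuous parameters (beta, alpha, sigma, non-centered
// area effects u_k). R's RNG is used throughout so seeding via set.seed()
// on the R side makes runs reproducible.

#include <Rcpp.h>
using namespace Rcpp;

// log( sum_{N=maxy}^{K} Pois(N; lambda) * prod_j Binom(y_j; N, p_j) )
// decomposed as t(N) = N*loglam - lambda - lgamma(N+1) + C(N) + A + N*B
// with C(N) = sum_j lchoose(N, y_j),
//      A    = sum_j y_j * (log p_j - log(1-p_j)),
//      B    = sum_j log(1 - p_j).
// `exact` disables the early tail cutoff (used by the exported exact
// likelihood; the sampler uses the cutoff, 45 log-units below the running
// maximum, which is far below double precision resolution).

static double site_ll_core(int maxy, int K, double loglam, double lambda,
                           const double* Crow, double A, double B,
                           const double* lgam, bool exact) {
  // streaming logsumexp: running maximum m and rescaled sum s
  double m = R_NegInf, s = 0.0;
  for (int N = maxy; N <= K; ++N) {
    double tn = N * loglam - lambda - lgam[N] + Crow[N] + A + N * B;
    if (ISNAN(tn)) return R_NegInf;
    if (tn == R_NegInf) continue;
    if (tn <= m) {
      s += std::exp(tn - m);
      if (!exact && N > lambda && tn < m - 45.0) break;
    } else {
      s = s * std::exp(m - tn) + 1.0;
      m = tn;
    }
  }
  if (!R_finite(m)) return R_NegInf;
  return m + std::log(s);
}

// Per-site exact marginal log-likelihood. y: n x J counts; log_lambda: n;
// P: n x J detection probabilities; K: truncation bound.
// [[Rcpp::export]]
NumericVector cpp_site_marginal_loglik(IntegerMatrix y, NumericVector log_lambda,
                                       NumericMatrix P, int K) {
  int n = y.nrow(), J = y.ncol();
  std::vector<double> lgam(K + 1);
  for (int N = 0; N <= K; ++N) lgam[N] = std::lgamma(N + 1.0);
  NumericVector out(n);
  std::vector<double> Crow(K + 1, R_NegInf);
  for (int i = 0; i < n; ++i) {
    int maxy = 0;
    for (int j = 0; j < J; ++j) if (y(i, j) > maxy) maxy = y(i, j);
    if (maxy > K) stop("K is smaller than an observed count");
    for (int N = maxy; N <= K; ++N) {
      double c = 0.0;
      for (int j = 0; j < J; ++j) c += Rf_lchoose(N, y(i, j));
      Crow[N] = c;
    }
    double A = 0.0, B = 0.0;
    for (int j = 0; j < J; ++j) {
      double p = P(i, j);
      if (p < 0.0 || p > 1.0) stop("detection probability outside [0, 1]");
      if (p == 1.0) {
        B += R_NegInf;                 // forces N = y_j; handled below
      } else {
        if (y(i, j) > 0) A += y(i, j) * (std::log(p) - std::log1p(-p));
        B += std::log1p(-p);
      }
    }
    double lam = std::exp(log_lambda[i]);
    if (!R_finite(lam) || lam <= 0) stop("non-finite or non-positive lambda");
    if (!std::isfinite(B)) {
      // perfect detection on some visit: N must equal that visit's count;
      // likelihood = Pois(maxy; lambda) * prod_j Binom(y_j; maxy, p_j) if
      // consistent, else 0. Evaluate directly.
      double ll = Rf_dpois(maxy, lam, 1);
      for (int j = 0; j < J; ++j) ll += Rf_dbinom(y(i, j), maxy, P(i, j), 1);
      out[i] = ll;
    } else {
      out[i] = site_ll_core(maxy, K, log_lambda[i], lam, Crow.data(), A, B,
                            lgam.data(), true);
    }
  }
  return out;
}

struct NmixWork {
  int n, J, K, pb, pd, narea;
  IntegerMatrix y;
  NumericMatrix Xab;            // n x pb
  NumericVector Xdet;           // n*J*pd flattened, index i + n*j + n*J*m
  IntegerVector area;           // 0-based
  std::vector<int> maxy;
  std::vector<double> lgam;     // lgamma(N+1)
  NumericMatrix Ctab;           // (K+1) x n, column i = sum_j lchoose(N, y_ij)
  double fixed_p;               // in (0,1]; < 0 means covariate-driven
};

static void fill_AB(const NmixWork& w, const NumericMatrix& P,
                    std::vector<double>& A, std::vector<double>& B) {
  for (int i = 0; i < w.n; ++i) {
    double a = 0.0, b = 0.0;
    for (int j = 0; j < w.J; ++j) {
      double p = P(i, j);
      if (w.y(i, j) > 0) a += w.y(i, j) * (std::log(p) - std::log1p(-p));
      b += std::log1p(-p);
    }
    A[i] = a; B[i] = b;
  }
}

static double site_ll(const NmixWork& w, int i, double loglam,
                      const std::vector<double>& A,
                      const std::vector<double>& B) {
  double lam = std::exp(loglam);
  if (!R_finite(lam)) return R_NegInf;
  return site_ll_core(w.maxy[i], w.K, loglam, lam, &w.Ctab(0, i), A[i], B[i],
                      w.lgam.data(), false);
}

// Sample N_i from its conditional given (lambda_i, p_i.) by inverse CDF
// over the truncated summands.
static int sample_N(const NmixWork& w, int i, double loglam,
                    const std::vector<double>& A,
                    const std::vector<double>& B) {
  double lam = std::exp(loglam);
  int maxy = w.maxy[i];
  int m = w.K - maxy + 1;
  std::vector<double> t(m);
  double tmax = R_NegInf;
  for (int N = maxy; N <= w.K; ++N) {
    double tn = N * loglam - lam - w.lgam[N] + w.Ctab(N, i) + A[i] + N * B[i];
    t[N - maxy] = tn;
    if (tn > tmax) tmax = tn;
  }
  double tot = 0.0;
  for (int k = 0; k < m; ++k) { t[k] = std::exp(t[k] - tmax); tot += t[k]; }
  double u = R::runif(0.0, tot);
  double acc = 0.0;
  for (int k = 0; k < m; ++k) {
    acc += t[k];
    if (u <= acc) return maxy + k;
  }
  return w.K;
}

// One-chain adaptive Metropolis-within-Gibbs run. Returns kept draws plus
// chi-squared discrepancy pairs and posterior-mean latent abundance.
// [[Rcpp::export]]
List cpp_nmix_mcmc(IntegerMatrix y, NumericMatrix Xab, NumericVector Xdet,
                   IntegerVector xdet_dim, IntegerVector area, int narea,
                   int K, double fixed_p,
                   double prior_sd_beta, double prior_sd_alpha,
                   double sigma_upper, bool fit_sigma,
                   int n_iter, int burn, int thin,
                   NumericVector beta_init, NumericVector alpha_init,
                   double sigma_init) {
  NmixWork w;
  w.n = y.nrow(); w.J = y.ncol(); w.K = K;
  w.pb = Xab.ncol(); w.pd = xdet_dim[2];
  w.narea = narea;
  w.y = y; w.Xab = Xab; w.Xdet = Xdet; w.area = area;
  w.fixed_p = fixed_p;
  w.maxy.resize(w.n);
  for (int i = 0; i < w.n; ++i) {
    int m = 0;
    for (int j = 0; j < w.J; ++j) if (y(i, j) > m) m = y(i, j);
    if (m > K) stop("K is smaller than an observed count");
    w.maxy[i] = m;
  }
  w.lgam.resize(K + 1);
  for (int N = 0; N <= K; ++N) w.lgam[N] = std::lgamma(N + 1.0);
  w.Ctab = NumericMatrix(K + 1, w.n);
  for (int i = 0; i < w.n; ++i) {
    for (int N = w.maxy[i]; N <= K; ++N) {
      double c = 0.0;
      for (int j = 0; j < w.J; ++j) c += Rf_lchoose(N, y(i, j));
      w.Ctab(N, i) = c;
    }
  }

  // state
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> alpha(alpha_init.begin(), alpha_init.end());
  double sigma = fit_sigma ? sigma_init : 0.0;
  std::vector<double> u(narea, 0.0);

  std::vector<double> etaab(w.n, 0.0);
  for (int i = 0; i < w.n; ++i) {
    double e = 0.0;
    for (int m = 0; m < w.pb; ++m) e += Xab(i, m) * beta[m];
    etaab[i] = e;
  }
  auto loglam_of = [&](int i) { return etaab[i] + sigma * u[area[i]]; };

  NumericMatrix P(w.n, w.J), etadet(w.n, w.J);
  auto refresh_P = [&](void) {
    if (w.pd == 0) {
      std::fill(P.begin(), P.end(), fixed_p);
    } else {
      for (int i = 0; i < w.n; ++i)
        for (int j = 0; j < w.J; ++j) {
          double e = 0.0;
          for (int m = 0; m < w.pd; ++m)
            e += Xdet[i + (size_t)w.n * j + (size_t)w.n * w.J * m] * alpha[m];
          etadet(i, j) = e;
          P(i, j) = 1.0 / (1.0 + std::exp(-e));
        }
    }
  };
  refresh_P();
  std::vector<double> A(w.n), B(w.n);
  fill_AB(w, P, A, B);

  std::vector<double> sll(w.n);
  double sumll = 0.0;
  for (int i = 0; i < w.n; ++i) { sll[i] = site_ll(w, i, loglam_of(i), A, B); sumll += sll[i]; }
  if (!R_finite(sumll)) stop("non-finite posterior at initialization");

  // sites per area for cheap u updates
  std::vector<std::vector<int>> asite(narea);
  for (int i = 0; i < w.n; ++i) asite[area[i]].push_back(i);

  // one proposal scale per scalar update; when the random intercept is
  // fitted there are two sigma moves (non-centered + centered interweave)
  int npar = w.pb + w.pd + (fit_sigma ? 3 + narea : 0);
  std::vector<double> scale(npar, 0.1), acc(npar, 0.0), tries(npar, 0.0);
  std::vector<double> accept_total(npar, 0.0), tries_total(npar, 0.0);
  const int adapt_every = 25;

  // adaptive joint proposal (AM) on the concatenated coefficient vector
  // theta = (beta, alpha): running mean/covariance accumulated during
  // burn-in, Cholesky refreshed periodically, global scale tuned to the
  // acceptance rate, all frozen after burn-in. The single-parameter
  // sweeps above keep the chain irreducible; the joint move carries the
  // mixing along correlated directions (correlated landscape covariates,
  // the abundance-detection intercept trade-off, and coefficients of
  // between-area covariates trading off against the random effects).
  const int pt = w.pb + w.pd + (fit_sigma ? narea : 0);
  std::vector<double> bmean(pt, 0.0), bM2((size_t)pt * pt, 0.0);
  std::vector<double> bchol((size_t)pt * pt, 0.0);
  int bcount = 0;
  bool have_chol = false;
  double jscale = 1.0, jacc = 0.0, jtries = 0.0;
  auto refresh_chol = [&](void) {
    if (bcount < 2 * pt + 20) return;
    double f = 5.6644 / pt * jscale;  // 2.38^2 / d
    std::vector<double> S((size_t)pt * pt);
    for (int a = 0; a < pt; ++a)
      for (int b = 0; b < pt; ++b) {
        double cov = bM2[a * pt + b] / (bcount - 1);
        if (a != b) cov *= 0.9;  // mild shrinkage towards the diagonal
        S[a * pt + b] = f * cov;
        if (a == b) S[a * pt + b] += 1e-10;
      }
    // dense Cholesky, lower triangular
    for (int a = 0; a < pt; ++a) {
      for (int b = 0; b <= a; ++b) {
        double sum = S[a * pt + b];
        for (int k = 0; k < b; ++k)
          sum -= bchol[a * pt + k] * bchol[b * pt + k];
        if (a == b) {
          if (sum <= 0) return;  // keep previous factor
          bchol[a * pt + a] = std::sqrt(sum);
        } else {
          bchol[a * pt + b] = sum / bchol[b * pt + b];
        }
      }
      for (int b = a + 1; b < pt; ++b) bchol[a * pt + b] = 0.0;
    }
    have_chol = true;
  };

  int n_keep = (n_iter - burn) / thin;
  NumericMatrix draws(n_keep, w.pb + w.pd + 1 + narea);
  NumericVector D_obs(n_keep), D_rep(n_keep), ll_keep(n_keep);
  std::vector<double> Nsum(w.n, 0.0);
  int kept = 0;

  std::vector<double> prop_ll(w.n), prop_A(w.n), prop_B(w.n);
  NumericMatrix Pp(w.n, w.J);

  for (int it = 1; it <= n_iter; ++it) {
    int pidx = 0;
    // --- beta updates ---
    for (int m = 0; m < w.pb; ++m, ++pidx) {
      double d = R::norm_rand() * scale[pidx];
      double bnew = beta[m] + d;
      double dprior = (-0.5 * bnew * bnew + 0.5 * beta[m] * beta[m]) /
                      (prior_sd_beta * prior_sd_beta);
      double newsum = 0.0;
      for (int i = 0; i < w.n; ++i) {
        prop_ll[i] = site_ll(w, i, loglam_of(i) + d * Xab(i, m), A, B);
        newsum += prop_ll[i];
      }
      tries[pidx] += 1; tries_total[pidx] += 1;
      if (R_finite(newsum) &&
          std::log(R::unif_rand()) < newsum - sumll + dprior) {
        beta[m] = bnew;
        for (int i = 0; i < w.n; ++i) { etaab[i] += d * Xab(i, m); sll[i] = prop_ll[i]; }
        sumll = newsum;
        acc[pidx] += 1; accept_total[pidx] += 1;
      }
    }
    // --- alpha updates ---
    for (int m = 0; m < w.pd; ++m, ++pidx) {
      double d = R::norm_rand() * scale[pidx];
      double anew = alpha[m] + d;
      double dprior = (-0.5 * anew * anew + 0.5 * alpha[m] * alpha[m]) /
                      (prior_sd_alpha * prior_sd_alpha);
      double newsum = 0.0;
      for (int i = 0; i < w.n; ++i) {
        double a = 0.0, b = 0.0;
        for (int j = 0; j < w.J; ++j) {
          double e = etadet(i, j) +
                     d * Xdet[i + (size_t)w.n * j + (size_t)w.n * w.J * m];
          double p = 1.0 / (1.0 + std::exp(-e));
          Pp(i, j) = p;
          if (w.y(i, j) > 0) a += w.y(i, j) * (std::log(p) - std::log1p(-p));
          b += std::log1p(-p);
        }
        prop_A[i] = a; prop_B[i] = b;
        prop_ll[i] = site_ll_core(w.maxy[i], w.K, loglam_of(i),
                                  std::exp(loglam_of(i)), &w.Ctab(0, i),
                                  a, b, w.lgam.data(), false);
        newsum += prop_ll[i];
      }
      tries[pidx] += 1; tries_total[pidx] += 1;
      if (R_finite(newsum) &&
          std::log(R::unif_rand()) < newsum - sumll + dprior) {
        alpha[m] = anew;
        for (int i = 0; i < w.n; ++i) {
          A[i] = prop_A[i]; B[i] = prop_B[i]; sll[i] = prop_ll[i];
          for (int j = 0; j < w.J; ++j) {
            etadet(i, j) += d * Xdet[i + (size_t)w.n * j + (size_t)w.n * w.J * m];
            P(i, j) = Pp(i, j);
          }
        }
        sumll = newsum;
        acc[pidx] += 1; accept_total[pidx] += 1;
      }
    }
    // --- joint (beta, alpha) updates along the adapted covariance
    // (several per sweep: they carry the mixing in correlated
    // directions) ---
    for (int jrep = 0; jrep < 5 && have_chol; ++jrep) {
      std::vector<double> z(pt), d(pt, 0.0);
      for (int a = 0; a < pt; ++a) z[a] = R::norm_rand();
      for (int a = 0; a < pt; ++a)
        for (int b = 0; b <= a; ++b) d[a] += bchol[a * pt + b] * z[b];
      double dprior = 0.0;
      for (int a = 0; a < w.pb; ++a) {
        double bn = beta[a] + d[a];
        dprior += (-0.5 * bn * bn + 0.5 * beta[a] * beta[a]) /
                  (prior_sd_beta * prior_sd_beta);
      }
      for (int m = 0; m < w.pd; ++m) {
        double an = alpha[m] + d[w.pb + m];
        dprior += (-0.5 * an * an + 0.5 * alpha[m] * alpha[m]) /
                  (prior_sd_alpha * prior_sd_alpha);
      }
      if (fit_sigma) {
        for (int k = 0; k < narea; ++k) {
          double un = u[k] + d[w.pb + w.pd + k];
          dprior += -0.5 * un * un + 0.5 * u[k] * u[k];
        }
      }
      bool move_alpha = false;
      for (int m = 0; m < w.pd; ++m) if (d[w.pb + m] != 0.0) move_alpha = true;
      double newsum = 0.0;
      for (int i = 0; i < w.n; ++i) {
        double a_i = A[i], b_i = B[i];
        if (move_alpha) {
          a_i = 0.0; b_i = 0.0;
          for (int j = 0; j < w.J; ++j) {
            double e = etadet(i, j);
            for (int m = 0; m < w.pd; ++m)
              e += d[w.pb + m] *
                   Xdet[i + (size_t)w.n * j + (size_t)w.n * w.J * m];
            double p = 1.0 / (1.0 + std::exp(-e));
            Pp(i, j) = p;
            if (w.y(i, j) > 0)
              a_i += w.y(i, j) * (std::log(p) - std::log1p(-p));
            b_i += std::log1p(-p);
          }
          prop_A[i] = a_i; prop_B[i] = b_i;
        }
        double de = 0.0;
        for (int a = 0; a < w.pb; ++a) de += Xab(i, a) * d[a];
        if (fit_sigma) de += sigma * d[w.pb + w.pd + area[i]];
        prop_ll[i] = site_ll_core(w.maxy[i], w.K, loglam_of(i) + de,
                                  std::exp(loglam_of(i) + de), &w.Ctab(0, i),
                                  a_i, b_i, w.lgam.data(), false);
        newsum += prop_ll[i];
      }
      jtries += 1;
      if (R_finite(newsum) &&
          std::log(R::unif_rand()) < newsum - sumll + dprior) {
        for (int a = 0; a < w.pb; ++a) beta[a] += d[a];
        for (int m = 0; m < w.pd; ++m) alpha[m] += d[w.pb + m];
        if (fit_sigma) {
          for (int k = 0; k < narea; ++k) u[k] += d[w.pb + w.pd + k];
        }
        for (int i = 0; i < w.n; ++i) {
          double de = 0.0;
          for (int a = 0; a < w.pb; ++a) de += Xab(i, a) * d[a];
          etaab[i] += de;
          sll[i] = prop_ll[i];
          if (move_alpha) {
            A[i] = prop_A[i]; B[i] = prop_B[i];
            for (int j = 0; j < w.J; ++j) {
              double e = etadet(i, j);
              for (int m = 0; m < w.pd; ++m)
                e += d[w.pb + m] *
                     Xdet[i + (size_t)w.n * j + (size_t)w.n * w.J * m];
              etadet(i, j) = e;
              P(i, j) = Pp(i, j);
            }
          }
        }
        sumll = newsum;
        jacc += 1;
      }
    }
    if (fit_sigma) {
      // --- sigma update (uniform prior, non-centered) ---
      {
        double d = R::norm_rand() * scale[pidx];
        double snew = sigma + d;
        tries[pidx] += 1; tries_total[pidx] += 1;
        if (snew >= 0.0 && snew <= sigma_upper) {
          double newsum = 0.0;
          for (int i = 0; i < w.n; ++i) {
            prop_ll[i] = site_ll(w, i, etaab[i] + snew * u[area[i]], A, B);
            newsum += prop_ll[i];
          }
          if (R_finite(newsum) && std::log(R::unif_rand()) < newsum - sumll) {
            sigma = snew;
            for (int i = 0; i < w.n; ++i) sll[i] = prop_ll[i];
            sumll = newsum;
            acc[pidx] += 1; accept_total[pidx] += 1;
          }
        }
        ++pidx;
      }
      // --- centered interweaving move for sigma: hold gamma = sigma*u
      // fixed (likelihood unchanged), rescale u; acceptance ratio is the
      // prior of gamma under the proposed vs current SD ---
      {
        if (sigma > 1e-12) {
          double snew = sigma + R::norm_rand() * scale[pidx];
          tries[pidx] += 1; tries_total[pidx] += 1;
          if (snew > 1e-12 && snew <= sigma_upper) {
            double Sg = 0.0;
            for (int k = 0; k < narea; ++k) Sg += sigma * sigma * u[k] * u[k];
            double dpost = -narea * (std::log(snew) - std::log(sigma)) -
                           0.5 * Sg * (1.0 / (snew * snew) -
                                       1.0 / (sigma * sigma));
            if (std::log(R::unif_rand()) < dpost) {
              double ratio = sigma / snew;
              for (int k = 0; k < narea; ++k) u[k] *= ratio;
              sigma = snew;
              acc[pidx] += 1; accept_total[pidx] += 1;
            }
          }
        }
        ++pidx;
      }
      // --- likelihood-invariant intercept shift: move the intercept and
      // compensate through the random effects (gamma fixed in total);
      // only the priors on beta[0] and u enter the ratio ---
      {
        if (sigma > 1e-12) {
          double dlt = R::norm_rand() * scale[pidx];
          double b0n = beta[0] + dlt;
          double dpost = (-0.5 * b0n * b0n + 0.5 * beta[0] * beta[0]) /
                         (prior_sd_beta * prior_sd_beta);
          for (int k = 0; k < narea; ++k) {
            double un = u[k] - dlt / sigma;
            dpost += -0.5 * un * un + 0.5 * u[k] * u[k];
          }
          tries[pidx] += 1; tries_total[pidx] += 1;
          if (std::log(R::unif_rand()) < dpost) {
            beta[0] = b0n;
            for (int k = 0; k < narea; ++k) u[k] -= dlt / sigma;
            for (int i = 0; i < w.n; ++i) etaab[i] += dlt;
            acc[pidx] += 1; accept_total[pidx] += 1;
          }
        }
        ++pidx;
      }
      // --- u_k updates ---
      for (int k = 0; k < narea; ++k, ++pidx) {
        double d = R::norm_rand() * scale[pidx];
        double unew = u[k] + d;
        double dprior = -0.5 * unew * unew + 0.5 * u[k] * u[k];
        double dll = 0.0;
        for (size_t s = 0; s < asite[k].size(); ++s) {
          int i = asite[k][s];
          prop_ll[i] = site_ll(w, i, etaab[i] + sigma * unew, A, B);
          dll += prop_ll[i] - sll[i];
        }
        tries[pidx] += 1; tries_total[pidx] += 1;
        if (R_finite(dll) && std::log(R::unif_rand()) < dll + dprior) {
          u[k] = unew;
          for (size_t s = 0; s < asite[k].size(); ++s) {
            int i = asite[k][s];
            sumll += prop_ll[i] - sll[i];
            sll[i] = prop_ll[i];
          }
          acc[pidx] += 1; accept_total[pidx] += 1;
        }
      }
    }

    // --- proposal adaptation, burn-in only ---
    if (it <= burn) {
      // accumulate the running (beta, alpha) mean/covariance (Welford)
      ++bcount;
      std::vector<double> theta(pt), delta(pt);
      for (int a = 0; a < w.pb; ++a) theta[a] = beta[a];
      for (int m = 0; m < w.pd; ++m) theta[w.pb + m] = alpha[m];
      if (fit_sigma) {
        for (int k = 0; k < narea; ++k) theta[w.pb + w.pd + k] = u[k];
      }
      for (int a = 0; a < pt; ++a) {
        delta[a] = theta[a] - bmean[a];
        bmean[a] += delta[a] / bcount;
      }
      for (int a = 0; a < pt; ++a)
        for (int b = 0; b < pt; ++b)
          bM2[a * pt + b] += delta[a] * (theta[b] - bmean[b]);
      if (it % adapt_every == 0) {
        for (int q = 0; q < npar; ++q) {
          if (tries[q] > 0) {
            double rate = acc[q] / tries[q];
            if (rate > 0.45) scale[q] *= 1.4;
            else if (rate < 0.25) scale[q] *= 0.7;
            acc[q] = 0; tries[q] = 0;
          }
        }
        if (jtries > 0) {
          double jrate = jacc / jtries;
          if (jrate > 0.45) jscale *= 1.4;
          else if (jrate < 0.25) jscale *= 0.7;
          jacc = 0; jtries = 0;
        }
        refresh_chol();
      }
    }

    // --- retention ---
    if (it > burn && (it - burn) % thin == 0) {
      int col = 0;
      for (int m = 0; m < w.pb; ++m) draws(kept, col++) = beta[m];
      for (int m = 0; m < w.pd; ++m) draws(kept, col++) = alpha[m];
      draws(kept, col++) = sigma;
      for (int k = 0; k < narea; ++k) draws(kept, col++) = sigma * u[k];
      ll_keep[kept] = sumll;
      // latent N draw, chi-squared discrepancies for observed and
      // replicated counts (replicates share the drawn N_i)
      double dobs = 0.0, drep = 0.0;
      for (int i = 0; i < w.n; ++i) {
        int Ni = sample_N(w, i, loglam_of(i), A, B);
        Nsum[i] += Ni;
        for (int j = 0; j < w.J; ++j) {
          double ex = Ni * P(i, j);
          double obs = w.y(i, j) - ex;
          dobs += obs * obs / (ex + 0.5);
          double yr = R::rbinom(Ni, P(i, j));
          double rep = yr - ex;
          drep += rep * rep / (ex + 0.5);
        }
      }
      D_obs[kept] = dobs; D_rep[kept] = drep;
      ++kept;
    }
  }

  NumericVector Nmean(w.n);
  for (int i = 0; i < w.n; ++i) Nmean[i] = Nsum[i] / std::max(kept, 1);
  NumericVector arate(npar);
  for (int q = 0; q < npar; ++q)
    arate[q] = tries_total[q] > 0 ? accept_total[q] / tries_total[q] : NA_REAL;

  return List::create(
    _["draws"] = draws, _["loglik"] = ll_keep,
    _["D_obs"] = D_obs, _["D_rep"] = D_rep,
    _["N_mean"] = Nmean, _["accept_rate"] = arate,
    _["final_scales"] = NumericVector(scale.begin(), scale.end())
  );
}
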
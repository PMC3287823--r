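#include <Rcpp.h>
using namespace Rcpp;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

static inline double clamp30(double e) {
  if (e > 30.0) return 30.0;
  if (e < -30.0) return -30.0;
  return e;
}

// in-place Cholesky of a small SPD matrix (lower triangle, column-major)
static bool chol_factor(std::vector<double> &A, const int q) {
  for (int j = 0; j < q; ++j) {
    double d = A[j + j * q];
    for (int k = 0; k < j; ++k) d -= A[j + k * q] * A[j + k * q];
    if (d <= 1e-12) return false;
    d = std::sqrt(d);
    A[j + j * q] = d;
    for (int i = j + 1; i < q; ++i) {
      double s = A[i + j * q];
      for (int k = 0; k < j; ++k) s -= A[i + k * q] * A[j + k * q];
      A[i + j * q] = s / d;
    }
  }
  return true;
}

static void chol_solve_factored(const std::vector<double> &L,
                                std::vector<double> &b, const int q) {
  for (int i = 0; i < q; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i + k * q] * b[k];
    b[i] = s / L[i + i * q];
  }
  for (int i = q - 1; i >= 0; --i) {
    double s = b[i];
    for (int k = i + 1; k < q; ++k) s -= L[k + i * q] * b[k];
    b[i] = s / L[i + i * q];
  }
}

// Coordinate-descent path for the L1-penalized logistic likelihood with
// unpenalized columns. Outer loop: iteratively reweighted least squares,
// stopped on the exact KKT conditions. Inner loop on each weighted
// quadratic: the unpenalized block (intercept + covariates) is solved
// exactly by Cholesky, the penalized coordinates by cyclic coordinate
// descent with soft thresholding. Warm starts along the decreasing path.
// [[Rcpp::export(name = ".cd_logistic_path")]]
List cd_logistic_path(NumericMatrix X, NumericVector y,
                      LogicalVector penalized, NumericVector lambda,
                      NumericVector beta_init, double tol, double beta_cap) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  std::vector<int> U, P;
  for (int j = 0; j < p; ++j) (penalized[j] ? P : U).push_back(j);
  const int q = (int) U.size();

  std::vector<double> beta(beta_init.begin(), beta_init.end());
  NumericMatrix betas(p, L);
  LogicalVector capped(L);
  std::vector<double> eta(n), z(n), w(n), r(n), wx2(p);

  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    eta[i] = e;
  }

  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    bool hit_cap = false;
    for (int outer = 0; outer < 100 && !hit_cap; ++outer) {
      for (int i = 0; i < n; ++i) {
        const double e = clamp30(eta[i]);
        const double pi = 1.0 / (1.0 + std::exp(-e));
        double wi = pi * (1.0 - pi);
        if (wi < 1e-6) wi = 1e-6;
        w[i] = wi;
        r[i] = (y[i] - pi) / wi;
        z[i] = eta[i] + r[i];
      }
      for (int j = 0; j < p; ++j) {
        double s = 0.0;
        const double *xj = &X(0, j);
        for (int i = 0; i < n; ++i) s += w[i] * xj[i] * xj[i];
        wx2[j] = s;
      }
      // the unpenalized-block Gram matrix depends only on w: factor once
      // per IRLS step
      std::vector<double> A(q * q), L_fac(q * q);
      bool have_fac = false;
      if (q > 0) {
        for (int a = 0; a < q; ++a) {
          const double *xa = &X(0, U[a]);
          for (int c = 0; c <= a; ++c) {
            const double *xc = &X(0, U[c]);
            double s = 0.0;
            for (int i = 0; i < n; ++i) s += w[i] * xa[i] * xc[i];
            A[a + c * q] = A[c + a * q] = s;
          }
        }
        L_fac = A;
        have_fac = chol_factor(L_fac, q);
      }
      for (int cycle = 0; cycle < 200; ++cycle) {
        double delta = 0.0;
        if (q > 0 && have_fac) {
          // exact WLS solve of the unpenalized block given the penalized fit
          std::vector<double> b(q);
          // t = r + Z beta_U is the residual with the U block removed
          for (int a = 0; a < q; ++a) {
            const double *xa = &X(0, U[a]);
            double s = 0.0;
            for (int i = 0; i < n; ++i) s += w[i] * xa[i] * r[i];
            for (int c = 0; c < q; ++c) s += A[a + c * q] * beta[U[c]];
            b[a] = s;
          }
          chol_solve_factored(L_fac, b, q);
          {
            for (int a = 0; a < q; ++a) {
              const double diff = beta[U[a]] - b[a];
              if (diff != 0.0) {
                const double *xa = &X(0, U[a]);
                for (int i = 0; i < n; ++i) r[i] += xa[i] * diff;
                beta[U[a]] = b[a];
                const double ad = std::fabs(diff);
                if (ad > delta) delta = ad;
              }
            }
          }
        }
        // full penalized sweep admits entering variables
        for (size_t a = 0; a < P.size(); ++a) {
          const int j = P[a];
          if (wx2[j] < 1e-12) continue;
          double num = beta[j] * wx2[j];
          const double *xj = &X(0, j);
          for (int i = 0; i < n; ++i) num += w[i] * xj[i] * r[i];
          const double bnew = soft(num, lam) / wx2[j];
          if (bnew != beta[j]) {
            const double diff = beta[j] - bnew;
            for (int i = 0; i < n; ++i) r[i] += xj[i] * diff;
            beta[j] = bnew;
            const double ad = std::fabs(diff);
            if (ad > delta) delta = ad;
          }
        }
        if (delta < tol) break;
        // fast iterations on the nonzero penalized set
        std::vector<int> active;
        for (size_t a = 0; a < P.size(); ++a)
          if (wx2[P[a]] >= 1e-12 && beta[P[a]] != 0.0) active.push_back(P[a]);
        for (int sweep = 0; sweep < 2000; ++sweep) {
          double d2 = 0.0;
          for (size_t a = 0; a < active.size(); ++a) {
            const int j = active[a];
            double num = beta[j] * wx2[j];
            const double *xj = &X(0, j);
            for (int i = 0; i < n; ++i) num += w[i] * xj[i] * r[i];
            const double bnew = soft(num, lam) / wx2[j];
            if (bnew != beta[j]) {
              const double diff = beta[j] - bnew;
              for (int i = 0; i < n; ++i) r[i] += xj[i] * diff;
              beta[j] = bnew;
              const double ad = std::fabs(diff);
              if (ad > d2) d2 = ad;
            }
          }
          if (d2 < tol) break;
        }
      }
      for (int i = 0; i < n; ++i) eta[i] = z[i] - r[i];
      for (int j = 0; j < p; ++j) {
        if (std::fabs(beta[j]) > beta_cap) {
          beta[j] = beta[j] > 0 ? beta_cap : -beta_cap;
          hit_cap = true;
        }
      }
      if (hit_cap) {
        for (int i = 0; i < n; ++i) {
          double e = 0.0;
          for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
          eta[i] = e;
        }
        break;
      }
      // KKT certificate on the true (non-quadratic) likelihood
      double viol = 0.0;
      std::vector<double> resid(n);
      for (int i = 0; i < n; ++i) {
        const double pi = 1.0 / (1.0 + std::exp(-clamp30(eta[i])));
        resid[i] = y[i] - pi;
      }
      for (int j = 0; j < p; ++j) {
        if (wx2[j] < 1e-12) continue;
        double score = 0.0;
        const double *xj = &X(0, j);
        for (int i = 0; i < n; ++i) score += xj[i] * resid[i];
        double v;
        if (!penalized[j]) v = std::fabs(score);
        else if (beta[j] == 0.0) v = std::max(std::fabs(score) - lam, 0.0);
        else v = std::fabs(score - lam * (beta[j] > 0 ? 1.0 : -1.0));
        if (v > viol) viol = v;
      }
      if (viol < 1e-8) break;
    }
    capped[l] = hit_cap;
    for (int j = 0; j < p; ++j) betas(j, l) = beta[j];
  }
  return List::create(_["beta"] = betas, _["capped"] = capped);
}
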
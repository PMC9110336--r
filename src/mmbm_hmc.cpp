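// Multilevel multinomial behavioural model: joint log-posterior with
// analytic gradients in the fully unconstrained (non-centered) space, and a
// Hamiltonian Monte Carlo chain runner with dual-averaging step-size and
// diagonal metric adaptation. All randomness comes from R's RNG, so chains
// are reproducible under set.seed().
//
// Unconstrained parameter vector theta (re_mode = 1, "both" levels):
//   [0, 4M)            beta[k + 4*m], 4 non-reference categories x M terms
//   [4M, 4M+4)         log sigma_individual
//   [4M+4, 4M+8)       log sigma_society
//   [4M+8, 4M+14)      y_individual: CPC (tanh^-1) coords of corr Cholesky
//   [4M+14, 4M+20)     y_society
//   [.., +4n)          z_individual, column-major (n x 4)
//   [.., +4J)          z_society, column-major (J x 4)
// re_mode = 0 drops everything after the betas (fixed effects only).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int CPC_ROW[6] = {1, 2, 2, 3, 3, 3}; // 0-based lower-tri order
static const int CPC_COL[6] = {0, 0, 1, 0, 1, 2};

// Build lower Cholesky factor L (4x4, row-major) from 6 unconstrained y.
static void cpc_chol(const double* y, double* L, double* w) {
  for (int t = 0; t < 16; ++t) L[t] = 0.0;
  L[0] = 1.0;
  for (int t = 0; t < 6; ++t) w[t] = std::tanh(y[t]);
  for (int i = 1; i < 4; ++i) {
    double prod_s = 1.0;
    for (int j = 0; j < i; ++j) {
      // find CPC slot for (i, j)
      int slot = -1;
      for (int t = 0; t < 6; ++t)
        if (CPC_ROW[t] == i && CPC_COL[t] == j) { slot = t; break; }
      double wij = w[slot];
      L[4 * i + j] = wij * prod_s;
      prod_s *= std::sqrt(1.0 - wij * wij);
    }
    L[4 * i + i] = prod_s;
  }
}

struct ModelData {
  int n, J, M;
  std::vector<double> Y;    // n x 5, column-major
  std::vector<double> T;    // row sums of Y
  std::vector<double> X;    // n x M, column-major
  std::vector<int> soc;     // 0-based society index per child
  double beta_sd, sigma_rate, lkj_eta;
  int re_mode;              // 0 = none, 1 = both levels
  int dim() const {
    return re_mode ? 4 * M + 20 + 4 * n + 4 * J : 4 * M;
  }
};

// Log-posterior and gradient. Returns lp; grad filled (length data.dim()).
static double lp_grad(const ModelData& d, const double* th, double* grad) {
  const int n = d.n, J = d.J, M = d.M;
  const int D = d.dim();
  for (int t = 0; t < D; ++t) grad[t] = 0.0;

  const double* beta = th;
  double lp = 0.0;

  // unpack random-effect blocks
  double sigI[4], sigS[4], LI[16], LS[16], wI[6], wS[6], MI[16], MS[16];
  const double* zI = nullptr; const double* zS = nullptr;
  int off_lamI = 4 * M, off_lamS = 4 * M + 4, off_yI = 4 * M + 8,
      off_yS = 4 * M + 14, off_zI = 4 * M + 20, off_zS = 4 * M + 20 + 4 * n;
  if (d.re_mode) {
    for (int k = 0; k < 4; ++k) {
      sigI[k] = std::exp(th[off_lamI + k]);
      sigS[k] = std::exp(th[off_lamS + k]);
    }
    cpc_chol(th + off_yI, LI, wI);
    cpc_chol(th + off_yS, LS, wS);
    for (int k = 0; k < 4; ++k)
      for (int m = 0; m <= k; ++m) {
        MI[4 * k + m] = sigI[k] * LI[4 * k + m];
        MS[4 * k + m] = sigS[k] * LS[4 * k + m];
      }
    zI = th + off_zI; zS = th + off_zS;
  }

  // society random effects nu_S (J x 4)
  std::vector<double> nuS(4 * J, 0.0);
  if (d.re_mode)
    for (int j = 0; j < J; ++j)
      for (int k = 0; k < 4; ++k) {
        double acc = 0.0;
        for (int m = 0; m <= k; ++m) acc += MS[4 * k + m] * zS[j + J * m];
        nuS[j + J * k] = acc;
      }

  // likelihood over children; accumulate residuals
  std::vector<double> GI; if (d.re_mode) GI.assign(4 * n, 0.0);
  std::vector<double> GS; if (d.re_mode) GS.assign(4 * J, 0.0);
  std::vector<double> gbeta(4 * M, 0.0);

  for (int i = 0; i < n; ++i) {
    double eta[4];
    for (int k = 0; k < 4; ++k) {
      double acc = 0.0;
      for (int m = 0; m < M; ++m) acc += beta[k + 4 * m] * d.X[i + n * m];
      if (d.re_mode) {
        for (int m = 0; m <= k; ++m) acc += MI[4 * k + m] * zI[i + n * m];
        acc += nuS[d.soc[i] + J * k];
      }
      eta[k] = acc;
    }
    double mx = 0.0;
    for (int k = 0; k < 4; ++k) if (eta[k] > mx) mx = eta[k];
    double denom = std::exp(-mx);
    double e[4];
    for (int k = 0; k < 4; ++k) { e[k] = std::exp(eta[k] - mx); denom += e[k]; }
    double lse = std::log(denom) + mx;
    double Ti = d.T[i];
    for (int k = 0; k < 4; ++k) lp += d.Y[i + n * k] * eta[k];
    lp -= Ti * lse;
    for (int k = 0; k < 4; ++k) {
      double g = d.Y[i + n * k] - Ti * (e[k] / denom);
      for (int m = 0; m < M; ++m) gbeta[k + 4 * m] += g * d.X[i + n * m];
      if (d.re_mode) { GI[i + n * k] = g; GS[d.soc[i] + J * k] += g; }
    }
  }

  // beta prior
  double bv = d.beta_sd * d.beta_sd;
  for (int t = 0; t < 4 * M; ++t) {
    lp += -0.5 * beta[t] * beta[t] / bv;
    grad[t] = gbeta[t] - beta[t] / bv;
  }
  if (!d.re_mode) return lp;

  // z gradients and priors
  for (int i = 0; i < n; ++i)
    for (int m = 0; m < 4; ++m) {
      double acc = 0.0;
      for (int k = m; k < 4; ++k) acc += GI[i + n * k] * MI[4 * k + m];
      double z = zI[i + n * m];
      grad[off_zI + i + n * m] = acc - z;
      lp += -0.5 * z * z;
    }
  for (int j = 0; j < J; ++j)
    for (int m = 0; m < 4; ++m) {
      double acc = 0.0;
      for (int k = m; k < 4; ++k) acc += GS[j + J * k] * MS[4 * k + m];
      double z = zS[j + J * m];
      grad[off_zS + j + J * m] = acc - z;
      lp += -0.5 * z * z;
    }

  // dM = G' z (4x4 lower), then chain to sigma and L, for each level
  for (int level = 0; level < 2; ++level) {
    const double* z = level == 0 ? zI : zS;
    const std::vector<double>& G = level == 0 ? GI : GS;
    const double* L = level == 0 ? LI : LS;
    const double* w = level == 0 ? wI : wS;
    const double* sig = level == 0 ? sigI : sigS;
    int rows = level == 0 ? n : J;
    int off_lam = level == 0 ? off_lamI : off_lamS;
    int off_y = level == 0 ? off_yI : off_yS;

    double dM[16] = {0};
    for (int k = 0; k < 4; ++k)
      for (int m = 0; m <= k; ++m) {
        double acc = 0.0;
        for (int r = 0; r < rows; ++r) acc += G[r + rows * k] * z[r + rows * m];
        dM[4 * k + m] = acc;
      }
    // sigma: lp += -sigma + lambda (Exponential(rate) prior + log-Jacobian)
    for (int k = 0; k < 4; ++k) {
      double dsig = 0.0;
      for (int m = 0; m <= k; ++m) dsig += dM[4 * k + m] * L[4 * k + m];
      lp += -d.sigma_rate * sig[k] + th[off_lam + k];
      grad[off_lam + k] = dsig * sig[k] - d.sigma_rate * sig[k] + 1.0;
    }
    // dL[k][m] = dM[k][m] * sigma_k
    double dL[16] = {0};
    for (int k = 0; k < 4; ++k)
      for (int m = 0; m <= k; ++m) dL[4 * k + m] = dM[4 * k + m] * sig[k];
    // CPC prior and transform gradient:
    // lp += a_j log(1 - w^2); d lp / d y = -2 a_j w + likelihood chain
    for (int t = 0; t < 6; ++t) {
      int i = CPC_ROW[t], c = CPC_COL[t];
      double wt = w[t];
      double a = d.lkj_eta + (4.0 - 1.0 - (c + 1.0)) / 2.0;
      lp += a * std::log1p(-wt * wt);
      double prod_s = 1.0;
      for (int m = 0; m < c; ++m) {
        // w[i][m]: find slot
        for (int s = 0; s < 6; ++s)
          if (CPC_ROW[s] == i && CPC_COL[s] == m)
            prod_s *= std::sqrt(1.0 - w[s] * w[s]);
      }
      double dy = (1.0 - wt * wt) * prod_s * dL[4 * i + c];
      for (int j = c + 1; j <= i; ++j) dy -= wt * L[4 * i + j] * dL[4 * i + j];
      dy += -2.0 * a * wt;
      grad[off_y + t] = dy;
    }
  }
  return lp;
}

static ModelData make_data(const NumericMatrix& Y, const NumericMatrix& X,
                           const IntegerVector& soc, int n_society,
                           double beta_sd, double sigma_rate, double lkj_eta,
                           int re_mode) {
  ModelData d;
  d.n = Y.nrow(); d.M = X.ncol(); d.J = n_society;
  d.beta_sd = beta_sd; d.sigma_rate = sigma_rate; d.lkj_eta = lkj_eta;
  d.re_mode = re_mode;
  d.Y.assign(Y.begin(), Y.end());
  d.X.assign(X.begin(), X.end());
  d.T.assign(d.n, 0.0);
  for (int i = 0; i < d.n; ++i)
    for (int k = 0; k < 5; ++k) d.T[i] += Y(i, k);
  d.soc.resize(d.n);
  for (int i = 0; i < d.n; ++i) d.soc[i] = soc[i] - 1;
  return d;
}

// [[Rcpp::export]]
List mmbm_lp_grad(NumericVector theta, NumericMatrix Y, NumericMatrix X,
                  IntegerVector society, int n_society, double beta_sd,
                  double sigma_rate, double lkj_eta, int re_mode) {
  ModelData d = make_data(Y, X, society, n_society, beta_sd, sigma_rate,
                          lkj_eta, re_mode);
  if ((int)theta.size() != d.dim())
    stop("theta has length %d, expected %d", (int)theta.size(), d.dim());
  NumericVector grad(d.dim());
  double lp = lp_grad(d, theta.begin(), grad.begin());
  return List::create(_["lp"] = lp, _["grad"] = grad);
}

// ---- ancillarity-sufficiency interweaving for (sigma, corr) --------------
// With non-centered coordinates, scale and correlation parameters couple
// tightly to the whole latent field when random effects are well informed.
// After each trajectory update we therefore re-draw (log sigma, corr CPCs)
// from their exact conditional given the reconstructed effects nu (centered
// coordinates) by univariate slice sampling, then map nu back to z under the
// new scales. Both moves leave the joint posterior invariant.

#include <functional>

// conditional log-density of (lam, y) given sufficient statistic S = nu'nu
static double centered_cond_logp(const double* lam, const double* y,
                                 const double S4[16], int nrows,
                                 double sigma_rate, double lkj_eta) {
  double sig[4], L[16], w[6];
  for (int k = 0; k < 4; ++k) sig[k] = std::exp(lam[k]);
  cpc_chol(y, L, w);
  // B = diag(sig) * L (lower); C = B^{-1} by forward substitution
  double B[16], C[16] = {0};
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j <= i; ++j) B[4 * i + j] = sig[i] * L[4 * i + j];
  for (int c = 0; c < 4; ++c) {
    for (int i = 0; i < 4; ++i) {
      double rhs = (i == c) ? 1.0 : 0.0;
      for (int j = 0; j < i; ++j) rhs -= B[4 * i + j] * C[4 * j + c];
      C[4 * i + c] = rhs / B[4 * i + i];
    }
  }
  // tr(Omega^{-1} S) = tr(C' C S)
  double tr = 0.0;
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      double m2 = 0.0;
      for (int k = 0; k < 4; ++k) m2 += C[4 * k + i] * C[4 * k + j];
      tr += m2 * S4[4 * j + i];
    }
  double logdet = 0.0;
  for (int k = 0; k < 4; ++k) logdet += 2.0 * (lam[k] + std::log(L[4 * k + k]));
  double lp = -0.5 * tr - 0.5 * nrows * logdet;
  for (int k = 0; k < 4; ++k) lp += -sigma_rate * sig[k] + lam[k];
  for (int t = 0; t < 6; ++t) {
    double a = lkj_eta + (4.0 - 1.0 - (CPC_COL[t] + 1.0)) / 2.0;
    lp += a * std::log1p(-w[t] * w[t]);
  }
  return lp;
}

// univariate slice sampler (stepping out + shrinkage)
static double slice1(const std::function<double(double)>& f, double x0,
                     double w) {
  double logy = f(x0) - exp_rand();
  double u = unif_rand() * w;
  double Lb = x0 - u, Rb = x0 + (w - u);
  for (int m = 0; m < 50 && f(Lb) > logy; ++m) Lb -= w;
  for (int m = 0; m < 50 && f(Rb) > logy; ++m) Rb += w;
  for (int k = 0; k < 100; ++k) {
    double x1 = Lb + unif_rand() * (Rb - Lb);
    if (f(x1) > logy) return x1;
    if (x1 < x0) Lb = x1; else Rb = x1;
  }
  return x0;
}

// one interweaving sweep over both random-effect levels; updates th in place
static void interweave_update(const ModelData& d, std::vector<double>& th) {
  const int n = d.n, J = d.J, M = d.M;
  int off_lam[2] = {4 * M, 4 * M + 4};
  int off_y[2] = {4 * M + 8, 4 * M + 14};
  int off_z[2] = {4 * M + 20, 4 * M + 20 + 4 * n};
  int rows_lv[2] = {n, J};
  for (int lv = 0; lv < 2; ++lv) {
    int rows = rows_lv[lv];
    double* lam = th.data() + off_lam[lv];
    double* y = th.data() + off_y[lv];
    double* z = th.data() + off_z[lv];
    // nu = z * (diag(sig) L)'
    double sig[4], L[16], w[6], B[16];
    for (int k = 0; k < 4; ++k) sig[k] = std::exp(lam[k]);
    cpc_chol(y, L, w);
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j <= i; ++j) B[4 * i + j] = sig[i] * L[4 * i + j];
    std::vector<double> nu(4 * rows);
    double S4[16] = {0};
    for (int r = 0; r < rows; ++r) {
      for (int k = 0; k < 4; ++k) {
        double acc = 0.0;
        for (int m = 0; m <= k; ++m) acc += B[4 * k + m] * z[r + rows * m];
        nu[r + rows * k] = acc;
      }
    }
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) {
        double acc = 0.0;
        for (int r = 0; r < rows; ++r) acc += nu[r + rows * a] * nu[r + rows * b];
        S4[4 * a + b] = acc;
      }
    // slice-sample the 10 coordinates of (lam, y) | nu, two sweeps
    double cur[10];
    for (int k = 0; k < 4; ++k) cur[k] = lam[k];
    for (int t = 0; t < 6; ++t) cur[4 + t] = y[t];
    for (int sweep = 0; sweep < 2; ++sweep)
    for (int c = 0; c < 10; ++c) {
      auto f = [&](double x) {
        double tmp[10];
        std::copy(cur, cur + 10, tmp);
        tmp[c] = x;
        return centered_cond_logp(tmp, tmp + 4, S4, rows, d.sigma_rate,
                                  d.lkj_eta);
      };
      cur[c] = slice1(f, cur[c], 0.5);
    }
    for (int k = 0; k < 4; ++k) lam[k] = cur[k];
    for (int t = 0; t < 6; ++t) y[t] = cur[4 + t];
    // z = B^{-1} nu under the new (sigma, corr)
    for (int k = 0; k < 4; ++k) sig[k] = std::exp(lam[k]);
    cpc_chol(y, L, w);
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j <= i; ++j) B[4 * i + j] = sig[i] * L[4 * i + j];
    for (int r = 0; r < rows; ++r) {
      for (int i = 0; i < 4; ++i) {
        double rhs = nu[r + rows * i];
        for (int j = 0; j < i; ++j) rhs -= B[4 * i + j] * z[r + rows * j];
        z[r + rows * i] = rhs / B[4 * i + i];
      }
    }
  }
}

// ---- exact interweaving of fixed effects with random-effect locations ----
// Holding the summed linear predictor fixed, the conditional of the fixed
// effects given the covariance parameters is Gaussian (normal prior times
// the multivariate-normal random-effect prior evaluated at nu = mu - X beta),
// so the ridge between beta and the latent means can be resampled exactly.

// dense Cholesky (lower) of an s x s SPD matrix, in place; returns false on
// failure
static bool chol_lower(std::vector<double>& A, int s) {
  for (int j = 0; j < s; ++j) {
    double diag = A[j * s + j];
    for (int k = 0; k < j; ++k) diag -= A[j * s + k] * A[j * s + k];
    if (diag <= 0.0 || !std::isfinite(diag)) return false;
    diag = std::sqrt(diag);
    A[j * s + j] = diag;
    for (int i = j + 1; i < s; ++i) {
      double v = A[i * s + j];
      for (int k = 0; k < j; ++k) v -= A[i * s + k] * A[j * s + k];
      A[i * s + j] = v / diag;
    }
    for (int i = 0; i < j; ++i) A[i * s + j] = 0.0;
  }
  return true;
}

// draw x ~ N(P^{-1} b, P^{-1}) given precision P (destroyed) and rhs b
static bool mvn_prec_draw(std::vector<double>& P, std::vector<double>& b,
                          int s, std::vector<double>& out) {
  if (!chol_lower(P, s)) return false;
  // solve L v = b ; L' m = v  for the mean
  std::vector<double> v(s);
  for (int i = 0; i < s; ++i) {
    double r = b[i];
    for (int j = 0; j < i; ++j) r -= P[i * s + j] * v[j];
    v[i] = r / P[i * s + i];
  }
  std::vector<double> m(s);
  for (int i = s - 1; i >= 0; --i) {
    double r = v[i];
    for (int j = i + 1; j < s; ++j) r -= P[j * s + i] * m[j];
    m[i] = r / P[i * s + i];
  }
  // noise: solve L' e = z
  std::vector<double> z(s), e(s);
  for (int i = 0; i < s; ++i) z[i] = norm_rand();
  for (int i = s - 1; i >= 0; --i) {
    double r = z[i];
    for (int j = i + 1; j < s; ++j) r -= P[j * s + i] * e[j];
    e[i] = r / P[i * s + i];
  }
  out.resize(s);
  for (int i = 0; i < s; ++i) out[i] = m[i] + e[i];
  return true;
}

// Omega^{-1} = B^{-T} B^{-1} from the lower factor B = diag(sig) L
static void omega_inverse(const double* B, double OmInv[16]) {
  double C[16] = {0};
  for (int c = 0; c < 4; ++c)
    for (int i = 0; i < 4; ++i) {
      double rhs = (i == c) ? 1.0 : 0.0;
      for (int j = 0; j < i; ++j) rhs -= B[4 * i + j] * C[4 * j + c];
      C[4 * i + c] = rhs / B[4 * i + i];
    }
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) {
      double acc = 0.0;
      for (int k = 0; k < 4; ++k) acc += C[4 * k + a] * C[4 * k + b];
      OmInv[4 * a + b] = acc;
    }
}

// Move (a): resample all of beta jointly with the individual effects,
// holding mu_i = X_i beta + nu_I[i] fixed. Move (b): the same for the
// society-constant columns of X against the society effects.
static void beta_interweave_update(const ModelData& d, std::vector<double>& th,
                                   const std::vector<int>& soc_cols,
                                   const std::vector<double>& soc_W) {
  const int n = d.n, J = d.J, M = d.M;
  double* beta = th.data();
  double* lamI = th.data() + 4 * M; double* lamS = th.data() + 4 * M + 4;
  double* yI = th.data() + 4 * M + 8; double* yS = th.data() + 4 * M + 14;
  double* zI = th.data() + 4 * M + 20; double* zS = th.data() + 4 * M + 20 + 4 * n;
  double bv = d.beta_sd * d.beta_sd;

  // --- (a) beta vs individual effects -------------------------------------
  {
    double sig[4], L[16], w[6], B[16];
    for (int k = 0; k < 4; ++k) sig[k] = std::exp(lamI[k]);
    cpc_chol(yI, L, w);
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j <= i; ++j) B[4 * i + j] = sig[i] * L[4 * i + j];
    double OmInv[16];
    omega_inverse(B, OmInv);
    // mu_i = X_i beta + nu_i
    std::vector<double> mu(4 * n);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 4; ++k) {
        double acc = 0.0;
        for (int m = 0; m < M; ++m) acc += beta[k + 4 * m] * d.X[i + n * m];
        for (int m = 0; m <= k; ++m) acc += B[4 * k + m] * zI[i + n * m];
        mu[i + n * k] = acc;
      }
    // precision P[(k,m),(l,m')] = OmInv[k,l] XtX[m,m'] + I/bv
    std::vector<double> XtX(M * M, 0.0);
    for (int m = 0; m < M; ++m)
      for (int m2 = 0; m2 <= m; ++m2) {
        double acc = 0.0;
        for (int i = 0; i < n; ++i) acc += d.X[i + n * m] * d.X[i + n * m2];
        XtX[m * M + m2] = XtX[m2 * M + m] = acc;
      }
    int s = 4 * M;
    std::vector<double> P(s * s), b(s, 0.0), draw;
    for (int m = 0; m < M; ++m)
      for (int k = 0; k < 4; ++k)
        for (int m2 = 0; m2 < M; ++m2)
          for (int l = 0; l < 4; ++l) {
            double v = OmInv[4 * k + l] * XtX[m * M + m2];
            if (k == l && m == m2) v += 1.0 / bv;
            P[(k + 4 * m) * s + (l + 4 * m2)] = v;
          }
    // rhs: b[(k,m)] = sum_i [OmInv mu_i]_k x_im
    for (int i = 0; i < n; ++i) {
      double om_mu[4];
      for (int k = 0; k < 4; ++k) {
        double acc = 0.0;
        for (int l = 0; l < 4; ++l) acc += OmInv[4 * k + l] * mu[i + n * l];
        om_mu[k] = acc;
      }
      for (int m = 0; m < M; ++m)
        for (int k = 0; k < 4; ++k) b[k + 4 * m] += om_mu[k] * d.X[i + n * m];
    }
    if (mvn_prec_draw(P, b, s, draw)) {
      for (int t = 0; t < s; ++t) beta[t] = draw[t];
      // nu = mu - X beta ; z = B^{-1} nu
      for (int i = 0; i < n; ++i) {
        double nu[4];
        for (int k = 0; k < 4; ++k) {
          double acc = mu[i + n * k];
          for (int m = 0; m < M; ++m) acc -= beta[k + 4 * m] * d.X[i + n * m];
          nu[k] = acc;
        }
        for (int k = 0; k < 4; ++k) {
          double rhs = nu[k];
          for (int j = 0; j < k; ++j) rhs -= B[4 * k + j] * zI[i + n * j];
          zI[i + n * k] = rhs / B[4 * k + k];
        }
      }
    }
  }

  // --- (b) society-constant columns vs society effects --------------------
  int q = (int)soc_cols.size();
  if (q > 0) {
    double sig[4], L[16], w[6], B[16];
    for (int k = 0; k < 4; ++k) sig[k] = std::exp(lamS[k]);
    cpc_chol(yS, L, w);
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j <= i; ++j) B[4 * i + j] = sig[i] * L[4 * i + j];
    double OmInv[16];
    omega_inverse(B, OmInv);
    // mu_j = W_j gamma + nu_S[j]
    std::vector<double> mu(4 * J);
    for (int j = 0; j < J; ++j)
      for (int k = 0; k < 4; ++k) {
        double acc = 0.0;
        for (int c = 0; c < q; ++c)
          acc += beta[k + 4 * soc_cols[c]] * soc_W[j + J * c];
        for (int m = 0; m <= k; ++m) acc += B[4 * k + m] * zS[j + J * m];
        mu[j + J * k] = acc;
      }
    std::vector<double> WtW(q * q, 0.0);
    for (int c = 0; c < q; ++c)
      for (int c2 = 0; c2 <= c; ++c2) {
        double acc = 0.0;
        for (int j = 0; j < J; ++j) acc += soc_W[j + J * c] * soc_W[j + J * c2];
        WtW[c * q + c2] = WtW[c2 * q + c] = acc;
      }
    int s = 4 * q;
    std::vector<double> P(s * s), b(s, 0.0), draw;
    for (int c = 0; c < q; ++c)
      for (int k = 0; k < 4; ++k)
        for (int c2 = 0; c2 < q; ++c2)
          for (int l = 0; l < 4; ++l) {
            double v = OmInv[4 * k + l] * WtW[c * q + c2];
            if (k == l && c == c2) v += 1.0 / bv;
            P[(k + 4 * c) * s + (l + 4 * c2)] = v;
          }
    for (int j = 0; j < J; ++j) {
      double om_mu[4];
      for (int k = 0; k < 4; ++k) {
        double acc = 0.0;
        for (int l = 0; l < 4; ++l) acc += OmInv[4 * k + l] * mu[j + J * l];
        om_mu[k] = acc;
      }
      for (int c = 0; c < q; ++c)
        for (int k = 0; k < 4; ++k) b[k + 4 * c] += om_mu[k] * soc_W[j + J * c];
    }
    if (mvn_prec_draw(P, b, s, draw)) {
      for (int c = 0; c < q; ++c)
        for (int k = 0; k < 4; ++k) beta[k + 4 * soc_cols[c]] = draw[k + 4 * c];
      for (int j = 0; j < J; ++j) {
        double nu[4];
        for (int k = 0; k < 4; ++k) {
          double acc = mu[j + J * k];
          for (int c = 0; c < q; ++c)
            acc -= beta[k + 4 * soc_cols[c]] * soc_W[j + J * c];
          nu[k] = acc;
        }
        for (int k = 0; k < 4; ++k) {
          double rhs = nu[k];
          for (int jj = 0; jj < k; ++jj) rhs -= B[4 * k + jj] * zS[j + J * jj];
          zS[j + J * k] = rhs / B[4 * k + k];
        }
      }
    }
  }
}

// Move (c): holding each child's total random effect tau_i = nu_I[i] +
// nu_S[soc(i)] fixed, the conditional of nu_S[j] is Gaussian with precision
// OmS^{-1} + n_j OmI^{-1}; resampling it decorrelates the society-effect
// locations (and through them the society-level scales).
static void level_split_update(const ModelData& d, std::vector<double>& th) {
  const int n = d.n, J = d.J, M = d.M;
  double* lamI = th.data() + 4 * M; double* lamS = th.data() + 4 * M + 4;
  double* yI = th.data() + 4 * M + 8; double* yS = th.data() + 4 * M + 14;
  double* zI = th.data() + 4 * M + 20; double* zS = th.data() + 4 * M + 20 + 4 * n;

  double sigI[4], sigS[4], LI[16], LS[16], wI[6], wS[6], BI[16], BS[16];
  for (int k = 0; k < 4; ++k) { sigI[k] = std::exp(lamI[k]); sigS[k] = std::exp(lamS[k]); }
  cpc_chol(yI, LI, wI); cpc_chol(yS, LS, wS);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j <= i; ++j) {
      BI[4 * i + j] = sigI[i] * LI[4 * i + j];
      BS[4 * i + j] = sigS[i] * LS[4 * i + j];
    }
  double OmInvI[16], OmInvS[16];
  omega_inverse(BI, OmInvI); omega_inverse(BS, OmInvS);

  std::vector<double> nuI(4 * n), nuS(4 * J);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 4; ++k) {
      double acc = 0.0;
      for (int m = 0; m <= k; ++m) acc += BI[4 * k + m] * zI[i + n * m];
      nuI[i + n * k] = acc;
    }
  for (int j = 0; j < J; ++j)
    for (int k = 0; k < 4; ++k) {
      double acc = 0.0;
      for (int m = 0; m <= k; ++m) acc += BS[4 * k + m] * zS[j + J * m];
      nuS[j + J * k] = acc;
    }

  for (int j = 0; j < J; ++j) {
    // sufficient statistics over the society's children
    double tau_sum[4] = {0, 0, 0, 0};
    int nj = 0;
    for (int i = 0; i < n; ++i) {
      if (d.soc[i] != j) continue;
      ++nj;
      for (int k = 0; k < 4; ++k) tau_sum[k] += nuI[i + n * k] + nuS[j + J * k];
    }
    if (nj == 0) continue;
    std::vector<double> P(16), b(4), draw;
    for (int a = 0; a < 4; ++a)
      for (int c = 0; c < 4; ++c)
        P[a * 4 + c] = OmInvS[4 * a + c] + nj * OmInvI[4 * a + c];
    for (int a = 0; a < 4; ++a) {
      double acc = 0.0;
      for (int c = 0; c < 4; ++c) acc += OmInvI[4 * a + c] * tau_sum[c];
      b[a] = acc;
    }
    if (!mvn_prec_draw(P, b, 4, draw)) continue;
    double delta[4];
    for (int k = 0; k < 4; ++k) {
      delta[k] = draw[k] - nuS[j + J * k];
      nuS[j + J * k] = draw[k];
    }
    // children absorb the shift so tau stays fixed
    for (int i = 0; i < n; ++i) {
      if (d.soc[i] != j) continue;
      for (int k = 0; k < 4; ++k) nuI[i + n * k] -= delta[k];
      for (int k = 0; k < 4; ++k) {
        double rhs = nuI[i + n * k];
        for (int m = 0; m < k; ++m) rhs -= BI[4 * k + m] * zI[i + n * m];
        zI[i + n * k] = rhs / BI[4 * k + k];
      }
    }
    for (int k = 0; k < 4; ++k) {
      double rhs = nuS[j + J * k];
      for (int m = 0; m < k; ++m) rhs -= BS[4 * k + m] * zS[j + J * m];
      zS[j + J * k] = rhs / BS[4 * k + k];
    }
  }
}

// ---- conditional refresh of the latent field -----------------------------
// Given the global parameters, the z rows are conditionally independent
// across children (and across societies). One coordinate-wise slice-sampling
// sweep per iteration decorrelates aggregate functions of the latent field,
// which otherwise dominate the autocorrelation of the scale and correlation
// parameters.

static void z_field_update(const ModelData& d, std::vector<double>& th) {
  const int n = d.n, J = d.J, M = d.M;
  const double* beta = th.data();
  double* lamI = th.data() + 4 * M; double* lamS = th.data() + 4 * M + 4;
  double* yI = th.data() + 4 * M + 8; double* yS = th.data() + 4 * M + 14;
  double* zI = th.data() + 4 * M + 20; double* zS = th.data() + 4 * M + 20 + 4 * n;

  double sigI[4], sigS[4], LI[16], LS[16], wI[6], wS[6], BI[16], BS[16];
  for (int k = 0; k < 4; ++k) { sigI[k] = std::exp(lamI[k]); sigS[k] = std::exp(lamS[k]); }
  cpc_chol(yI, LI, wI); cpc_chol(yS, LS, wS);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j <= i; ++j) {
      BI[4 * i + j] = sigI[i] * LI[4 * i + j];
      BS[4 * i + j] = sigS[i] * LS[4 * i + j];
    }

  // fixed-effect part per child
  std::vector<double> xb(4 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 4; ++k) {
      double acc = 0.0;
      for (int m = 0; m < M; ++m) acc += beta[k + 4 * m] * d.X[i + n * m];
      xb[i + n * k] = acc;
    }
  std::vector<double> nuS(4 * J);
  for (int j = 0; j < J; ++j)
    for (int k = 0; k < 4; ++k) {
      double acc = 0.0;
      for (int m = 0; m <= k; ++m) acc += BS[4 * k + m] * zS[j + J * m];
      nuS[j + J * k] = acc;
    }

  // child-level rows: slice each z[i, m] | rest
  for (int i = 0; i < n; ++i) {
    double base[4];
    for (int k = 0; k < 4; ++k) base[k] = xb[i + n * k] + nuS[d.soc[i] + J * k];
    double zi[4];
    for (int m = 0; m < 4; ++m) zi[m] = zI[i + n * m];
    auto child_lp = [&](const double* zrow) {
      double eta[4], mx = 0.0;
      for (int k = 0; k < 4; ++k) {
        double acc = base[k];
        for (int m = 0; m <= k; ++m) acc += BI[4 * k + m] * zrow[m];
        eta[k] = acc;
        if (acc > mx) mx = acc;
      }
      double denom = std::exp(-mx), ll = 0.0;
      for (int k = 0; k < 4; ++k) {
        denom += std::exp(eta[k] - mx);
        ll += d.Y[i + n * k] * eta[k];
      }
      ll -= d.T[i] * (std::log(denom) + mx);
      for (int m = 0; m < 4; ++m) ll += -0.5 * zrow[m] * zrow[m];
      return ll;
    };
    for (int m = 0; m < 4; ++m) {
      auto f = [&](double x) {
        double tmp[4] = {zi[0], zi[1], zi[2], zi[3]};
        tmp[m] = x;
        return child_lp(tmp);
      };
      zi[m] = slice1(f, zi[m], 1.0);
    }
    for (int m = 0; m < 4; ++m) zI[i + n * m] = zi[m];
  }

  // society-level rows: slice each z[j, m] | rest (uses updated zI)
  std::vector<double> ci(4 * n);   // child part incl. individual effects
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 4; ++k) {
      double acc = xb[i + n * k];
      for (int m = 0; m <= k; ++m) acc += BI[4 * k + m] * zI[i + n * m];
      ci[i + n * k] = acc;
    }
  for (int j = 0; j < J; ++j) {
    double zj[4];
    for (int m = 0; m < 4; ++m) zj[m] = zS[j + J * m];
    auto soc_lp = [&](const double* zrow) {
      double nu[4];
      for (int k = 0; k < 4; ++k) {
        double acc = 0.0;
        for (int m = 0; m <= k; ++m) acc += BS[4 * k + m] * zrow[m];
        nu[k] = acc;
      }
      double ll = 0.0;
      for (int i = 0; i < n; ++i) {
        if (d.soc[i] != j) continue;
        double eta[4], mx = 0.0;
        for (int k = 0; k < 4; ++k) {
          eta[k] = ci[i + n * k] + nu[k];
          if (eta[k] > mx) mx = eta[k];
        }
        double denom = std::exp(-mx);
        for (int k = 0; k < 4; ++k) {
          denom += std::exp(eta[k] - mx);
          ll += d.Y[i + n * k] * eta[k];
        }
        ll -= d.T[i] * (std::log(denom) + mx);
      }
      for (int m = 0; m < 4; ++m) ll += -0.5 * zrow[m] * zrow[m];
      return ll;
    };
    for (int m = 0; m < 4; ++m) {
      auto f = [&](double x) {
        double tmp[4] = {zj[0], zj[1], zj[2], zj[3]};
        tmp[m] = x;
        return soc_lp(tmp);
      };
      zj[m] = slice1(f, zj[m], 1.0);
    }
    for (int m = 0; m < 4; ++m) zS[j + J * m] = zj[m];
  }
}

// ---- non-centered hyperparameter slice sweep -----------------------------
// Slice-samples each log-scale and correlation coordinate on the full
// posterior with the standardized effects z held fixed. In these coordinates
// the low-sigma funnel neck is wide, so this move complements the centered
// interweaving re-draw.

static void hyper_slice_update(const ModelData& d, std::vector<double>& th,
                               std::vector<double>& scratch) {
  const int M = d.M;
  scratch.resize(th.size());
  int coords[20];
  for (int t = 0; t < 20; ++t) coords[t] = 4 * M + t;
  std::vector<double> tmp = th;
  for (int c = 0; c < 20; ++c) {
    int idx = coords[c];
    auto f = [&](double x) {
      tmp[idx] = x;
      return lp_grad(d, tmp.data(), scratch.data());
    };
    double newv = slice1(f, th[idx], 0.5);
    th[idx] = newv;
    tmp[idx] = newv;
  }
}

// ---- multinomial NUTS (dynamic HMC with a diagonal metric) ---------------

struct NutsState {
  std::vector<double> th, p, grad;
  double lp;
};

struct NutsTree {
  NutsState left, right;          // trajectory endpoints
  std::vector<double> th_prop;    // multinomial proposal from the subtree
  double lp_prop;
  double log_w;                   // log sum of exp(H0 - H) over the subtree
  bool turning, divergent;
  double sum_alpha;               // accept-statistic accumulator
  int n_alpha;
};

static double log_sum_exp(double a, double b) {
  double m = a > b ? a : b;
  if (!std::isfinite(m)) return m;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

static double kinetic(const std::vector<double>& p,
                      const std::vector<double>& var) {
  double k = 0.0;
  for (size_t t = 0; t < p.size(); ++t) k += 0.5 * var[t] * p[t] * p[t];
  return k;
}

static void leapfrog(const ModelData& d, NutsState& s, double dir_eps,
                     const std::vector<double>& var) {
  const int D = (int)s.th.size();
  for (int t = 0; t < D; ++t) s.p[t] += 0.5 * dir_eps * s.grad[t];
  for (int t = 0; t < D; ++t) s.th[t] += dir_eps * var[t] * s.p[t];
  s.lp = lp_grad(d, s.th.data(), s.grad.data());
  for (int t = 0; t < D; ++t) s.p[t] += 0.5 * dir_eps * s.grad[t];
}

// U-turn criterion across two endpoints under the diagonal metric
static bool is_turning(const NutsState& left, const NutsState& right,
                       const std::vector<double>& var) {
  double a = 0.0, b = 0.0;
  for (size_t t = 0; t < var.size(); ++t) {
    double dth = right.th[t] - left.th[t];
    a += dth * var[t] * left.p[t];
    b += dth * var[t] * right.p[t];
  }
  return a < 0.0 || b < 0.0;
}

static NutsTree build_tree(const ModelData& d, const NutsState& from,
                           int depth, double dir_eps,
                           const std::vector<double>& var, double H0) {
  NutsTree tree;
  if (depth == 0) {
    NutsState s = from;
    leapfrog(d, s, dir_eps, var);
    double H = std::isfinite(s.lp) ? -s.lp + kinetic(s.p, var) : INFINITY;
    double dH = H0 - H;
    tree.divergent = !std::isfinite(H) || (H - H0) > 1000.0;
    tree.turning = false;
    tree.log_w = tree.divergent ? -INFINITY : dH;
    tree.sum_alpha = tree.divergent ? 0.0 : (dH > 0 ? 1.0 : std::exp(dH));
    tree.n_alpha = 1;
    tree.left = s; tree.right = s;
    tree.th_prop = s.th; tree.lp_prop = s.lp;
    return tree;
  }
  NutsTree first = build_tree(d, from, depth - 1, dir_eps, var, H0);
  if (first.divergent || first.turning) return first;
  const NutsState& edge = dir_eps > 0 ? first.right : first.left;
  NutsTree second = build_tree(d, edge, depth - 1, dir_eps, var, H0);
  NutsTree tree2 = first;
  tree2.sum_alpha = first.sum_alpha + second.sum_alpha;
  tree2.n_alpha = first.n_alpha + second.n_alpha;
  tree2.divergent = second.divergent;
  if (second.divergent) return tree2;
  // multinomial sampling between the two halves
  double log_w = log_sum_exp(first.log_w, second.log_w);
  if (std::isfinite(second.log_w) &&
      unif_rand() < std::exp(second.log_w - log_w)) {
    tree2.th_prop = second.th_prop; tree2.lp_prop = second.lp_prop;
  }
  tree2.log_w = log_w;
  if (dir_eps > 0) tree2.right = second.right; else tree2.left = second.left;
  tree2.turning = second.turning || is_turning(tree2.left, tree2.right, var);
  return tree2;
}

// [[Rcpp::export]]
List mmbm_hmc_chain(NumericMatrix Y, NumericMatrix X, IntegerVector society,
                    int n_society, double beta_sd, double sigma_rate,
                    double lkj_eta, int re_mode, NumericVector init,
                    int iter, int warmup, int max_treedepth,
                    double target_accept, int cond_sweeps,
                    int interweave_period, int updates_per_iter) {
  ModelData d = make_data(Y, X, society, n_society, beta_sd, sigma_rate,
                          lkj_eta, re_mode);
  const int D = d.dim();
  if ((int)init.size() != D) stop("init has wrong length");

  std::vector<double> th(init.begin(), init.end());
  std::vector<double> grad(D), th_p(D), grad_p(D), p(D), var(D, 1.0);
  std::vector<double> hyper_scratch;
  double lp = lp_grad(d, th.data(), grad.data());
  if (!std::isfinite(lp)) stop("non-finite log-posterior at initial values");

  // columns of X that are constant within each society (candidates for the
  // society-level fixed-effect interweaving move)
  std::vector<int> soc_cols;
  std::vector<double> soc_W;
  if (re_mode) {
    std::vector<std::vector<double>> vals;
    for (int m = 0; m < d.M; ++m) {
      std::vector<double> val(d.J, NA_REAL);
      bool constant = true;
      for (int i = 0; i < d.n; ++i) {
        double v = d.X[i + d.n * m];
        int j = d.soc[i];
        if (ISNAN(val[j])) val[j] = v;
        else if (val[j] != v) { constant = false; break; }
      }
      if (constant) { soc_cols.push_back(m); vals.push_back(val); }
    }
    soc_W.resize(d.J * soc_cols.size());
    for (size_t c = 0; c < soc_cols.size(); ++c)
      for (int j = 0; j < d.J; ++j) soc_W[j + d.J * c] = vals[c][j];
  }

  // crude reasonable-epsilon search with unit metric
  double eps = 0.1;
  {
    for (int trial = 0; trial < 30; ++trial) {
      for (int t = 0; t < D; ++t) p[t] = norm_rand();
      double H0 = -lp;
      for (int t = 0; t < D; ++t) H0 += 0.5 * p[t] * p[t];
      th_p = th;
      std::vector<double> pp = p;
      for (int t = 0; t < D; ++t) pp[t] += 0.5 * eps * grad[t];
      for (int t = 0; t < D; ++t) th_p[t] += eps * pp[t];
      double lp1 = lp_grad(d, th_p.data(), grad_p.data());
      double H1 = -lp1;
      for (int t = 0; t < D; ++t) {
        double pf = pp[t] + 0.5 * eps * grad_p[t];
        H1 += 0.5 * pf * pf;
      }
      double dH = H0 - H1;
      bool ok = std::isfinite(dH) && dH > std::log(0.5);
      if (trial == 0) { if (ok) { eps *= 2; } else { eps /= 2; } continue; }
      if (ok) { if (eps > 1.0) break; eps *= 2; }
      else { eps /= 2; if (eps < 1e-6) break; }
      if (trial >= 12) break;
    }
    if (eps > 1.0) eps = 1.0;
  }

  // dual averaging state
  double mu = std::log(10.0 * eps), log_eps_bar = std::log(eps), H_bar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int adapt_t = 0;

  // expanding (doubling) metric-adaptation windows between an initial and a
  // terminal step-size-only phase, as in windowed HMC adaptation
  int init_buf = (int)(0.15 * warmup), term_buf = (int)(0.10 * warmup);
  int slow_end = warmup - term_buf;
  std::vector<int> win_ends;
  {
    int pos = init_buf, wlen = 25;
    while (pos < slow_end) {
      int end = pos + wlen;
      if (end > slow_end || slow_end - end < wlen) end = slow_end;
      win_ends.push_back(end);
      pos = end;
      wlen *= 2;
    }
  }
  size_t cur_win = 0;
  std::vector<double> wsum(D, 0.0), wsum2(D, 0.0);
  int wcount = 0;

  int n_keep = iter - warmup;
  NumericMatrix draws(n_keep, D);
  NumericVector lp_keep(n_keep);
  int divergences = 0;
  double sum_accept_stat = 0.0; int n_post = 0;

  for (int it = 0; it < iter; ++it) {
    double it_sum_alpha = 0.0; int it_n_alpha = 0;
    bool it_diverged = false;
    for (int upd = 0; upd < updates_per_iter; ++upd) {
    // momentum p ~ N(0, diag(1/var))
    NutsState cur;
    cur.th = th; cur.grad = grad; cur.lp = lp;
    cur.p.resize(D);
    for (int t = 0; t < D; ++t) cur.p[t] = norm_rand() / std::sqrt(var[t]);
    double H0 = -lp + kinetic(cur.p, var);

    NutsState left = cur, right = cur;
    std::vector<double> th_prop = th;
    double lp_prop = lp;
    double log_w = 0.0;           // weight of the initial point: exp(H0-H0)=1
    bool diverged = false;
    double sum_alpha = 0.0; int n_alpha = 0;

    for (int depth = 0; depth < max_treedepth; ++depth) {
      double dir = unif_rand() < 0.5 ? -1.0 : 1.0;
      const NutsState& edge = dir > 0 ? right : left;
      NutsTree sub = build_tree(d, edge, depth, dir * eps, var, H0);
      sum_alpha += sub.sum_alpha; n_alpha += sub.n_alpha;
      if (sub.divergent) { diverged = true; break; }
      if (sub.turning) break;
      // biased progressive sampling toward the new subtree
      if (std::isfinite(sub.log_w)) {
        double pr = std::exp(sub.log_w - log_w);
        if (pr > 1.0) pr = 1.0;
        if (unif_rand() < pr) { th_prop = sub.th_prop; lp_prop = sub.lp_prop; }
      }
      log_w = log_sum_exp(log_w, sub.log_w);
      if (dir > 0) right = sub.right; else left = sub.left;
      if (is_turning(left, right, var)) break;
    }
    th = th_prop;
    if (d.re_mode) {
      for (int sweep = 0; sweep < cond_sweeps; ++sweep) {
        z_field_update(d, th);
        level_split_update(d, th);
        beta_interweave_update(d, th, soc_cols, soc_W);
        // applying the centered re-draw of (sigma, corr) only every
        // interweave_period-th iteration leaves pure non-centered
        // iterations in between, which traverse the low-sigma funnel
        // neck more freely
        if (interweave_period > 0 && it % interweave_period == 0)
          interweave_update(d, th);
      }
      // the full-posterior hyperparameter slice costs as much as a short
      // NUTS trajectory, so it runs once per iteration
      hyper_slice_update(d, th, hyper_scratch);
    }
    lp = lp_grad(d, th.data(), grad.data());
    (void)lp_prop;
    it_sum_alpha += sum_alpha; it_n_alpha += n_alpha;
    it_diverged = it_diverged || diverged;
    }
    double alpha = it_n_alpha > 0 ? it_sum_alpha / it_n_alpha : 0.0;
    if (it >= warmup) {
      if (it_diverged) ++divergences;
      sum_accept_stat += alpha;
      ++n_post;
    }

    if (it < warmup) {
      // step-size adaptation
      ++adapt_t;
      H_bar = (1.0 - 1.0 / (adapt_t + t0)) * H_bar +
              (target_accept - alpha) / (adapt_t + t0);
      double log_eps = mu - std::sqrt((double)adapt_t) / gamma * H_bar;
      double wgt = std::pow((double)adapt_t, -kappa);
      log_eps_bar = wgt * log_eps + (1.0 - wgt) * log_eps_bar;
      eps = std::exp(log_eps);
      // metric windows
      if (cur_win < win_ends.size() && it >= init_buf) {
        for (int t = 0; t < D; ++t) { wsum[t] += th[t]; wsum2[t] += th[t] * th[t]; }
        ++wcount;
        if (it == win_ends[cur_win] - 1) {
          if (wcount > 10) {
            for (int t = 0; t < D; ++t) {
              double m = wsum[t] / wcount;
              double v = wsum2[t] / wcount - m * m;
              double reg = ((double)wcount / (wcount + 5.0)) * v +
                           1e-3 * (5.0 / (wcount + 5.0));
              var[t] = reg > 1e-8 ? reg : 1e-8;
            }
            // restart step-size adaptation around current average
            eps = std::exp(log_eps_bar);
            mu = std::log(10.0 * eps);
            H_bar = 0.0; adapt_t = 0; log_eps_bar = std::log(eps);
          }
          std::fill(wsum.begin(), wsum.end(), 0.0);
          std::fill(wsum2.begin(), wsum2.end(), 0.0);
          wcount = 0;
          ++cur_win;
        }
      }
      if (it == warmup - 1) eps = std::exp(log_eps_bar);
    } else {
      for (int t = 0; t < D; ++t) draws(it - warmup, t) = th[t];
      lp_keep[it - warmup] = lp;
    }
  }

  return List::create(
    _["draws"] = draws, _["lp"] = lp_keep,
    _["divergences"] = divergences,
    _["accept_rate"] = n_post ? sum_accept_stat / n_post : NA_REAL,
    _["step_size"] = eps);
}
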
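// Tri-cube local-linear smoothing and logistic local scoring.
//
// Neighborhoods and kernel weights depend only on the coordinates, so they
// are computed once per (coords, targets, span) as a "plan" and reused across
// local-scoring iterations and across conditional permutations (which permute
// outcomes/covariates against the fixed coordinate set).

#include <RcppArmadillo.h>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double tricube(double u) {
  if (u >= 1.0) return 0.0;
  double t = 1.0 - u * u * u;
  return t * t * t;
}

// k nearest neighbours of each target among rows of X, ties broken by row
// order; bandwidth = distance to the k-th neighbour in that order.
// [[Rcpp::export]]
List loess_plan_cpp(const arma::mat& X, const arma::mat& T, double span) {
  const int n = X.n_rows, m = T.n_rows, d = X.n_cols;
  int k = (int)std::ceil(span * n);
  // the boundary neighbour's tri-cube weight is exactly zero, so a
  // local-linear fit needs d+2 neighbours to avoid rank deficiency
  if (k < d + 2) k = d + 2;
  if (k > n) k = n;

  arma::imat idx(k, m);
  arma::mat kw(k, m);
  arma::vec bw(m);

  std::vector<std::pair<double, int> > dv(n);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double dd = X(i, c) - T(j, c);
        s += dd * dd;
      }
      dv[i] = std::make_pair(s, i);
    }
    // lexicographic (distance, index) order implements the tie-break rule:
    // ties at the neighbourhood boundary go to the earlier record
    std::nth_element(dv.begin(), dv.begin() + (k - 1), dv.end());
    std::sort(dv.begin(), dv.begin() + k);  // deterministic accumulation order
    double h = std::sqrt(dv[k - 1].first);
    bw(j) = h;
    for (int i = 0; i < k; ++i) {
      idx(i, j) = dv[i].second;
      double dist = std::sqrt(dv[i].first);
      kw(i, j) = (h > 0.0) ? tricube(dist / h) : 1.0;
    }
  }
  return List::create(_["idx"] = idx, _["kw"] = kw, _["bw"] = bw, _["k"] = k);
}

// Solve the symmetric p x p system A beta = b in place via Cholesky with a
// relative pivot tolerance; returns false on (near-)rank-deficiency.
// A packed as upper triangle row-wise: p=2 -> {a00,a01,a11};
// p=3 -> {a00,a01,a02,a11,a12,a22}.
static bool chol_solve(int p, const double* A, const double* b, double* out) {
  double L[6], z[3];
  double dmax = 0.0;
  if (p == 2) {
    dmax = std::max(A[0], A[2]);
    double tol = 1e-12 * (dmax > 0 ? dmax : 1.0);
    if (A[0] <= tol) return false;
    double l00 = std::sqrt(A[0]);
    double l10 = A[1] / l00;
    double d1 = A[2] - l10 * l10;
    if (d1 <= tol) return false;
    double l11 = std::sqrt(d1);
    z[0] = b[0] / l00;
    z[1] = (b[1] - l10 * z[0]) / l11;
    out[1] = z[1] / l11;
    out[0] = (z[0] - l10 * out[1]) / l00;
    return true;
  }
  // p == 3
  dmax = std::max(A[0], std::max(A[3], A[5]));
  double tol = 1e-12 * (dmax > 0 ? dmax : 1.0);
  if (A[0] <= tol) return false;
  L[0] = std::sqrt(A[0]);               // l00
  L[1] = A[1] / L[0];                   // l10
  L[2] = A[2] / L[0];                   // l20
  double d1 = A[3] - L[1] * L[1];
  if (d1 <= tol) return false;
  L[3] = std::sqrt(d1);                 // l11
  L[4] = (A[4] - L[2] * L[1]) / L[3];   // l21
  double d2 = A[5] - L[2] * L[2] - L[4] * L[4];
  if (d2 <= tol) return false;
  L[5] = std::sqrt(d2);                 // l22
  z[0] = b[0] / L[0];
  z[1] = (b[1] - L[1] * z[0]) / L[3];
  z[2] = (b[2] - L[2] * z[0] - L[4] * z[1]) / L[5];
  out[2] = z[2] / L[5];
  out[1] = (z[1] - L[4] * out[2]) / L[3];
  out[0] = (z[0] - L[1] * out[1] - L[2] * out[2]) / L[0];
  return true;
}

// Local-linear WLS at one target; returns fitted value; optionally the hat
// weight on data row `self`. Coordinates scaled by bandwidth for conditioning.
static double local_fit(const arma::mat& X, const arma::mat& T,
                        const arma::imat& idx, const arma::mat& kw,
                        const arma::vec& bw, int j,
                        const double* y, const double* w,
                        int self, double* hat_self, int* fallback) {
  const int k = idx.n_rows, d = X.n_cols;
  const double h = bw(j) > 0.0 ? bw(j) : 1.0;
  const double inv_h = 1.0 / h;
  const int* ip = idx.colptr(j);
  const double* kp = kw.colptr(j);
  double sw = 0.0, swy = 0.0;
  double beta[3];
  if (d == 1) {
    const double t0 = T(j, 0);
    const double* x0 = X.colptr(0);
    double a00 = 0, a01 = 0, a11 = 0, b0 = 0, b1 = 0;
    for (int i = 0; i < k; ++i) {
      int r = ip[i];
      double wt = kp[i] * w[r];
      if (wt <= 0.0) continue;
      double u = (x0[r] - t0) * inv_h;
      double yy = y[r];
      a00 += wt; a01 += wt * u; a11 += wt * u * u;
      b0 += wt * yy; b1 += wt * u * yy;
      sw += wt; swy += wt * yy;
    }
    if (sw <= 0.0) { if (hat_self) *hat_self = NA_REAL; return NA_REAL; }
    double A[3] = {a00, a01, a11};
    double b[2] = {b0, b1};
    if (chol_solve(2, A, b, beta)) {
      if (hat_self) {
        double e1[2] = {1.0, 0.0}, a1[2];
        chol_solve(2, A, e1, a1);
        double hs = 0.0;
        for (int i = 0; i < k; ++i) {
          if (ip[i] != self) continue;
          double wt = kp[i] * w[self];
          double u = (x0[self] - t0) * inv_h;
          hs = wt * (a1[0] + a1[1] * u);
        }
        *hat_self = hs;
      }
      return beta[0];
    }
  } else {
    const double t0 = T(j, 0), t1 = T(j, 1);
    const double* x0 = X.colptr(0);
    const double* x1 = X.colptr(1);
    double a00 = 0, a01 = 0, a02 = 0, a11 = 0, a12 = 0, a22 = 0;
    double b0 = 0, b1 = 0, b2 = 0;
    for (int i = 0; i < k; ++i) {
      int r = ip[i];
      double wt = kp[i] * w[r];
      if (wt <= 0.0) continue;
      double u = (x0[r] - t0) * inv_h;
      double v = (x1[r] - t1) * inv_h;
      double yy = y[r];
      a00 += wt; a01 += wt * u; a02 += wt * v;
      a11 += wt * u * u; a12 += wt * u * v; a22 += wt * v * v;
      b0 += wt * yy; b1 += wt * u * yy; b2 += wt * v * yy;
      sw += wt; swy += wt * yy;
    }
    if (sw <= 0.0) { if (hat_self) *hat_self = NA_REAL; return NA_REAL; }
    double A[6] = {a00, a01, a02, a11, a12, a22};
    double b[3] = {b0, b1, b2};
    if (chol_solve(3, A, b, beta)) {
      if (hat_self) {
        double e1[3] = {1.0, 0.0, 0.0}, a1[3];
        chol_solve(3, A, e1, a1);
        double hs = 0.0;
        for (int i = 0; i < k; ++i) {
          if (ip[i] != self) continue;
          double wt = kp[i] * w[self];
          double u = (x0[self] - t0) * inv_h;
          double v = (x1[self] - t1) * inv_h;
          hs = wt * (a1[0] + a1[1] * u + a1[2] * v);
        }
        *hat_self = hs;
      }
      return beta[0];
    }
  }
  // degenerate local design: weighted mean
  if (fallback) ++(*fallback);
  if (hat_self) {
    double hs = 0.0;
    for (int i = 0; i < k; ++i)
      if (ip[i] == self) hs = kp[i] * w[self] / sw;
    *hat_self = hs;
  }
  return swy / sw;
}

// [[Rcpp::export]]
List loess_apply_cpp(const arma::mat& X, const arma::mat& T,
                     const arma::imat& idx, const arma::mat& kw,
                     const arma::vec& bw,
                     const arma::vec& y, const arma::vec& w,
                     const arma::ivec& self, bool want_hat) {
  const int m = T.n_rows;
  arma::vec fitted(m), hat(m, arma::fill::zeros);
  int fb = 0;
  for (int j = 0; j < m; ++j) {
    double hs = 0.0;
    fitted(j) = local_fit(X, T, idx, kw, bw, j, y.memptr(), w.memptr(),
                          want_hat ? (int)self(j) : -1,
                          want_hat ? &hs : (double*)0, &fb);
    if (want_hat) hat(j) = hs;
  }
  return List::create(_["fitted"] = fitted, _["hat_diag"] = hat,
                      _["n_fallback"] = fb);
}

static double binom_dev(const arma::vec& y, const arma::vec& eta) {
  double dev = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    double mu = 1.0 / (1.0 + std::exp(-eta(i)));
    if (mu < 1e-10) mu = 1e-10;
    if (mu > 1.0 - 1e-10) mu = 1.0 - 1e-10;
    dev += y(i) * std::log(mu) + (1.0 - y(i)) * std::log(1.0 - mu);
  }
  return -2.0 * dev;
}

struct GamState {
  double intercept;
  arma::vec gamma;
  arma::vec S, r, w;
  double dev;
  int iter;
};

// Logistic GAM by local scoring with one backfit cycle per iteration.
// Z: parametric covariates (no intercept column). beta0: (1+p) start values.
// Keeps the best-deviance iterate (iterate 0 = parametric-only start).
static GamState gam_fit_core(const arma::mat& X, const arma::imat& idx,
                             const arma::mat& kw, const arma::vec& bw,
                             const arma::mat& Z, const arma::vec& y,
                             const arma::vec& beta0,
                             int maxit, double tol,
                             bool* converged, int* niter, int* fallbacks) {
  const int n = X.n_rows, p = Z.n_cols;
  arma::mat D(n, p + 1);         // parametric design [1 Z]
  D.col(0).ones();
  if (p > 0) D.cols(1, p) = Z;

  arma::vec eta = D * beta0;
  arma::vec S(n, arma::fill::zeros);

  GamState best;
  best.intercept = beta0(0);
  best.gamma = (p > 0) ? arma::vec(beta0.subvec(1, p)) : arma::vec();
  best.S = S;
  best.r = arma::vec(n, arma::fill::zeros);
  best.w = arma::vec(n, arma::fill::zeros);
  best.dev = binom_dev(y, eta);
  best.iter = 0;
  {
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    best.w = mu % (1.0 - mu);
  }

  double dev_prev = best.dev;
  *converged = false;
  int it = 0, fb = 0;
  for (it = 1; it <= maxit; ++it) {
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    mu = arma::clamp(mu, 1e-8, 1.0 - 1e-8);
    arma::vec w = mu % (1.0 - mu);
    arma::vec zeta = eta + (y - mu) / w;

    // weighted parametric solve on zeta - S
    arma::mat A = D.t() * (D.each_col() % w);
    arma::vec bvec = D.t() * ((zeta - S) % w);
    arma::vec beta = arma::solve(A, bvec, arma::solve_opts::no_approx);

    arma::vec par = D * beta;
    arma::vec r = zeta - par;

    // loess smooth of partial residual, prior weights w
    arma::vec Sraw(n);
    for (int j = 0; j < n; ++j)
      Sraw(j) = local_fit(X, X, idx, kw, bw, j, r.memptr(), w.memptr(),
                          -1, (double*)0, &fb);
    double c = arma::dot(w, Sraw) / arma::accu(w);
    S = Sraw - c;
    double intercept = beta(0) + c;

    eta = par + Sraw;            // = intercept + Z*gamma + S
    double dev = binom_dev(y, eta);

    if (dev < best.dev) {
      best.intercept = intercept;
      best.gamma = (p > 0) ? arma::vec(beta.subvec(1, p)) : arma::vec();
      best.S = S;
      best.r = r - c;            // smoothing (r - c) reproduces the centered S
      best.w = w;
      best.dev = dev;
      best.iter = it;
    }
    if (std::fabs(dev - dev_prev) / (0.1 + std::fabs(dev)) < tol) {
      *converged = true;
      break;
    }
    dev_prev = dev;
  }
  *niter = (it > maxit) ? maxit : it;
  *fallbacks = fb;
  return best;
}

// [[Rcpp::export]]
List gam_fit_cpp(const arma::mat& X, const arma::imat& idx,
                 const arma::mat& kw, const arma::vec& bw,
                 const arma::mat& Z, const arma::vec& y,
                 const arma::vec& beta0, int maxit, double tol,
                 bool want_hat) {
  bool conv = false;
  int niter = 0, fb = 0;
  GamState st = gam_fit_core(X, idx, kw, bw, Z, y, beta0, maxit, tol,
                             &conv, &niter, &fb);
  double trace = NA_REAL;
  if (want_hat) {
    arma::ivec self(X.n_rows);
    for (arma::uword i = 0; i < X.n_rows; ++i) self(i) = (int)i;
    trace = 0.0;
    int fb2 = 0;
    for (arma::uword j = 0; j < X.n_rows; ++j) {
      double hs = 0.0;
      local_fit(X, X, idx, kw, bw, (int)j, st.r.memptr(), st.w.memptr(),
                (int)j, &hs, &fb2);
      if (!ISNA(hs)) trace += hs;
    }
  }
  return List::create(
      _["intercept"] = st.intercept, _["gamma"] = st.gamma,
      _["S"] = st.S, _["r"] = st.r, _["w"] = st.w,
      _["deviance"] = st.dev, _["trace"] = trace,
      _["converged"] = conv, _["n_iter"] = niter,
      _["best_iter"] = st.iter, _["n_fallback"] = fb);
}

// Conditional permutation loop: rows of (y, Z) are permuted against fixed
// coordinates. Returns deviance statistics and (optionally) predicted
// log-odds surfaces on the grid at covariate reference zref.
// perm: n x B matrix of 0-based row permutations.
// [[Rcpp::export]]
List gam_perm_cpp(const arma::mat& X, const arma::imat& idx,
                  const arma::mat& kw, const arma::vec& bw,
                  const arma::mat& Z, const arma::vec& y,
                  const arma::vec& beta0, double dev_reduced,
                  const arma::imat& perm,
                  const arma::mat& G, const arma::imat& gidx,
                  const arma::mat& gkw, const arma::vec& gbw,
                  const arma::vec& zref, bool want_surfaces,
                  int maxit, double tol) {
  const int B = perm.n_cols, n = X.n_rows, p = Z.n_cols;
  const int mg = want_surfaces ? G.n_rows : 0;
  arma::vec stats(B);
  arma::mat surf(mg, B);
  int nonconv = 0;
  for (int b = 0; b < B; ++b) {
    arma::vec yb(n);
    arma::mat Zb(n, p);
    for (int i = 0; i < n; ++i) {
      int r = perm(i, b);
      yb(i) = y(r);
      if (p > 0) Zb.row(i) = Z.row(r);
    }
    bool conv = false;
    int niter = 0, fb = 0;
    GamState st = gam_fit_core(X, idx, kw, bw, Zb, yb, beta0, maxit, tol,
                               &conv, &niter, &fb);
    if (!conv) ++nonconv;
    stats(b) = dev_reduced - st.dev;
    if (want_surfaces) {
      double par = st.intercept + ((p > 0) ? arma::dot(st.gamma, zref) : 0.0);
      int fb2 = 0;
      for (int j = 0; j < mg; ++j) {
        double sg = local_fit(X, G, gidx, gkw, gbw, j,
                              st.r.memptr(), st.w.memptr(), -1, (double*)0, &fb2);
        surf(j, b) = ISNA(sg) ? NA_REAL : (par + sg);
      }
    }
    if (b % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["stats"] = stats, _["surfaces"] = surf,
                      _["n_nonconverged"] = nonconv);
}
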
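// SMO solvers for RBF-kernel C-SVC and nu-SVR, plus the searchlight
// grid-search cross-validation loop and SVR LOOCV/permutation loops.
//
// The solvers follow the standard libsvm formulation: second-order
// working-set selection (maximal violating pair with second-order
// tie-break), stopping tolerance 1e-3 on the duality gap, two-variable
// analytic update with box clipping.  Kernel matrices are precomputed:
// every problem solved here is tiny (n <= a few hundred subjects).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double TAU = 1e-12;

// ---------------------------------------------------------------------------
// C-SVC dual:  min 1/2 a'Qa - e'a,  0 <= a_i <= C,  y'a = 0,  Q = yy' o K.
// K is the kernel matrix over training points (column-major, n x n).
// Returns alpha and rho; decision f(x) = sum_i a_i y_i K(x_i, x) - rho.
// ---------------------------------------------------------------------------
struct SvcModel {
  std::vector<double> alpha;
  double rho;
};

static void smo_csvc(const double* K, int n, const signed char* y,
                     double C, double tol, SvcModel& out) {
  std::vector<double>& alpha = out.alpha;
  alpha.assign(n, 0.0);
  std::vector<double> G(n, -1.0);  // gradient of dual objective
  const long max_iter = std::max(10000000L, 100L * (long)n);
  long iter = 0;

  while (iter++ < max_iter) {
    // working-set selection (libsvm WSS2)
    double Gmax = -std::numeric_limits<double>::infinity();
    double Gmin =  std::numeric_limits<double>::infinity();
    int i = -1;
    for (int t = 0; t < n; ++t) {
      if ((y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0)) {
        double v = -y[t] * G[t];
        if (v >= Gmax) { Gmax = v; i = t; }
      }
    }
    int j = -1;
    double obj_min = std::numeric_limits<double>::infinity();
    const double* Ki = K + (size_t)i * n;
    for (int t = 0; t < n; ++t) {
      if ((y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C)) {
        double v = -y[t] * G[t];
        if (v < Gmin) Gmin = v;
        double grad_diff = Gmax - v;
        if (grad_diff > 0) {
          double quad = K[(size_t)i * n + i] + K[(size_t)t * n + t] - 2.0 * Ki[t];
          if (quad <= 0) quad = TAU;
          double obj = -(grad_diff * grad_diff) / quad;
          if (obj <= obj_min) { obj_min = obj; j = t; }
        }
      }
    }
    if (Gmax - Gmin < tol || j == -1) break;

    const double* Kj = K + (size_t)j * n;
    double quad = Ki[i] + Kj[j] - 2.0 * Ki[j];
    if (quad <= 0) quad = TAU;
    double old_ai = alpha[i], old_aj = alpha[j];

    if (y[i] != y[j]) {
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; } }
      else          { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; } }
      if (diff > 0) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; } }
      else          { if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; } }
    } else {
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; } }
      else         { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; } }
      if (sum > C) { if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; } }
      else         { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; } }
    }
    double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    for (int t = 0; t < n; ++t)
      G[t] += (y[t] * y[i] * Ki[t]) * dai + (y[t] * y[j] * Kj[t]) * daj;
  }

  // rho
  double ub = std::numeric_limits<double>::infinity();
  double lb = -std::numeric_limits<double>::infinity();
  double sum_free = 0; int nr_free = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    bool upper = alpha[t] >= C - 1e-12, lower = alpha[t] <= 1e-12;
    if (upper)      { if (y[t] == -1) ub = std::min(ub, yG); else lb = std::max(lb, yG); }
    else if (lower) { if (y[t] == 1)  ub = std::min(ub, yG); else lb = std::max(lb, yG); }
    else { ++nr_free; sum_free += yG; }
  }
  out.rho = nr_free > 0 ? sum_free / nr_free : (ub + lb) / 2.0;
}

// squared euclidean distances between rows of A (na x d) and B (nb x d),
// written into D (na x nb, column-major: D[i + na*j])
static void sqdist(const std::vector<double>& A, int na,
                   const std::vector<double>& B, int nb, int d,
                   std::vector<double>& D) {
  D.assign((size_t)na * nb, 0.0);
  for (int j = 0; j < nb; ++j)
    for (int i = 0; i < na; ++i) {
      double s = 0;
      const double* a = &A[(size_t)i * d];
      const double* b = &B[(size_t)j * d];
      for (int k = 0; k < d; ++k) { double u = a[k] - b[k]; s += u * u; }
      D[(size_t)j * na + i] = s;
    }
}

// ---------------------------------------------------------------------------
// M-fold grid-search CV of the RBF C-SVC over (C, gamma).
// X: n x d feature matrix; y in {-1, +1}; fold in 0..M-1 (fixed assignment);
// features are z-scored with training-fold statistics when standardize=TRUE
// (zero-variance training columns map to 0).
// Returns the matrix of correct-prediction counts (nC x nGamma) aggregated
// over all folds: CV accuracy = correct / n.
// ---------------------------------------------------------------------------
static void grid_cv_counts(const double* X, int n, int d,
                           const signed char* y, const int* fold, int M,
                           const std::vector<double>& Cg,
                           const std::vector<double>& Gg,
                           bool standardize, double tol,
                           std::vector<int>& correct) {
  size_t nC = Cg.size(), nG = Gg.size();
  correct.assign(nC * nG, 0);
  std::vector<double> Xtr, Xte, Dtr, Dte, Ktr, Kte;
  std::vector<signed char> ytr;
  std::vector<int> te_idx;
  SvcModel mod;

  for (int f = 0; f < M; ++f) {
    int ntr = 0, nte = 0;
    for (int t = 0; t < n; ++t) (fold[t] == f ? nte : ntr)++;
    if (nte == 0) continue;
    Xtr.assign((size_t)ntr * d, 0.0);
    Xte.assign((size_t)nte * d, 0.0);
    ytr.assign(ntr, 0);
    te_idx.assign(nte, 0);
    int a = 0, b = 0;
    for (int t = 0; t < n; ++t) {
      if (fold[t] == f) {
        for (int k = 0; k < d; ++k) Xte[(size_t)b * d + k] = X[(size_t)k * n + t];
        te_idx[b++] = t;
      } else {
        for (int k = 0; k < d; ++k) Xtr[(size_t)a * d + k] = X[(size_t)k * n + t];
        ytr[a++] = y[t];
      }
    }
    if (standardize) {
      for (int k = 0; k < d; ++k) {
        double m = 0, s2 = 0;
        for (int t = 0; t < ntr; ++t) m += Xtr[(size_t)t * d + k];
        m /= ntr;
        for (int t = 0; t < ntr; ++t) { double u = Xtr[(size_t)t * d + k] - m; s2 += u * u; }
        double sd = ntr > 1 ? std::sqrt(s2 / (ntr - 1)) : 0.0;
        if (sd < 1e-12) {
          for (int t = 0; t < ntr; ++t) Xtr[(size_t)t * d + k] = 0.0;
          for (int t = 0; t < nte; ++t) Xte[(size_t)t * d + k] = 0.0;
        } else {
          for (int t = 0; t < ntr; ++t) Xtr[(size_t)t * d + k] = (Xtr[(size_t)t * d + k] - m) / sd;
          for (int t = 0; t < nte; ++t) Xte[(size_t)t * d + k] = (Xte[(size_t)t * d + k] - m) / sd;
        }
      }
    }
    sqdist(Xtr, ntr, Xtr, ntr, d, Dtr);
    sqdist(Xte, nte, Xtr, ntr, d, Dte);

    for (size_t g = 0; g < nG; ++g) {
      double gamma = Gg[g];
      Ktr.resize(Dtr.size()); Kte.resize(Dte.size());
      for (size_t t = 0; t < Dtr.size(); ++t) Ktr[t] = std::exp(-gamma * Dtr[t]);
      for (size_t t = 0; t < Dte.size(); ++t) Kte[t] = std::exp(-gamma * Dte[t]);
      for (size_t c = 0; c < nC; ++c) {
        smo_csvc(Ktr.data(), ntr, ytr.data(), Cg[c], tol, mod);
        for (int t = 0; t < nte; ++t) {
          double dec = -mod.rho;
          for (int s = 0; s < ntr; ++s)
            dec += mod.alpha[s] * ytr[s] * Kte[(size_t)s * nte + t];
          int pred = dec > 0 ? 1 : -1;
          if (pred == y[te_idx[t]]) correct[g * nC + c]++;
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".svm_grid_cv_cpp")]]
List svm_grid_cv_cpp(NumericMatrix X, IntegerVector y, IntegerVector fold,
                     int M, NumericVector C_grid, NumericVector gamma_grid,
                     bool standardize = true, double tol = 1e-3) {
  int n = X.nrow(), d = X.ncol();
  std::vector<signed char> ys(n);
  for (int i = 0; i < n; ++i) ys[i] = (signed char)y[i];
  std::vector<double> Cg(C_grid.begin(), C_grid.end());
  std::vector<double> Gg(gamma_grid.begin(), gamma_grid.end());
  std::vector<int> correct;
  grid_cv_counts(REAL(X), n, d, ys.data(), INTEGER(fold), M, Cg, Gg,
                 standardize, tol, correct);
  IntegerMatrix out(Cg.size(), Gg.size());
  for (size_t g = 0; g < Gg.size(); ++g)
    for (size_t c = 0; c < Cg.size(); ++c)
      out(c, g) = correct[g * Cg.size() + c];
  return List::create(_["correct"] = out, _["n"] = n);
}

// Single C-SVC fit + decision values, for oracle cross-checks against libsvm.
// [[Rcpp::export(name = ".svc_fit_decision_cpp")]]
NumericVector svc_fit_decision_cpp(NumericMatrix Xtr, IntegerVector ytr,
                                   NumericMatrix Xte, double C, double gamma,
                                   double tol = 1e-3) {
  int ntr = Xtr.nrow(), d = Xtr.ncol(), nte = Xte.nrow();
  std::vector<double> A((size_t)ntr * d), B((size_t)nte * d), Dtr, Dte;
  for (int i = 0; i < ntr; ++i)
    for (int k = 0; k < d; ++k) A[(size_t)i * d + k] = Xtr(i, k);
  for (int i = 0; i < nte; ++i)
    for (int k = 0; k < d; ++k) B[(size_t)i * d + k] = Xte(i, k);
  sqdist(A, ntr, A, ntr, d, Dtr);
  sqdist(B, nte, A, ntr, d, Dte);
  std::vector<double> K(Dtr.size()), Kt(Dte.size());
  for (size_t t = 0; t < Dtr.size(); ++t) K[t] = std::exp(-gamma * Dtr[t]);
  for (size_t t = 0; t < Dte.size(); ++t) Kt[t] = std::exp(-gamma * Dte[t]);
  std::vector<signed char> ys(ntr);
  for (int i = 0; i < ntr; ++i) ys[i] = (signed char)ytr[i];
  SvcModel mod;
  smo_csvc(K.data(), ntr, ys.data(), C, tol, mod);
  NumericVector dec(nte);
  for (int t = 0; t < nte; ++t) {
    double s = -mod.rho;
    for (int i = 0; i < ntr; ++i) s += mod.alpha[i] * ys[i] * Kt[(size_t)i * nte + t];
    dec[t] = s;
  }
  return dec;
}

// ---------------------------------------------------------------------------
// Full searchlight loop: at every in-mask voxel with enough in-mask
// neighbors, extract the neighborhood pattern (zero-padded to fixed length),
// run the M-fold grid-search CV, and record CA = total correct / n plus the
// selected (C, gamma) (ties broken toward smallest C, then smallest gamma).
// vol: V x n matrix of voxel values (V = prod(dims)); mask: length-V 0/1;
// offsets: k x 3 integer voxel offsets defining the neighborhood.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".searchlight_cpp")]]
List searchlight_cpp(NumericMatrix vol, IntegerVector dims, IntegerVector mask,
                     IntegerMatrix offsets, IntegerVector y, IntegerVector fold,
                     int M, NumericVector C_grid, NumericVector gamma_grid,
                     int min_in_mask, bool standardize = true, double tol = 1e-3) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int V = nx * ny * nz, n = vol.ncol(), k = offsets.nrow();
  std::vector<double> Cg(C_grid.begin(), C_grid.end());
  std::vector<double> Gg(gamma_grid.begin(), gamma_grid.end());
  size_t nC = Cg.size(), nG = Gg.size();

  NumericVector ca(V, NA_REAL), bestC(V, NA_REAL), bestG(V, NA_REAL);
  IntegerVector nneigh(V, NA_INTEGER);
  std::vector<signed char> ys(n);
  for (int i = 0; i < n; ++i) ys[i] = (signed char)y[i];

  std::vector<double> feat((size_t)n * k);  // column-major n x k
  std::vector<int> correct;
  int checked = 0;

  for (int z = 0; z < nz; ++z)
    for (int yy = 0; yy < ny; ++yy)
      for (int x = 0; x < nx; ++x) {
        int v = x + nx * (yy + ny * z);
        if (!mask[v]) continue;
        if (++checked % 256 == 0) Rcpp::checkUserInterrupt();
        int nin = 0;
        for (int o = 0; o < k; ++o) {
          int xo = x + offsets(o, 0), yo = yy + offsets(o, 1), zo = z + offsets(o, 2);
          bool in = xo >= 0 && xo < nx && yo >= 0 && yo < ny && zo >= 0 && zo < nz;
          int vo = in ? xo + nx * (yo + ny * zo) : -1;
          if (in && mask[vo]) {
            ++nin;
            for (int s = 0; s < n; ++s) feat[(size_t)o * n + s] = vol(vo, s);
          } else {
            for (int s = 0; s < n; ++s) feat[(size_t)o * n + s] = 0.0;
          }
        }
        nneigh[v] = nin;
        if (nin < min_in_mask) continue;  // skipped (recorded via nneigh)
        grid_cv_counts(feat.data(), n, k, ys.data(), INTEGER(fold), M,
                       Cg, Gg, standardize, tol, correct);
        int best = -1; size_t bc = 0, bg = 0;
        for (size_t c = 0; c < nC; ++c)
          for (size_t g = 0; g < nG; ++g)
            if (correct[g * nC + c] > best) { best = correct[g * nC + c]; bc = c; bg = g; }
        ca[v] = (double)best / n;
        bestC[v] = Cg[bc];
        bestG[v] = Gg[bg];
      }
  return List::create(_["ca"] = ca, _["bestC"] = bestC, _["bestG"] = bestG,
                      _["n_in_mask"] = nneigh);
}

// ---------------------------------------------------------------------------
// nu-SVR (libsvm Solver_NU formulation on 2l variables).
// Dual variables a = (alpha, alpha*); Q = ss' o Khat, s = (+1...,-1...),
// p = (-y, +y); 0 <= a <= C; working-set pairs are same-sign.
// Decision f(x) = sum_i (alpha_i - alpha*_i) K(x_i, x) + b, b = -rho.
// ---------------------------------------------------------------------------
struct SvrModel {
  std::vector<double> beta;  // alpha - alpha*
  double b;
};

static void smo_nusvr(const double* K, int l, const double* yv,
                      double C, double nu, double tol, SvrModel& out) {
  int n2 = 2 * l;
  std::vector<double> alpha(n2), p(n2);
  std::vector<signed char> s(n2);
  double sum = C * nu * l / 2.0;
  for (int i = 0; i < l; ++i) {
    alpha[i] = alpha[i + l] = std::min(sum, C);
    sum -= alpha[i];
    p[i] = -yv[i]; s[i] = 1;
    p[i + l] = yv[i]; s[i + l] = -1;
  }
  // Q entry accessor: Q[i][j] = s_i s_j K[(i%l) + l*(j%l)]
  auto Q = [&](int i, int j) -> double {
    return (double)(s[i] * s[j]) * K[(size_t)(j % l) * l + (i % l)];
  };
  std::vector<double> G(n2, 0.0);
  for (int i = 0; i < n2; ++i) {
    G[i] = p[i];
    for (int j = 0; j < n2; ++j)
      if (alpha[j] > 0) G[i] += Q(i, j) * alpha[j];
  }
  const long max_iter = std::max(10000000L, 100L * (long)n2);
  long iter = 0;
  while (iter++ < max_iter) {
    double Gmaxp = -std::numeric_limits<double>::infinity();
    double Gmaxp2 = Gmaxp, Gmaxn = Gmaxp, Gmaxn2 = Gmaxp;
    int ip = -1, in = -1;
    for (int t = 0; t < n2; ++t) {
      if (s[t] == 1) {
        if (alpha[t] < C && -G[t] >= Gmaxp) { Gmaxp = -G[t]; ip = t; }
      } else {
        if (alpha[t] > 0 && G[t] >= Gmaxn) { Gmaxn = G[t]; in = t; }
      }
    }
    int j = -1; bool j_pos = true;
    double obj_min = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n2; ++t) {
      if (s[t] == 1) {
        if (alpha[t] > 0) {
          double grad_diff = Gmaxp + G[t];
          if (G[t] >= Gmaxp2) Gmaxp2 = G[t];
          if (grad_diff > 0 && ip >= 0) {
            double quad = Q(ip, ip) + Q(t, t) - 2.0 * Q(ip, t);
            if (quad <= 0) quad = TAU;
            double obj = -(grad_diff * grad_diff) / quad;
            if (obj <= obj_min) { obj_min = obj; j = t; j_pos = true; }
          }
        }
      } else {
        if (alpha[t] < C) {
          double grad_diff = Gmaxn - G[t];
          if (-G[t] >= Gmaxn2) Gmaxn2 = -G[t];
          if (grad_diff > 0 && in >= 0) {
            double quad = Q(in, in) + Q(t, t) - 2.0 * Q(in, t);
            if (quad <= 0) quad = TAU;
            double obj = -(grad_diff * grad_diff) / quad;
            if (obj <= obj_min) { obj_min = obj; j = t; j_pos = false; }
          }
        }
      }
    }
    if (std::max(Gmaxp + Gmaxp2, Gmaxn + Gmaxn2) < tol || j == -1) break;
    int i = j_pos ? ip : in;
    // same-sign two-variable update
    double quad = Q(i, i) + Q(j, j) - 2.0 * Q(i, j);
    if (quad <= 0) quad = TAU;
    double old_ai = alpha[i], old_aj = alpha[j];
    double delta = (G[i] - G[j]) / quad;
    double sij = alpha[i] + alpha[j];
    alpha[i] -= delta; alpha[j] += delta;
    if (sij > C) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = sij - C; } }
    else         { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sij; } }
    if (sij > C) { if (alpha[j] > C) { alpha[j] = C; alpha[i] = sij - C; } }
    else         { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sij; } }
    double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    for (int t = 0; t < n2; ++t) G[t] += Q(t, i) * dai + Q(t, j) * daj;
  }
  // rho for the nu solver: separate free-variable averages per sign class
  double ub1 = std::numeric_limits<double>::infinity(), ub2 = ub1;
  double lb1 = -ub1, lb2 = -ub1;
  double sf1 = 0, sf2 = 0; int nf1 = 0, nf2 = 0;
  for (int t = 0; t < n2; ++t) {
    bool upper = alpha[t] >= C - 1e-12, lower = alpha[t] <= 1e-12;
    if (s[t] == 1) {
      if (upper) lb1 = std::max(lb1, G[t]);
      else if (lower) ub1 = std::min(ub1, G[t]);
      else { ++nf1; sf1 += G[t]; }
    } else {
      if (upper) lb2 = std::max(lb2, G[t]);
      else if (lower) ub2 = std::min(ub2, G[t]);
      else { ++nf2; sf2 += G[t]; }
    }
  }
  double r1 = nf1 > 0 ? sf1 / nf1 : (ub1 + lb1) / 2.0;
  double r2 = nf2 > 0 ? sf2 / nf2 : (ub2 + lb2) / 2.0;
  double rho = (r1 - r2) / 2.0;
  out.beta.assign(l, 0.0);
  for (int i = 0; i < l; ++i) out.beta[i] = alpha[i] - alpha[i + l];
  out.b = -rho;
}

// Single nu-SVR fit + predictions, for cross-checks against libsvm.
// [[Rcpp::export(name = ".nusvr_fit_predict_cpp")]]
NumericVector nusvr_fit_predict_cpp(NumericMatrix Xtr, NumericVector ytr,
                                    NumericMatrix Xte, double C, double nu,
                                    double gamma, double tol = 1e-3) {
  int ntr = Xtr.nrow(), d = Xtr.ncol(), nte = Xte.nrow();
  std::vector<double> A((size_t)ntr * d), B((size_t)nte * d), Dtr, Dte;
  for (int i = 0; i < ntr; ++i)
    for (int k = 0; k < d; ++k) A[(size_t)i * d + k] = Xtr(i, k);
  for (int i = 0; i < nte; ++i)
    for (int k = 0; k < d; ++k) B[(size_t)i * d + k] = Xte(i, k);
  sqdist(A, ntr, A, ntr, d, Dtr);
  sqdist(B, nte, A, ntr, d, Dte);
  std::vector<double> K(Dtr.size()), Kt(Dte.size());
  for (size_t t = 0; t < Dtr.size(); ++t) K[t] = std::exp(-gamma * Dtr[t]);
  for (size_t t = 0; t < Dte.size(); ++t) Kt[t] = std::exp(-gamma * Dte[t]);
  SvrModel mod;
  smo_nusvr(K.data(), ntr, REAL(ytr), C, nu, tol, mod);
  NumericVector pred(nte);
  for (int t = 0; t < nte; ++t) {
    double sum = mod.b;
    for (int i = 0; i < ntr; ++i) sum += mod.beta[i] * Kt[(size_t)i * nte + t];
    pred[t] = sum;
  }
  return pred;
}

// ---------------------------------------------------------------------------
// LOOCV nu-SVR predictions for one feature set and a matrix of score vectors
// (columns: observed scores and/or permuted surrogates).  The full kernel is
// computed once; each leave-one-out fit indexes into it.
// Returns an n x ncol(Y) matrix of held-out predictions.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".svr_loocv_multi_cpp")]]
NumericMatrix svr_loocv_multi_cpp(NumericMatrix X, NumericMatrix Y,
                                  double C, double nu, double gamma,
                                  double tol = 1e-3) {
  int n = X.nrow(), d = X.ncol(), m = Y.ncol();
  std::vector<double> A((size_t)n * d), D;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) A[(size_t)i * d + k] = X(i, k);
  sqdist(A, n, A, n, d, D);
  std::vector<double> K((size_t)n * n);
  for (size_t t = 0; t < D.size(); ++t) K[t] = std::exp(-gamma * D[t]);

  NumericMatrix pred(n, m);
  int l = n - 1;
  std::vector<double> Ktr((size_t)l * l), Kte(l), ytr(l);
  SvrModel mod;
  for (int col = 0; col < m; ++col) {
    Rcpp::checkUserInterrupt();
    for (int held = 0; held < n; ++held) {
      int a = 0;
      for (int i = 0; i < n; ++i) {
        if (i == held) continue;
        int b = 0;
        for (int j = 0; j < n; ++j) {
          if (j == held) continue;
          Ktr[(size_t)b * l + a] = K[(size_t)j * n + i];
          ++b;
        }
        Kte[a] = K[(size_t)held * n + i];
        ytr[a] = Y(i, col);
        ++a;
      }
      smo_nusvr(Ktr.data(), l, ytr.data(), C, nu, tol, mod);
      double s = mod.b;
      for (int i = 0; i < l; ++i) s += mod.beta[i] * Kte[i];
      pred(held, col) = s;
    }
  }
  return pred;
}
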
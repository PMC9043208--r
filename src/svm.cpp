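#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Kernels: 0 = linear, 1 = polynomial (gamma * <x,z> + coef0)^degree, 2 = RBF.
static inline double kernel_eval(const double* xi, const double* xj, int d,
                                 int kernel, double gamma, double coef0,
                                 int degree) {
  if (kernel == 2) {
    double s = 0.0;
    for (int k = 0; k < d; ++k) { const double diff = xi[k] - xj[k]; s += diff * diff; }
    return std::exp(-gamma * s);
  }
  double dot = 0.0;
  for (int k = 0; k < d; ++k) dot += xi[k] * xj[k];
  if (kernel == 0) return dot;
  return std::pow(gamma * dot + coef0, (double)degree);
}

struct SMO {
  const NumericMatrix& X;   // n x d, row-major access via column pointers
  const NumericVector& y;   // +1 / -1
  int n, d, kernel, degree;
  double C, gamma, coef0, tol, eps;
  std::vector<double> alpha, E, b_holder, xrow;
  std::vector<std::vector<double> > Xr; // row copies for cache-friendly kernels
  std::vector<double> Kdiag;
  std::vector<double> Kfull; // dense kernel matrix when n is moderate
  bool cached;
  double b;
  long steps;

  SMO(const NumericMatrix& X_, const NumericVector& y_, double C_, int kernel_,
      double gamma_, double coef0_, int degree_, double tol_)
    : X(X_), y(y_), n(X_.nrow()), d(X_.ncol()), kernel(kernel_),
      degree(degree_), C(C_), gamma(gamma_), coef0(coef0_), tol(tol_),
      eps(1e-3), alpha(n, 0.0), E(n), b(0.0), steps(0) {
    Xr.assign(n, std::vector<double>(d));
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < d; ++k) Xr[i][k] = X(i, k);
    Kdiag.resize(n);
    for (int i = 0; i < n; ++i)
      Kdiag[i] = kernel_eval(&Xr[i][0], &Xr[i][0], d, kernel, gamma, coef0, degree);
    for (int i = 0; i < n; ++i) E[i] = -y[i]; // f = 0 initially
    // the error-cache update touches a full kernel row per step, so a dense
    // precomputed matrix pays for itself immediately (64 MB cap)
    cached = (double)n * n * 8.0 <= 64.0 * 1024 * 1024;
    if (cached) {
      Kfull.resize((size_t)n * n);
      for (int i = 0; i < n; ++i) {
        Kfull[(size_t)i * n + i] = Kdiag[i];
        for (int j = i + 1; j < n; ++j) {
          const double v = kernel_eval(&Xr[i][0], &Xr[j][0], d, kernel,
                                       gamma, coef0, degree);
          Kfull[(size_t)i * n + j] = v;
          Kfull[(size_t)j * n + i] = v;
        }
      }
    }
  }

  inline double kij(int i, int j) const {
    if (cached) return Kfull[(size_t)i * n + j];
    return kernel_eval(&Xr[i][0], &Xr[j][0], d, kernel, gamma, coef0, degree);
  }

  bool takeStep(int i1, int i2) {
    if (i1 == i2) return false;
    const double a1 = alpha[i1], a2 = alpha[i2];
    const double y1 = y[i1], y2 = y[i2];
    const double E1 = E[i1], E2 = E[i2];
    const double s = y1 * y2;
    double L, H;
    if (s < 0) { L = std::max(0.0, a2 - a1); H = std::min(C, C + a2 - a1); }
    else       { L = std::max(0.0, a2 + a1 - C); H = std::min(C, a2 + a1); }
    if (L >= H) return false;
    const double k11 = Kdiag[i1], k22 = Kdiag[i2], k12 = kij(i1, i2);
    const double eta = k11 + k22 - 2.0 * k12;
    double a2new;
    if (eta > 0) {
      a2new = a2 + y2 * (E1 - E2) / eta;
      if (a2new < L) a2new = L; else if (a2new > H) a2new = H;
    } else {
      // Objective at the clip bounds (rare: duplicate points).
      const double f1 = y1 * (E1 + b) - a1 * k11 - s * a2 * k12;
      const double f2 = y2 * (E2 + b) - s * a1 * k12 - a2 * k22;
      const double L1 = a1 + s * (a2 - L), H1 = a1 + s * (a2 - H);
      const double objL = L1 * f1 + L * f2 + 0.5 * L1 * L1 * k11 +
        0.5 * L * L * k22 + s * L * L1 * k12;
      const double objH = H1 * f1 + H * f2 + 0.5 * H1 * H1 * k11 +
        0.5 * H * H * k22 + s * H * H1 * k12;
      if (objL < objH - eps) a2new = L;
      else if (objL > objH + eps) a2new = H;
      else a2new = a2;
    }
    if (std::fabs(a2new - a2) < eps * (a2new + a2 + eps)) return false;
    const double a1new = a1 + s * (a2 - a2new);
    const double b1 = E1 + y1 * (a1new - a1) * k11 + y2 * (a2new - a2) * k12 + b;
    const double b2 = E2 + y1 * (a1new - a1) * k12 + y2 * (a2new - a2) * k22 + b;
    double bnew;
    if (a1new > 0 && a1new < C) bnew = b1;
    else if (a2new > 0 && a2new < C) bnew = b2;
    else bnew = 0.5 * (b1 + b2);
    const double db = bnew - b;
    b = bnew;
    alpha[i1] = a1new; alpha[i2] = a2new;
    const double d1 = y1 * (a1new - a1), d2 = y2 * (a2new - a2);
    if (cached) {
      const double* r1 = &Kfull[(size_t)i1 * n];
      const double* r2 = &Kfull[(size_t)i2 * n];
      for (int i = 0; i < n; ++i) E[i] += d1 * r1[i] + d2 * r2[i] - db;
    } else {
      for (int i = 0; i < n; ++i)
        E[i] += d1 * kij(i1, i) + d2 * kij(i2, i) - db;
    }
    ++steps;
    return true;
  }

  int examineExample(int i2) {
    const double y2 = y[i2], a2 = alpha[i2], E2 = E[i2];
    const double r2 = E2 * y2;
    if ((r2 < -tol && a2 < C) || (r2 > tol && a2 > 0)) {
      // heuristic 1: maximise |E1 - E2| over non-bound multipliers
      int best = -1; double bestGap = -1.0;
      for (int i = 0; i < n; ++i) {
        if (alpha[i] > 0 && alpha[i] < C) {
          const double gap = std::fabs(E[i] - E2);
          if (gap > bestGap) { bestGap = gap; best = i; }
        }
      }
      if (best >= 0 && takeStep(best, i2)) return 1;
      // heuristic 2: all non-bound, deterministic start offset; attempts
      // are capped so one stuck example cannot burn a full O(n) scan
      const int cap_try = n < 256 ? n : 256;
      int tried = 0;
      for (int k = 0; k < n && tried < cap_try; ++k) {
        const int i = (i2 + 1 + k) % n;
        if (alpha[i] > 0 && alpha[i] < C) {
          ++tried;
          if (takeStep(i, i2)) return 1;
        }
      }
      tried = 0;
      for (int k = 0; k < n && tried < cap_try; ++k) {
        const int i = (i2 + 1 + k) % n;
        ++tried;
        if (takeStep(i, i2)) return 1;
      }
    }
    return 0;
  }

  void solve(long max_steps) {
    int numChanged = 0;
    bool examineAll = true;
    while ((numChanged > 0 || examineAll) && steps < max_steps) {
      numChanged = 0;
      if (examineAll) {
        for (int i = 0; i < n && steps < max_steps; ++i)
          numChanged += examineExample(i);
      } else {
        for (int i = 0; i < n && steps < max_steps; ++i)
          if (alpha[i] > 0 && alpha[i] < C) numChanged += examineExample(i);
      }
      if (examineAll) examineAll = false;
      else if (numChanged == 0) examineAll = true;
    }
  }
};

// Train a soft-margin SVM by sequential minimal optimisation.
// y must be +1/-1. Returns alpha, bias b (decision f(x) = sum_i alpha_i y_i
// K(x_i, x) - b is NOT used; convention here is f(x) = sum - b with the
// returned b, matching the E = f - y bookkeeping above).
// [[Rcpp::export(name = ".svm_smo_cpp")]]
List svm_smo_cpp(NumericMatrix X, NumericVector y, double C, int kernel,
                 double gamma, double coef0, int degree, double tol) {
  if (X.nrow() != y.size()) stop("X and y size mismatch");
  SMO smo(X, y, C, kernel, gamma, coef0, degree, tol);
  smo.solve(80L * (long)X.nrow());
  return List::create(_["alpha"] = NumericVector(smo.alpha.begin(), smo.alpha.end()),
                      _["b"] = smo.b,
                      _["steps"] = (double)smo.steps);
}

// Decision values f(x) = sum_i alpha_i y_i K(x_i, x) - b for new rows.
// [[Rcpp::export(name = ".svm_decision_cpp")]]
NumericVector svm_decision_cpp(NumericMatrix Xtrain, NumericVector y,
                               NumericVector alpha, double b,
                               NumericMatrix Xnew, int kernel, double gamma,
                               double coef0, int degree) {
  const int n = Xtrain.nrow(), m = Xnew.nrow(), d = Xtrain.ncol();
  if (Xnew.ncol() != d) stop("feature dimension mismatch");
  std::vector<std::vector<double> > Xr(n, std::vector<double>(d));
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) Xr[i][k] = Xtrain(i, k);
  NumericVector out(m);
  std::vector<double> xnew(d);
  for (int j = 0; j < m; ++j) {
    for (int k = 0; k < d; ++k) xnew[k] = Xnew(j, k);
    double f = -b;
    for (int i = 0; i < n; ++i) {
      if (alpha[i] == 0.0) continue;
      f += alpha[i] * y[i] *
        kernel_eval(&Xr[i][0], &xnew[0], d, kernel, gamma, coef0, degree);
    }
    out[j] = f;
  }
  return out;
}
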
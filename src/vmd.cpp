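#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef std::complex<double> cplx;

// Naive DFT / inverse DFT. Inputs here are short (mirrored QRS segments,
// a few hundred samples), so O(n^2) is cheaper than pulling in an FFT
// dependency and keeps the ADMM loop self-contained.
static std::vector<cplx> dft(const std::vector<cplx>& x, bool inverse) {
  const int n = (int)x.size();
  std::vector<cplx> out(n);
  const double sgn = inverse ? 1.0 : -1.0;
  for (int k = 0; k < n; ++k) {
    cplx acc(0.0, 0.0);
    for (int t = 0; t < n; ++t) {
      const double ang = sgn * 2.0 * M_PI * (double)k * (double)t / (double)n;
      acc += x[t] * cplx(std::cos(ang), std::sin(ang));
    }
    out[k] = inverse ? acc / (double)n : acc;
  }
  return out;
}

// Variational mode decomposition by ADMM in the frequency domain
// (Dragomiretskiy & Zosso scheme): Wiener-filter mode updates, centre
// frequencies as power-weighted mean frequencies, optional dual ascent.
// Centre frequencies are initialised uniformly over (0, 0.5) so the
// decomposition is deterministic.
//
// Returns a list: modes (K x T matrix, rows are modes in update order),
// omega (normalised centre frequencies, cycles/sample), n_iter, converged.
// [[Rcpp::export(name = ".vmd_cpp")]]
List vmd_cpp(NumericVector signal, int K, double alpha, double tau,
             double tol, int max_iter) {
  const int T0 = signal.size();
  if (T0 < 4) stop("signal too short for VMD");
  if (K < 1) stop("K must be >= 1");

  // Mirror extension: half the signal reflected on each side.
  const int half = T0 / 2;
  const int T = T0 + 2 * half;
  std::vector<cplx> f(T);
  for (int i = 0; i < half; ++i) f[i] = cplx(signal[half - 1 - i], 0.0);
  for (int i = 0; i < T0; ++i) f[half + i] = cplx(signal[i], 0.0);
  for (int i = 0; i < half; ++i) f[half + T0 + i] = cplx(signal[T0 - 1 - i], 0.0);

  std::vector<cplx> f_hat = dft(f, false);
  // One-sided (analytic) spectrum: zero the negative frequencies.
  // Frequency of bin k: k/T for k <= T/2, k/T - 1 above.
  std::vector<double> freqs(T);
  for (int k = 0; k < T; ++k) {
    double fr = (double)k / (double)T;
    if (fr > 0.5) fr -= 1.0;
    freqs[k] = fr;
    if (fr < 0.0) f_hat[k] = cplx(0.0, 0.0);
  }

  std::vector<std::vector<cplx> > u_hat(K, std::vector<cplx>(T, cplx(0.0, 0.0)));
  std::vector<std::vector<cplx> > u_hat_prev(K, std::vector<cplx>(T, cplx(0.0, 0.0)));
  std::vector<cplx> lambda_hat(T, cplx(0.0, 0.0));
  std::vector<double> omega(K);
  for (int k = 0; k < K; ++k) omega[k] = 0.5 * ((double)k + 0.5) / (double)K;

  std::vector<cplx> sum_u(T, cplx(0.0, 0.0));
  int iter = 0;
  bool converged = false;
  for (iter = 0; iter < max_iter; ++iter) {
    for (int k = 0; k < K; ++k) u_hat_prev[k] = u_hat[k];
    for (int k = 0; k < K; ++k) {
      // sum of all other modes
      for (int t = 0; t < T; ++t) {
        sum_u[t] = cplx(0.0, 0.0);
        for (int j = 0; j < K; ++j) if (j != k) sum_u[t] += u_hat[j][t];
      }
      double num = 0.0, den = 0.0;
      for (int t = 0; t < T; ++t) {
        const double d = freqs[t] - omega[k];
        const cplx val = (f_hat[t] - sum_u[t] + lambda_hat[t] * 0.5) /
                         (1.0 + 2.0 * alpha * d * d);
        u_hat[k][t] = val;
        if (freqs[t] >= 0.0) {
          const double p = std::norm(val);
          num += freqs[t] * p;
          den += p;
        }
      }
      if (den > 0.0) omega[k] = num / den;
    }
    if (tau != 0.0) {
      for (int t = 0; t < T; ++t) {
        cplx s(0.0, 0.0);
        for (int k = 0; k < K; ++k) s += u_hat[k][t];
        lambda_hat[t] += tau * (f_hat[t] - s);
      }
    }
    double diff = 0.0, denom = 0.0;
    for (int k = 0; k < K; ++k)
      for (int t = 0; t < T; ++t) {
        diff += std::norm(u_hat[k][t] - u_hat_prev[k][t]);
        denom += std::norm(u_hat_prev[k][t]);
      }
    if (denom > 0.0 && diff / denom < tol) { converged = true; ++iter; break; }
  }

  // Back to time domain: hermitian-symmetrise the one-sided spectrum so the
  // reconstruction is real, then crop the mirror extension.
  NumericMatrix modes(K, T0);
  for (int k = 0; k < K; ++k) {
    std::vector<cplx> spec(T, cplx(0.0, 0.0));
    for (int t = 0; t < T; ++t) {
      if (freqs[t] > 0.0) {
        spec[t] = u_hat[k][t];
        spec[(T - t) % T] = std::conj(u_hat[k][t]);
      } else if (freqs[t] == 0.0) {
        spec[t] = cplx(u_hat[k][t].real(), 0.0);
      }
    }
    std::vector<cplx> u = dft(spec, true);
    for (int i = 0; i < T0; ++i) modes(k, i) = u[half + i].real();
  }

  return List::create(_["modes"] = modes,
                      _["omega"] = NumericVector(omega.begin(), omega.end()),
                      _["n_iter"] = iter,
                      _["converged"] = converged);
}
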
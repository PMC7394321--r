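#include <Rcpp.h>
using namespace Rcpp;

// Extended Lander-Waterman expected spectrum and variance weights.
//
// For genotype i with relative abundance f[i], the probability that a read
// from it is "recruited" (overlaps the next read by at least o) is
//   p_i = 1 - exp(-(r - o) * f_i * R / L).
// The expected number of reads in contigs of exactly q reads is
//   E_q = sum_i f_i * R * q * p_i^(q-1) * (1 - p_i)^2,
// and its variance
//   V2_q = sum_i f_i * R * q * p_i^(q-1) * (1 - p_i)^2 *
//          (1 - q * p_i^(q-1) * (1 - p_i)^2).
// Powers of p_i are accumulated multiplicatively per genotype (stable:
// products of numbers in [0,1) underflow gracefully to 0); p_i itself is
// computed via expm1 for accuracy at small exponents. The variance factor
// is clamped at 0 from below as a numerical guard (analytically it lies in
// [0,1] for p in [0,1]).

static void accumulate_spectrum(const NumericVector& f, double R, double r,
                                double o, double L, int q_max,
                                std::vector<double>& E,
                                std::vector<double>& V2) {
  const int M = f.size();
  const double scale = (r - o) * R / L;
  for (int i = 0; i < M; ++i) {
    const double x = scale * f[i];
    const double p = -expm1(-x);       // 1 - exp(-x)
    const double a = 1.0 - p;          // exp(-x)
    const double base = f[i] * R * a * a;
    if (base <= 0.0 && p >= 1.0) {
      // p == 1 in floating point: all mass in arbitrarily deep contigs,
      // every finite bin gets 0.
      continue;
    }
    double pw = 1.0;                   // p^(q-1)
    for (int q = 1; q <= q_max; ++q) {
      const double e = base * q * pw;  // f R q p^(q-1) (1-p)^2
      E[q - 1] += e;
      double fac = 1.0 - q * pw * a * a;
      if (fac < 0.0) fac = 0.0;
      V2[q - 1] += e * fac;
      // once terms are negligible and decreasing (p (q+1) <= q), the
      // remaining tail is below double precision of the read counts
      if (e < 1e-13 && p * (q + 1) <= q) break;
      pw *= p;
      if (pw == 0.0) break;
    }
  }
}

// [[Rcpp::export(name = ".expected_spectrum_cpp")]]
List expected_spectrum_cpp(NumericVector f, double R, double r, double o,
                           double L, int q_max) {
  std::vector<double> E(q_max, 0.0), V2(q_max, 0.0);
  accumulate_spectrum(f, R, r, o, L, q_max, E, V2);
  return List::create(_["E"] = NumericVector(E.begin(), E.end()),
                      _["V2"] = NumericVector(V2.begin(), V2.end()));
}

// Variance-weighted cost S = sum_q (O_q - E_q)^2 / V2_q over q = 1..q_max.
// Zero-variance bins: V2 <= eps with O == 0 contribute 0; V2 <= eps with
// O > 0 use the floor eps (penalises impossible observations without a
// division blow-up).
// [[Rcpp::export(name = ".model_error_cpp")]]
double model_error_cpp(NumericVector f, double R, double r, double o,
                       double L, NumericVector O, double eps) {
  const int q_max = O.size();
  std::vector<double> E(q_max, 0.0), V2(q_max, 0.0);
  accumulate_spectrum(f, R, r, o, L, q_max, E, V2);
  double S = 0.0;
  for (int q = 0; q < q_max; ++q) {
    const double d = O[q] - E[q];
    if (V2[q] <= eps) {
      if (O[q] > 0.0) S += d * d / eps;
    } else {
      S += d * d / V2[q];
    }
  }
  return S;
}
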
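// Compiled kernels for the synthetic-cohort generator and the
// complex-demodulation transform. Both are hot paths: a default cohort holds
// ~1.3e8 voltage samples and the demodulator touches every analysis bin at
// nine carrier frequencies.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Self-contained xoshiro256++ generator (seeded via splitmix64) so that
// cohorts are bit-identical for a given integer seed regardless of the state
// of R's own RNG, and so that per-channel streams are independent.
static inline uint64_t splitmix64(uint64_t& x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];
  Xoshiro256pp(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (stream * 0xD2B74407B1CE6E93ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1); never exactly 0 so log() below is safe
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// [[Rcpp::export]]
Rcpp::NumericVector cpp_gaussian_noise(int n, double seed, double stream) {
  Xoshiro256pp rng((uint64_t)seed, (uint64_t)stream);
  Rcpp::NumericVector out(n);
  int i = 0;
  while (i < n) {
    double u1 = rng.unif(), u2 = rng.unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 2.0 * M_PI * u2;
    out[i++] = r * std::cos(a);
    if (i < n) out[i++] = r * std::sin(a);
  }
  return out;
}

// White Gaussian noise passed through a cascade of first-order pole-zero
// sections, H(z) = prod_k (1 - z_k q) / (1 - p_k q), q = z^-1. With zeros at
// the log-midpoints between log-spaced poles the cascade has a -10 dB/decade
// power slope, i.e. 1/f "pink" noise over the corner range.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_pink_noise(int n, double seed, double stream,
                                   Rcpp::NumericVector poles,
                                   Rcpp::NumericVector zeros) {
  if (poles.size() != zeros.size())
    Rcpp::stop("poles and zeros must have equal length");
  const int M = poles.size();
  // plain arrays in the hot loop: Rcpp proxy indexing costs ~5x here
  std::vector<double> p(poles.begin(), poles.end()),
      z(zeros.begin(), zeros.end()), xprev(M, 0.0), yprev(M, 0.0);
  Xoshiro256pp rng((uint64_t)seed, (uint64_t)stream);
  Rcpp::NumericVector out(n);
  double* o = REAL(out);
  double spare = 0.0;
  bool have_spare = false;
  for (int i = 0; i < n; ++i) {
    double w;
    if (have_spare) { w = spare; have_spare = false; }
    else {
      double u1 = rng.unif(), u2 = rng.unif();
      double r = std::sqrt(-2.0 * std::log(u1)), a = 2.0 * M_PI * u2;
      w = r * std::cos(a);
      spare = r * std::sin(a);
      have_spare = true;
    }
    double x = w;
    for (int k = 0; k < M; ++k) {
      double y = x - z[k] * xprev[k] + p[k] * yprev[k];
      xprev[k] = x;
      yprev[k] = y;
      x = y;
    }
    o[i] = x;
  }
  return out;
}

// Demodulated band amplitude at requested sample indices (1-based centers).
// amplitude(f, t_k) = 2 | sum_j taps_j x[t_k + j - half] e^{-i 2 pi f j / fs} |
// The constant phase factor e^{-i 2 pi f (t_k - half)} has unit modulus and is
// dropped. Caller guarantees every slice lies inside x.
// [[Rcpp::export]]
arma::mat cpp_demod_amplitude(const arma::vec& x,
                              const arma::uvec& centers,
                              const arma::vec& taps,
                              const arma::vec& freqs,
                              double fs) {
  const int L = taps.n_elem, K = centers.n_elem, F = freqs.n_elem;
  const int half = (L - 1) / 2;
  arma::mat Wr(L, F), Wi(L, F);
  for (int f = 0; f < F; ++f) {
    const double w = -2.0 * M_PI * freqs[f] / fs;
    for (int j = 0; j < L; ++j) {
      Wr(j, f) = taps[j] * std::cos(w * j);
      Wi(j, f) = taps[j] * std::sin(w * j);
    }
  }
  arma::mat S(K, L);
  for (int k = 0; k < K; ++k) {
    const arma::uword s0 = centers[k] - 1 - half;
    for (int j = 0; j < L; ++j) S(k, j) = x[s0 + j];
  }
  arma::mat A = S * Wr, B = S * Wi;
  return 2.0 * arma::sqrt(A % A + B % B);
}
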
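// Dropout on the feed-forward hidden activations of the fast univariate
// training path.  The hidden vector is identical across batch and position
// (see R/engine.R), so the sub-layer output per position is the masked sum
// of a fixed coefficient vector; generating the Bernoulli mask and reducing
// it here avoids materialising (batch x position) x ff_dim mask matrices in
// R.  Randomness comes from a xorshift128+ stream seeded from R's RNG, so
// runs remain reproducible under set.seed().
#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

static inline uint64_t xorshift128p(uint64_t& s0, uint64_t& s1) {
  uint64_t x = s0;
  const uint64_t y = s1;
  s0 = y;
  x ^= x << 23;
  s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
  return s1 + y;
}

static void seed_from_r(uint64_t& s0, uint64_t& s1) {
  // two R uniforms give 64 bits of state each; avoid the all-zero state
  s0 = (uint64_t)(unif_rand() * 4294967296.0) << 32 |
       (uint64_t)(unif_rand() * 4294967296.0);
  s1 = (uint64_t)(unif_rand() * 4294967296.0) << 32 |
       (uint64_t)(unif_rand() * 4294967296.0);
  if (s0 == 0 && s1 == 0) s0 = 0x9E3779B97F4A7C15ULL;
  // warm up
  for (int i = 0; i < 8; ++i) xorshift128p(s0, s1);
}

// Per position s: draw one keep/drop decision per hidden unit k and return
// out[s] = sum_k kept c[k] / keep, plus the packed mask for the backward
// pass (one byte per (s, k), position-major).
// [[Rcpp::export]]
List ff_dropout_forward(int npos, NumericVector cvec, double keep) {
  int nf = cvec.size();
  RawVector mask((R_xlen_t)npos * nf);
  NumericVector out(npos);
  uint64_t s0, s1;
  seed_from_r(s0, s1);
  const uint64_t thresh = (uint64_t)(keep * 18446744073709551616.0);
  const double inv = 1.0 / keep;
  R_xlen_t idx = 0;
  for (int s = 0; s < npos; ++s) {
    double acc = 0.0;
    for (int k = 0; k < nf; ++k, ++idx) {
      if (xorshift128p(s0, s1) < thresh) {
        mask[idx] = 1;
        acc += cvec[k];
      }
    }
    out[s] = acc * inv;
  }
  return List::create(_["out"] = out, _["mask"] = mask);
}

// Gradient of the masked sum w.r.t. the coefficient vector:
// gc[k] = sum_s mask(s,k) * dz[s] / keep.
// [[Rcpp::export]]
NumericVector ff_dropout_backward(RawVector mask, NumericVector dz, int nf,
                                  double keep) {
  int npos = dz.size();
  NumericVector gc(nf);
  const double inv = 1.0 / keep;
  R_xlen_t idx = 0;
  for (int s = 0; s < npos; ++s) {
    const double d = dz[s];
    for (int k = 0; k < nf; ++k, ++idx) {
      if (mask[idx]) gc[k] += d;
    }
  }
  for (int k = 0; k < nf; ++k) gc[k] *= inv;
  return gc;
}
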
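// Local Moran's I conditional-permutation engine.
//
// Each pixel's permutation stream is keyed on (master seed, the focal
// value's bit pattern, neighbour count) and draws index into the *sorted*
// pool of all other on-mask deviations. Keying on the value rather than the
// pixel position makes pseudo p-values independent of traversal order,
// exactly invariant under translation of image+mask, and exactly equal for
// identical samples stitched at different positions of a super image.
// perm_pool_indices() exposes the identical stream so a loop-based oracle
// can replay the exact draws.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <cstring>
#include <random>
#include <vector>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t double_bits(double v) {
  uint64_t u;
  std::memcpy(&u, &v, sizeof(u));
  return u;
}

static inline std::mt19937_64 stream_rng(double seed, double zval, int k) {
  uint64_t s = splitmix64(static_cast<uint64_t>(seed)) ^
               splitmix64(double_bits(zval)) ^
               splitmix64(static_cast<uint64_t>(k) * 0xD1B54A32D192ED03ULL);
  return std::mt19937_64(splitmix64(s));
}

// draw k distinct indices from 0..m-1 by partial Fisher-Yates on `idx`,
// recording the swaps so the identity permutation is restored in O(k)
static inline void draw_k(std::mt19937_64 &rng, int m, int k,
                          std::vector<int> &idx, std::vector<int> &out,
                          std::vector<int> &swapped_j) {
  for (int t = 0; t < k; ++t) {
    int j = t + static_cast<int>(rng() % static_cast<uint64_t>(m - t));
    std::swap(idx[t], idx[j]);
    out[t] = idx[t];
    swapped_j[t] = j;
  }
  for (int t = k - 1; t >= 0; --t) std::swap(idx[t], idx[swapped_j[t]]);
}

// [[Rcpp::export]]
IntegerMatrix perm_pool_indices(double seed, double zval, int k, int m,
                                int n_perm) {
  std::mt19937_64 rng = stream_rng(seed, zval, k);
  std::vector<int> idx(m), out(k), sw(k);
  for (int i = 0; i < m; ++i) idx[i] = i;
  IntegerMatrix res(n_perm, k);
  for (int p = 0; p < n_perm; ++p) {
    draw_k(rng, m, k, idx, out, sw);
    for (int t = 0; t < k; ++t) res(p, t) = out[t];  // 0-based pool indices
  }
  return res;
}

// z: deviations of on-mask pixels; m2 = mean(z^2); nb_w: per-pixel
// neighbour weights (applied to draws in order); obs_I: observed local
// Moran values. Returns the one-sided pseudo p per on-mask pixel (NA for
// isolated pixels). The pool for pixel i is the ascending-sorted z with one
// occurrence of z_i removed.
// [[Rcpp::export]]
NumericVector moran_perm_p(NumericVector z, double m2, List nb_w,
                           NumericVector obs_I, int n_perm, double seed) {
  int n = z.size();
  int m = n - 1;
  std::vector<double> zs(z.begin(), z.end());
  std::sort(zs.begin(), zs.end());
  NumericVector p(n, NA_REAL);
  std::vector<int> idx(m), out, sw;
  for (int i = 0; i < n; ++i) {
    NumericVector w = nb_w[i];
    int k = w.size();
    if (k == 0) continue;                 // isolated: no inference
    if (k > static_cast<int>(out.size())) { out.resize(k); sw.resize(k); }
    for (int t = 0; t < m; ++t) idx[t] = t;
    // first occurrence of z_i in the sorted pool is the excluded copy
    int pos = static_cast<int>(
      std::lower_bound(zs.begin(), zs.end(), z[i]) - zs.begin());
    std::mt19937_64 rng = stream_rng(seed, z[i], k);
    double zi_over_m2 = z[i] / m2;
    double Iobs = obs_I[i];
    int count = 0;
    for (int pr = 0; pr < n_perm; ++pr) {
      draw_k(rng, m, k, idx, out, sw);
      double lag = 0.0;
      for (int t = 0; t < k; ++t) {
        int pool = out[t];
        lag += w[t] * zs[pool < pos ? pool : pool + 1];
      }
      double Ip = zi_over_m2 * lag;
      if (Iobs >= 0) { if (Ip >= Iobs) ++count; }
      else           { if (Ip <= Iobs) ++count; }
    }
    p[i] = (count + 1.0) / (n_perm + 1.0);
  }
  return p;
}
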
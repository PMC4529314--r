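// Bitmask utilities for genotype sets stored as 32-bit presence masks
// (one bit per internal reaction; usable for universes with N <= 30).

#include <Rcpp.h>
using namespace Rcpp;

static inline int pc(unsigned int x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcount(x);
#else
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
#endif
}

// [[Rcpp::export(name = ".popcount_cpp")]]
IntegerVector popcount_cpp(IntegerVector masks) {
  int n = masks.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pc((unsigned int)masks[i]);
  return out;
}

// Hamming distance from one mask to each element of `masks`.
// [[Rcpp::export(name = ".hamming_to_all_cpp")]]
IntegerVector hamming_to_all_cpp(int mask, IntegerVector masks) {
  int n = masks.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = pc((unsigned int)(masks[i] ^ mask));
  return out;
}

// Maximum pairwise Hamming distance within a set of masks.
// [[Rcpp::export(name = ".max_pair_distance_cpp")]]
int max_pair_distance_cpp(IntegerVector masks) {
  int n = masks.size(), best = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int d = pc((unsigned int)(masks[i] ^ masks[j]));
      if (d > best) best = d;
    }
  return best;
}

// All unordered index pairs (1-based) at a given Hamming distance.
// [[Rcpp::export(name = ".pairs_at_distance_cpp")]]
IntegerMatrix pairs_at_distance_cpp(IntegerVector masks, int dist) {
  std::vector<int> pi, pj;
  int n = masks.size();
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (pc((unsigned int)(masks[i] ^ masks[j])) == dist) {
        pi.push_back(i + 1);
        pj.push_back(j + 1);
      }
  IntegerMatrix out(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    out(k, 0) = pi[k];
    out(k, 1) = pj[k];
  }
  return out;
}

// Minimum Hamming distance across two sets of masks.
// [[Rcpp::export(name = ".cross_min_distance_cpp")]]
int cross_min_distance_cpp(IntegerVector a, IntegerVector b) {
  int best = INT_MAX;
  for (int i = 0; i < a.size(); ++i)
    for (int j = 0; j < b.size(); ++j) {
      int d = pc((unsigned int)(a[i] ^ b[j]));
      if (d < best) best = d;
      if (best == 0) return 0;
    }
  return best == INT_MAX ? NA_INTEGER : best;
}
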
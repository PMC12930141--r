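#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Classic O(m*n) longest-common-subsequence DP with a two-row rolling
// buffer. Tokens arrive as integer codes (factor levels assigned in R).
static int lcs_len(const IntegerVector& a, const IntegerVector& b) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0) return 0;
  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  for (int i = 1; i <= m; ++i) {
    const int ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      if (ai == b[j - 1])
        cur[j] = prev[j - 1] + 1;
      else
        cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// [[Rcpp::export]]
int lcs_length_int(IntegerVector a, IntegerVector b) {
  return lcs_len(a, b);
}

// Bit-parallel LCS row update (Allison-Dix): the DP row is packed into
// machine words, one bit per position of b; each character of a updates the
// whole row with word-parallel add/or/and, so the cost is O(m * n/64).
// Used for the all-pairs matrix; agrees with lcs_len (tested property).
struct BitMasks {
  int n, W;
  std::vector<uint64_t> m;  // sigma * W words; bit j of symbol c set iff b[j]==c
};

static BitMasks build_masks(const IntegerVector& b, int sigma) {
  BitMasks s;
  s.n = b.size();
  s.W = s.n > 0 ? (s.n + 63) / 64 : 1;
  s.m.assign((size_t)sigma * s.W, 0ULL);
  for (int j = 0; j < s.n; ++j) {
    int c = b[j] - 1;
    s.m[(size_t)c * s.W + (j >> 6)] |= (1ULL << (j & 63));
  }
  return s;
}

static int lcs_len_bits(const IntegerVector& a, const BitMasks& B) {
  const int W = B.W, n = B.n, m = a.size();
  if (n == 0 || m == 0) return 0;
  std::vector<uint64_t> V(W, ~0ULL), U(W);
  for (int i = 0; i < m; ++i) {
    const uint64_t* M = &B.m[(size_t)(a[i] - 1) * W];
    uint64_t carry = 0;
    for (int w = 0; w < W; ++w) {
      U[w] = V[w] & M[w];
      uint64_t sum = V[w] + U[w] + carry;
      carry = (sum < V[w] || (carry && sum == V[w])) ? 1 : 0;
      V[w] = sum | (V[w] & ~M[w]);
    }
  }
  // LCS length = number of zero bits among the n meaningful positions
  int ones = 0;
  for (int w = 0; w < W; ++w) {
    uint64_t v = V[w];
    if (w == W - 1 && (n & 63)) v &= (1ULL << (n & 63)) - 1;
    ones += __builtin_popcountll(v);
  }
  return n - ones;
}

// All unordered pairs among a list of integer-coded sequences, normalized
// by the geometric mean of the two lengths. Empty sequences yield NA
// (similarity undefined; such trials are excluded upstream).
// [[Rcpp::export]]
NumericMatrix lcs_pairwise_sim(List seqs) {
  const int n = seqs.size();
  std::vector<IntegerVector> v(n);
  int sigma = 1;
  for (int i = 0; i < n; ++i) {
    v[i] = as<IntegerVector>(seqs[i]);
    for (int k = 0; k < v[i].size(); ++k)
      if (v[i][k] > sigma) sigma = v[i][k];
  }
  std::vector<BitMasks> masks(n);
  for (int i = 0; i < n; ++i) masks[i] = build_masks(v[i], sigma);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = v[i].size() > 0 ? 1.0 : NA_REAL;
    for (int j = i + 1; j < n; ++j) {
      double s;
      if (v[i].size() == 0 || v[j].size() == 0) {
        s = NA_REAL;
      } else {
        s = lcs_len_bits(v[i], masks[j]) /
            std::sqrt((double)v[i].size() * (double)v[j].size());
      }
      out(i, j) = s;
      out(j, i) = s;
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
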
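#include "store.h"
#include <functional>
using namespace Rcpp;

// Gapped-seed extraction over every window of seq; windows containing any
// non-ACGT character are skipped. Codes returned as doubles, so the caller
// must restrict to k <= 26 (codes < 2^52, exactly representable).
// [[Rcpp::export(name = ".extract_gapped_cpp")]]
List extract_gapped_cpp(std::string seq, IntegerVector kappa, int w) {
  GapMask m = mask_from_kappa(kappa, w);
  const char* s = seq.c_str();
  long L = (long)seq.size();
  std::vector<double> codes;
  std::vector<int> offsets;
  if (L >= w) {
    // prefix counts of invalid characters for O(1) window validity
    std::vector<int> bad(L + 1, 0);
    for (long i = 0; i < L; ++i) bad[i + 1] = bad[i] + (base_digit(s[i]) < 0);
    for (long i = 0; i + w <= L; ++i) {
      if (bad[i + w] - bad[i] > 0) continue;
      codes.push_back((double)canonical_gapped(s + i, m));
      offsets.push_back((int)i);
    }
  }
  return List::create(_["offset"] = wrap(offsets), _["code"] = wrap(codes));
}

// Exhaustive worst-case coverage certifier for a mask.
//
// For every set S of at most s_max substitution positions in [0, L):
//   a placement at offset i (0..L-w) survives iff S hits none of {i+j : j in kappa};
//   covered(S) = union over surviving placements of either
//     - their significant positions (semantics = 0), or
//     - their whole windows [i, i+w)     (semantics = 1).
// Returns min over S of |covered(S)|.
//
// Bitset arithmetic: positions and placements both fit in 3x64 = 192 bits.
// [[Rcpp::export(name = ".min_coverage_cpp")]]
double min_coverage_cpp(IntegerVector kappa, int w, int L, int s_max,
                        int semantics) {
  const int NW = 3;                       // 192-bit words
  if (L > 192) stop("L must be <= 192");
  int P = L - w + 1;                      // number of placements
  if (P > 192) stop("too many placements");

  // cov[i]: positions covered by placement i
  std::vector<uint64_t> cov(NW * P, 0);
  for (int i = 0; i < P; ++i) {
    if (semantics == 0) {
      for (int j : mask_from_kappa(kappa, w).kappa) {
        int pos = i + j;
        cov[NW * i + pos / 64] |= 1ULL << (pos % 64);
      }
    } else {
      for (int j = 0; j < w; ++j) {
        int pos = i + j;
        cov[NW * i + pos / 64] |= 1ULL << (pos % 64);
      }
    }
  }
  // kill[pos]: placements killed by a substitution at pos
  std::vector<uint64_t> kill(NW * L, 0);
  for (int i = 0; i < P; ++i)
    for (int j = 0; j < (int)kappa.size(); ++j) {
      int pos = i + kappa[j];
      kill[NW * pos + i / 64] |= 1ULL << (i % 64);
    }

  std::vector<uint64_t> alive0(NW, 0);
  for (int i = 0; i < P; ++i) alive0[i / 64] |= 1ULL << (i % 64);

  long best = L + 1;
  // iterate subsets of size 0..s_max via nested loop with sentinel positions
  std::vector<int> sel(s_max, -1);
  // recursive enumeration
  std::function<void(int, int, uint64_t*, int)> rec =
    [&](int depth, int start, uint64_t* killed, int smax) {
      // evaluate current subset
      uint64_t alive[NW];
      for (int t = 0; t < NW; ++t) alive[t] = alive0[t] & ~killed[t];
      uint64_t un[NW] = {0, 0, 0};
      for (int t = 0; t < NW; ++t) {
        uint64_t a = alive[t];
        while (a) {
          int b = __builtin_ctzll(a);
          a &= a - 1;
          int i = t * 64 + b;
          for (int q = 0; q < NW; ++q) un[q] |= cov[NW * i + q];
        }
      }
      long c = 0;
      for (int q = 0; q < NW; ++q) c += __builtin_popcountll(un[q]);
      if (c < best) best = c;
      if (depth == smax || best == 0) return;
      for (int pos = start; pos < L; ++pos) {
        uint64_t nk[NW];
        for (int q = 0; q < NW; ++q) nk[q] = killed[q] | kill[NW * pos + q];
        rec(depth + 1, pos + 1, nk, smax);
      }
    };
  uint64_t none[NW] = {0, 0, 0};
  rec(0, 0, none, s_max);
  return (double)best;
}
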
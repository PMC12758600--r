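#ifndef HOSTSIEVE_STORE_H
#define HOSTSIEVE_STORE_H

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>

// ---- hashing / RNG primitives -------------------------------------------
// splitmix64: full-avalanche 64-bit mixer; used both as the hash family core
// and to derive independent seed streams from one user seed.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// xorshift64* stream for eviction walks and key generation
struct Rng64 {
  uint64_t s;
  explicit Rng64(uint64_t seed) : s(splitmix64(seed) | 1ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545f4914f6cdd1dULL;
  }
  // uniform in [0, m) — m tiny here, modulo bias negligible
  uint64_t below(uint64_t m) { return next() % m; }
};

// ---- 2-bit alphabet ------------------------------------------------------
// Digits: A=0, C=1, T=2, G=3 (so complement is digit XOR 2: A<->T, C<->G).
// NOTE this differs from the common A=0,C=1,G=2,T=3 convention.
static inline int base_digit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'T': case 't': return 2;
    case 'G': case 'g': return 3;
    default: return -1;
  }
}

// ---- mask ----------------------------------------------------------------
struct GapMask {
  int w;                    // width (window length)
  int k;                    // weight (number of significant positions)
  std::vector<int> kappa;   // 0-based significant offsets, ascending
};

static inline GapMask mask_from_kappa(const Rcpp::IntegerVector& kappa, int w) {
  GapMask m;
  m.w = w;
  m.k = (int)kappa.size();
  m.kappa.assign(kappa.begin(), kappa.end());
  return m;
}

// Canonical gapped code of the window starting at s+off (caller guarantees
// ACGT-only). Returns max(enc(fwd seed), enc(rc seed)); by mask symmetry the
// rc seed is the complement digits gathered in reverse kappa order.
static inline uint64_t canonical_gapped(const char* s, const GapMask& m) {
  uint64_t fwd = 0, rcv = 0;
  for (int j = 0; j < m.k; ++j) {
    int df = base_digit(s[m.kappa[j]]);
    int dr = base_digit(s[m.kappa[m.k - 1 - j]]) ^ 2;
    fwd = (fwd << 2) | (uint64_t)df;
    rcv = (rcv << 2) | (uint64_t)dr;
  }
  return fwd > rcv ? fwd : rcv;
}

// ---- cuckoo stores -------------------------------------------------------
static const uint64_t SLOT_EMPTY = ~0ULL;

struct CuckooStore {
  // kind 0 = exact bucketed table (full codes); 1 = windowed filter (p-bit fp)
  int kind;
  int d;            // number of hash functions (filter: fixed 2)
  int ell;          // bucket / window size
  int p_bits;       // fingerprint width (filter only)
  int max_kicks;
  uint64_t seed;
  uint64_t n_slots;     // actual slot count
  uint64_t n_addr;      // buckets (kind 0) or windows, power of two (kind 1)
  uint64_t n_keys;      // distinct keys successfully inserted
  uint64_t occupied;    // non-empty slots (== n_keys for both kinds here)
  std::string mask_pattern;  // attached mask, "" if none

  std::vector<uint64_t> slots;    // kind 0
  std::vector<uint16_t> fps;      // kind 1: fingerprint, 0 = empty
  std::vector<uint8_t>  tags;     // kind 1: slot offset from home window start

  std::vector<uint64_t> hseed;    // per-hash-function seeds
  uint64_t fpseed, offseed;
  Rng64 walk_rng;

  CuckooStore() : walk_rng(0) {}

  void derive_seeds() {
    hseed.resize(d);
    for (int i = 0; i < d; ++i) hseed[i] = splitmix64(seed + 0xa5a5ULL * (i + 1));
    fpseed  = splitmix64(seed ^ 0x0f0f0f0f0f0f0f0fULL);
    offseed = splitmix64(seed ^ 0x3c3c3c3c3c3c3c3cULL);
    walk_rng = Rng64(seed ^ 0x77777777deadbeefULL);
  }

  // ---- exact bucketed table ----
  uint64_t bucket_of(uint64_t code, int i) const {
    return splitmix64(code ^ hseed[i]) % n_addr;
  }

  bool ht_lookup(uint64_t code) const {
    for (int i = 0; i < d; ++i) {
      uint64_t b = bucket_of(code, i) * ell;
      for (int j = 0; j < ell; ++j) {
        uint64_t v = slots[b + j];
        if (v == code) return true;
        if (v == SLOT_EMPTY) break;  // bucket filled left-to-right
      }
    }
    return false;
  }

  bool ht_try_place(uint64_t code) {
    for (int i = 0; i < d; ++i) {
      uint64_t b = bucket_of(code, i) * ell;
      for (int j = 0; j < ell; ++j) {
        if (slots[b + j] == SLOT_EMPTY) { slots[b + j] = code; return true; }
      }
    }
    return false;
  }

  // returns true on success (duplicates are no-op successes)
  bool ht_insert(uint64_t code) {
    if (ht_lookup(code)) return true;
    if (ht_try_place(code)) { ++occupied; ++n_keys; return true; }
    // random-walk eviction, path recorded for rollback on failure
    std::vector<uint64_t> path;
    path.reserve(max_kicks);
    uint64_t cur = code;
    for (int kick = 0; kick < max_kicks; ++kick) {
      int i = (int)walk_rng.below(d);
      uint64_t s = bucket_of(cur, i) * ell + walk_rng.below(ell);
      std::swap(slots[s], cur);
      path.push_back(s);
      if (ht_try_place(cur)) { ++occupied; ++n_keys; return true; }
    }
    // rollback: undo swaps in reverse
    for (size_t t = path.size(); t-- > 0; ) std::swap(slots[path[t]], cur);
    return false;
  }

  // ---- windowed filter ----
  uint16_t fingerprint(uint64_t code) const {
    uint64_t f = splitmix64(code ^ fpseed) & ((1ULL << p_bits) - 1);
    return (uint16_t)(f == 0 ? 1 : f);
  }
  uint64_t home_window(uint64_t code) const {
    return splitmix64(code ^ hseed[0]) & (n_addr - 1);
  }
  // XOR offset depends only on the fingerprint -> partner map is an involution
  uint64_t alt_offset(uint16_t fp) const {
    uint64_t o = splitmix64((uint64_t)fp ^ offseed) & (n_addr - 1);
    return o == 0 ? 1 : o;
  }
  uint64_t partner_window(uint64_t win, uint16_t fp) const {
    return win ^ alt_offset(fp);
  }

  bool window_has(uint64_t win, uint16_t fp) const {
    for (int j = 0; j < ell; ++j) if (fps[win + j] == fp) return true;
    return false;
  }
  bool cf_lookup(uint64_t code) const {
    uint16_t fp = fingerprint(code);
    uint64_t w1 = home_window(code);
    return window_has(w1, fp) || window_has(partner_window(w1, fp), fp);
  }
  bool place_in_window(uint64_t win, uint16_t fp) {
    for (int j = 0; j < ell; ++j) {
      if (fps[win + j] == 0) {
        fps[win + j] = fp; tags[win + j] = (uint8_t)j;
        return true;
      }
    }
    return false;
  }

  bool cf_insert(uint64_t code) {
    uint16_t fp = fingerprint(code);
    uint64_t w1 = home_window(code);
    uint64_t w2 = partner_window(w1, fp);
    if (window_has(w1, fp) || window_has(w2, fp)) return true;  // duplicate fp
    if (place_in_window(w1, fp) || place_in_window(w2, fp)) {
      ++occupied; ++n_keys; return true;
    }
    struct Step { uint64_t slot; uint16_t fp; uint8_t tag; };
    std::vector<Step> path;
    path.reserve(max_kicks);
    uint64_t cw = walk_rng.below(2) ? w1 : w2;
    uint16_t cfp = fp;
    for (int kick = 0; kick < max_kicks; ++kick) {
      int j = (int)walk_rng.below(ell);
      uint64_t s = cw + j;
      Step st = { s, fps[s], tags[s] };
      path.push_back(st);
      fps[s] = cfp; tags[s] = (uint8_t)(s - cw);
      // displaced fingerprint: home recoverable from its tag; windows
      // overlap, so its home may still hold a free slot elsewhere
      uint64_t victim_home = st.slot - st.tag;
      cfp = st.fp;
      if (place_in_window(victim_home, cfp)) { ++occupied; ++n_keys; return true; }
      cw = partner_window(victim_home, cfp);
      if (place_in_window(cw, cfp)) { ++occupied; ++n_keys; return true; }
    }
    for (size_t t = path.size(); t-- > 0; ) {
      fps[path[t].slot] = path[t].fp;
      tags[path[t].slot] = path[t].tag;
    }
    return false;
  }

  bool insert(uint64_t code) { return kind == 0 ? ht_insert(code) : cf_insert(code); }
  bool lookup(uint64_t code) const { return kind == 0 ? ht_lookup(code) : cf_lookup(code); }
  double load() const { return (double)occupied / (double)n_slots; }
};

#endif
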
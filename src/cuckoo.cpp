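#include "store.h"
#include <cstring>
using namespace Rcpp;

typedef XPtr<CuckooStore> StorePtr;

static uint64_t next_pow2(uint64_t x) {
  uint64_t p = 1;
  while (p < x) p <<= 1;
  return p;
}

// [[Rcpp::export(name = ".store_new_cpp")]]
SEXP store_new_cpp(int kind, double n_slots, int d, int ell, int p_bits,
                   int max_kicks, double seed) {
  CuckooStore* st = new CuckooStore();
  st->kind = kind;
  st->d = d;
  st->ell = ell;
  st->p_bits = p_bits;
  st->max_kicks = max_kicks;
  st->seed = (uint64_t)seed;
  st->n_keys = 0;
  st->occupied = 0;
  st->mask_pattern = "";
  uint64_t n = (uint64_t)n_slots;
  if (kind == 0) {
    st->n_addr = (n + ell - 1) / ell;            // buckets
    st->n_slots = st->n_addr * ell;
    st->slots.assign(st->n_slots, SLOT_EMPTY);
  } else {
    // windows rounded up to a power of two so the partner-window map is an
    // XOR involution; ell-1 padding slots at the end
    uint64_t nw = next_pow2(n >= (uint64_t)ell ? n - ell + 1 : 1);
    st->n_addr = nw;
    st->n_slots = nw + ell - 1;
    st->fps.assign(st->n_slots, 0);
    st->tags.assign(st->n_slots, 0);
  }
  st->derive_seeds();
  return StorePtr(st, true);
}

// [[Rcpp::export(name = ".store_insert_cpp")]]
LogicalVector store_insert_cpp(SEXP xp, NumericVector codes) {
  StorePtr st(xp);
  LogicalVector out(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i)
    out[i] = st->insert((uint64_t)codes[i]);
  return out;
}

// [[Rcpp::export(name = ".store_lookup_cpp")]]
LogicalVector store_lookup_cpp(SEXP xp, NumericVector codes) {
  StorePtr st(xp);
  LogicalVector out(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i)
    out[i] = st->lookup((uint64_t)codes[i]);
  return out;
}

// [[Rcpp::export(name = ".store_info_cpp")]]
List store_info_cpp(SEXP xp) {
  StorePtr st(xp);
  return List::create(
    _["kind"] = st->kind, _["d"] = st->d, _["ell"] = st->ell,
    _["p_bits"] = st->p_bits, _["max_kicks"] = st->max_kicks,
    _["seed"] = (double)st->seed, _["n_slots"] = (double)st->n_slots,
    _["n_addr"] = (double)st->n_addr, _["n_keys"] = (double)st->n_keys,
    _["occupied"] = (double)st->occupied, _["load"] = st->load(),
    _["mask"] = st->mask_pattern);
}

// [[Rcpp::export(name = ".store_set_mask_cpp")]]
void store_set_mask_cpp(SEXP xp, std::string pattern) {
  StorePtr st(xp);
  st->mask_pattern = pattern;
}

// ---- measurement harnesses ----------------------------------------------
// 58-bit key space mirrors the code range of a weight-29 mask.
static const uint64_t KEYBITS_MASK = (1ULL << 58) - 1;

// Insert distinct random 58-bit keys until target load reached or an insert
// fails; returns achieved load.
// [[Rcpp::export(name = ".fill_to_load_cpp")]]
double fill_to_load_cpp(SEXP xp, double target_load, double rng_seed) {
  StorePtr st(xp);
  Rng64 rng((uint64_t)rng_seed ^ 0x51ee7ULL);
  uint64_t want = (uint64_t)std::ceil(target_load * (double)st->n_slots);
  while (st->occupied < want) {
    uint64_t key = rng.next() & KEYBITS_MASK;
    if (!st->insert(key)) break;
  }
  return st->load();
}

// FPR on guaranteed-absent keys: fill_to_load inserts from [0, 2^58),
// queries here are drawn from [2^58, 2^59).
// [[Rcpp::export(name = ".measure_fpr_cpp")]]
double measure_fpr_cpp(SEXP xp, double n_queries, double rng_seed) {
  StorePtr st(xp);
  Rng64 rng((uint64_t)rng_seed ^ 0xab5e97ULL);
  uint64_t n = (uint64_t)n_queries, fp = 0;
  for (uint64_t i = 0; i < n; ++i) {
    uint64_t key = (1ULL << 58) | (rng.next() & KEYBITS_MASK);
    if (st->lookup(key)) ++fp;
  }
  return (double)fp / (double)n;
}

// ---- sequence-level operations (codes never leave C++) -------------------

// Insert every valid window's canonical code of each sequence.
// Returns counts; stops early with failed=TRUE if an insertion fails
// (caller rebuilds with more slots or a new seed).
// [[Rcpp::export(name = ".store_insert_seqs_cpp")]]
List store_insert_seqs_cpp(SEXP xp, CharacterVector seqs, IntegerVector kappa,
                           int w) {
  StorePtr st(xp);
  GapMask m = mask_from_kappa(kappa, w);
  double windows = 0, skipped = 0;
  uint64_t keys_before = st->n_keys;
  bool failed = false;
  for (R_xlen_t r = 0; r < seqs.size() && !failed; ++r) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    long L = (long)strlen(s);
    if (L < w) continue;
    std::vector<int> bad(L + 1, 0);
    for (long i = 0; i < L; ++i) bad[i + 1] = bad[i] + (base_digit(s[i]) < 0);
    for (long i = 0; i + w <= L; ++i) {
      if (bad[i + w] - bad[i] > 0) { ++skipped; continue; }
      ++windows;
      if (!st->insert(canonical_gapped(s + i, m))) { failed = true; break; }
    }
  }
  return List::create(_["windows"] = windows, _["skipped"] = skipped,
                      _["new_keys"] = (double)(st->n_keys - keys_before),
                      _["failed"] = failed);
}

// Per-read coverage classification.
// mode 0 = sensitive: query every window, mark significant positions of hits.
// mode 1 = sampling:  query offsets 0, s, 2s, ... with s = floor(w/2)+1,
//                     mark all w window positions of hits.
// Windows containing non-ACGT characters count as queried but cannot hit.
// [[Rcpp::export(name = ".classify_batch_cpp")]]
DataFrame classify_batch_cpp(SEXP xp, CharacterVector seqs, IntegerVector kappa,
                             int w, int mode, double threshold) {
  StorePtr st(xp);
  GapMask m = mask_from_kappa(kappa, w);
  R_xlen_t n = seqs.size();
  IntegerVector read_length(n), windows_queried(n), windows_hit(n),
      covered_bases(n);
  LogicalVector is_host(n);
  int step = (mode == 1) ? (w / 2 + 1) : 1;
  std::vector<uint8_t> covered;
  std::vector<int> bad;
  for (R_xlen_t r = 0; r < n; ++r) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    long L = (long)strlen(s);
    read_length[r] = (int)L;
    int q = 0, h = 0;
    long cov = 0;
    if (L >= w) {
      covered.assign(L, 0);
      bad.assign(L + 1, 0);
      for (long i = 0; i < L; ++i) bad[i + 1] = bad[i] + (base_digit(s[i]) < 0);
      for (long i = 0; i + w <= L; i += step) {
        ++q;
        if (bad[i + w] - bad[i] > 0) continue;
        if (st->lookup(canonical_gapped(s + i, m))) {
          ++h;
          if (mode == 1) {
            for (int j = 0; j < w; ++j) covered[i + j] = 1;
          } else {
            for (int j : m.kappa) covered[i + j] = 1;
          }
        }
      }
      for (long i = 0; i < L; ++i) cov += covered[i];
    }
    windows_queried[r] = q;
    windows_hit[r] = h;
    covered_bases[r] = (int)cov;
    is_host[r] = (double)cov >= threshold * (double)L;
  }
  return DataFrame::create(
    _["read_length"] = read_length, _["windows_queried"] = windows_queried,
    _["windows_hit"] = windows_hit, _["covered_bases"] = covered_bases,
    _["is_host"] = is_host);
}

// ---- serialization -------------------------------------------------------
// Little-endian layout:
//   char[8]  magic "HSIVCKIX"
//   u32      version (1)
//   u32      kind, d, ell, p_bits, max_kicks
//   u64      n_slots, n_addr, seed, n_keys, occupied
//   u32      mask length, then mask bytes
//   slot array: kind 0 -> n_slots * u64; kind 1 -> n_slots * u16 + n_slots * u8

static const char MAGIC[8] = {'H','S','I','V','C','K','I','X'};
static const uint32_t FORMAT_VERSION = 1;

template <typename T> static void put(std::vector<uint8_t>& buf, T v) {
  size_t o = buf.size();
  buf.resize(o + sizeof(T));
  std::memcpy(&buf[o], &v, sizeof(T));
}
template <typename T> static T get(const uint8_t* b, size_t len, size_t& off) {
  if (off + sizeof(T) > len) stop("index file truncated");
  T v;
  std::memcpy(&v, b + off, sizeof(T));
  off += sizeof(T);
  return v;
}

// [[Rcpp::export(name = ".store_serialize_cpp")]]
RawVector store_serialize_cpp(SEXP xp) {
  StorePtr st(xp);
  std::vector<uint8_t> buf;
  buf.insert(buf.end(), MAGIC, MAGIC + 8);
  put<uint32_t>(buf, FORMAT_VERSION);
  put<uint32_t>(buf, (uint32_t)st->kind);
  put<uint32_t>(buf, (uint32_t)st->d);
  put<uint32_t>(buf, (uint32_t)st->ell);
  put<uint32_t>(buf, (uint32_t)st->p_bits);
  put<uint32_t>(buf, (uint32_t)st->max_kicks);
  put<uint64_t>(buf, st->n_slots);
  put<uint64_t>(buf, st->n_addr);
  put<uint64_t>(buf, st->seed);
  put<uint64_t>(buf, st->n_keys);
  put<uint64_t>(buf, st->occupied);
  put<uint32_t>(buf, (uint32_t)st->mask_pattern.size());
  buf.insert(buf.end(), st->mask_pattern.begin(), st->mask_pattern.end());
  if (st->kind == 0) {
    size_t o = buf.size();
    buf.resize(o + st->n_slots * 8);
    std::memcpy(&buf[o], st->slots.data(), st->n_slots * 8);
  } else {
    size_t o = buf.size();
    buf.resize(o + st->n_slots * 2);
    std::memcpy(&buf[o], st->fps.data(), st->n_slots * 2);
    o = buf.size();
    buf.resize(o + st->n_slots);
    std::memcpy(&buf[o], st->tags.data(), st->n_slots);
  }
  RawVector out(buf.size());
  std::memcpy(RAW(out), buf.data(), buf.size());
  return out;
}

// [[Rcpp::export(name = ".store_deserialize_cpp")]]
SEXP store_deserialize_cpp(RawVector raw) {
  const uint8_t* b = RAW(raw);
  size_t len = raw.size(), off = 0;
  if (len < 8 || std::memcmp(b, MAGIC, 8) != 0)
    stop("not a hostsieve index (bad magic)");
  off = 8;
  uint32_t ver = get<uint32_t>(b, len, off);
  if (ver != FORMAT_VERSION) stop("unsupported index format version");
  CuckooStore* st = new CuckooStore();
  st->kind = (int)get<uint32_t>(b, len, off);
  st->d = (int)get<uint32_t>(b, len, off);
  st->ell = (int)get<uint32_t>(b, len, off);
  st->p_bits = (int)get<uint32_t>(b, len, off);
  st->max_kicks = (int)get<uint32_t>(b, len, off);
  st->n_slots = get<uint64_t>(b, len, off);
  st->n_addr = get<uint64_t>(b, len, off);
  st->seed = get<uint64_t>(b, len, off);
  st->n_keys = get<uint64_t>(b, len, off);
  st->occupied = get<uint64_t>(b, len, off);
  uint32_t ml = get<uint32_t>(b, len, off);
  if (off + ml > len) { delete st; stop("index file truncated"); }
  st->mask_pattern.assign((const char*)(b + off), ml);
  off += ml;
  size_t need = (st->kind == 0) ? st->n_slots * 8 : st->n_slots * 3;
  if (off + need != len) { delete st; stop("index file truncated or oversized"); }
  if (st->kind == 0) {
    st->slots.resize(st->n_slots);
    std::memcpy(st->slots.data(), b + off, st->n_slots * 8);
  } else {
    st->fps.resize(st->n_slots);
    std::memcpy(st->fps.data(), b + off, st->n_slots * 2);
    off += st->n_slots * 2;
    st->tags.resize(st->n_slots);
    std::memcpy(st->tags.data(), b + off, st->n_slots);
  }
  st->derive_seeds();
  return StorePtr(st, true);
}
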
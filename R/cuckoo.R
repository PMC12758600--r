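#' Cuckoo key stores: exact bucketed table and windowed filter
#'
#' Two interchangeable stores for canonical gapped k-mer codes.
#'
#' `cuckoo_table()` creates an exact (d, l) bucketed Cuckoo hash table: `n`
#' slots divided into `ceiling(n/l)` buckets of `l` slots; a key may reside
#' in any slot of the `d` buckets addressed by its `d` hash functions, and
#' insertion displaces residents along a bounded random walk. Membership
#' answers are exact (full codes are stored).
#'
#' `cuckoo_filter()` creates a probabilistic (2, l) windowed Cuckoo filter:
#' slots are covered by overlapping windows of `l` slots starting at every
#' slot, and only a p-bit fingerprint of each key is stored (0 is reserved
#' for empty, so fingerprints are remapped from 0 to 1). Inserted keys are
#' always found (no false negatives); an absent key is falsely reported
#' present with probability at most `d*l*2^-p` (2^-14 for the default
#' p=16, d=2, l=2). The windowed layout sustains higher loads than the
#' bucketed layout at equal (d, l) — 95% load is the operating point, giving
#' 16/0.95 = 16.8 bits per key. The number of windows is rounded up to a
#' power of two so that a fingerprint's two admissible windows are linked by
#' an XOR involution and relocation never needs the original key.
#'
#' @param n_slots requested number of slots (rounded up to a whole number of
#'   buckets, or to a power-of-two window count plus padding).
#' @param d number of hash functions (table only; the filter uses 2).
#' @param ell bucket/window size.
#' @param p_bits fingerprint width in bits (filter only), 2..16.
#' @param max_kicks bound on eviction-walk steps before an insert fails.
#'   Defaults: 500 for the table, 10000 for the filter — the windowed (2,2)
#'   walk has only two follow-on choices per kick and needs long walks to
#'   operate at its 95% load point (capacity ~96.3%).
#' @param seed integer seed for the hash family and the eviction walk.
#' @return an object of class `cuckoo_index`.
#' @examples
#' ht <- cuckoo_table(1000, seed = 1)
#' cuckoo_insert(ht, c(541, 888))
#' cuckoo_lookup(ht, c(541, 4))   # TRUE FALSE
#' @name cuckoo
NULL

new_store <- function(ptr) structure(list(ptr = ptr), class = "cuckoo_index")

#' @rdname cuckoo
#' @export
cuckoo_table <- function(n_slots, d = 3, ell = 4, max_kicks = 500, seed = 1) {
  stopifnot(n_slots >= ell, d >= 2, ell >= 1, max_kicks >= 1)
  new_store(.store_new_cpp(0L, n_slots, as.integer(d), as.integer(ell),
                           0L, as.integer(max_kicks), seed))
}

#' @rdname cuckoo
#' @export
cuckoo_filter <- function(n_slots, ell = 2, p_bits = 16, max_kicks = 10000,
                          seed = 1) {
  stopifnot(n_slots >= ell, ell >= 1, p_bits >= 2, p_bits <= 16,
            max_kicks >= 1)
  new_store(.store_new_cpp(1L, n_slots, 2L, as.integer(ell),
                           as.integer(p_bits), as.integer(max_kicks), seed))
}

check_store <- function(x) {
  if (!inherits(x, "cuckoo_index")) stop("not a cuckoo_index")
  x
}
check_codes <- function(codes) {
  stopifnot(is.numeric(codes), all(codes >= 0), all(codes < 2^53),
            all(codes == floor(codes)))
  as.numeric(codes)
}

#' Insert keys into / look up keys in a Cuckoo store
#'
#' `cuckoo_insert` inserts canonical codes; a duplicate insert is a no-op
#' success. An insert fails (returns `FALSE`) when the bounded eviction walk
#' is exhausted; the walk is then rolled back, leaving the store unchanged,
#' and the caller should rebuild with more slots or a different seed.
#' `cuckoo_lookup` answers membership: exactly for the table, with bounded
#' false-positive probability for the filter.
#'
#' Codes passed through R must be below 2^53 (masks of weight up to 26); the
#' sequence-level pipeline ([build_index()], [classify_reads()]) has no such
#' limit.
#'
#' @param store a `cuckoo_index`.
#' @param codes numeric vector of non-negative integer-valued codes.
#' @return logical vector, one element per code.
#' @export
cuckoo_insert <- function(store, codes) {
  .store_insert_cpp(check_store(store)$ptr, check_codes(codes))
}

#' @rdname cuckoo_insert
#' @export
cuckoo_lookup <- function(store, codes) {
  .store_lookup_cpp(check_store(store)$ptr, check_codes(codes))
}

#' Fill a store with random keys up to a target load
#'
#' Measurement harness for the achievable-load properties of the two
#' layouts: inserts distinct uniformly random 58-bit keys (the code range of
#' a weight-29 mask) until the target load is reached or an insertion fails,
#' and returns the achieved load.
#'
#' @param store a `cuckoo_index`.
#' @param target_load fraction in (0, 1].
#' @param seed RNG seed for the key stream.
#' @return achieved load (occupied slots / total slots).
#' @export
fill_to_load <- function(store, target_load, seed = 1) {
  stopifnot(target_load > 0, target_load <= 1)
  .fill_to_load_cpp(check_store(store)$ptr, target_load, seed)
}

#' Measure the false positive rate of a store on absent keys
#'
#' Queries `n_queries` random keys drawn from a key range disjoint from the
#' one [fill_to_load()] inserts from (so absence is guaranteed by
#' construction) and returns the fraction reported present. For the exact
#' table this is 0; for a windowed filter it is bounded by
#' `load * d * l * 2^-p`.
#'
#' @param store a `cuckoo_index`.
#' @param n_queries number of absent-key queries.
#' @param seed RNG seed for the query stream.
#' @return observed false positive rate.
#' @export
measure_fpr <- function(store, n_queries, seed = 1) {
  stopifnot(n_queries >= 1)
  .measure_fpr_cpp(check_store(store)$ptr, n_queries, seed)
}

#' Summary statistics of a store
#'
#' @param store a `cuckoo_index` (or the list returned by [build_index()]).
#' @return list with structure kind, mask weight/width (if a mask is
#'   attached), d, l, fingerprint bits, slot and key counts, load, and bits
#'   per key (slot width divided by load: 16/0.95 = 16.8 for the default
#'   filter configuration, 64/load for the exact table).
#' @export
index_stats <- function(store) {
  if (is.list(store) && !inherits(store, "cuckoo_index") &&
      !is.null(store$index)) store <- store$index
  info <- .store_info_cpp(check_store(store)$ptr)
  slot_bits <- if (info$kind == 0L) 64 else info$p_bits
  mk <- if (nzchar(info$mask)) parse_mask(info$mask) else NULL
  list(structure = if (info$kind == 0L) "exact" else "filter",
       k = if (is.null(mk)) NA_integer_ else mk$k,
       w = if (is.null(mk)) NA_integer_ else mk$w,
       mask = info$mask,
       d = info$d, ell = info$ell, p_bits = info$p_bits,
       slots = info$n_slots, keys = info$n_keys, load = info$load,
       bits_per_key = if (info$load > 0) slot_bits / info$load else Inf)
}

#' @method print cuckoo_index
#' @export
print.cuckoo_index <- function(x, ...) {
  s <- index_stats(x)
  cat(sprintf("cuckoo_index [%s] (d=%d, l=%d%s): %d keys in %d slots, load %.3f\n",
              s$structure, s$d, s$ell,
              if (s$structure == "filter") sprintf(", p=%d", s$p_bits) else "",
              s$keys, s$slots, s$load))
  if (nzchar(s$mask)) cat(sprintf("  mask: %s (k=%d, w=%d)\n", s$mask, s$k, s$w))
  invisible(x)
}

#' Save / load a serialized index
#'
#' The on-disk format is little-endian and versioned: an 8-byte magic, a
#' format version, the store parameters (structure kind, d, l, fingerprint
#' bits, eviction bound, slot and window/bucket counts, hash seed, key
#' count), the attached mask string, then the raw slot array (64-bit codes
#' for the exact table; 16-bit fingerprints plus home-offset tags for the
#' filter).
#'
#' @param store a `cuckoo_index` or the list returned by [build_index()].
#' @param path file path.
#' @return `save_index` returns `path` invisibly; `load_index` returns a
#'   `cuckoo_index`.
#' @export
save_index <- function(store, path) {
  if (is.list(store) && !inherits(store, "cuckoo_index") &&
      !is.null(store$index)) store <- store$index
  raw <- .store_serialize_cpp(check_store(store)$ptr)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw, con)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  if (!file.exists(path)) stop("index file not found: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  new_store(.store_deserialize_cpp(raw))
}
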
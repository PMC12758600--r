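#' 2-bit k-mer encoding and canonical codes
#'
#' A k-mer is read as a base-4 number with digits A=0, C=1, T=2, G=3 (note:
#' not the common A,C,G,T digit order). Under this alphabet the complement of
#' a digit is the digit XOR 2, so the encoding of the reverse complement can
#' be computed purely on integers. The canonical code of a k-mer is the
#' *maximum* of the encodings of the k-mer and its reverse complement, so
#' both strands map to the same code.
#'
#' These R-level scalar functions are exact for `k <= 26` (codes below 2^52
#' fit exactly in a double); the index-building and classification pipelines
#' keep larger codes (e.g. the default weight-29 mask) internal and never
#' round-trip them through R numerics.
#'
#' @param seq DNA string over A, C, G, T (case-insensitive).
#' @param code non-negative integer-valued numeric, `0 <= code < 4^k`.
#' @param k k-mer length (2 to 26).
#' @return `encode_kmer`, `revcomp_code` and `canonical_code` return a
#'   numeric code; `decode_kmer` returns the k-mer string.
#' @examples
#' encode_kmer("TACGC")                 # 541
#' revcomp_code(541, 5)                 # 888  (GCGTA)
#' canonical_code(541, 5)               # 888
#' decode_kmer(888, 5)                  # "GCGTA"
#' @name seedcodes
NULL

.digit_of <- c(A = 0, C = 1, T = 2, G = 3)

check_k <- function(k) {
  stopifnot(length(k) == 1L, k == as.integer(k), k >= 1, k <= 26)
  as.integer(k)
}
check_code <- function(code, k) {
  stopifnot(length(code) == 1L, is.numeric(code))
  if (code < 0 || code >= 4^k || code != floor(code))
    stop(sprintf("code must be an integer in [0, 4^%d)", k))
  code
}

#' @rdname seedcodes
#' @export
encode_kmer <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "")[[1]]
  k <- check_k(length(chars))
  d <- .digit_of[chars]
  if (anyNA(d)) stop("ambiguous base in k-mer: ",
                     paste(unique(chars[is.na(d)]), collapse = ","))
  sum(d * 4^((k - 1):0))
}

#' @rdname seedcodes
#' @export
decode_kmer <- function(code, k) {
  k <- check_k(k)
  code <- check_code(code, k)
  digits <- integer(k)
  for (i in k:1) {
    digits[i] <- code %% 4
    code <- code %/% 4
  }
  paste(names(.digit_of)[digits + 1L], collapse = "")
}

#' @rdname seedcodes
#' @export
revcomp_code <- function(code, k) {
  k <- check_k(k)
  code <- check_code(code, k)
  out <- 0
  for (i in seq_len(k)) {
    d <- code %% 4
    code <- (code - d) / 4
    out <- out * 4 + bitwXor(d, 2L)  # complement: A<->T, C<->G
  }
  out
}

#' @rdname seedcodes
#' @export
canonical_code <- function(code, k) {
  max(check_code(code, check_k(k)), revcomp_code(code, k))
}

#' Extract canonical gapped k-mer codes from a sequence
#'
#' Slides the mask window over `seq`; for every offset whose full window
#' consists only of A/C/G/T (case-insensitive), emits the canonical code of
#' the gapped k-mer (characters at the mask's significant positions).
#' Windows containing any other character — N, IUPAC ambiguity codes — are
#' skipped, so an index built from these codes contains only fully defined
#' seeds. Because masks are symmetric, reverse-complementing the full window
#' and then masking equals masking and then reverse-complementing the seed.
#'
#' @param seq DNA string.
#' @param mask a `seed_mask` or pattern string with weight `k <= 26` (codes
#'   are returned as exact doubles).
#' @return data.frame with columns `offset` (0-based window start) and
#'   `code` (canonical gapped k-mer code). A sequence shorter than the mask
#'   width yields zero rows.
#' @examples
#' extract_gapped("TACGCGTAAG", "##_#_##")
#' @export
extract_gapped <- function(seq, mask) {
  stopifnot(is.character(seq), length(seq) == 1L)
  mask <- as_mask(mask)
  if (mask$k > 26)
    stop("extract_gapped returns codes as doubles and requires weight <= 26; ",
         "use build_index()/classify_reads() for heavier masks")
  res <- .extract_gapped_cpp(seq, mask$kappa, mask$w)
  data.frame(offset = res$offset, code = res$code)
}
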
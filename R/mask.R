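#' Parse and validate a spaced-seed mask
#'
#' A (k, w)-mask is a string over `{#, _}` of width `w` containing exactly
#' `k` significant positions (`#`). Masks must start and end with `#`, have
#' weight at least 2, and be symmetric (equal to their own reversal) so that
#' a window and its reverse complement yield the same canonical code.
#'
#' @param pattern mask string over `#` (significant) and `_` (insignificant),
#'   e.g. `"##_#_##"`.
#' @return an object of class `seed_mask`: a list with elements `pattern`,
#'   `k` (weight), `w` (width), and `kappa` (0-based offsets of the
#'   significant positions).
#' @examples
#' parse_mask("##_#_##")
#' parse_mask("#####")
#' @export
parse_mask <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  if (nchar(pattern) == 0L) stop("mask pattern must be non-empty")
  chars <- strsplit(pattern, "")[[1]]
  if (!all(chars %in% c("#", "_")))
    stop("mask may only contain '#' and '_': ", pattern)
  w <- length(chars)
  kappa <- which(chars == "#") - 1L
  k <- length(kappa)
  if (chars[1] != "#" || chars[w] != "#")
    stop("first and last mask position must be significant ('#')")
  if (k < 2L) stop("mask weight must be at least 2")
  if (paste(rev(chars), collapse = "") != pattern)
    stop("mask must be symmetric: ", pattern)
  structure(list(pattern = pattern, k = k, w = w, kappa = kappa),
            class = "seed_mask")
}

#' @method print seed_mask
#' @export
print.seed_mask <- function(x, ...) {
  cat(sprintf("(%d,%d)-mask %s\n", x$k, x$w, x$pattern))
  invisible(x)
}

# Accept either a seed_mask or a pattern string.
as_mask <- function(mask) {
  if (inherits(mask, "seed_mask")) mask else parse_mask(mask)
}

#' The default (29,33) mask
#'
#' The symmetric weight-29, width-33 mask used for human host depletion. It
#' guarantees at least 50 covered positions in any length-100 read substring
#' that matches the genome with at most three substitutions (certifiable with
#' [min_coverage()]).
#'
#' @return a `seed_mask`.
#' @export
default_mask <- function() {
  parse_mask("######_#######_###_#######_######")
}

#' Certify the worst-case coverage guarantee of a mask
#'
#' Exhaustively enumerates every set of at most `s_max` substitution
#' positions in a window of `L` bases. A seed placement at offset `i`
#' survives a substitution set if no substitution falls on one of its
#' significant positions `i + kappa`. The coverage of a set is the size of
#' the union of covered positions over all surviving placements; the
#' function returns the minimum coverage over all substitution sets — the
#' guaranteed number of covered bases for any read region within `s_max`
#' substitutions of an indexed sequence.
#'
#' @param mask a `seed_mask` or pattern string.
#' @param L region length (at least the mask width, at most 192).
#' @param s_max maximum number of substitutions (non-negative).
#' @param semantics `"significant"` (default) counts only the significant
#'   positions of surviving placements as covered, matching how the
#'   sensitive classification mode marks coverage; `"window"` counts all
#'   `w` window positions.
#' @param budget refuse enumerations with more than this many substitution
#'   sets (default 1e7).
#' @return integer: the guaranteed minimum number of covered positions.
#' @examples
#' min_coverage("###", L = 6, s_max = 1)
#' @export
min_coverage <- function(mask, L, s_max,
                         semantics = c("significant", "window"),
                         budget = 1e7) {
  mask <- as_mask(mask)
  semantics <- match.arg(semantics)
  stopifnot(L >= mask$w, s_max >= 0)
  n_sets <- sum(choose(L, 0:s_max))
  if (n_sets > budget)
    stop(sprintf("enumeration of %.3g substitution sets exceeds budget %.3g",
                 n_sets, budget))
  as.integer(.min_coverage_cpp(mask$kappa, mask$w, as.integer(L),
                               as.integer(s_max),
                               if (semantics == "window") 1L else 0L))
}
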
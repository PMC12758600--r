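# Shared helpers and independent oracles for the test suite.
# The oracles deliberately re-derive results from first principles (string
# slicing, set arithmetic) and never call the package's extraction or
# coverage code paths.

rand_dna <- function(len, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

revcomp_str <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(ch)
    paste(rev(ch), collapse = ""), ""))
}

# Naive per-window gapped-seed extraction. Reverse complement is computed on
# the masked seed characters (mask-then-rc), the opposite route to the
# implementation's full-window gather, so agreement also exercises mask
# symmetry.
oracle_extract <- function(seq, pattern) {
  chars <- strsplit(pattern, "")[[1]]
  w <- length(chars)
  kap <- which(chars == "#")              # 1-based within window
  k <- length(kap)
  L <- nchar(seq)
  if (L < w) return(data.frame(offset = integer(), code = numeric()))
  digit <- c(A = 0, C = 1, T = 2, G = 3)
  dvec <- digit[strsplit(toupper(seq), "")[[1]]]
  offs <- 0:(L - w)
  out_off <- integer(0); out_code <- numeric(0)
  pw <- 4^((k - 1):0)
  for (i in offs) {
    win <- dvec[(i + 1):(i + w)]
    if (anyNA(win)) next
    d <- win[kap]
    fwd <- sum(d * pw)
    rc <- sum(rev(bitwXor(as.integer(d), 2L)) * pw)
    out_off <- c(out_off, i)
    out_code <- c(out_code, max(fwd, rc))
  }
  data.frame(offset = out_off, code = out_code)
}

# Exhaustive coverage certifier by direct subset enumeration with explicit
# set-union arithmetic.
oracle_min_coverage <- function(pattern, L, s_max) {
  chars <- strsplit(pattern, "")[[1]]
  w <- length(chars)
  kap <- which(chars == "#") - 1L
  cover_of <- lapply(0:(L - w), function(i) i + kap)
  subsets <- list(integer(0))
  for (s in seq_len(s_max))
    subsets <- c(subsets, utils::combn(0:(L - 1), s, simplify = FALSE))
  best <- L
  for (S in subsets) {
    surv <- vapply(cover_of, function(cv) !any(S %in% cv), TRUE)
    best <- min(best, length(unique(unlist(cover_of[surv]))))
  }
  best
}

# Write a data.frame(id, seq, qual) as a FASTQ file, independent of the
# package writer.
write_fastq_plain <- function(records, path) {
  lines <- as.vector(rbind(paste0("@", records$id), records$seq, "+",
                           records$qual))
  writeLines(lines, path)
  path
}
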
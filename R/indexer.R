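#' Build a host index from reference FASTA sequences
#'
#' Streams the reference sequences, extracts the canonical gapped k-mer code
#' of every ACGT-only window under the mask, and inserts the codes into an
#' exact bucketed Cuckoo table or a windowed Cuckoo filter. Optionally
#' augments the index with common variants from a VCF file: every variant
#' with allele frequency at least `min_af` is applied to the reference
#' individually and the gapped k-mers of the altered sequence plus `flank`
#' bases of context on each side are added (see [apply_variants()]).
#' Additional collections (HLA alleles, cDNA, extra assemblies) are simply
#' further FASTA inputs.
#'
#' If an insertion fails or the load exceeds `fill_limit`, the index is
#' rebuilt automatically: first with 1.5x the slots, then with a different
#' hash seed, then the build errors out.
#'
#' @param fasta character vector of FASTA file paths (gzip accepted), or a
#'   `Biostrings::DNAStringSet`, or a named character vector of sequences
#'   (names distinguish sequences from paths: anything that is not an
#'   existing file is treated as a literal sequence).
#' @param mask a `seed_mask` or pattern string (default: [default_mask()]).
#' @param structure `"exact"` (bucketed table, default) or `"filter"`
#'   (windowed filter).
#' @param size_estimate expected number of distinct codes; defaults to the
#'   total window count of the inputs (an overestimate of the distinct
#'   count, which is safe).
#' @param fill_limit maximum load to size for (default 0.88 exact, 0.95
#'   filter).
#' @param vcf optional VCF path (plain or gzipped) with `AF` in INFO.
#' @param min_af allele-frequency cutoff for variants (default 0.01).
#' @param flank context bases kept around an applied variant (default 50).
#' @param p_bits fingerprint bits for the filter (default 16).
#' @param d,ell table geometry (defaults: exact (3,4); filter (2,2)).
#' @param max_kicks eviction-walk bound (default 500 exact, 10000 filter).
#' @param seed hash/eviction seed (default 1).
#' @return list with `index` (a `cuckoo_index`, mask attached) and `report`
#'   (sequence, fragment, window, skipped-window, key counts, final load,
#'   and variant application counts).
#' @examples
#' b <- build_index(c(g = "TACGCGTAAG"), mask = "##_#_##", size_estimate = 10)
#' index_stats(b$index)$keys
#' @export
build_index <- function(fasta, mask = default_mask(),
                        structure = c("exact", "filter"),
                        size_estimate = NULL, fill_limit = NULL,
                        vcf = NULL, min_af = 0.01, flank = 50,
                        p_bits = 16, d = NULL, ell = NULL,
                        max_kicks = NULL, seed = 1) {
  mask <- as_mask(mask)
  structure <- match.arg(structure)
  if (is.null(fill_limit)) fill_limit <- if (structure == "exact") 0.88 else 0.95
  stopifnot(fill_limit > 0, fill_limit < 1, min_af >= 0, min_af <= 1,
            flank >= 0)
  if (is.null(d)) d <- if (structure == "exact") 3L else 2L
  if (is.null(ell)) ell <- if (structure == "exact") 4L else 2L
  if (is.null(max_kicks)) max_kicks <- if (structure == "exact") 500L else 10000L

  seqs <- read_reference_seqs(fasta)

  var_report <- list(n_records = 0L, n_applied = 0L, n_filtered_af = 0L,
                     n_ref_mismatch = 0L, n_no_af = 0L)
  fragments <- character(0)
  if (!is.null(vcf)) {
    variants <- read_vcf_variants(vcf)
    var_report$n_records <- nrow(variants)
    var_report$n_no_af <- attr(variants, "n_no_af") %||% 0L
    for (chrom in unique(variants$chrom)) {
      if (!chrom %in% names(seqs)) {
        warning("VCF chromosome not in reference, skipped: ", chrom)
        next
      }
      av <- apply_variants(seqs[[chrom]], variants[variants$chrom == chrom, ],
                           min_af = min_af, flank = flank)
      fragments <- c(fragments, av$fragments)
      var_report$n_applied <- var_report$n_applied + av$n_applied
      var_report$n_filtered_af <- var_report$n_filtered_af + av$n_filtered_af
      var_report$n_ref_mismatch <- var_report$n_ref_mismatch + av$n_ref_mismatch
    }
  }

  all_seqs <- c(unname(unlist(seqs)), fragments)
  if (is.null(size_estimate)) {
    size_estimate <- sum(pmax(nchar(all_seqs) - mask$w + 1, 0))
    if (size_estimate == 0) size_estimate <- 1
  }
  stopifnot(size_estimate > 0)

  build_once <- function(n_slots, build_seed) {
    store <- if (structure == "exact")
      cuckoo_table(n_slots, d = d, ell = ell, max_kicks = max_kicks,
                   seed = build_seed)
    else
      cuckoo_filter(n_slots, ell = ell, p_bits = p_bits,
                    max_kicks = max_kicks, seed = build_seed)
    ins <- if (length(all_seqs))
      .store_insert_seqs_cpp(store$ptr, all_seqs, mask$kappa, mask$w)
    else
      list(windows = 0, skipped = 0, new_keys = 0, failed = FALSE)
    list(store = store, ins = ins)
  }

  base_slots <- max(ceiling(size_estimate / fill_limit), ell)
  attempts <- list(c(base_slots, seed),
                   c(ceiling(base_slots * 1.5), seed),
                   c(ceiling(base_slots * 1.5), seed + 7919))
  res <- NULL
  for (a in attempts) {
    res <- build_once(a[1], a[2])
    ok <- !res$ins$failed && index_stats(res$store)$load <= fill_limit
    if (ok) break
    res <- NULL
  }
  if (is.null(res))
    stop("index build failed after 3 attempts (resize + reseed); ",
         "increase size_estimate or slots")

  .store_set_mask_cpp(res$store$ptr, mask$pattern)
  stats <- index_stats(res$store)
  list(index = res$store,
       report = list(structure = structure,
                     mask = mask$pattern, k = mask$k, w = mask$w,
                     n_sequences = length(seqs),
                     n_fragments = length(fragments),
                     windows = res$ins$windows,
                     skipped_windows = res$ins$skipped,
                     keys = stats$keys, slots = stats$slots,
                     load = stats$load,
                     variants = var_report))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FASTA paths -> named list of sequences; also accepts a DNAStringSet or
# literal sequences.
read_reference_seqs <- function(fasta) {
  if (inherits(fasta, "DNAStringSet")) {
    s <- as.character(fasta)
    return(as.list(s))
  }
  stopifnot(is.character(fasta))
  if (length(fasta) && all(file.exists(fasta))) {
    out <- list()
    for (p in fasta) {
      s <- as.character(Biostrings::readDNAStringSet(p))
      out <- c(out, as.list(s))
    }
    return(out)
  }
  if (any(file.exists(fasta)))
    stop("reference input mixes existing files and literal sequences")
  if (is.null(names(fasta)))
    names(fasta) <- paste0("seq", seq_along(fasta))
  as.list(fasta)
}

#' Read variant records with allele frequencies from a VCF file
#'
#' Parses a VCF (plain or gzipped) and returns one record per ALT allele
#' with its allele frequency taken from the INFO `AF` field (comma-split for
#' multi-allelic sites). Records without an AF value are skipped with a
#' warning.
#'
#' @param path VCF file path.
#' @return data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `af`; attribute `n_no_af` counts skipped AF-less records.
#' @export
read_vcf_variants <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0)
    return(structure(data.frame(chrom = character(), pos = integer(),
                                ref = character(), alt = character(),
                                af = numeric()), n_no_af = 0L))
  af_str <- vcfR::extract.info(v, element = "AF")
  rows <- list()
  n_no_af <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    afs <- if (is.na(af_str[i])) NA_character_
           else strsplit(af_str[i], ",", fixed = TRUE)[[1]]
    if (length(afs) == 1L && is.na(afs)) {
      n_no_af <- n_no_af + 1L
      next
    }
    afs <- suppressWarnings(as.numeric(afs))
    afs <- rep_len(afs, length(alts))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      ref = fix$REF[i], alt = alts, af = afs,
      stringsAsFactors = FALSE)
  }
  if (n_no_af > 0)
    warning(n_no_af, " VCF record(s) without INFO AF skipped")
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(chrom = character(), pos = integer(),
                         ref = character(), alt = character(), af = numeric())
  structure(out, n_no_af = n_no_af)
}

#' Apply variants to a reference sequence and emit flanked fragments
#'
#' For each variant with `af >= min_af`, replaces the affected reference
#' region with the alternative allele and returns the altered sequence
#' together with up to `flank` reference bases of context on each side.
#' Variants are applied independently (no haplotype combinations). VCF-style
#' records sharing a leading base between REF and ALT (the indel convention)
#' are normalized first, so a pure deletion contributes no alternative
#' bases of its own. A variant whose REF allele does not match the reference
#' is skipped with a warning.
#'
#' @param ref_seq reference sequence (single string).
#' @param variants data.frame with columns `pos` (1-based), `ref`, `alt`,
#'   `af` (as from [read_vcf_variants()]).
#' @param min_af allele-frequency cutoff.
#' @param flank context bases on each side.
#' @return list with `fragments` (character vector) and counts `n_applied`,
#'   `n_filtered_af`, `n_ref_mismatch`.
#' @export
apply_variants <- function(ref_seq, variants, min_af = 0.01, flank = 50) {
  stopifnot(is.character(ref_seq), length(ref_seq) == 1L)
  L <- nchar(ref_seq)
  fragments <- character(0)
  n_applied <- 0L; n_filtered <- 0L; n_mismatch <- 0L
  for (i in seq_len(nrow(variants))) {
    pos <- variants$pos[i]
    ref <- toupper(variants$ref[i])
    alt <- toupper(variants$alt[i])
    af <- variants$af[i]
    if (is.na(af) || af < min_af) { n_filtered <- n_filtered + 1L; next }
    if (substr(ref_seq, pos, pos + nchar(ref) - 1L) != ref) {
      warning(sprintf("REF mismatch at %d (expected %s), variant skipped",
                      pos, ref))
      n_mismatch <- n_mismatch + 1L
      next
    }
    # normalize shared leading base (VCF indel convention)
    while (nchar(ref) > 0 && nchar(alt) > 0 &&
           substr(ref, 1, 1) == substr(alt, 1, 1)) {
      ref <- substr(ref, 2, nchar(ref))
      alt <- substr(alt, 2, nchar(alt))
      pos <- pos + 1L
    }
    # replaced region, 0-based half-open: [start0, end0)
    start0 <- pos - 1L
    end0 <- start0 + nchar(ref)
    left <- substr(ref_seq, max(1L, start0 - flank + 1L), start0)
    right <- substr(ref_seq, end0 + 1L, min(L, end0 + flank))
    fragments <- c(fragments, paste0(left, alt, right))
    n_applied <- n_applied + 1L
  }
  list(fragments = fragments, n_applied = n_applied,
       n_filtered_af = n_filtered, n_ref_mismatch = n_mismatch)
}
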
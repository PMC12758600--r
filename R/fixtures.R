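#' Deterministic synthetic fixtures
#'
#' Generators for test and benchmark inputs so every pipeline stage can be
#' exercised without downloads: a uniform random genome, host-derived reads
#' with i.i.d. substitution errors (single- or paired-end) plus truth
#' labels, and a small valid VCF of SNVs and short indels with explicit
#' allele frequencies. All generators are pure functions of their arguments
#' and the seed; the caller's RNG state is untouched.
#'
#' @param length genome length (>= 1).
#' @param seed integer seed.
#' @return `synth_genome` returns a single uppercase ACGT string.
#' @examples
#' g <- synth_genome(1000, seed = 1)
#' r <- sample_reads(g, n = 10, read_length = 100, seed = 2)
#' @export
synth_genome <- function(length, seed = 1) {
  stopifnot(is.numeric(length), length >= 1)
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                        collapse = ""))
}

revcomp_seq <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Sample reads from a genome with substitution errors
#'
#' Draws read start positions and strands uniformly; each base is
#' substituted independently with probability `substitution_rate` (always
#' to a different base). In paired mode, fragments of `insert_size` bases
#' are drawn and the pair is the forward prefix and the
#' reverse-complemented suffix of the fragment, each of `read_length`
#' bases, sharing one record id.
#'
#' @param genome template sequence (string).
#' @param n number of reads (or pairs).
#' @param read_length read length; at most the genome (or insert) length.
#' @param substitution_rate per-base substitution probability in \[0, 1\].
#' @param seed integer seed.
#' @param paired emit read pairs?
#' @param insert_size fragment length for paired mode (default
#'   `2.5 * read_length`).
#' @param id_prefix record id prefix.
#' @param label truth label stored for every read (e.g. `"host"`).
#' @return list with `reads` (data.frame `id`, `seq`, `qual`; paired mode
#'   instead has `reads1` and `reads2`) and `truth` (data.frame `id`,
#'   `label`, `pos` (0-based template start), `strand`, `n_subs`).
#' @export
sample_reads <- function(genome, n, read_length, substitution_rate = 0,
                         seed = 1, paired = FALSE, insert_size = NULL,
                         id_prefix = "read", label = "host") {
  stopifnot(is.character(genome), length(genome) == 1L, n >= 0,
            substitution_rate >= 0, substitution_rate <= 1)
  L <- nchar(genome)
  stopifnot(read_length <= L)
  if (paired) {
    if (is.null(insert_size)) insert_size <- ceiling(2.5 * read_length)
    if (insert_size < read_length || insert_size > L)
      stop("infeasible insert size: ", insert_size)
  }
  with_seed(seed, {
    ids <- sprintf("%s_%06d", id_prefix, seq_len(n))
    span <- if (paired) insert_size else read_length
    starts <- if (n > 0) sample.int(L - span + 1L, n, replace = TRUE) else integer()
    strands <- if (n > 0) sample(c("+", "-"), n, replace = TRUE) else character()
    frags <- substring(genome, starts, starts + span - 1L)
    frags[strands == "-"] <- revcomp_seq(frags[strands == "-"])
    qual <- strrep("I", read_length)
    if (!paired) {
      res <- mutate_reads(frags, substitution_rate)
      truth <- data.frame(id = ids, label = label, pos = starts - 1L,
                          strand = strands, n_subs = res$n_subs,
                          stringsAsFactors = FALSE)
      list(reads = data.frame(id = ids, seq = res$seqs, qual = qual,
                              stringsAsFactors = FALSE),
           truth = truth)
    } else {
      r1 <- substring(frags, 1L, read_length)
      r2 <- revcomp_seq(substring(frags, span - read_length + 1L, span))
      m1 <- mutate_reads(r1, substitution_rate)
      m2 <- mutate_reads(r2, substitution_rate)
      truth <- data.frame(id = ids, label = label, pos = starts - 1L,
                          strand = strands, n_subs = m1$n_subs + m2$n_subs,
                          stringsAsFactors = FALSE)
      list(reads1 = data.frame(id = ids, seq = m1$seqs, qual = qual,
                               stringsAsFactors = FALSE),
           reads2 = data.frame(id = ids, seq = m2$seqs, qual = qual,
                               stringsAsFactors = FALSE),
           truth = truth)
    }
  })
}

# i.i.d. substitutions, always to a different base (uses the current RNG)
mutate_reads <- function(seqs, rate) {
  n_subs <- integer(length(seqs))
  if (rate > 0 && length(seqs)) {
    len <- nchar(seqs)
    n_subs <- rbinom(length(seqs), len, rate)
    bases <- c("A", "C", "G", "T")
    for (i in which(n_subs > 0L)) {
      pos <- sample.int(len[i], n_subs[i])
      s <- seqs[i]
      for (p in pos) {
        old <- substr(s, p, p)
        substr(s, p, p) <- sample(setdiff(bases, old), 1L)
      }
      seqs[i] <- s
    }
  }
  list(seqs = seqs, n_subs = n_subs)
}

#' Generate a small synthetic VCF
#'
#' Emits a mixture of SNVs, short insertions and deletions at
#' non-overlapping positions of the genome, with valid REF alleles, the
#' shared-leading-base convention for indels, and explicit `AF` values in
#' INFO.
#'
#' @param genome template sequence (string).
#' @param n_variants number of variant records.
#' @param afs allele frequencies, recycled over records.
#' @param seed integer seed.
#' @param chrom contig name used in the records.
#' @return data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   `af`; write it with [write_vcf()].
#' @export
synth_vcf <- function(genome, n_variants, afs = 0.5, seed = 1,
                      chrom = "synth1") {
  stopifnot(n_variants >= 0)
  L <- nchar(genome)
  gap <- 12L
  if (n_variants > 0 && L < n_variants * gap + 20L)
    stop("genome too short for ", n_variants, " variants")
  with_seed(seed, {
    # non-overlapping positions with a safety gap (indels span <= 4 bases)
    pos <- sort(sample(seq(5L, L - 10L, by = gap), n_variants))
    type <- rep_len(c("snv", "ins", "del"), n_variants)
    af <- rep_len(afs, n_variants)
    bases <- c("A", "C", "G", "T")
    ref <- character(n_variants)
    alt <- character(n_variants)
    for (i in seq_len(n_variants)) {
      p <- pos[i]
      anchor <- substr(genome, p, p)
      if (type[i] == "snv") {
        ref[i] <- anchor
        alt[i] <- sample(setdiff(bases, anchor), 1L)
      } else if (type[i] == "ins") {
        ref[i] <- anchor
        alt[i] <- paste0(anchor, paste(sample(bases, sample(1:3, 1L),
                                              replace = TRUE), collapse = ""))
      } else {
        dl <- sample(1:3, 1L)
        ref[i] <- substr(genome, p, p + dl)
        alt[i] <- anchor
      }
    }
    data.frame(chrom = chrom, pos = pos,
               id = sprintf("var%04d", seq_len(n_variants)),
               ref = ref, alt = alt, af = af, stringsAsFactors = FALSE)
  })
}

#' @rdname synth_vcf
#' @param variants data.frame as returned by `synth_vcf`.
#' @param path output VCF path.
#' @param contig_length contig length for the header (defaults to beyond the
#'   last variant).
#' @export
write_vcf <- function(variants, path, contig_length = NULL) {
  chrom <- if (nrow(variants)) variants$chrom[1] else "synth1"
  if (is.null(contig_length))
    contig_length <- if (nrow(variants)) max(variants$pos) + 100L else 1000L
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", chrom, contig_length),
           paste0("##INFO=<ID=AF,Number=A,Type=Float,",
                  "Description=\"Allele Frequency\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO"), collapse = "\t"))
  rec <- if (nrow(variants))
    sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tAF=%s",
            variants$chrom, variants$pos, variants$id, variants$ref,
            variants$alt,
            vapply(variants$af, function(a)
              format(a, scientific = FALSE, trim = TRUE), ""))
  else character()
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write a complete fixture set to a directory
#'
#' Presets:
#' * `"small"`: 50 kb host genome, 20-variant VCF, 500 host + 500 foreign
#'   150 bp reads (1% substitutions on host reads).
#' * `"classify-bench"`: 2 Mb host genome and an independent 2 Mb foreign
#'   genome, 1e5 host reads (150 bp, 1% substitutions) and 1e5 foreign
#'   reads.
#'
#' Foreign reads are sampled from an independently seeded synthetic genome
#' (not uniform random strings) so their k-mer composition resembles real
#' negatives. Files written: `host.fasta`, `reads.fastq`, `truth.tsv`, and
#' (preset `"small"`) `variants.vcf`.
#'
#' @param preset `"small"` or `"classify-bench"`.
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return invisible named list of written file paths.
#' @export
write_fixtures <- function(preset = c("small", "classify-bench"), dir,
                           seed = 1) {
  preset <- match.arg(preset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- if (preset == "small")
    list(glen = 50000L, n = 500L, rl = 150L, rate = 0.01, vcf = 20L)
  else
    list(glen = 2000000L, n = 100000L, rl = 150L, rate = 0.01, vcf = 0L)

  host <- synth_genome(cfg$glen, seed = seed)
  foreign <- synth_genome(cfg$glen, seed = seed + 104729L)
  hr <- sample_reads(host, cfg$n, cfg$rl, cfg$rate, seed = seed + 1L,
                     id_prefix = "host", label = "host")
  fr <- sample_reads(foreign, cfg$n, cfg$rl, 0, seed = seed + 2L,
                     id_prefix = "foreign", label = "foreign")
  reads <- rbind(hr$reads, fr$reads)
  truth <- rbind(hr$truth, fr$truth)

  paths <- list(host_fasta = file.path(dir, "host.fasta"),
                reads_fastq = file.path(dir, "reads.fastq"),
                truth_tsv = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(host1 = host)), paths$host_fasta)
  write_fastq(reads, paths$reads_fastq)
  write.table(truth, paths$truth_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (cfg$vcf > 0) {
    paths$variants_vcf <- file.path(dir, "variants.vcf")
    v <- synth_vcf(host, cfg$vcf, afs = c(0.005, 0.5), seed = seed + 3L,
                   chrom = "host1")
    write_vcf(v, paths$variants_vcf, contig_length = cfg$glen)
  }
  invisible(paths)
}
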
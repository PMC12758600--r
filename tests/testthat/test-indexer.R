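test_that("a tiny genome indexes exactly its canonical gapped codes", {
  b <- build_index(c(g = "TACGCGTAAG"), mask = "##_#_##", size_estimate = 10)
  want <- oracle_extract("TACGCGTAAG", "##_#_##")   # 574, 574, 663, 867
  expect_true(all(cuckoo_lookup(b$index, unique(want$code))))
  set.seed(51)
  absent <- setdiff(floor(runif(10000) * 4^5), want$code)
  expect_false(any(cuckoo_lookup(b$index, absent)))
  expect_equal(b$report$windows, 4)
  expect_equal(b$report$keys, length(unique(want$code)))
  expect_equal(index_stats(b)$mask, "##_#_##")
})

test_that("inputs without any full window give an empty index", {
  b <- build_index(c(s1 = "ACGT", s2 = "TTT"), mask = "##_#_##",
                   size_estimate = 1)
  expect_equal(b$report$keys, 0)
  expect_equal(index_stats(b)$load, 0)
})

test_that("indexing is idempotent over repeated sequences (set semantics)", {
  g <- rand_dna(2000, seed = 52)
  b1 <- build_index(c(a = g), mask = "####_####")
  b2 <- build_index(c(a = g, b = g), mask = "####_####")
  expect_equal(b1$report$keys, b2$report$keys)
})

test_that("built index matches brute-force code sets with zero FN (and zero FP when exact)", {
  g <- rand_dna(10000, seed = 53)
  want <- unique(oracle_extract(g, "####_####")$code)
  for (structure in c("exact", "filter")) {
    b <- build_index(c(chr = g), mask = "####_####", structure = structure)
    expect_true(all(cuckoo_lookup(b$index, want)), info = structure)
    expect_equal(b$report$keys, length(want), info = structure)
  }
  bx <- build_index(c(chr = g), mask = "####_####")
  set.seed(54)
  absent <- setdiff(floor(runif(20000) * 4^8), want)
  expect_false(any(cuckoo_lookup(bx$index, absent)))
})

test_that("FASTA files (plain and gzipped) are accepted as input", {
  g <- rand_dna(3000, seed = 55)
  fa <- withr::local_tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(c(c1 = g)), fa)
  fagz <- withr::local_tempfile(fileext = ".fa.gz")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(c(c1 = g)), fagz,
                              compress = TRUE)
  b1 <- build_index(fa, mask = "####_####")
  b2 <- build_index(fagz, mask = "####_####")
  expect_equal(b1$report$keys, b2$report$keys)
  expect_gt(b1$report$keys, 0)
})

test_that("variant fragments carry the flanked alternative sequence", {
  g <- rand_dna(1000, seed = 56)
  # SNV at position 100: 50 left + 1 alt + 50 right = 101 bases
  snv <- data.frame(pos = 100L, ref = substr(g, 100, 100),
                    alt = setdiff(c("A", "C"), substr(g, 100, 100))[1],
                    af = 0.5)
  av <- apply_variants(g, snv, min_af = 0.01, flank = 50)
  expect_equal(av$n_applied, 1L)
  expect_equal(nchar(av$fragments), 101L)
  expect_equal(av$fragments,
               paste0(substr(g, 50, 99), snv$alt, substr(g, 101, 150)))

  # low-frequency variant is filtered out
  rare <- transform(snv, af = 0.005)
  av2 <- apply_variants(g, rare, min_af = 0.01, flank = 50)
  expect_equal(av2$n_applied, 0L)
  expect_equal(av2$n_filtered_af, 1L)
  expect_length(av2$fragments, 0)

  # 3 bp deletion (VCF shared-leading-base) near the sequence start:
  # left context is clipped at the boundary
  del <- data.frame(pos = 8L, ref = substr(g, 8, 11), alt = substr(g, 8, 8),
                    af = 0.9)
  av3 <- apply_variants(g, del, min_af = 0.01, flank = 50)
  # normalized deletion removes bases 9..11 (1-based); left = 8, right = 50
  expect_equal(nchar(av3$fragments), 8 + 0 + 50)
  expect_equal(av3$fragments, paste0(substr(g, 1, 8), substr(g, 12, 61)))
})

test_that("REF mismatches are warned about and skipped", {
  g <- "ACGTACGTACGTACGT"
  bad <- data.frame(pos = 3L, ref = "T", alt = "A", af = 0.5)  # actual is G
  expect_warning(av <- apply_variants(g, bad), "mismatch")
  expect_equal(av$n_ref_mismatch, 1L)
  expect_length(av$fragments, 0)
})

test_that("VCF round-trip through the independent parser feeds the index", {
  g <- rand_dna(5000, seed = 57)
  vars <- synth_vcf(g, 12, afs = c(0.005, 0.5), seed = 58, chrom = "chr")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vars, vcf, contig_length = 5000)
  parsed <- read_vcf_variants(vcf)
  expect_equal(nrow(parsed), 12)
  expect_equal(parsed$pos, vars$pos)
  expect_equal(parsed$af, vars$af)

  plain <- build_index(c(chr = g), mask = "####_####")
  aug <- build_index(c(chr = g), mask = "####_####", vcf = vcf)
  # augmentation only adds keys, and applies exactly the af >= 1% records
  expect_gte(aug$report$keys, plain$report$keys)
  expect_equal(aug$report$variants$n_applied, sum(vars$af >= 0.01))
  expect_equal(aug$report$variants$n_filtered_af, sum(vars$af < 0.01))
  base_codes <- unique(oracle_extract(g, "####_####")$code)
  expect_true(all(cuckoo_lookup(aug$index, base_codes)))
  # fragment codes are present too (recomputed independently)
  av <- apply_variants(g, vars, min_af = 0.01, flank = 50)
  for (fr in av$fragments) {
    fc <- oracle_extract(fr, "####_####")$code
    if (length(fc)) expect_true(all(cuckoo_lookup(aug$index, fc)))
  }
})

test_that("index builds are deterministic given inputs and seed", {
  g <- rand_dna(4000, seed = 59)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  save_index(build_index(c(a = g), mask = "####_####", seed = 3), p1)
  save_index(build_index(c(a = g), mask = "####_####", seed = 3), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("stats report bits per key from slot width and load", {
  g <- rand_dna(3000, seed = 60)
  bf <- build_index(c(a = g), mask = "####_####", structure = "filter")
  s <- index_stats(bf)
  expect_equal(s$structure, "filter")
  expect_equal(s$bits_per_key, 16 / s$load)
  expect_equal(s$k, 8)
  expect_equal(s$w, 9)
})
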
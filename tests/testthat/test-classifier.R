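# One shared medium fixture: 50 kb host genome indexed exactly under the
# default (29,33) mask, plus an unrelated foreign genome.
host <- synth_genome(50000, seed = 71)
foreign <- synth_genome(50000, seed = 72)
bx <- build_index(c(host1 = host), size_estimate = 5e4)

test_that("an exact genomic substring is fully covered in sensitive mode", {
  read <- substr(host, 2001, 2150)
  r <- classify_reads(read, bx, "sensitive", 0.5)
  expect_equal(r$read_length, 150)
  expect_equal(r$windows_queried, 150 - 33 + 1)
  expect_equal(r$windows_hit, r$windows_queried)
  expect_equal(r$covered_bases, 150)
  expect_true(r$is_host)
  # reverse-complement strand is equivalent under canonical codes
  rrc <- classify_reads(revcomp_str(read), bx, "sensitive", 0.5)
  expect_equal(rrc$covered_bases, 150)
})

test_that("reads shorter than the window and non-matching reads are non-host", {
  short <- substr(host, 100, 100 + 31)             # length 32 < w = 33
  r <- classify_reads(short, bx)
  expect_equal(r$windows_queried, 0)
  expect_equal(r$covered_bases, 0)
  expect_false(r$is_host)

  f <- classify_reads(substr(foreign, 1000, 1149), bx)
  expect_equal(f$windows_hit, 0)                   # exact store: no FP
  expect_equal(f$covered_bases, 0)
  expect_false(f$is_host)
})

test_that("sampling mode queries a fixed offset grid and marks whole windows", {
  read <- substr(host, 5001, 5150)
  r <- classify_reads(read, bx, "sampling", 0.5)
  # step = floor(33/2) + 1 = 17; offsets 0,17,...,102
  expect_equal(r$windows_queried, 7)
  expect_equal(r$windows_hit, 7)
  expect_equal(r$covered_bases, 135)               # union [0,135)
  expect_true(r$is_host)

  # every position in [0,135) lies in 1 or 2 sampled windows
  offs <- seq(0, 150 - 33, by = 17)
  hits <- tabulate(unlist(lapply(offs, function(i) (i + 1):(i + 33))),
                   nbins = 150)
  expect_true(all(hits[1:135] >= 1 & hits[1:135] <= 2))
  expect_true(all(hits[136:150] == 0))
})

test_that("the host decision threshold is inclusive", {
  # read: 75 host bases then 75 foreign bases -> exactly 75 covered
  read <- paste0(substr(host, 10001, 10075), substr(foreign, 20001, 20075))
  r <- classify_reads(read, bx, "sensitive", 0.5)
  expect_equal(r$covered_bases, 75)
  expect_true(r$is_host)                            # 75 >= 0.5 * 150
  expect_false(classify_reads(read, bx, "sensitive", 0.51)$is_host)
})

test_that("threshold edge cases behave as documented", {
  f <- substr(foreign, 100, 249)
  expect_true(classify_reads(f, bx, threshold = 0)$is_host)   # T=0: everything
  h <- substr(host, 30001, 30150)
  expect_true(classify_reads(h, bx, threshold = 1)$is_host)   # full coverage
  one_sub <- h
  substr(one_sub, 75, 75) <- setdiff(c("A", "C"), substr(h, 75, 75))[1]
  expect_false(classify_reads(one_sub, bx, threshold = 1)$is_host)
})

test_that("raising the threshold never turns a non-host read into host", {
  set.seed(73)
  reads <- c(vapply(1:50, function(i) {
    s <- sample(49000, 1)
    r <- substr(host, s, s + 149)
    mutate_pos <- sample(150, sample(0:8, 1))
    for (p in mutate_pos)
      substr(r, p, p) <- sample(c("A", "C", "G", "T"), 1)
    r
  }, ""), vapply(1:20, function(i) {
    s <- sample(49000, 1)
    substr(foreign, s, s + 149)
  }, ""))
  prev <- rep(TRUE, length(reads))
  for (T in c(0, 0.25, 0.5, 0.75, 1)) {
    cur <- classify_reads(reads, bx, "sensitive", T)$is_host
    expect_true(all(prev | !cur))                  # cur implies prev
    prev <- cur
  }
})

test_that("windows containing N count as queried but never hit", {
  read <- substr(host, 40001, 40150)
  substr(read, 60, 60) <- "N"
  r <- classify_reads(read, bx, "sensitive", 0.5)
  expect_equal(r$windows_queried, 118)
  expect_equal(r$windows_hit, 118 - 33)            # offsets 27..59 blocked
  expect_true(r$is_host)
  allN <- strrep("N", 100)
  rn <- classify_reads(allN, bx)
  expect_equal(rn$windows_hit, 0)
  expect_false(rn$is_host)
})

test_that("pair decisions remove the pair if either end is host", {
  h <- substr(host, 1001, 1150)
  f <- substr(foreign, 1001, 1150)
  expect_true(classify_pair(h, f, bx)$remove_pair)
  expect_true(classify_pair(f, h, bx)$remove_pair)   # symmetric
  expect_false(classify_pair(f, f, bx)$remove_pair)
  expect_true(classify_pair(h, h, bx)$remove_pair)
})

test_that("filter_fastq partitions single-end input losslessly", {
  hr <- sample_reads(host, 60, 150, 0, seed = 74, id_prefix = "h")
  fr <- sample_reads(foreign, 40, 150, 0, seed = 75, id_prefix = "f")
  recs <- rbind(hr$reads, fr$reads)
  recs <- recs[sample(nrow(recs)), ]
  fin <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(recs, fin)
  kept <- withr::local_tempfile(fileext = ".fastq")
  rem <- withr::local_tempfile(fileext = ".fastq")
  s <- filter_fastq(fin, kept, bx, removed = rem)
  expect_equal(s$total, 100)
  expect_equal(s$removed, 60)
  expect_equal(s$retained, 40)
  k <- read_fastq(kept); r <- read_fastq(rem)
  expect_equal(nrow(k) + nrow(r), 100)
  expect_true(all(grepl("^@f", k$header)))
  expect_true(all(grepl("^@h", r$header)))
  # retained records preserve order and bytes
  want <- recs[grepl("^f", recs$id), ]
  expect_equal(k$seq, want$seq)
  expect_equal(k$header, paste0("@", want$id))
  expect_equal(k$qual, want$qual)
})

test_that("filter_fastq on empty input yields empty output and zero counts", {
  fin <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(), fin)
  kept <- withr::local_tempfile(fileext = ".fastq")
  s <- filter_fastq(fin, kept, bx)
  expect_equal(s$total, 0)
  expect_equal(s$removed, 0)
  expect_equal(s$retained, 0)
  expect_equal(file.size(kept), 0)
})

test_that("paired filtering removes whole pairs and validates inputs", {
  pr <- sample_reads(host, 30, 100, 0, seed = 76, paired = TRUE,
                     insert_size = 260, id_prefix = "hp")
  fr <- sample_reads(foreign, 30, 100, 0, seed = 77, paired = TRUE,
                     insert_size = 260, id_prefix = "fp")
  # make 10 chimeric pairs: host end 1, foreign end 2
  r1 <- rbind(pr$reads1, fr$reads1[1:10, ], fr$reads1[11:30, ])
  r2 <- rbind(pr$reads2, pr$reads2[1:10, ], fr$reads2[11:30, ])
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fastq(r1, f1); write_fastq(r2, f2)
  k1 <- withr::local_tempfile(); k2 <- withr::local_tempfile()
  s <- filter_fastq(f1, k1, bx, reads2 = f2, out2 = k2)
  expect_equal(s$total, 60)                        # pairs as units
  expect_equal(s$removed, 40)                      # 30 host + 10 chimeric
  expect_equal(s$retained, 20)
  out1 <- read_fastq(k1); out2 <- read_fastq(k2)
  expect_equal(nrow(out1), 20)
  expect_equal(out1$header, paste0("@", fr$reads1$id[11:30]))
  expect_equal(out2$header, paste0("@", fr$reads2$id[11:30]))

  # unequal record counts are an error
  f3 <- withr::local_tempfile()
  write_fastq(r2[1:10, ], f3)
  expect_error(filter_fastq(f1, k1, bx, reads2 = f3, out2 = k2), "unequal")
  expect_error(filter_fastq(f1, k1, bx, reads2 = f2), "out2")
  expect_error(filter_fastq(f1, k1, bx, out2 = k2), "reads2")
})

test_that("exact and filter stores agree on nearly all classifications", {
  bf <- build_index(c(host1 = host), structure = "filter",
                    size_estimate = 5e4)
  hr <- sample_reads(host, 500, 150, 0.01, seed = 78)
  fr <- sample_reads(foreign, 500, 150, 0, seed = 79)
  reads <- c(hr$reads$seq, fr$reads$seq)
  a <- classify_reads(reads, bx)$is_host
  b <- classify_reads(reads, bf)$is_host
  expect_gte(mean(a == b), 0.999)
})
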
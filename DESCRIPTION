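Package: hostsieve
Title: Alignment-Free Host-Read Depletion with Gapped k-mer Cuckoo Indexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes host (e.g. human) contamination from microbiome sequencing
    reads without alignment. A reference genome or pangenome is indexed as the
    set of canonical gapped k-mers (spaced seeds) under a symmetric mask, stored
    either exactly in a multi-way bucketed Cuckoo hash table or probabilistically
    in a windowed Cuckoo filter of p-bit fingerprints. Reads are classified as
    host if the fraction of their bases covered by matching seeds reaches a
    threshold, in a sensitive mode (query every window) or a faster sampling
    mode, and FASTQ files (single- or paired-end, optionally gzipped) are
    filtered in streaming fashion. Includes a brute-force certifier for the
    substitution-robustness guarantee of a mask, VCF-based pangenome
    augmentation, deterministic synthetic fixtures, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    vcfR,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
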
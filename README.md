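# hostsieve

Alignment-free removal of host (e.g. human) reads from microbiome
sequencing data, in R with a C++ core.

Microbiome samples taken from a host inevitably contain host DNA. It must
be removed before publication (human reads are personal data) and before
downstream analysis (host reads distort profiling, binning and assembly).
`hostsieve` does this without alignment: the host genome — optionally a
pangenome augmented with population variants — is indexed as the set of its
*canonical gapped k-mers* (spaced seeds), and each read is classified by
how much of it is covered by seeds found in the index.

## Method

A **(k, w)-mask** is a string over `{#, _}` of width *w* with *k*
significant positions (`#`), symmetric, starting and ending with `#`. The
default is the (29,33) mask

```
######_#######_###_#######_######
```

Each window of *w* bases yields a gapped k-mer: the bases at the
significant positions. It is encoded as a base-4 integer with digits
**A=0, C=1, T=2, G=3** (note: not the usual A,C,G,T order; the complement
of a digit is the digit XOR 2), and represented by its **canonical code**

```
cc(x) = max{ enc(x), enc(rc(x)) }
```

so both strands map to the same integer. Gaps make the seed robust to
substitutions: a single SNV destroys only the windows that see it at a
significant position. `min_coverage()` certifies the guarantee
exhaustively: for the default mask, any 100 bp stretch matching the genome
with at most 3 substitutions keeps **at least 50 covered positions**.

The code set is stored in one of two interchangeable structures:

* an **exact (3,4) bucketed Cuckoo hash table** (full codes, zero false
  positives, usable up to ~98–99% load), or
* a **probabilistic (2,2) windowed Cuckoo filter** storing 16-bit
  fingerprints in overlapping 2-slot windows, operated at 95% load —
  about 16/0.95 ≈ 16.8 bits per key — with false positive rate bounded by
  `d·l·2^-p = 2^-14 < 1/16000` and no false negatives.

A read *s* is classified as host when at least `T·|s|` of its bases are
covered by matching seeds (default `T = 0.5`), in one of two modes:

* **sensitive** — query every window; a hit marks its significant
  positions as covered;
* **sampling** — query every `floor(w/2)+1`-th window; a hit marks all
  *w* window positions as covered (faster, slightly less sensitive).

For paired-end data the pair is removed if either end is host.

## Worked example

```r
library(hostsieve)

# canonical codes of the k-mers of TACGCGTAAG, k = 5
encode_kmer("TACGC")                  # 541
revcomp_code(541, 5)                  # 888   (GCGTA)
canonical_code(541, 5)                # 888

# gapped extraction under the (5,7)-mask ##_#_##
extract_gapped("TACGCGTAAG", "##_#_##")
#   offset code
# 1      0  574
# 2      1  574
# 3      2  663
# 4      3  867

# certify the default mask's substitution guarantee
min_coverage(default_mask(), L = 100, s_max = 3)
# [1] 50

# index a (synthetic) host genome and filter reads
host <- synth_genome(2e6, seed = 1)
b    <- build_index(c(host1 = host), structure = "exact")
r    <- sample_reads(host, 5, 150, substitution_rate = 0.01, seed = 2)
classify_reads(r$reads$seq, b, mode = "sensitive", threshold = 0.5)
#   read_length windows_queried windows_hit covered_bases is_host
# 1         150             118          89           149    TRUE
# 2         150             118          89           142    TRUE
# 3         150             118         118           150    TRUE
# 4         150             118          80           148    TRUE
# 5         150             118          89           149    TRUE
```

Each 150 bp read exposes 118 windows of the (29,33) mask; a read sampled
with 1% substitution errors still has nearly all its bases covered by
surviving seeds, comfortably above the 75-base threshold.

The command line mirrors the R API (`exec/hostsieve`):

```sh
hostsieve index  --structure filter --out host.idx host.fasta \
                 --vcf common.vcf --min-af 0.01 --flank 50
hostsieve filter --index host.idx --reads r1.fq.gz --reads2 r2.fq.gz \
                 --out clean1.fq.gz --out2 clean2.fq.gz --mode sampling
hostsieve stats  --index host.idx
```

On the small built-in fixture set (`hostsieve fixtures --preset small`),
`index` reports `49968 windows (0 skipped), 49968 keys, load 0.880` and
`filter` prints `filtered 1000 reads: removed 500 (host), retained 500` —
all 500 synthetic host reads removed, all 500 foreign reads kept. The
summary is also available as JSON via `--json-summary`.

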
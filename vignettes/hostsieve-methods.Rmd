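---
title: "Host-read depletion with gapped k-mers: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host-read depletion with gapped k-mers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostsieve)
```

## The problem and the model

Sequencing a host-associated microbiome yields a mixture of microbial
reads and host reads. The host reads must go: they are personal data when
the host is human, and they bias downstream profiling and assembly.
`hostsieve` removes them without alignment. The host genome is reduced to
the set of its **canonical gapped k-mers** under a spaced-seed mask, that
set is stored in a membership structure, and each read is classified by
the fraction of its bases covered by seeds found in the structure.

### Seeds and canonical codes

A `(k, w)`-mask is a string over `{#, _}` of width `w` with `k`
significant positions. Masks must begin and end with `#` (otherwise the
effective window is narrower than claimed) and be **symmetric**, which
makes the code of a window and the code of its reverse complement
computable from the same significant positions. Bases are encoded as
base-4 digits `A=0, C=1, T=2, G=3` — deliberately not the common
`A,C,G,T` digit order — so that the complement of a digit is the digit
XOR 2 and reverse complements can be computed on integers. A seed `x` is
represented by the canonical code `cc(x) = max(enc(x), enc(rc(x)))`; the
**maximum**, where many k-mer tools take the minimum. Both conventions
are self-consistent; all worked examples and stored indexes here depend
on the max convention.

Windows containing any character outside `A/C/G/T` (case-insensitive) are
skipped during indexing and counted as queried-but-missed during
classification: the index contains only fully defined seeds, and an
undefined base can never support host evidence.

### Why gapped: the coverage guarantee

A substitution destroys every *contiguous* k-mer that overlaps it, but
only those *gapped* k-mers that see it at a significant position.
`min_coverage()` certifies this exhaustively rather than by simulation:
it enumerates every set of at most `s_max` substitution positions in a
length-`L` region, kills the seed placements whose significant positions
are hit, and reports the worst-case size of the union of covered
positions of the surviving placements. For the default (29,33) mask,

```r
min_coverage(default_mask(), L = 100, s_max = 3)
```

returns 50: any 100 bp stretch of a read that matches the genome with at
most three substitutions keeps at least half its positions covered, which
is exactly the default classification threshold. Two counting semantics
are available: `"significant"` (default) counts only significant
positions of surviving placements, matching how sensitive-mode
classification marks coverage; `"window"` counts whole windows, matching
sampling-mode marking. The certifier works on 192-bit position sets and
refuses enumerations beyond a configurable budget (default 10^7
substitution sets), since the subset count grows as `choose(L, s_max)`.

## The two stores

Both stores resolve collisions the Cuckoo way: each key has `d`
admissible locations, and insertion may displace residents along a
bounded random walk.

**Exact bucketed table.** `n` slots in `ceiling(n/l)` disjoint buckets of
`l`; a key may live in any slot of the `d` buckets given by `d` seeded
hash functions (odd-multiplier 64-bit mixing, reduced to the bucket
range). Full canonical codes are stored (64-bit slots), so membership is
exact in both directions. The configuration (3,4) sustains ~98–99% load.
Compressed (quotiented) key storage would roughly halve this footprint
but is deliberately out of scope; exactness is kept by storing full
codes.

**Windowed filter.** `n` slots covered by *overlapping* windows of `l`
slots, one starting at every slot; only a `p`-bit fingerprint per key is
stored (value 0 is reserved for "empty"; fingerprint 0 is remapped to 1,
so value 1 is about twice as likely as any other — the false-positive
bound is unaffected). A lookup compares the query's fingerprint against
the `d*l` slots of its two windows, so an absent key is falsely reported
present with probability at most `d*l*2^-p`; inserted keys are always
found. The overlapping layout packs tighter than disjoint buckets at
equal `(d, l)`: the suite demonstrates (2,2) windowed sustaining 95%
load where (2,2) bucketed saturates well below it. At `p = 16` and 95%
load the filter costs `16/0.95 = 16.8` bits per key with FPR bounded by
`2^-14 < 1/16000`.

### Numerical and structural choices

* **Partner addressing.** The number of windows is rounded up to a power
  of two (with `l − 1` padding slots) so that a fingerprint's two
  admissible windows are linked by `w2 = w1 XOR h(fp)` — an involution
  that depends only on the fingerprint, so relocation never needs the
  original key. The XOR offset is forced nonzero.
* **Home-offset tags.** A slot belongs to `l` overlapping windows, so the
  window a fingerprint was stored *for* is not recoverable from the slot
  index alone. Each slot therefore carries a `ceil(log2 l)`-bit tag
  giving the slot's offset from its home window; relocation computes the
  partner of `slot − tag`. This costs one extra bit per slot at `l = 2`
  beyond the `p` fingerprint bits (visible in the serialized file size).
* **Eviction effort (`max_kicks`).** The table default is 500 kicks: at
  (3,4), each displaced key has 11 alternative slots and the walk mixes
  fast, reaching ~99% load. The filter default is 10,000: at (2,2) a
  displaced fingerprint has exactly one alternative window (two slots),
  the walk is nearly a path, and short walks stall around 92–93% —
  measurably below both the structure's capacity (~96.3% with unbounded
  kicks) and its 95% operating point. 10,000 kicks reach 95.8–95.9%
  across seeds; below capacity the *expected* insertion cost remains
  small, the bound only caps the tail.
* **Failure is clean.** A failed insert rolls the eviction walk back, so
  the store is unchanged and the no-false-negative guarantee survives
  failures. Index building reacts to a failure (or to exceeding the
  target fill) by rebuilding with 1.5x slots, then with a different hash
  seed, then giving up — at most three attempts.
* **Duplicates.** Inserts are preceded by a lookup and duplicates succeed
  as no-ops; genome k-mer multisets collapse to sets. In the filter this
  deduplication acts at fingerprint granularity, which is the filter's
  native notion of identity.
* **Measurement harnesses.** `fill_to_load()` draws uniformly random
  58-bit keys (the code range of a weight-29 mask); `measure_fpr()` draws
  queries from `[2^58, 2^59)`, a range disjoint from the insertion
  keyspace, so absence is guaranteed by construction instead of tracked.
* **Serialization.** Little-endian, versioned: magic, format version,
  structure parameters, hash seed, key count, the attached mask string,
  then the raw slot array. Loading validates magic, version and payload
  length. The flat layout is deliberately memory-map friendly.

## Index construction

`build_index()` streams FASTA references (gzip transparently), extracts
every valid window's canonical code and inserts it. Sizing uses the total
window count as the distinct-key estimate (a safe overestimate) against a
target fill of 0.88 (exact) or 0.95 (filter).

A VCF of population variants can augment the index: every record with
INFO `AF` at least `min_af` (default 1%) is applied to the reference
individually — no haplotype combinations — and the altered sequence plus
`flank` (default 50) reference bases on each side is indexed as an extra
fragment. VCF 1-based coordinates and the shared-leading-base indel
convention are normalized to 0-based half-open replacement intervals
first, so a pure deletion contributes flanks only. The flank is taken
around the replaced allele, the natural reading of "context around the
new sequence". Records whose REF allele contradicts the reference are
skipped with a warning and counted. Multi-allelic records are split, one
variant per ALT with its own AF. Additional collections — HLA alleles,
cDNA, further assemblies — need no special handling: they are simply more
FASTA inputs.

## Classification

Coverage is accumulated per read as a set of base positions:

* **sensitive** queries every window offset and marks the significant
  positions of hits — maximal evidence, `L − w + 1` lookups per read;
* **sampling** queries offsets `0, s, 2s, ...` with
  `s = floor(w/2) + 1` and marks *all* `w` window positions of hits, so
  every base can be covered by up to two queried windows; for
  `w = 33, L = 150` that is 7 lookups instead of 118. Offsets advance on
  a fixed grid from 0; no final window is force-queried (the simplest
  reading of "skip the next `floor(w/2)` k-mers", and the choice keeps
  query positions independent of read length).

A read is host when `covered >= T * L` — inclusive, so at `T = 0` every
read is host (a documented edge) and a read of exactly `T * L` covered
bases is removed. Reads shorter than `w` query nothing and are always
retained; they are counted separately in filtering summaries. Raising `T`
can only move reads from host to non-host, never the reverse. For pairs,
each end is classified independently and the pair is removed when either
end is host.

Using the filter instead of the exact table perturbs classification only
negligibly at `T = 0.5`: a false-positive lookup adds at most `w` covered
bases, far below `T * L` for reads longer than `2w/T`, so several
spurious hits would be needed — the suite measures >= 99.9% per-read
agreement between the stores on 2x10^5 reads. The caveat is very short
reads, where one window hit can decide the classification.

## The synthetic benchmark: what it shows, and what it cannot

The fixtures module generates everything the tests consume: a uniform
ACGT genome, reads drawn from uniform positions and strands with i.i.d.
substitution errors (never to the same base), proper forward/reverse
pairs at a fixed insert size, truth tables, and a small syntactically
valid VCF. All generators are pure functions of their seed and leave the
caller's RNG state untouched.

The benchmark conditions are: a 2 Mb host genome, an *independently
generated* 2 Mb foreign genome (so negative reads have genome-like k-mer
composition rather than being uniform strings), 10^5 host reads of
150 bp with 1% substitutions, and 10^5 foreign reads. The acceptance
suite computes: >= 99% of host reads removed in sensitive mode at
`T = 0.5`, 100% of foreign reads retained on the exact store, and
exact/filter agreement >= 99.9%.

Sampling mode is *measurably* less sensitive under these conditions: at a
1% substitution rate a queried window survives with probability
`0.99^29 ≈ 0.75`, only 7 windows are queried per 150 bp read, and
crossing `T = 0.5` needs at least three non-adjacent hits — so a
percent-scale fraction of host reads (about 6–7 percentage points in the
suite's benchmark; an independent Monte Carlo over substitution positions
gives the same figure) falls below threshold in sampling mode while
sensitive mode still removes it. At the much lower error rates of real
short-read data this gap shrinks to fractions of a percent; the 1%
benchmark rate is deliberately harsh and the measured gap should be read
as a property of that rate, not of real sequencing data.

More generally, the generator does not emulate quality-dependent error
profiles, indels, long-read noise, shared k-mer content between host and
contaminant genomes, or real pangenome redundancy — passing the benchmark
shows the machinery is correct and calibrated on its own terms, not that
these accuracy figures transfer to any particular real dataset.

## Problem sizes used by the checks

The acceptance checks run at: 10^6 slots for both load experiments (three
seeds each; the weakest run is what counts), 4x10^7 absent-key queries
for the FPR measurement, the full 166,751-subset enumeration for the mask
guarantee, 2x10^5 mixed probes for store/oracle equivalence, 10^4 random
sequences for extraction/oracle equivalence, and the 2x10^5-read
benchmark above. Unit tests use smaller instances of the same
constructions.

## Known limitations

* The exact table stores full 64-bit codes; the quotienting tricks that
  compress exact Cuckoo storage are not implemented.
* Single-process streaming; `--threads` is accepted for workflow
  compatibility but advisory. Chunked, order-preserving processing keeps
  the door open for parallel classification.
* Paired input as two parallel files only; interleaved format is not
  supported.
* R-facing scalar code helpers (`encode_kmer` etc.) are exact only to
  `k = 26` (doubles); heavier masks are handled entirely inside the C++
  pipeline, which is why `extract_gapped()` refuses them while
  `build_index()`/`classify_reads()` do not.
* Mask *design* is out of scope: `min_coverage()` verifies a given mask,
  it does not search for good ones.
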
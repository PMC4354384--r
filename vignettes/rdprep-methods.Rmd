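---
title: "Preparing read-depth signals for CNV detection: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preparing read-depth signals for CNV detection: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rdprep` implements the data-preparation and normalization stages that sit
in front of read-depth (RD) CNV calling: quality control of FASTQ reads,
alignment-free duplicate removal, post-filtering of SAM alignments, and
construction of a GC-corrected windowed depth signal. This vignette explains
the underlying models, the tunable parameters, and the design decisions
taken where the problem left genuine latitude. Everything quantitative
stated here is recomputed by the test suite or by `scripts/acceptance.R`;
nothing is asserted from memory.

## The read-depth model

Under uniform sequencing, the number of reads whose footprint centers fall
in a fixed window of length $L$ is approximately Poisson with mean
proportional to $L$ and to the local copy number. Two artifacts distort
this: PCR duplicates inflate counts multiplicatively, and sequencing depth
varies systematically with the GC content of the window. The pipeline
therefore (i) removes duplicates *before* alignment counting, and
(ii) rescales the counts per GC stratum afterwards. The ideal-aligner
simulator (`ideal_alignment_sam()`) generates the null situation — uniform
placement, no errors, unique mappings — and the test suite checks that the
resulting window counts have a variance-to-mean ratio inside $[0.8, 1.2]$,
i.e. are consistent with the Poisson model the downstream callers assume.

## Quality model

FASTQ quality strings are ASCII-encoded Phred scores with a
platform-dependent offset. Three Illumina conventions are supported
(`quality_encodings()`): Illumina 1.0 (Solexa, offset 64, scores $-5..62$,
ASCII 59–126), Illumina 1.3–1.7 (offset 64, scores $0..62$, ASCII 64–126)
and Illumina 1.8+ (offset 33, scores $0..93$, ASCII 33–126). The three
ASCII ranges overlap above 64, so only the *minimum* observed code
discriminates: below 59 forces 1.8+, 59–63 forces 1.0, and otherwise 1.3 is
assumed. `detect_encoding()` samples the first 10,000 reads by default —
enough that any library with sub-64 codes anywhere almost surely shows one
in the sample — and an explicit `quality_encoding()` overrides detection.
Solexa scores are treated as plain offset-64 integers and compared directly
against the user's threshold; the historical odds-based score
transformation is deliberately not applied, since the filters only ever
compare scores to a threshold.

A base is *low quality* when its score is strictly below `qual_threshold`
(default 20). A read is removed when its percentage of low-quality bases
strictly exceeds $100 - \text{min\_good\_pct}$ (default 90, i.e. an
allowance of 10%): a 100 bp read with 11 low-quality bases is removed, one
with exactly 10 is kept. The strictness of both inequalities is a
deliberate reading of "exceeds"; the boundary case is pinned by a test.
Percentages are computed over the full read length, with `N` bases carrying
their own scores. In paired mode a pair is removed when either mate fails,
keeping mate files synchronized. Masking (`mask_low_quality()`) replaces
sub-threshold bases with `N`, never touches the quality string, and is
idempotent.

## Integer encodings for duplicate removal

Duplicate removal is alignment-free and exploits the Illumina error
profile: substitution errors increase towards the 3' end while indels are
rare, so true PCR duplicates almost always agree on a prefix and differ by
substitutions only. Reads are clustered by identical $k$-prefix and each
cluster is collapsed greedily.

Two integer encodings, both over the digit map A→0, C→1, G→2, T→3, N→4, do
the heavy lifting:

* **Prefix keys** are base-5 positional values,
  $\sum_i d_i 5^{k-1-i}$. The encoding is injective and strictly
  order-preserving for $k \le 27$ because $5^{27} < 2^{64} < 5^{28}$;
  `prefix_capacity()` computes the limit at run time by exact unsigned
  arithmetic rather than hard-coding it. Clustering is a stable sort of
  (key, original index) followed by run detection, and is verified against
  a hash-grouping oracle.
* **Chunk codes** concatenate the same digits as a *decimal* number, e.g.
  `NT` → 43. Any string of up to 19 digits fits, since
  $10^{19} < 2^{64}$ (`chunk_capacity()`). The decimal form is what makes
  mismatch localization arithmetic: when two equal-length chunk codes
  differ, the order of magnitude of their difference pins the leftmost
  differing base, so the comparison can count a mismatch, truncate both
  codes below it, and continue — skipping runs of equal bases in O(1) and
  aborting early once the allowed mismatch count $m$ is exceeded.

One numerical subtlety deserves record. With digits restricted to 0–4, the
leading differing digit contributes at least $10^p$ to the difference while
all lower digits contribute less than $0.445 \cdot 10^p$ — but the lower
digits can *partially cancel* the leading contribution, pulling the
magnitude to $p-1$ (codes 03 vs 10 differ by 7, yet their leftmost mismatch
is at the tens digit). Truncating at the naive $\lfloor\log_{10}|x-y|\rfloor$
silently drops a real mismatch in exactly these cases. The implementation
therefore compares the single digit at power $q+1$ (where $q$ is the
observed magnitude) to disambiguate between $p = q$ and $p = q+1$, which
restores exactness at negligible cost. The property is enforced
exhaustively: over *every* ordered pair of strings of length up to 6 on the
5-letter alphabet, the chunked counter equals a naive character-comparison
Hamming oracle, both uncapped and under early stopping; randomized checks
repeat this at read scale (length 75).

Greedy collapse takes the first remaining cluster member (lowest original
index) as seed; members of equal length within $m$ suffix mismatches are
its duplicates and the group is condensed to a per-position majority
consensus (ties resolve to the seed's base; id and quality string come from
the seed). Reads of unequal length are never duplicates — the no-indel
assumption — and reads shorter than $k$ bypass deduplication entirely.
Subsequent seeds are compared against the original reads, not against
consensus sequences, keeping the procedure order-deterministic. Surviving
representatives of equal length within a cluster are pairwise more than $m$
apart, and removal counts are monotone in $m$; both are tested properties.

## Alignment post-filtering

`filter_mapq()` drops unmapped records and keeps mapped ones with
MAPQ ≥ threshold (inclusive, since the threshold describes what must be
reported). `resolve_multimappers()` groups by query name; the best set
maximizes the `AS` alignment score where present, falling back to MAPQ.
Unique-best emits a read only when its best set is a singleton; random-best
draws uniformly from the best set using a seeded generator — implemented as
one seeded uniform draw per record with the largest draw winning among
tied-best records, which is reproducible given input order and seed and is
χ²-tested for uniformity across seeds.

## Windowed GC signal and correction

Windows tile each chromosome with fixed length $L$ (user-set; the last
window may be short) in 0-based half-open coordinates, while SAM input
stays 1-based — the conversion happens in `assign_window()`, which by
default assigns each alignment to the window containing the center of its
reference-consumed footprint, $\lfloor (2\,\text{pos} + \text{span} - 1)/2
\rfloor$, so clipped or gapped alignments center on what they actually
cover. Window GC is the integer percentage of G+C among informative (non-N)
bases, rounded half up. A window with fewer than $L/2$ informative bases is
flagged invalid: this excludes N-rich windows *and* short terminal windows
from the correction statistics, since both have systematically deflated
counts. Invalid windows keep their raw value, flagged uncorrected.

Correction rescales each valid window by the ratio of the global mean depth
to its GC-bin mean:
$RD'_w = \frac{\overline{RD}}{\overline{RD}_{GC(w)}} \, RD_w$.
Statistics are computed per chromosome by default, with a
`scope = "genome"` switch — per-chromosome is the conservative default
because chromosome-scale depth differences (e.g. sex chromosomes) would
otherwise leak into the GC profile. Two exact invariants follow and are
tested at $10^{-9}$ relative tolerance: after correction, the mean of
corrected depth within every GC bin equals the global mean, and hence the
global mean is preserved. Conservation ($\sum RD_w$ = number of assigned
alignments) holds for every rule and window length. A window with positive
count always contributes to its own bin, so a positive count with a zero
bin mean is impossible; the code asserts this internal consistency.

## The synthetic-data generators

The generators define the conditions under which the pipeline is validated.

* **Reference**: i.i.d. bases at a specified GC fraction (scalar,
  per-chromosome, or region overrides), so expected window GC is known.
* **Reads**: sampled uniformly (forward strand) from the reference.
  Substitution errors follow $p(i) = A e^{s\,i/L}$ with shape $s = 3$ and
  $A$ fixed so the mean equals the 2% target — an exponential-decay curve
  reproducing the position-increasing Illumina error profile; the precise
  shape constant is this package's choice, and with $s = 3$ the 3' end sees
  roughly three times the mean rate. Fragment lengths are
  $\mathcal{N}(150, 50)$ (a realistic short-insert library; roughly 16% of
  fragments fall under the 100 bp read length and get 3' adapter
  read-through, clamped so the 32-base adapter prefix exactly fills the
  read). Quality strings enforce *exact* quotas — by default 9% of reads
  fail the filter rule and 3% of bases score below 20 — by assigning each
  designated low-quality read just over the allowance and distributing the
  remaining low-quality base budget over the other reads up to their cap;
  erroneous bases preferentially receive the low scores. Infeasible quota
  combinations raise a configuration error up front. Good-read scores are
  drawn from 28–40 and low scores from 2–19, cleanly separated from the
  threshold at 20.
* **Duplicates**: copies are sampled with replacement from the source
  library and appended after it, identical over the first 25 bases and
  carrying between 1 and `dup_max_suffix_mismatch` (default 1) suffix
  substitutions, drawn from a clamped binomial at the 2% error rate. The
  lower bound of 1 makes zero-mismatch deduplication remove essentially
  nothing, and the appended order guarantees the greedy seed of every
  duplicate group is the original read, so prefix-25/one-mismatch
  deduplication removes the constructed 30% exactly up to the handful of
  naturally colliding read pairs.
* **Ideal SAM**: uniform placement, one perfect full-length primary record
  per read at MAPQ 60, giving expected window depth
  $\text{coverage} \cdot L / \text{read\_len}$.

Every generator is a pure function of (configuration, seed); reruns are
bit-identical, and the truth logs (origin, adapter insertion point,
low-quality status, copy–source pairs) serve as oracles for the filter,
masker, trimmer and deduplicator without re-deriving ground truth.

What the generators do *not* emulate: real base-composition structure
(repeats, segmental duplications — so prefix-collision rates are lower than
on a real genome), strand sampling, indel errors, quality-score correlation
along the read beyond the error coupling, optical duplicates, and
alignment errors. Passing tests on synthetic data therefore validate the
*mechanics* of each operator and the exact bookkeeping of the pipeline, not
its end-to-end behavior on real libraries.

## Adapter trimming

The built-in trimmer is intentionally minimal plumbing: a single 3'
adapter, mismatch-only matching (no indels), leftmost match wins among
positions meeting the error bound (default rate 0.1, minimum overlap 3),
with post-trim length filtering. Because the error curve concentrates
errors at the 3' end — exactly where the adapter sits — a few percent of
contaminated reads are cut at the wrong position or missed; on
adapter-spans that are error-free and at least as long as the minimum
overlap, recovery of the logged insert is essentially complete (a tested
property). Users with 5' adapters, indel-tolerant matching, or multiple
adapters should run a dedicated trimmer before the pipeline.

## Problem sizes and numerical choices

The validation suite runs the quality experiments at 100,000 reads × 100 bp
(quotas are enforced exactly, so the filter and masker percentages are 9
and 3 by construction), the duplicate experiment at 100,000 reads (70,000
sources + 30,000 copies on a 10 Mb reference, chosen so natural start-
position collisions contribute well under half a percent), and the
read-depth suite at a 1 Mb reference, 100 bp windows, 30× coverage. The
exhaustive mismatch-equivalence check enumerates all $5^{12}$ ordered pairs
at length 6. Chunk length defaults to the maximal 19; the final partial
chunk is encoded at its natural length. Ties everywhere (sort order, seed
choice, consensus) are broken deterministically, so every stage is
byte-identical across reruns with fixed seeds.

## Known limitations

Duplicate removal is single-end only (paired layouts are rejected
explicitly). FASTQ I/O is eager — whole libraries are held as tibbles —
which is comfortable to hundreds of millions of bases but not for
arbitrarily large production runs. The 4-line FASTQ dialect is required;
multi-line FASTA-style records are rejected. BAM/CRAM are out of scope
(text SAM only), as are CNV segmentation and copy-number estimation, which
consume this package's output.
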
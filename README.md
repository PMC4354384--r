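# rdprep

Read-depth (RD) methods detect copy number variants (CNVs) by counting, in
non-overlapping genomic windows, how many aligned reads fall into each
window: under uniform sequencing the count is Poisson with mean proportional
to local copy number. The counts are only interpretable after the library
has been cleaned — low-quality reads filtered, low-quality bases masked,
adapters trimmed, PCR duplicates removed, ambiguous alignments resolved —
and after the per-window signal has been corrected for GC-content bias.
Most CNV callers start *after* these steps and leave them to ad hoc
third-party tooling.

`rdprep` packages this preparation pipeline for R, with tibbles in and out
of every stage so the steps compose with the pipe. It is aimed at people
building or evaluating RD-based CNV pipelines who want the preprocessing
reproducible, testable, and runnable on synthetic data with known ground
truth.

## What is inside

* **FASTQ quality control** — automatic detection of the Illumina quality
  encoding (Illumina 1.0 / 1.3 / 1.8+ from the minimum ASCII code), Phred
  decoding, removal of reads whose percentage of low-quality bases
  (score < threshold) strictly exceeds an allowance, and masking of
  low-quality bases with `N`.
* **Alignment-free duplicate removal** — reads are clustered by an identical
  k-prefix after encoding each prefix as a base-5 positional integer
  (A→0, C→1, G→2, T→3, N→4); a 64-bit unsigned key supports k ≤ 27 since
  5²⁷ < 2⁶⁴ < 5²⁸. Within a cluster, suffixes are compared in chunks of up
  to 19 bases, each chunk encoded by concatenating the same digits as a
  decimal number (10¹⁹ < 2⁶⁴): the order of magnitude of the difference of
  two chunk codes localizes their leftmost mismatching base, so runs of
  equal bases are skipped in O(1). Duplicates of a greedy seed (equal
  length, ≤ m suffix mismatches, no indels) are condensed into a
  per-position majority consensus.
* **SAM post-filtering** — MAPQ thresholding and resolution of multi-mapped
  reads by unique-best or seeded random-best selection.
* **GC-corrected read-depth signal** — per-window GC from the reference,
  raw RD by assigning each alignment to the window holding its reference
  footprint's center, and depth-ratio GC correction

  RD′ᵂ = (R̄D / R̄D₍GC(w)₎) · RDᵂ

  where R̄D is the mean depth over valid windows and R̄D₍GC(w)₎ the mean over
  windows sharing window w's integer GC percentage.
* **Synthetic data with truth logs** — reference sequences with controlled
  GC, read libraries with exponential-decay substitution errors, normal
  fragment-size adapter read-through, exact low-quality quotas, controlled
  duplicate fractions, and an ideal-aligner SAM generator; every stage of
  the pipeline can be validated against the generators' bookkeeping.

## Worked example

```r
library(rdprep)

ref <- simulate_reference(c(chr1 = 1e6), gc = 0.45, seed = 1)
cfg <- sim_config(n_reads = 20000L, seed = 1)          # study defaults
s2  <- inject_duplicates(simulate_reads(ref, cfg)$reads, cfg)

reads <- decode_qualities(s2$reads)
kept  <- filter_low_quality(reads, filter_policy(qual_threshold = 20,
                                                 min_good_pct = 90))
glance(kept)
#>   total removed  kept pct_removed
#> 1 28571    2612 25959        9.14

masked <- mask_low_quality(kept, qual_threshold = 20)
glance(masked)
#>     bases masked pct_masked
#> 1 2595900  52166       2.01

dd <- dedup_library(masked, dedup_policy(prefix_len = 25, max_mismatches = 1))
dd
#> <rdprep_dedup> 25959 reads, 18124 prefix clusters (k=25), 7759 removed (29.89%) at m=1

aln   <- ideal_alignment_sam(ref, coverage = 30, read_len = 100, seed = 2)
track <- gc_correct(raw_rd(aln, gc_signal(ref, window_len = 100)))
glance(track)
#>   windows valid_windows assigned mean_raw mean_corrected
#> 1   10000         10000   300000       30             30
```

The library was built with 9% low-quality reads, so the filter removes 9.14%
of the duplicate-bearing library (copies inherit their source's qualities).
Masking the survivors replaces 2.01% of bases with `N` — below the library's
3% construction quota because the filter already removed the reads in which
low-quality bases were concentrated. Duplicate removal at prefix 25 and one
suffix mismatch collapses 29.89%, the injected 30% minus the few copies
whose source was itself filtered into a different collapse order. The
ideal-aligner track conserves all 300,000 alignments and GC correction
preserves the mean depth of 30.

`autoplot(track)` draws the raw and corrected signal along each chromosome;
`autoplot(gc_profile(track))` shows the depth-vs-GC trend the correction
removes. `run_pipeline(pipeline_config(...))` executes the same stages from
files to files with a JSON run report, and `inst/cli/rdprep.R` exposes each
stage as a shell subcommand.

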
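---
title: "Methods: gold-set construction, NSVR, and SV benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gold-set construction, NSVR, and SV benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goldset)
```

## The problem

Benchmarking a variant caller requires two things a single sequencing
experiment cannot provide: a set of calls known to be *right* (a truth or
"gold" set) and a way to recognise calls known to be *wrong*. `goldset`
implements a complete workflow for building both from multi-platform,
multi-caller evidence on a single genome, and for scoring structural-variant
(SV) callers against them. Everything runs on simulated data, so the
machinery is testable end to end without any external download.

Throughout the package an SV is an insertion or deletion of at least 50 bp;
coordinates are 0-based half-open everywhere internally, converted only at
the VCF (1-based) boundary.

## Small-variant consensus

Small variants are admitted to the gold set by two criteria evaluated over
the set of (platform, caller) origins that reported the variant:

1. **Cross-platform** — the variant is called by at least one caller on
   *every* declared platform. This cancels sequencing-technology biases.
2. **Cross-caller** — the variant is called by at least two *distinct*
   callers, counted regardless of platform. The same caller reporting the
   variant on two platforms does **not** satisfy this criterion (that is
   precisely the caller-specific bias the rule exists to cancel).

A variant satisfying both goes to the **gold** set; at least one, to the
**complete** set. Before any comparison, every callset is normalized to the
minimal left-aligned representation (`normalize_variants()`), because
different callers legitimately emit the same indel in different textual
forms; "the same variant" then means exact equality of the normalized
(chrom, pos, ref, alt). Genotypes are carried but never compared — the
criteria are statements about call *presence*.

Homozygous-reference call regions get the same treatment at base
resolution: a base belongs to the consensus reference-call regions iff the
origins covering it satisfy both criteria. The implementation disjoins the
input intervals into elementary segments and re-assembles maximal passing
intervals; a per-base oracle in the test suite checks the equivalence.

## SV candidates and validation

Candidate SVs come from two sources that are then merged:

* **Gapped alignments** — a `D`/`I` cigar operation of at least 50 bp in a
  long-read alignment.
* **Split reads** — a primary + supplementary alignment pair of one read on
  the same contig and strand whose query intervals are adjacent within
  10 bp: a reference gap of at least 50 bp is a deletion, an unaligned
  query middle of at least 50 bp over a near-zero reference gap is an
  insertion (sequence lifted from the read when available).

Merging across sources requires, for deletions, reciprocal overlap of at
least 0.5 *and* both breakpoints within 10 bp; for insertions, anchors
within 10 bp and size ratio at least 0.5. The 50% reciprocal-overlap
convention is the field's standard; the tight 10 bp breakpoint tolerance
preserves exact breakpoints while absorbing aligner jitter. Merged records
keep the breakpoints of the highest-priority (first-listed) source and
union their provenance labels; clustering is a greedy sweep over sorted
records, which makes the result independent of input order.

Each candidate is then validated by up to three independent sources:

* **Junction mapping** (`build_junction()`, `junction_support()`): the
  novel adjacency sequence is assembled from the reference flanks (500 bp
  each side; for insertions the flanks embrace the insert, giving two
  junction offsets). A read supports the junction when it has a gapless
  placement within a 5% mismatch budget covering a junction offset with at
  least 20 aligned bases on each side; 2 supporting reads (distinct names —
  duplicates count once) set the JUNCTION flag. The scorer asks whether a
  *qualifying placement exists* rather than scoring all placements and
  taking the best; for the support decision the two are equivalent, and
  only placements that can cover the junction are examined, which keeps
  the scan fast. Insertions without a known inserted sequence are marked
  junction-inapplicable rather than failed.
* **Discordant read pairs** (`discordant_pair_support()`): the insert-size
  model describes the *inner* mate distance (right-mate start minus
  left-mate end). A pair supports a deletion when its apparent insert
  exceeds mean + 3 sd, the pair brackets the event, and apparent insert
  minus deletion size falls back inside mean ± 3 sd; an insertion, when
  the apparent insert falls below mean − 3 sd across the anchor. Two
  supporting pairs set the READPAIR flag.
* **Known-variant database** (`known_db_validate()`): a type-compatible
  database record (loss ↔ DEL, gain/insertion ↔ INS) with reciprocal
  overlap ≥ 0.5 (DEL) or anchor within 100 bp and size ratio ≥ 0.5 (INS).
  Records from excluded samples are removed first, so a genome is never
  validated against database entries derived from itself.

Tiers count validation sources: **Gold** ≥ 2, **Pass** = 1, **Notval** = 0.
The tier is a pure function of the validation set, so re-running validators
is idempotent.

## No-structural-variant regions (NSVR)

The NSVR is the negative space of the gold set: intervals certified free of
structural variation because *only* clean reads align there. A read
qualifies when it aligns end-to-end (no soft/hard clips), uniquely
(MAPQ ≥ 40), with edit fraction NM/aligned-length ≤ 0.02, and is not
secondary/supplementary; any mapped read failing a condition *poisons* the
bases it spans. The NSVR is then the set of maximal intervals with
qualifying depth ≥ 2 and zero disqualifying coverage, at least 100 bp long.

The thresholds deserve comment, since "multiple", "uniquely" and "low edit
distance" are qualitative requirements: 2 reads is the weakest reading of
"multiple"; MAPQ 40 excludes multi-mapping placements under every common
aligner's scale; 2% edit fraction is comfortably above sequencing error
but below what a missed SV inflicts; 100 bp ensures an NSVR interval
carries non-trivial context around any breakpoint it certifies. In-read
deletions (`D` ops) below 50 bp do not break end-to-end status, but a `D`
of SV scale (≥ 50 bp) disqualifies the read — it is itself SV evidence.
Reads are assumed quality-trimmed upstream; the builder does no trimming.
A missing NM tag disqualifies conservatively, with a warning.

## Evaluation metrics

A call matches a gold deletion by reciprocal overlap ≥ 0.5 *or* both
breakpoints within 100 bp; a gold insertion by anchor within 100 bp and
size ratio ≥ 0.5 (skipped when a size is unknown). Each call matches at
most one gold record (best overlap, ties to the smaller start); a gold
record matched by any number of calls counts once. The metrics are:

* `TPR = TP / n_gold`, with TP counted gold-side (gold records recovered);
* `NSVR-FP`: an unmatched call with **both** breakpoints inside the NSVR;
  unmatched calls outside the NSVR are labelled UNKNOWN and enter no
  metric, because nothing certifies them wrong;
* `NSVR-FDR = NSVR-FP / (TP + NSVR-FP)`, precision `= 1 − NSVR-FDR`, and
  F1 the harmonic mean of precision and TPR (0 when TP = 0).

Reusing the gold-side TP in the FDR denominator is a deliberate choice:
it is the arithmetic that published deletion benchmarks of this design
report, and the package's acceptance tests verify it cell by cell against
such a benchmark. Rates are exact internally and rounded to 4 decimals
only in report tables. The deletion benchmark applies a 100 bp size floor
to both calls and gold records, since some callers cannot report below
that range; the floor is a parameter (`match_criteria(min_size=)`).

## What the simulator emulates — and what it does not

`simulate_genome()` draws an i.i.d. contig at a target GC (default 0.41)
and embeds repeat-like cassettes (a dispersed 300 bp SINE-length unit and
short tandem arrays) with a declared interval track, so repeat-overlap
reporting is exercisable. `implant_variants()` places SNVs, 1–10 bp
indels, and SVs (sizes power-law-decaying above 50 bp, matching the decay
real SV size spectra follow) pairwise ≥ 200 bp apart, with genotypes
homozygous with probability 1/3, and derives the diploid donor sequences
plus per-haplotype alignment block maps. `simulate_reads()` draws reads
from the donor and assigns reference-space alignments *by construction* —
no aligner runs: reads inside unchanged segments are end-to-end with NM
from substitution errors; reads crossing implanted SV breakpoints are
soft-clipped or split, exactly the signature the NSVR builder and the
candidate extractor key on. `simulate_callset()` applies per-caller
false-negative rates, Poisson false positives (optionally confined to
given regions, for FDR calibration), breakpoint jitter, and right-shifted
indel representations that must normalize back to truth keys.

Not emulated: base-quality models, platform-specific error spectra,
indel sequencing errors (available as an option but off by default),
coverage biases, mapping ambiguity in repeats (simulated reads are always
placed at their true origin with MAPQ 60), and multi-contig genomes'
inter-chromosomal events. Passing tests therefore demonstrate the
*logic* of consensus, validation, NSVR construction and scoring — not
robustness to alignment artefacts of real repetitive DNA.

All randomness flows through one seed per operation call, so every
simulation is reproducible; the command-line stages record their seeds and
parameters in JSON sidecars, and `--no-timestamp` makes outputs
byte-reproducible.

## Problem sizes in the test suite

The suite's end-to-end check runs on a 1 Mb contig with 2,000 implanted
small variants and 200 SVs — enough for three-digit statistical checks:
empirical gold recall against the closed-form consensus probability
(enumerated over all 2^6 origin patterns) within 3 binomial sigma; Gold
tiering of junction-supported, database-confirmed deletions at ≥ 95%; and
recovery of a planted NSVR-confined false-positive rate by NSVR-FDR within
3 sigma (delta-method) of the planted value. With perfect recall the
gold-side-TP arithmetic estimates a per-call FP fraction only when each
gold record attracts a single true call, so the calibration experiment
emits exactly one call per gold deletion plus the planted FPs. Oracle
equivalences run at smaller scale per trial but high trial counts (1,000
randomized read sets for NSVR; 1,000 random indels for normalization).

## Known limitations

* Only deletions and insertions are modelled; breakends, inversions,
  duplications and translocations are out of scope, as are CRAM input and
  phased genotypes.
* Sequence-resolved SV alleles in VCFs are interpreted as left-anchored.
* The junction scorer is gapless; a read carrying a true indel *within*
  the junction window may fail its mismatch budget and not be counted.
  With the default thresholds this costs sensitivity only at extreme
  error rates.
* Split-read insertion sequences are recovered only for forward-strand
  primaries with full (soft-clipped, not hard-clipped) sequence; other
  configurations yield an insertion record of known size without sequence,
  which downstream validation handles (junction validation becomes
  inapplicable, database and read-pair validation still apply).
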
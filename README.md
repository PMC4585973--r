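# goldset

Gold-standard variant truth sets and structural-variant benchmarking for a
single genome.

Validating a variant caller needs a truth set (calls known to be right) and
a negative space (regions where a call is known to be wrong). `goldset`
builds both from multi-platform, multi-caller evidence and scores SV
callers against them:

* **Small-variant consensus** — a variant enters the *gold* set when it is
  called on every platform (cross-platform criterion, C1) **and** by at
  least two distinct callers (cross-caller criterion, C2; the same caller
  on two platforms does not count). One criterion suffices for the
  *complete* set. Indel representations are normalized (minimal,
  left-aligned) before comparison so representational differences between
  callers cannot break the intersection. The same per-base criteria build
  consensus homozygous-reference call regions.
* **SV gold set** — candidate deletions/insertions ≥ 50 bp are extracted
  from gapped and split long-read alignments, merged across sources
  (reciprocal overlap ≥ 0.5 and breakpoints within 10 bp), and validated
  by three independent sources: breakpoint-junction read mapping,
  discordant read-pair analysis, and known-variant database overlap
  (excluding entries derived from the same individual). Tiers: **Gold**
  ≥ 2 sources, **Pass** = 1, **Notval** = 0.
* **NSVR** — "no structural variant regions": intervals covered only by
  ≥ 2 uniquely-mapped (MAPQ ≥ 40), end-to-end, low-edit-distance
  (NM/len ≤ 0.02) reads. A call that matches no gold SV *and* has both
  breakpoints inside an NSVR is a certified false positive (NSVR-FP).
* **Evaluation** — with TP counted gold-side:

  ```
  TPR      = TP / n_gold
  NSVR-FDR = NSVR-FP / (TP + NSVR-FP)
  F1       = harmonic mean of (1 − NSVR-FDR) and TPR
  ```

* **Simulator** — seeded generation of reference contigs (with repeat-like
  cassettes), diploid donors with implanted SNVs/indels/SVs, reads aligned
  by construction (breakpoint-crossing reads are clipped/split, exactly
  what the NSVR builder keys on), and noisy per-caller callsets with
  configurable FNR, FPR, breakpoint jitter and indel-representation
  shifts. The whole pipeline runs hermetically on synthetic data.

## Worked example

```r
library(goldset)

g     <- simulate_genome(200000, gc = 0.41, seed = 42)
truth <- implant_variants(g, n_snv = 300, n_indel = 100,
                          n_sv_del = 30, n_sv_ins = 20, seed = 43)
long  <- simulate_reads(truth, long_profile(), depth = 8, seed = 44)
nsvr  <- build_nsvr(long, nsvr_params())
calls <- simulate_callset(truth,
           caller_profile("toy_caller", fnr = 0.15, fpr_per_mb = 10,
                          breakpoint_jitter_sd = 5), seed = 45)
res <- evaluate_sv(calls$svs, truth$svs, nsvr,
                   match_criteria(min_size = 100))
print(res)
#> SV evaluation: n_gold=17 TP=13 TPR=0.7647 NSVR-FP=0 NSVR-FDR=0.0000 F1=0.8667
```

Reading: of the 17 implanted deletions ≥ 100 bp, the noisy caller
recovered 13 (TPR 0.76); none of its unmatched calls landed with both
breakpoints inside the 114 kb of NSVR built from the simulated long reads,
so the certified FDR is 0 and F1 is 0.87. Unmatched calls *outside* the
NSVR are labelled UNKNOWN and enter no metric — nothing certifies them
wrong.

The same arithmetic applied to a published caller's evaluation counts:

```r
m <- f1_from_counts(TP = 1683, NSVR_FP = 32, n_gold = 1963)
sprintf("TPR=%.4f NSVR-FDR=%.4f F1=%.4f", m$TPR, m$NSVR_FDR, m$F1)
#> "TPR=0.8574 NSVR-FDR=0.0187 F1=0.9152"
```

A command-line wrapper (`inst/cli/goldset.R`) exposes the workflow as
subcommands (`simulate`, `build-smallvar-gold`, `build-refregions`,
`extract-sv`, `merge-sv`, `validate-sv`, `build-nsvr`, `evaluate-sv`,
`report`) driven by a YAML config; every stage writes a JSON sidecar with
its inputs, parameters and seed. See `vignettes/goldset-methods.Rmd` for
the model, parameter rationale, and the simulator's scope.

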
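---
title: "Calling super-enhancers and integrating them with expression changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling super-enhancers and integrating them with expression changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sercall)
```

## The model

Super-enhancers (SEs) are clusters of nearby active enhancers that carry a
disproportionate share of a tissue's H3K27ac signal and dominate the
transcription of their target genes. sercall implements the standard
rank-ordering (ROSE-style) recipe for finding them from H3K27ac ChIP-seq
peaks, plus the downstream comparisons a two-condition study needs:

1. **TSS exclusion.** Peaks lying entirely within ±2 kb of a transcription
   start site are promoter signal, not enhancer signal, and are removed
   first (`filter_tss_proximal()`). The window is `[tss - r, tss + r + 1)`
   in 0-based half-open coordinates, so a peak exactly filling the window is
   excluded.
2. **Stitching.** Remaining peaks separated by at most 12.5 kb are merged
   into candidate enhancers (`stitch_peaks()`). The rule is the connected
   components of the gap-at-most-12.5-kb graph, with the boundary inclusive:
   a gap of exactly 12 500 bases stitches. A stitched enhancer's signal is
   the sum of its member peak signals (MACS2 `signalValue` by default; a
   bedGraph pileup area via `signal_over()` is the alternative entry point,
   since peak scores and pileup area are both defensible readings of
   "ChIP signal intensity" and neither is canonical).
3. **Ranking and the slope-1 tangent.** Enhancers are sorted by ascending
   total signal and both axes are min-max scaled to `[0, 1]`
   (`rank_and_scale()`). On this "hockey stick" the cutoff is the tangency
   point of the slope-1 line — equivalently the point minimizing
   `scaled_y - scaled_x` (`tangent_cutoff()`). Everything *strictly above*
   the tangency signal is a super-enhancer; the tangency enhancer itself is
   typical. Ties are resolved toward the highest-signal minimizer, i.e.
   toward fewer super-enhancers, which is the conservative choice on flat or
   degenerate curves. Because both axes are min-max scaled, the SE set is
   invariant under any positive rescaling of the signals and under input
   order.

Two-condition comparisons use an exact conditional binomial test on the
library-normalized signal of each consensus SE region
(`differential_signal_test()`): conditional on the pooled (rounded) count
`n = count_a + count_b`, the condition-B count is Binomial(`n`,
`lib_b/(lib_a + lib_b)`) under the null of equal normalized rates. The
log2 fold change uses a pseudocount of 1 on both sides and is computed as a
difference of logs so that swapping the conditions negates it exactly in
floating point. Calls use the strict printed gates `|log2FC| > 1` and raw
`P < 0.05`; a fold change of exactly the threshold is never called. The
method is deliberately replicate-free and transparent — when replicated
ChIP-seq or a dedicated DE caller is available, its table can be supplied
directly.

Expression screening works on FPKM (`fpkm()`, `count * 1e9 /
(library_size * gene_length)`): the fold change of group means with a
pseudocount of 1, and a two-sided Welch t-test on `log2(FPKM + 1)` when
both groups have at least two replicates (`expression_differential()`).
Calls use linear fold change > 2 and raw P < 0.05. At three replicates the
Welch test is slightly conservative: under a matched log-normal null its
rejection rate at the 0.05 gate is about 0.037-0.04, which the test suite
asserts; it never exceeds the nominal rate. External DE tables (for
example from a count-based negative-binomial caller) are accepted as
direct input to the integration step, which treats the table's `direction`
column as authoritative when present.

**Integration** (`integrate_se_genes()`) mirrors the usual ChIP/RNA
matching rules: each differential SE is assigned the gene whose TSS is
nearest to the SE midpoint (within a 100 kb window); when several SEs land
on one gene only the highest-signal one is kept; the SE must reach a
directional linear fold change of at least `se_fc_min` and the gene a fold
change of at least 1.2 (up) or at most 1/1.2 (down); and by default only
direction-concordant pairs are reported. Two readings here are genuinely
open and are resolved as configuration rather than silently:

* An SE fold-change floor of 1 on the linear scale is vacuous — any
  significant directional change passes. `se_fc_min` defaults to exactly
  that permissive reading and can be raised (for example to 2, matching the
  `|log2FC| > 1` peak criterion) in one argument.
* "Near the gene" has no published window; 100 kb is a common
  enhancer-target search radius and is configurable (`gene_window`).

## Peak annotation

`classify_peaks()` assigns each peak to one of four classes — promoter,
exon, intron, distal intergenic — by the position of its summit (midpoint
when no summit is available). Using a single point makes the classes
exhaustive and mutually exclusive without fractional assignment; precedence
promoter > exon > intron resolves containment. The promoter window reuses
the 2 kb TSS radius for consistency with SE calling. One representative
TSS per gene is used throughout (the span's 5' end): transcript-level
isoform models are out of scope, and for multi-isoform genes this is a
simplification, not a statement about the data.

## The synthetic benchmark

`simulate_landscape()` and `simulate_expression()` generate a deterministic
two-condition study with ground truth, emulating the structure such
analyses assume: a gene annotation (400 genes over 4 × 25 Mb by default),
2000 scattered background peaks of which 20% are planted inside TSS ±2 kb
windows (and should be consumed by the TSS filter), 30 planted SE clusters
of 3-8 peaks with intra-cluster gaps of 0.5-11 kb and per-peak signal
boosted ×5, 8 differential clusters (half up, half down, linear fold 4 in
condition B), and 3-replicate negative-binomial expression tables
(dispersion 0.05) in which the gene nearest each differential cluster
changes concordantly. Clusters are anchored 15-80 kb from a gene TSS —
outside the exclusion window, inside the integration window — so that every
planted SE has a recoverable target gene.

Two generator choices are deliberate benchmark-design choices, not claims
about real chromatin:

* **Background signals are tight** (log-normal, `sdlog = 0.06`) and
  **background peaks are isolated** (placed with more than one stitch gap
  of separation, so each is its own typical enhancer). The slope-1 tangent
  sits where the sorted curve's point-to-point spacing first exceeds
  `range/n`; any heavy upper tail of the background — wide signal spread,
  or Poisson clumping of scattered peaks into multi-peak stitched
  enhancers — moves the tangency several points into the background and
  the planted clusters are no longer cleanly separable. With the defaults
  the planted clusters sit far above the background band and recovery is
  essentially exact (precision and recall ≥ 0.9 in every tested seed).
* Consequently, **passing the recovery tests shows the pipeline implements
  the recipe correctly; it does not show that real H3K27ac landscapes
  separate this cleanly.** Real signal spreads are wider (`sdlog` 0.5-1),
  typical enhancers do cluster, and on such data the tangent necessarily
  calls a tail of high-background regions — which is also true of the
  original ROSE procedure. Raising `background_sdlog` or
  `n_typical_enhancers` in `simulation_config()` reproduces that regime.

`write_fixture()` emits the whole study as plain-text standard formats
(GTF, narrowPeak, bedGraph, TSV) with an MD5 manifest; identical seeds give
byte-identical files.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; GTF input is converted at
  the reader. The minus-strand TSS is `end - 1`, the last covered base.
* Ranking ties are broken by `(chrom, start)` so results are independent of
  input order; tangency ties within `1e-12` of the minimum resolve to the
  highest-signal point.
* A curve with fewer than 3 points, or with all signals equal, cannot
  support a tangent: the call returns zero super-enhancers with a warning
  rather than an arbitrary cutoff.
* Counts are rounded to integers for the exact binomial test; `0 vs 0`
  yields `log2fc = 0, p = 1` via the pseudocount.
* Genes absent from the DE table are reported in a side list
  (`attr(result, "unmatched")`), never silently dropped.
* The empty-annotation, empty-peak-set, single-replicate and
  constant-expression cases all degrade to warnings or `ns` calls, never to
  spurious positives.

## Problem sizes used by the test suite

The packaged tests run the full generator at its default size (2000
background peaks, 30 clusters) across ten seeds for recovery and
integration, 1000 random curves against an O(n²) brute-force tangency
oracle, 500 random peak sets against a breadth-first connected-components
oracle, and a 10 000-region Poisson null for test calibration — sizes at
which every property is exercised at full strength while the whole suite
stays in the low minutes on one core.

## Command line and configuration

`inst/scripts/sercall` is a thin Rscript wrapper over `run_pipeline()`
(`--simulate` or `--peaks-a/--peaks-b/--gtf/--de-table`, plus the threshold
flags). Configuration files are YAML, chosen as the structured-text format
with first-class support in the installed R stack; unknown keys are an
error naming the key, so typos cannot silently revert a parameter to its
default. All randomness flows from a single `--seed`.

## Known limitations

* No input-chromatin subtraction in enhancer scoring (the classic ROSE
  option); the flag space is reserved but scoring uses H3K27ac signal only.
* No unstitching of regions spanning many TSSs.
* One TSS per gene; no UTR/downstream annotation subclasses; no
  enhancer-promoter loop evidence in target assignment (nearest TSS only).
* The differential ChIP test models no biological replication; treat its
  p-values as screening statistics, as the strict raw-P gates imply.
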
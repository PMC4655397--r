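---
title: "Replicate-free three-tissue transcriptome comparison: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate-free three-tissue transcriptome comparison: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triodiff)
```

## The setting

`triodiff` targets a study design that is common when building a
transcriptome database for a non-model organism: RNA from several
specimens is pooled, one deep sequencing library is made per tissue (here
three: gill, foot, mantle), and there are no biological replicates on the
sequencing side. Without replicates there is no dispersion to estimate, so
the replicate-aware DE frameworks are off the table. The pragmatic
alternative implemented here treats each pairwise comparison's empirical
log2-ratio distribution as its own null: most transcripts do not change
between tissues, so the bulk of the distribution calibrates what "no
change plus technical noise" looks like, and only transcripts in the
extreme 2-SD tails are called. The price is that calls are deliberately
conservative and qualitative ("remarkably different"), which is why the
workflow pairs them with a qPCR validation step.

## The pipeline, step by step

1. **Quantification.** `compute_fpkm()` applies
   `FPKM(i,t) = C(i,t) * 1e9 / (L(i) * T(t))`. Each mapped read is
   treated as one fragment, so FPKM and RPKM coincide here. Library sizes
   `T(t)` default to the column sums of the supplied table, but can be
   overridden: when the table has already been filtered, the sequencing
   totals include reads mapping to transcripts no longer present, and the
   override lets the caller use the true totals. `run_dominance_pipeline()`
   does exactly that — it takes column sums *before* filtering. FPKM values
   are kept in double precision throughout; rounding happens only in
   report output.

2. **Abundance filter.** `filter_by_ppm()` keeps transcript *i* iff its
   summed count over the three tissues is at least
   `ppm * 1e-6 * grand_total` (default 5 ppm). Low-coverage transcripts
   have unreliable ratio estimates, and removing them before computing
   the comparison statistics keeps the empirical SD from being inflated
   by pure counting noise. The absolute threshold is carried as a real
   number, never rounded: 750 reads is what 5 ppm happens to equal when
   the grand total is 1.5e8. The comparison is `>=` (a transcript exactly
   at the threshold is kept), and both the statistics and the labels are
   computed on the filtered set only.

3. **Ratios and cutoffs.** `log2_ratio()` computes `log2(FPKM_A/FPKM_B)`.
   Zeros are handled by policy: the default `floor` policy replaces zero
   FPKM with half the smallest nonzero FPKM observed in the pair (a
   data-driven pseudo-value that keeps every filtered transcript in the
   analysis); the `drop` policy instead omits affected transcripts and
   records their ids, and is provided for sensitivity analysis.
   `ratio_stats()` uses the *population* SD (divide by n): with thousands
   of retained transcripts the sample/population distinction is far below
   any other source of uncertainty, and the population form is the
   simplest to state. Cutoffs are `mean ± 2 * sd` exactly, so
   `upper + lower = 2 * mean` holds to machine precision.

4. **Calls and dominance.** `call_de_pair()` uses strict inequalities: a
   ratio exactly at a cutoff is *not* differentially expressed, matching
   the "greater than 2 SD" phrasing of the rule. `call_tissue_dominance()`
   declares a transcript dominant in tissue X iff it is high-in-X in both
   pairwise comparisons involving X; a case enumeration over all 27 label
   combinations (exercised in the test suite) shows at most one tissue
   can win, so the call is well defined.

5. **Enrichment.** `enrich_terms()` computes the upper-tail cumulative
   hypergeometric probability (through R's `phyper`, which works stably
   in log space) and the rich factor `k / K` — deliberately the literal
   in-list-over-universe-carriers ratio, not the `k / n` used in some
   other literatures. Two conventions needed fixing where the workflow's
   description is silent. First, the universe: for the top-fraction
   ("dominant transcript") analysis the natural universe is all annotated
   transcripts in the expression table; for tissue-dominant lists it is
   the filtered transcripts with at least one annotation. Both are
   explicit arguments, not hidden defaults. Second, `n` counts only
   annotated list members and `N` only annotated universe members —
   standard over-representation practice, since unannotated transcripts
   cannot contribute to any term's count. P-value thresholds are applied
   raw (0.001 for KEGG-style analyses, 0.0001 for GO Biological Process);
   a Benjamini–Hochberg column is written for reference but never gates
   the `enriched` flag, because the workflow being reproduced thresholds
   raw P values.

6. **Top-fraction selection.** `select_dominant_fraction()` ranks by
   summed FPKM over the three tissues and keeps the top
   `ceiling(fraction * N)` (default 5%). Ties at the boundary are broken
   by transcript id ascending, so the selection is deterministic. Whether
   the 5% is taken of all transcripts or of annotated ones only is left
   to the caller (pass the appropriate expression table); the package
   does not guess.

7. **qPCR.** `ddct_fold_change()` aggregates in a fixed order: technical
   replicates are averaged to one Ct per gene/tissue/biological
   replicate; dCt = target − reference per tissue; ddCt = dCt(A) −
   dCt(B) per biological replicate; replicate fold changes `2^-ddCt` are
   combined by geometric mean (arithmetic mean of −ddCt). The geometric
   mean is the right average for a multiplicative quantity, and it makes
   the swap property exact: exchanging the tissues inverts the fold
   change. Amplification efficiency is fixed at 2 — the method's name —
   with no dilution-series correction. `log2_concordance()` is plain
   Pearson correlation over the shared transcript set, reported as R²
   the way such validations are usually quoted.

8. **Sequence statistics.** `assembly_stats()` uses the weighted-median
   N50 convention: the length at which the descending cumulative sum
   first reaches half the total. (Published assembly tables sometimes
   disagree with their own text by ±1 bp on N50; that is
   rounding/convention noise, and this package simply fixes one
   convention.) `count_cxc_motifs()` counts Cys-Xaa-Cys windows with
   overlap allowed and Xaa unrestricted — `"CCC"` counts one motif,
   `"CACAC"` two. Overlap handling is rarely stated in papers that quote
   such counts; the sliding window is the simplest rule and is what the
   tests pin down.

## The synthetic-data generator

`simulate_dataset()` emulates the study conditions the pipeline is meant
for, with every parameter in `simulation_config()`:

- **Scale.** Three tissues at 5e7 mapped reads each by default (the
  ~55-million-clean-reads-per-tissue scale of the motivating design);
  10,000 transcripts by default. Transcript lengths are log-normal with
  median 673 bp (minimum 200), echoing published assembly summaries.
- **Counts.** Negative binomial per transcript and tissue,
  `size = 1/dispersion` with dispersion 0.1 — the minimal overdispersed
  count model; nothing in the workflow assumes more structure. The mean
  is proportional to baseline FPKM × length × library size, with the
  proportionality constant calibrated on the baseline (unspiked) mass so
  that expected column sums match the configured library sizes in the
  no-spike case; a spike then multiplies its transcript's mean by exactly
  `2^effect`. Consequently the 1%-accuracy column-sum calibration holds
  for spike-free simulations, while heavily spiked libraries carry the
  extra spike mass — mirroring the real phenomenon that a tissue's
  dominant transcripts absorb a large share of its reads.
- **Spikes.** 1% of transcripts per tissue, disjoint across tissues (so
  dominance scoring against truth is unambiguous), at a log2 effect of 8:
  the workflow targets transcripts that are *remarkably* different, and
  the planted effects are correspondingly large.
- **Annotations.** 100 background terms with log-normal sizes (clamped to
  5–500) sampled uniformly; one planted term per spiked set containing
  80% of the spiked transcripts plus five background transcripts, so the
  planted signal is strong but not degenerate.
- **qPCR.** Ten spiked transcripts per tissue (the 10-per-dominant-list
  validation design), 3 biological × 2 technical replicates, a single
  reference gene at Ct 15, target Ct =
  `reference_ct + 30 − log2(true FPKM)` plus Gaussian noise of 0.2
  cycles. The constants are arbitrary by construction — only ratios
  survive the ddCt arithmetic — and are documented config fields.
- **Determinism.** A seed is mandatory; the same config and seed
  regenerate bit-identical datasets and files.

What the generator does *not* emulate: read-level error, multi-mapping
ambiguity, isoform structure, correlated annotation (real GO/KEGG terms
overlap heavily), batch effects, or biological replicate variance. Tests
passing on this generator therefore demonstrate that the pipeline's logic
and arithmetic are correct under its stated model, not that the 2-SD rule
has any particular false-discovery rate on real tissue libraries.

## Validation problem sizes

The test suite validates the stochastic properties at sizes chosen to
give stable estimates while keeping the suite quick to run:

- Null DE rate: spike-free simulation of 1e5 transcripts at the default
  depth; the two-sided 2-SD tail fraction per pair is checked against
  the normal-tail expectation of 4.55% within ±0.5%. (The observed rate
  sits slightly above 4.55% because the post-filter ratio distribution
  is a mixture over expression levels and mildly heavy-tailed — visible,
  but well inside the band.)
- Recovery: 1e4 transcripts with libraries scaled to 2e6 reads, default
  spikes; spiked-set sensitivity ≥ 0.9 and precision ≥ 0.8 per tissue,
  planted terms detected at P ≤ 1e-4.
- qPCR concordance: evaluated at the default 5e7-read depth, where
  sequencing-side ratios are well measured and R² ≥ 0.95 reflects the
  0.2-cycle Ct noise rather than count noise; at 2e6 reads the
  sequencing side itself becomes the dominant error source for weakly
  expressed spiked transcripts (zero counts in the contrast tissue get
  floored), which is a property of shallow sequencing, not of the ddCt
  arithmetic.
- Exact oracles: the hypergeometric tail is compared with exhaustive
  combinatorial enumeration for every valid (k, K, n, N) with N ≤ 25 at
  1e-12 relative tolerance; N50 and motif counting are compared with
  brute-force oracles on 1,000 random inputs each.

## Degenerate inputs and tie-breaks

- Constant ratio vectors give SD 0 and both cutoffs equal to the mean;
  nothing is then called (strict inequality).
- A ratio exactly equal to a cutoff is not DE; a summed count exactly at
  the ppm threshold is kept.
- `k = 0` terms emit no enrichment row; `k = 0` passed to the tail
  function returns exactly 1.
- Boundary ties in top-fraction selection go to the lexicographically
  smaller transcript id.
- Empty dominance calls give sensitivity 0 and precision reported as
  not-applicable (`NA`), never 0/0.

## Known limitations

The 2-SD rule has no error-rate guarantee: it flags a fixed ~4.6% of
transcripts per pair regardless of how much true signal exists, and with
no replicates it cannot distinguish biological effect from
library-construction artifacts — which is exactly why the validation
(qPCR concordance) step is part of the workflow rather than an optional
extra. Enrichment P values are raw by design; users who need FDR control
across terms should use the supplementary BH column and say so. The
published R² values of the motivating study (0.9582 / 0.9697 / 0.8532)
depend on its supplementary qPCR measurements and are not recomputable
from public summaries; the synthetic concordance property is the
stand-in this package can honestly test.
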
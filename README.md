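# triodiff

Replicate-free differential expression across three tissue transcriptomes.

## What problem this solves

When a transcriptome database is built from pooled specimens — one
sequencing library per tissue, no biological replicates — the standard
dispersion-based differential-expression toolkits (DESeq2, edgeR, limma) do
not apply: there is no within-group variance to estimate. A common
alternative in such studies of non-model organisms (the motivating case is
a deep-sea bathymodiolid mussel with gill, foot and mantle libraries) is an
empirical rule: normalize counts to FPKM, drop low-abundance transcripts,
and in each pairwise tissue comparison call a transcript differentially
expressed when its log2 expression ratio lies more than two standard
deviations from the comparison-wide mean ratio. `triodiff` implements that
entire workflow as a tested, reusable pipeline, together with the
downstream analyses such studies run (tissue-dominance classification,
hypergeometric term enrichment, qPCR validation) and a synthetic-data
generator with planted ground truth so the whole chain can be validated
end to end.

## The model

For transcript *i* with length *L(i)* bases, mapped-read count *C(i,t)*
and library size *T(t)* total mapped reads in tissue *t*:

- **FPKM**: `FPKM(i,t) = C(i,t) * 1e9 / (L(i) * T(t))`.
- **Abundance filter**: transcript *i* is kept iff
  `sum_t C(i,t) >= ppm * 1e-6 * grand_total` (default 5 ppm; at a
  1.5e8-read study this is the familiar 750-read threshold).
- **DE call**, per ordered tissue pair (A, B): with
  `r(i) = log2(FPKM_A / FPKM_B)`, mean `m` and population SD `s` of the
  `r(i)`, transcript *i* is high in A iff `r(i) > m + 2s`, high in B iff
  `r(i) < m - 2s`.
- **Tissue dominance**: dominant in X iff high-in-X in *both* pairwise
  comparisons that involve X.
- **Enrichment**: for a list of *n* annotated transcripts from a universe
  of *N* (of which *K* carry a term, *k* in the list), the upper-tail
  cumulative hypergeometric
  `P = sum_{i=k}^{min(n,K)} C(K,i) C(N-K, n-i) / C(N,n)`, with rich
  factor `k / K`. Raw-P thresholds 0.001 (KEGG-style) and 0.0001 (GO
  Biological Process) are the conventional configurations.
- **qPCR validation**: relative expression by the 2^-ddCt method
  (technical-replicate mean Ct, target minus reference, tissue A minus
  tissue B, replicates combined as a geometric mean), compared with the
  sequencing log2 ratios by Pearson's r (reported as R^2).

## Worked example

Simulate a three-tissue study (10,000 transcripts, 2e6 mapped reads per
library, 1% of transcripts spiked per tissue at a log2 effect of 8) and
run the full pipeline:

```r
library(triodiff)

cfg  <- simulation_config(n_transcripts = 10000, library_sizes = 2e6, seed = 1)
ds   <- simulate_dataset(cfg)
pipe <- run_dominance_pipeline(ds$counts, threshold_ppm = 5)

pipe$pairs$gill_vs_foot
#> Pairwise log2-ratio stats (gill vs foot): n=5112 mean=0.731 sd=1.733
#>   cutoffs: high in gill > 4.197; high in foot < -2.735
#>   labels: gill=101 foot=102 not_DE=4909

table(pipe$dominance$dominant_tissue)
#>   foot   gill mantle
#>    100    100    100
```

5,112 of the 10,000 transcripts pass the 5-ppm filter; in the gill-vs-foot
comparison the empirical cutoffs (mean ± 2 SD of the log2 ratios) call 101
transcripts gill-high and 102 foot-high, and requiring a high call in both
comparisons per tissue yields exactly the 100 spiked transcripts per
tissue. Enrichment on the gill-dominant list recovers the planted term:

```r
lst <- subset(pipe$dominance, dominant_tissue == "gill")$transcript_id
enr <- enrich_terms(lst, ds$terms, universe = pipe$expr$transcript_id,
                    p_threshold = 1e-4)
head(enr[, c("term_id", "k", "n", "K", "N", "p", "rich_factor", "enriched")], 1)
#>             term_id  k  n  K    N             p rich_factor enriched
#> 1 TERM_PLANTED_gill 80 83 83 1973 7.483096e-135   0.9638554     TRUE
```

and the simulated qPCR assay (3 biological x 2 technical replicates,
0.2-cycle Ct noise, 18S-style reference gene) concords with sequencing:

```r
q <- qpcr_log2_ratios(ds$ct, "gill", "foot")
log2_concordance(q, log2_ratio(pipe$expr, "gill", "foot"))
#> qPCR/sequencing concordance: n=30 r=0.9925 R^2=0.9850
```

`evaluate_recovery(ds$truth, pipe$dominance)` scores the calls against the
planted truth (sensitivity and precision 1.0 per tissue in this run).

A command-line wrapper for the generator is installed at
`inst/scripts/simulate-dataset.R` (flat key=value config in, TSV/JSON
dataset out).

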
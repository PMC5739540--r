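# ripstab

Tools for studying how an RNA-binding protein (CNBP) stabilises target
mRNAs recruited through G-rich elements, built around three computational
procedures:

1. **Degenerate motif enrichment in RIP-seq peaks.** Peak sequences are
   scanned for IUPAC motifs (the default panel is TGGAGNW, TGGAG, GGAGNW,
   GGAG and GGR, the G-rich patterns preferred by CNBP) and the proportion
   of motif-containing peaks is tested against a randomisation null: 1000
   random sequence sets with exactly the same number of sequences and the
   same length multiset as the peaks. The primary statistic is the
   one-sided empirical p-value with add-one correction,
   `p = (1 + #{null ≥ observed}) / (n + 1)`, with a rank-sum p-value
   reported alongside. A sliding-window scanner locates G-rich regions
   carrying the GGAG core.
2. **mRNA half-life estimation.** Actinomycin-D chase qPCR courses are
   converted from Ct values by ΔΔCt, normalised per replicate to t = 0 and
   fitted by log-linear least squares, `ln A(t) = c − k t`, giving
   `t½ = ln 2 / k` with a t-based 95% CI. Conditions are compared by the
   half-life ratio and a two-sample t-test on log per-replicate
   half-lives. Absolute copy numbers per cell come from a qPCR standard
   curve (`E = 10^(−1/slope) − 1`).
3. **Target nomination.** Genes downregulated on lncRNA knockdown
   (log2 fold change strictly below −0.58) are intersected with genes
   enriched at least 4-fold over input in the protein's RIP fraction.

A seeded synthetic-data generator produces all inputs — peak sets with
planted motifs, exponential decay courses with lognormal noise, and paired
gene tables with a known true-target list — so every stage is validated by
parameter recovery.

## Worked example

```r
library(ripstab)

# a 200-peak set with GGAG planted in half the sequences
peaks <- gen_peak_set(200, lengths = 50, planted_motif = "GGAG",
                      planted_fraction = 0.5, seed = 1)
panel <- run_motif_panel(peaks, n_samples = 1000, seed = 2)
as.data.frame(panel)
#>     motif observed null_mean    null_sd empirical_p rank_test_p n_samples
#> 1 TGGAGNW    0.070  0.021330 0.01031443 0.000999001  0.04019045      1000
#> 2   TGGAG    0.155  0.044370 0.01433906 0.000999001  0.04105018      1000
#> 3  GGAGNW    0.275  0.083655 0.01993523 0.000999001  0.04150075      1000
#> 4    GGAG    0.580  0.167965 0.02636055 0.000999001  0.04166581      1000
#> 5     GGR    0.900  0.704080 0.03375193 0.000999001  0.04178489      1000
```

The observed GGAG proportion (0.58: the planted 0.50 plus chance
background hits) sits far above the null mean (0.17), so the empirical
p-value is at its floor, 1/1001. The nested motif GGR is common even in
random DNA (null mean 0.70), which is why the matched null matters.

```r
# half-life of CCND1 mRNA under control shRNA: simulate and re-estimate
course <- gen_decay_course(preset = "control", seed = 42)  # true t1/2 = 5 h
fit_half_life(course)
#> Half-life estimate (control, pooled): t1/2 = 4.86 h (k = 0.143 /h)
#>   95% CI [4.45, 5.35] h; R^2 = 0.977; n = 15 points

# target nomination on noiseless tables recovers the planted truth
tabs <- gen_gene_tables(800, 60, lfc_noise_sd = 0, enrich_noise_sd = 0, seed = 7)
ov <- intersect_targets(
  filter_downregulated(tabs$diff_expr$gene_id, tabs$diff_expr$log2fc),
  filter_rip_enriched(tabs$rip_enrich$gene_id, tabs$rip_enrich$fold_over_input))
length(ov$genes)  # 60
```

A command-line wrapper with `simulate`, `motif-test`, `grich-scan`,
`decay-fit` and `integrate` subcommands is installed at
`system.file("scripts", "ripstab", package = "ripstab")`; every run writes
a log with the resolved configuration, seeds and input digests.

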
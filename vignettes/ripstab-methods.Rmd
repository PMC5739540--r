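---
title: "Methods: motif enrichment, decay kinetics and target nomination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif enrichment, decay kinetics and target nomination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripstab)
```

ripstab implements the computational side of a common regulatory-RNA
question: does an RNA-binding protein (here CNBP) bind its targets through
a particular sequence element, and does that binding stabilise the target
mRNAs? The package answers it with three independent procedures — motif
enrichment in RIP-seq peaks, half-life estimation from actinomycin-D chase
qPCR, and intersection-based target nomination — plus a synthetic-data
generator that makes each procedure testable by parameter recovery.

## Motif model and matching

Motifs are degenerate IUPAC patterns. The default panel holds the five
G-rich patterns relevant to CNBP binding — TGGAGNW, TGGAG, GGAGNW, GGAG
and GGR — which are nested (every GGAG match is a GGR match), so their
observed proportions are automatically ordered. Matching is implemented by
translating the pattern into a character-class regular expression, one
class per position. Two semantic choices matter:

* An `N` in a *subject* sequence never matches any motif position, even
  motif `N`. Unknown bases should not manufacture matches.
* Matching is sense-strand only by default: RIP peaks represent
  transcribed RNA, which has a defined strand. A both-strand mode exists
  for DNA-context scans.

The test suite checks the matcher exhaustively against a full literal
expansion of each panel motif over every DNA string up to length 8.

## The randomisation null and its p-values

The enrichment statistic is the proportion of peaks containing a motif
(each peak counted once). Its null distribution comes from random sequence
sets that match the observed peaks in *number of sequences* and in the
*exact multiset of sequence lengths* — the strictest reading of matching
"size and length distribution", and one that removes any density-estimation
choice. The default of 1000 null samples gives a p-value floor of 1/1001.

Because G-rich motif frequencies are highly composition-sensitive, the
background model of the null is explicit and reportable:

* `uniform` (default): i.i.d. bases at probability 1/4 each;
* `composition`: i.i.d. bases at user-given probabilities;
* `match_peak_mononucleotide`: i.i.d. bases at the frequencies observed in
  the peaks;
* `dinucleotide_shuffle`: each peak shuffled preserving its exact
  dinucleotide counts (Altschul–Erickson Eulerian-walk shuffle), retaining
  both composition and neighbour structure per sequence.

The choice is genuinely open — random DNA can mean any of these — so the
package defaults to the simplest model and records the model used in every
report. Against G-rich peaks the uniform null is the most liberal; the
peak-matched and shuffle nulls are progressively more conservative.

Two p-values are reported. The primary one is the one-sided empirical
p-value with add-one correction,
`p = (1 + #{null >= observed}) / (n_samples + 1)`, which is exact,
discrete and bounded below by `1/(n_samples + 1)`. A rank-sum
(Mann–Whitney) p-value comparing the single observed proportion against
the null proportions is reported alongside as `rank_test_p`; a one-vs-many
rank test is close to degenerate (its one-sided p cannot go much below
~0.04 under the normal approximation), so it is provided for completeness,
not recommended as the decision statistic. Calibration of the empirical
p-value is verified by simulation: with observed sets drawn from the null
generator itself, the fraction of 200 runs with p < 0.05 must lie in
[0.02, 0.10].

## G-rich region scanning

`scan_g_rich()` is a deliberately simple surrogate for G-quadruplex
scoring tools: a window of `window` bases (default 20) qualifies when its
G fraction reaches `min_g_fraction` (default 0.6) and it contains a run of
at least `min_g_run` consecutive Gs (default 2); overlapping qualifying
windows are merged into maximal regions, and each region is flagged for
containment of the GGAG core by a plain sense-strand substring test, since
that tetranucleotide is what distinguishes functional CNBP sites among
G-rich elements. The scanner makes no attempt to compute quadruplex
G-scores; regions are candidates for inspection, not structure calls.

## Decay kinetics

First-order decay is assumed: `A(t) = A0 exp(-k t)`, `t1/2 = ln 2 / k`.
qPCR input is converted by delta-delta-Ct (`rel = 2^-(Ct_target -
Ct_reference)`), then each replicate is normalised to its t = 0 level.
Normalisation notwithstanding, the regression of `ln A` on `t` *estimates*
the intercept rather than pinning it at 0 — a noisy t0 well then perturbs
only the intercept, not the slope. Two estimators are provided:

* `pooled` (default): one OLS fit over all replicate points; the 95% CI
  for `t1/2` comes from the t-distribution on the slope.
* `per_replicate_mean`: one fit per replicate; the report is the mean
  half-life with its standard error. The per-replicate values also feed
  `compare_half_lives()`, which tests conditions by a two-sample t-test on
  log half-lives (log scale, because half-lives are ratios).

A 50%-crossing linear-interpolation estimator (`half_life_interp()`) is
included for comparison because half-lives are often read directly off
decay plots; regression is the default since it uses every point. The
fitter refuses non-decaying courses (slope >= 0) rather than reporting a
negative half-life.

The simulator's defaults encode the experimental design of the stability
experiments this package models: 3 replicates (figure legends report
mean ± SD with n = 3), timepoints {0, 1, 2, 4, 8} h (a grid spanning the
3–9 h half-life range of interest; the exact chase times are not printed
in the source experiments), and condition presets with half-lives of 5 h
(control shRNA), 3 h (LAST knockdown, CNBP knockdown), 9 h (LAST
over-expression), 4 h (CCND1 5'UTR reporter without cofactors) and 9 h
(the reporter with LAST and CNBP). Measurement noise is multiplicative
lognormal with mean 1, because qPCR abundances are positive and errors
scale with level; the 5% CV default is a stand-in (the source experiments
do not state a noise model) and is exposed in the configuration. At 5% CV
the pooled estimator recovers half-lives in the 3–9 h range with a median
absolute relative error under 5%.

## Standard curves and absolute quantification

Serial dilutions are fitted by OLS of Ct on log10 copies. The slope maps
to amplification efficiency as `E = 10^(-1/slope) - 1` (slope −3.3219 is
perfect doubling). Copies are recovered by inverting the line; the
inversion refuses Ct values more than one cycle outside the calibrated
range rather than extrapolating an exponential model silently. Copies per
cell divide by the cell count of the assayed sample.

## Target nomination

Candidate direct targets are genes simultaneously (i) downregulated on
lncRNA knockdown and (ii) enriched in the protein's RIP fraction. The
boundary semantics follow the most literal reading of the filters and are
configurable and echoed into the output provenance:

* log2 fold change strictly *below* −0.58 (a gene exactly at the
  threshold does not pass);
* fold over input *at least* 4 (a gene exactly at 4.0 passes).

Gene identity is exact string equality after whitespace trimming and case
folding; alias resolution would pull in an external annotation dependency
and is out of scope. Where several peaks map to one gene, the per-gene
fold must be aggregated by the caller before filtering; the maximum over
peaks is recommended (a gene is "enriched" if any of its peaks is), and
duplicated input rows are collapsed that way with a warning. Whether an
adjusted-p cutoff accompanied the fold-change filter in the source
analysis is unstated; none is applied by default, but `p_adj` columns pass
through the readers untouched so callers can pre-filter.

## Synthetic data: what it does and does not emulate

The generators produce exactly the structures the pipeline consumes, with
known ground truth and mandatory seeds (echoed into logs and attributes):

* `gen_peak_set()` plants a motif in exactly `round(fraction × n)`
  sequences at uniformly random valid offsets, instantiating degenerate
  positions uniformly over their allowed bases. Background sequences can
  contain the motif by chance, so the planted and realised (scanned)
  proportions are reported separately — the planted value is the truth
  for recovery tests, the realised value is what a scanner should see.
* `gen_decay_course()` and `gen_standard_curve()` follow the closed-form
  models above; with zero noise their output is exact to machine
  precision, which anchors the exactness tests.
* `gen_gene_tables()` gives true targets a log2FC effect (additive
  Gaussian noise) and a fold-over-input effect (multiplicative lognormal
  noise, so folds stay strictly positive); background genes sit at
  log2FC 0 and fold 1. The recorded true-target list supports
  sensitivity/specificity checks.

These are idealised: real peak sets have composition heterogeneity,
overlapping transcripts and peak-calling artefacts; real qPCR has
plate/batch effects; real differential-expression tables have
heteroscedastic, count-driven noise. Passing recovery tests therefore
demonstrates correctness of the estimators under their stated models, not
robustness to every property of sequencing data.

## Numerical and scale choices

Determinism is contractual: every randomised function takes a seed and
restores the global RNG state on exit, and identical configurations give
byte-identical outputs. Random DNA is generated as one character stream
and split, keeping large null simulations (hundreds of thousands of
sequences) in the tens of seconds. The test suite sizes its simulations
for desk-scale runs: 200 calibration replicates at 200 null samples, 100
power replicates (GGAG planted at fraction 0.5 in 200 × 50 bp sequences,
detected at p < 0.01 in ≥ 95% of runs), 60-seed recovery batches for the
decay fitter; the acceptance script re-simulates each half-life condition
once at the default design. The add-one empirical p-value keeps all
reported probabilities in (0, 1]; ties (`null == observed`) count against
enrichment, which is the conservative direction.

## Known limitations

* The enrichment null models sequence content only; it cannot correct for
  transcript-abundance bias in RIP input.
* Single-exponential decay only; biphasic decay will show as lack of fit
  (low R²) rather than being modelled.
* The G-rich scanner does not compute quadruplex scores.
* Target nomination treats one value per gene; peak-to-gene aggregation
  happens upstream by the caller's declared choice.
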
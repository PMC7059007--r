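# bezametab

Serum-metabolomics analysis for very small paired cohorts: six patients,
three timepoints (0/6/12 weeks of treatment), an untargeted LC-MS panel
of 867 metabolites. The package is aimed at analysts who face the three
problems such designs combine — left-censored missing values,
within-patient correlation, and sample sizes where asymptotics cannot be
trusted — and provides the complete pipeline as tested, reusable
functions plus a numbered analysis workflow.

## What it implements

**Normalization.** Removal of partially characterised compounds and the
Xenobiotics class (867 → 736 targeted metabolites with the default
catalogue), per-metabolite rescaling to median 1, log10 transformation,
and single-pass masking of points beyond 4 SD of their metabolite mean.

**KNN-TN imputation.** Values below the detection limit
DL = min(observed) are modelled per metabolite *m* as draws from a
left-truncated Gaussian; the MLE of (μ_m, σ_m) maximizes

    Σ_i [ log φ((x_i − μ)/σ) − log σ ] − n · log(1 − Φ((DL − μ)/σ))

and standardizes the metabolite. Each missing cell is filled with a
sign-corrected, |Pearson r|-weighted average of its K = 10 most
correlated metabolites observed in that sample, then back-transformed.

**Differential abundance.** Per-metabolite GLS with week as fixed
effect and an exchangeable intra-patient correlation pooled across
metabolites (duplicate-correlation design); empirical-Bayes variance
moderation with hyperparameters (d₀, s₀²) from moment matching on
log s²_m; moderated t on d + d₀ df; four contrasts; Benjamini-Hochberg
FDR at 10%.

**Pathways.** One-sided hypergeometric over-representation with
Holm-Bonferroni control at 10%, and a topology impact score in [0,1]:
the share of relative-betweenness centrality carried by the hit
metabolites in the pathway graph.

**Exact small-cohort tests.** Sign-flip Wilcoxon signed-rank with the
fully enumerated 2^n null (for n = 6 patients the two-sided floor is
2/64 = 0.031), permutation Mann-Whitney, and Kruskal-Wallis with Tukey
HSD on ranks.

**Clustering.** k-means (k-means++, 100 restarts) of patient-centred
residuals, separating untreated from treated timepoints.

**Synthetic cohort.** The generator reproduces the data-generating
process the analysis assumes — patient random effects, run-day batch
factors, pathway-concentrated treatment shifts, MNAR left-censoring at
a global detection limit, rare spikes — with full ground truth, so
every stage is validated by parameter recovery.

## Worked example

```r
library(bezametab)

# a paired biomarker decreasing in all six patients: the exact floor
signflip_wilcoxon(pre  = c(312, 290, 351, 288, 344, 301),
                  post = c(198, 201, 270, 222, 241, 258))
#> Exact permutation test: statistic = 0, p = 0.03125 (null size 64)

# full synthetic pipeline: simulate -> normalize -> impute -> test ->
# pathways -> cluster
out <- run_pipeline(pipeline_config(out_dir = "run", seed = 42))
out$matrix_raw
#> AbundanceMatrix: 18 samples x 867 metabolites [stage: raw]
#>   missing cells: 1561 (10.0%)
#>   patients: 6; weeks: 0/6/12; run days: 3
```

The differential stage recovers the planted signal — 39 of 694 analysed
metabolites significant at 10% FDR for the pooled treated-vs-untreated
contrast (36 were planted), with a consensus intra-patient correlation
of 0.623 — and the three effect-bearing pathways head the enrichment
table:

```
                             pathway_id n_hits        p_raw       p_holm    impact
 alanine_aspartate_glutamate_metabolism     11 8.413006e-11 1.934991e-09 0.8989899
                   histidine_metabolism      9 1.058051e-09 2.327712e-08 0.6282051
                              tca_cycle     10 5.137381e-09 1.078850e-07 0.7676768
                          background_01      3 4.923929e-01 1.000000e+00 0.0355286
```

`p_raw` is the hypergeometric over-representation tail, `p_holm` its
familywise-adjusted value, and `impact` the fraction of the pathway's
betweenness centrality sitting on significant metabolites. The k-means
stage assigns the 18 timepoints to three clusters of six; the untreated
(week-0) samples form one pure cluster.

The same stages are laid out as a narrative workflow in `analysis/`
(`01_simulate.R` … `07_small_cohort_tests.R`); each script reads the
previous stage's tables from `results/` and prints what it found.

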
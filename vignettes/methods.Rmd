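---
title: "Methods: small-cohort serum metabolomics with left-censored imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-cohort serum metabolomics with left-censored imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bezametab)
```

## The analysis problem

`bezametab` implements the serum-metabolomics arm of a longitudinal
treatment study in a very small paired cohort: six patients sampled at
weeks 0 (untreated), 6 and 12 of treatment, profiled on an untargeted
LC-MS platform reporting 867 metabolites grouped into "super-pathway"
classes. Three features of such data shape every downstream choice:

* **n is tiny.** Eighteen samples, six independent subjects. Parametric
  small-sample theory is fragile, so inference leans on exact
  permutation nulls and on borrowing strength across metabolites.
* **Missingness is left-censored (MNAR).** Values below the instrument's
  detection limit (DL) vanish preferentially from the low tail, so naive
  imputation (column means, k-NN on raw values) is biased upward.
* **Repeated measures.** Each patient contributes all three timepoints;
  ignoring the within-patient correlation misstates every standard
  error.

Because the study's metabolomics matrix was never deposited, the package
carries a first-class synthetic-data generator that reproduces the
statistical structure the analysis assumes, and the entire pipeline is
validated against that generator's ground truth.

## Normalization

Four steps in fixed order, enforced by stage tags on the matrix
container:

1. **Targeted filter.** Partially characterised compounds and the
   Xenobiotics class are removed. With the default catalogue (867
   compounds, 4 partially characterised, 127 Xenobiotics) exactly 736
   metabolites remain.
2. **Median rescaling.** Each metabolite is divided by the median of its
   observed values, giving every column median 1. An optional
   per-run-day mode computes the median within run-day blocks; it is
   *not* the default because in this design run days coincide with visit
   weeks, so block-wise rescaling would erase the treatment effect
   together with the batch factor (see *Known limitations*).
3. **log10 transform.**
4. **4-SD outlier masking.** Per metabolite, values with
   $|x - \bar x|/s > 4$ (sample SD) become missing, in a single pass.
   With a single extreme point the largest attainable $|z|$ is
   $(n-1)/\sqrt{n}$, so columns with fewer than 18 observed values can
   never lose a cell at this threshold; in an 18-sample cohort the rule
   only fires on near-degenerate columns. Masked cells become ordinary
   missing values eligible for imputation but are flagged in the
   provenance table, preserving auditability.

Columns never observed in any sample (possible in simulation when a
low-abundance metabolite is fully censored; impossible in a platform
report, which only lists detected compounds) are dropped before
rescaling and recorded in provenance.

## KNN-TN imputation

Missing values are treated as left-censored at a single detection limit,
estimated as the global minimum observed value (step I.1). For each
metabolite $m$ the observed values are modelled as draws from a normal
distribution truncated on the left at the DL, and $(\mu_m, \sigma_m)$
are obtained by direct numerical maximization of

$$\ell(\mu,\sigma) = \sum_i \log\phi\!\left(\tfrac{x_i-\mu}{\sigma}\right)
  - n\log\sigma - n\log\left(1 - \Phi\!\left(\tfrac{DL-\mu}{\sigma}\right)\right)$$

over $(\mu, \log\sigma)$ from the naive moment start (Nelder-Mead,
survival term computed on the log scale for stability). Direct
maximization rather than EM keeps the fit robust down to $n = 3$
observed values; below that the naive moments are returned with
`converged = FALSE` so the fallback is always visible. Values are
standardized with the truncated-normal MLEs, which is what distinguishes
KNN-TN from plain k-NN: the location/scale used for standardization are
corrected for the censoring.

Each missing cell (sample $i$, metabolite $m$) is then filled with a
weighted average of the $K = 10$ metabolites most correlated with $m$
(pairwise-complete Pearson correlation on the standardized values,
requiring at least 3 shared samples) among those observed in sample $i$.
The literature specifies only that the weights are "functions of the
Pearson correlations"; this implementation selects neighbours by $|r|$,
weights them $w_k = |r_k| / \sum_k |r_k|$, and negates a neighbour's
value when its correlation is negative — anti-correlated metabolites are
informative too, and the sign correction keeps the estimator unbiased
under linear dependence. Ties in $|r|$ break by metabolite ID so runs
are deterministic. A cell with no usable neighbour falls back to the
metabolite's observed mean. Half-DL is available as an alternative
fallback but is not the default: after median rescaling the global DL is
set by whichever metabolite has the deepest tail below its own median,
and DL/2 then undershoots badly for columns whose own censoring point
sits near their median. Back-transformation restores the original scale;
observed cells are never altered.

## Differential abundance

The stated design — repeated measures tested across time — is fitted as
the standard duplicate-correlation model for paired omics: week as a
fixed effect, patients as exchangeable-correlation blocks. A
per-metabolite intra-patient correlation is estimated from the two-way
ANOVA moment equations on the fixed-effect residuals (error df
$N - p - (n_{\text{pat}} - 1)$), clamped to the valid compound-symmetry
range, pooled across metabolites on the atanh scale, and the single
consensus value is used in a GLS fit per metabolite. Full per-metabolite
REML mixed models were deliberately avoided: with six patients the
per-metabolite correlation is barely identified, and pooling is what
makes the estimate usable.

Variances are moderated by empirical Bayes. With $s^2_m \sim s_0^2
F(d, d_0)$ (a scaled inverse-chi-square prior on the true variances),
the hyperparameters come from closed-form moment matching on
$\log s^2_m$ — the excess of $\mathrm{var}(\log s^2)$ over the
chi-square sampling contribution $\psi'(d/2)$ identifies $d_0$ through
the inverse trigamma; no excess means the variances are exchangeable and
$d_0 = \infty$ with the prior scale equal to the plain mean of the
$s^2_m$. Posterior variances $(d_0 s_0^2 + d s^2_m)/(d_0 + d)$ give
moderated t statistics referred to $t_{d + d_0}$. Four contrasts are
tested (mean of weeks 6 and 12 vs 0; 6 vs 0; 12 vs 0; 12 vs 6), each
BH-adjusted with significance declared at 10% FDR. The test suite checks
this implementation against limma at a shared correlation value
(identical effects, t statistics within numerical agreement) and checks
that forcing $d_0 = 0$ recovers the ordinary per-metabolite t-test.

Two residual matrices are returned. Model residuals (week and patient
structure removed) are diagnostics. The *patient-centred* matrix —
per-patient means removed, week effect retained — feeds the clustering:
an unsupervised separation of untreated from treated timepoints can only
exist in a matrix that still contains the week effect, so "residuals
from the mixed model" is read here as "abundances with the
between-patient variation removed".

## Pathway enrichment and topology

Over-representation is the one-sided hypergeometric tail
$P(X \ge n_{\text{hits}})$ within a universe restricted to analysed
metabolites carrying at least one pathway annotation (configurable to
the full filtered panel), Holm-adjusted with significance at 10%
familywise error. Pathways with no member in the universe are skipped
and logged; depletion is out of scope.

The topology impact of a hit set in a pathway graph is the share of
relative-betweenness centrality carried by the hit nodes:
nodes are scored by betweenness normalized per connected component by
$(n_c-1)(n_c-2)/2$, and impact is the hit-node sum over the all-node
sum, in $[0,1]$. A graph with no betweenness at all (components of
$\le 2$ nodes) falls back to the hit fraction of members; a pathway
without a graph reports `NA` rather than a guessed zero. The
implementation is verified against an exhaustive shortest-path-counting
oracle on every labelled graph up to 5 nodes and fixed-seed samples of
6-node graphs.

## Exact small-cohort tests

With six patients, the only permutation scheme that preserves the
pairing of a two-condition comparison is flipping each patient's
difference sign, giving a null of $2^6 = 64$ assignments and a smallest
attainable two-sided p of $2/64 = 0.03125$ — reported as 0.031, the
exact floor on which every significant paired biomarker comparison in a
six-patient cohort necessarily sits. The test uses the Wilcoxon
signed-rank statistic (zeros dropped, midranks for ties, exact integer
arithmetic on doubled ranks), a two-sided region defined by
$|W - E[W]|$ (well-defined under ties), the observed assignment counted
in the null (p never 0), full enumeration up to $2^{20}$ assignments
and seeded Monte Carlo beyond. The Mann-Whitney analogue enumerates
group relabelings up to $10^6$. Kruskal-Wallis uses the tie-corrected H
with its chi-square reference, and — when rejected at $\alpha = 0.05$,
the conventional gate — follows up with Tukey HSD applied to the global
midranks.

## Clustering

k-means on the patient-centred residuals: unit-variance columns,
Euclidean distance, k-means++ seeding, 100 restarts, best-of-restarts by
inertia, deterministic given the seed. The Lloyd loop retains its
per-iteration inertia trace so the monotone-descent property is testable
directly; `stats::kmeans` is used as an independent cross-check, not as
the implementation. k is fixed at 3 to mirror the three visit weeks; a
silhouette scan over k is provided as a diagnostic only. Clustering uses
all residual columns (no variance filter).

## The synthetic cohort

The generator emulates finished platform abundances (peak processing is
upstream of the model and out of scope):

$$x_{i m} = 10^{\mu_m + a_{p(i)} + \delta_{m,w(i)} + b_{d(i)} + \varepsilon_{im}}$$

with $\mu_m \sim N(4, 1)$ (log10 raw intensities spanning the usual
3-6 decade range), patient effects $a_p \sim N(0, 0.15^2)$, residual
noise $\varepsilon \sim N(0, 0.10^2)$ — an intraclass correlation of
0.69, typical of serum profiles — run-day factors
$b_d \sim N(0, 0.05^2)$ with samples batched by visit week, treatment
shifts $\delta = +0.3$ log10 (a doubling) at weeks 6 and 12 for the
members of three designated pathways of 12 metabolites each, global
left-censoring of the lowest 10% of values at the empirical quantile
(value-based deletion, exactly the MNAR-left premise of KNN-TN), and
spikes of $+3$ log10 at rate $10^{-3}$. The catalogue reproduces the
printed super-pathway proportions (187 Amino Acid, 27 Carbohydrate, 28
Cofactors and Vitamins, 11 Energy, 409 Lipid, 37 Nucleotide, 37
Peptide, 127 Xenobiotics, 4 partially characterised; 867 in total).
Where the study reports no value (effect size, variance components,
outlier rate), the defaults above were chosen once as field-typical
magnitudes and are not tuned thereafter.

What the generator does *not* emulate: correlated metabolite modules
beyond what shared patient/run-day effects induce, heavy-tailed or
metabolite-specific noise, drift within a run day, adducts or
misidentification. Passing tests therefore demonstrate correctness of
the statistical machinery under the model's own assumptions, not
robustness to everything real serum data can do.

## Numerical and design choices

* Truncated-normal MLE: Nelder-Mead on $(\mu, \log\sigma)$,
  `reltol 1e-12`, start at the naive moments; upper-tail survival via
  `pnorm(..., log.p = TRUE)`.
* Inverse trigamma by root bracketing on the log scale (monotone,
  tolerance 1e-12).
* Exchangeable-correlation clamp: $[-1/(k-1) + 0.05,\ 0.99]$.
* Sign-flip enumeration by subset-sum doubling on integer doubled
  ranks, so tie comparisons are exact.
* k-means empty-cluster repair: reseed at the point farthest from its
  centroid.
* All randomness flows through per-call seeds; generator and pipeline
  reruns are bit-identical (asserted in the suite).

Problem sizes in the validation suite are scaled to the study: the
catalogue checks run at the full 867/736 panel; null-calibration
resampling suites use 80-200 metabolite panels and 200 replicates,
sizes at which the Monte-Carlo error of the checked rates is a few
percentage points.

## Known limitations

* **Run-day is aliased with visit week.** One batch per visit means a
  run-day shift is formally indistinguishable from a treatment effect;
  global median rescaling cannot remove it, and per-run-day rescaling
  would remove the treatment effect with it. The generator therefore
  includes run-day variance in the default (effect-bearing) cohort, but
  null-calibration suites set it to zero, where false-discovery control
  is actually well-defined. Any real study with this confound inherits
  the same caveat.
* **Family-level calibration at small panels.** The consensus
  correlation and pooled prior scale are shared across metabolites, so
  their estimation error perturbs all tests in the same direction; at
  very small panels (tens of metabolites) the probability of at least
  one null BH discovery drifts above the nominal 10% (about 0.15-0.20
  at 80 metabolites in our measurements), and approaches nominal at the
  200+ panels the method is meant for.
* **A single global DL.** The KNN-TN premise places one detection limit
  on the whole rescaled matrix; after per-metabolite rescaling the
  effective censoring point is column-specific, so the truncated fit
  under-corrects some columns. This is inherent to the published
  procedure, not to this implementation.
* The smallest attainable paired p with six patients is 0.031; no
  multiplicity correction can rescue a single paired biomarker
  comparison below it.
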
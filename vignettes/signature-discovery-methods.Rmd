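---
title: "Methods: prognostic signature discovery from targeted plasma proteomics"
author: "plasmasig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prognostic signature discovery from targeted plasma proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmasig)
```

# The problem

Multiple-reaction-monitoring (MRM) plasma proteomics quantifies a few
hundred pre-selected proteins as normalized log2 light/heavy (L/H) ratios
— the log2 ratio of the endogenous peptide signal to a spiked
stable-isotope-labeled standard. `plasmasig` implements a complete
discovery workflow for small, three-group duration-of-response cohorts
(here: NSCLC patients on an ALK inhibitor, stratified as poor responders
with PFS ≤ 3 months, normal responders with 3 < PFS < 24, and long-term
responders with PFS ≥ 24), producing a candidate blood-based prognostic
protein signature. The reference configuration is a 22-patient cohort
(5/10/7 by group) with 126 of 327 monitored proteins detected in most
samples — small enough that every inferential choice below is dominated by
small-sample behavior, which is why the package leans on bias-reduced
logistic regression, permutation nulls, and repeated cross-validation
throughout.

The pipeline has five stages:

1. **Cohort I/O** — detection filtering, imputation, z-scoring, PFS-based
   group assignment.
2. **Differential expression** — per-protein one-way ANOVA and pairwise
   tests, BH correction, and a direction-consistent top-15 signature rule.
3. **Signature scoring** — single-sample enrichment (ssGSEA) per patient,
   plus Kaplan–Meier median-split reporting for individual proteins.
4. **Importance ensemble** — four learners under repeated half-split
   cross-validation, with a survivor-function rate-change cutoff selecting
   panel-search candidates.
5. **Panel search** — every 1–3-protein panel fit by Firth logistic
   regression, scored by optimism-corrected cross-validated AUC, distilled
   through a contribution analysis and a final multi-list combination.

# Stage choices and their rationale

## Detection, imputation, normalization

"Detected across most samples" is operationalized as a non-missing
fraction of at least `min_fraction = 0.8` (configurable). Remaining
missing values are imputed by the per-protein observed median (a
half-minimum left-censoring mode is available as a stress alternative;
MRM missingness at these abundances is not clearly intensity-dependent,
so median is the default). Z-scoring is per protein over non-missing
entries; classifiers consume centered unit-variance intensities.

## Differential expression

The group effect is screened with a classical one-way fixed-effects ANOVA;
pairwise contrasts default to Welch's t-test, which tolerates the unequal
group sizes (5–10) and variances typical here; Student's t and
Mann–Whitney are available. The signature rule requires a long-vs-normal
pairwise p below 0.1 *and* the same nonzero fold-change sign in the
long-vs-poor contrast, ranks by ascending p, and keeps at most 15
proteins. The p < 0.1 filter is read as applying to the *pairwise*
long-vs-normal test (the ANOVA reading is available via configuration).
Ties at the cutoff break by larger absolute fold change, then protein id,
so output is deterministic. Fold change is a difference of log2 means —
the log2 ratio of geometric means on the raw scale.

## Single-sample enrichment

The ssGSEA statistic ranks all proteins within a patient by expression and
accumulates the difference between a weighted in-signature ECDF (weights =
normalized rank value to the power `alpha = 0.25`, the canonical choice)
and the uniform out-of-signature ECDF, summed over the whole list. It
depends only on within-sample ranks, hence is invariant to any monotone
per-sample transformation. Raw (unnormalized) scores are reported because
the analysis only uses within-cohort ranking. A caveat worth stating: the
enrichment score treats the signature as an unsigned set. When the
selected signature mixes up- and down-regulated proteins — which the
direction-consistent rule permits, since "consistent" constrains the two
contrasts, not the sign itself — group-mean score ordering can degrade.
In simulations at a planted 1 SD effect, scoring the truly planted
(all-up) signature orders the group means (long > normal > poor) in well
over 80% of cohorts, while scoring the noisier selected signature does
not; the package therefore makes no claim that the end-to-end ordering is
robust at weak effect sizes.

## Importance ensemble

Four learners — gradient-boosted trees (100 trees, depth 3, learning rate
0.3), lasso, ridge, and elastic net (mixing 0.5) — are trained to separate
long-term responders from each comparison group on stratified half-splits,
repeated over 100 random column orders × 100 splits in the reference
configuration (tests and the acceptance script scale this to 10 × 10;
results are averaged either way). Importance is total split gain for the
tree learner and the squared fitted coefficient for the penalized
regressions, with the penalty chosen by an inner stratified 3-fold CV on
the training half over a 30-point lambda path. Column-order averaging
exists because tree split tie-breaks depend on column order. One
non-default hyperparameter is forced by the sample size: xgboost's
`min_child_weight` default of 1 forbids *any* split when the training half
has ~8 samples (a child's hessian bound is 0.25 per sample), so the
package sets it to 0.

### The rate-change cutoff

The importance vector of one learner is reduced to a candidate set by
detecting a change in the decay rate of its survivor function: a two-piece
exponential (piecewise-constant hazard along the importance axis) is fit
by profile maximum likelihood over all candidate breakpoints, and proteins
above a significant breakpoint are selected. Three numerical points
matter:

* The profile optimum over a continuous breakpoint always lands on an
  observed value (within an inter-event gap the likelihood is monotone),
  so candidate breakpoints are the distinct observed importances.
* Only breakpoints where the decay *slows* (a persistent high-importance
  tail) are eligible; a rate increase is a shape artifact, not a
  candidate tier.
* Real importance distributions are far from exponential (squared
  coefficients are chi-square-like; trial-averaged gains form a bump), so
  a literal exponential-null test rejects almost always and degenerates
  to selecting everything. The package therefore fits a one-piece gamma —
  which contains the exponential at shape 1 — probability-integral
  transforms the importances through it (making the null unit-exponential
  on the transformed scale), and calibrates the changepoint statistic by
  a seeded parametric bootstrap from the fitted gamma (199 replicates,
  level 0.05 by default). A model-free alternative (maximum drop of the
  empirical log-hazard) is available as `method = "second_diff"`.

A known limitation, documented deliberately: with a fixed label vector
over ~12–17 samples, some proteins correlate with the labels by chance
(|r| up to ~0.6 among 126 candidates), and repeated half-splitting
re-uses those same samples, so chance-correlated proteins accumulate
genuinely elevated mean importance under a null cohort. A calibrated
changepoint detector rightly flags that tail; consequently the candidate
union on label-permuted or null data is *not* near-empty at these sample
sizes, and candidate counts should be interpreted as "panel-search
inputs", not as significant discoveries. The exhaustive panel stage with
its permutation null is the stage that controls optimism.

## Panel search

Every subset of 1–3 candidates is fit by Firth bias-reduced logistic
regression: the Jeffreys-prior penalized likelihood maximized by
modified-score Newton iterations with step-halving (implemented in
compiled code; tens of thousands of refits per run). The penalty
guarantees finite coefficients under the complete separation that tiny
panels on 12–17 samples produce routinely. Performance is the
out-of-sample AUC over 100 stratified half-splits; within each split, 50
refits on shuffled training labels give a median null AUC whose excess
over 0.5 — the *optimism* — is subtracted from that split's AUC. The
panel estimate is the median corrected AUC with a 2.5–97.5% quantile
interval; ROC curves are vertically averaged on a fixed specificity grid
(0, 0.01, …, 1) with step interpolation. The optimism is computed per
split, not globally, following the reference procedure. Label shuffles
that produce a single-class training set are redrawn.

Panels whose corrected median AUC exceeds 0.85 are "high performance";
each protein's contribution is the fraction of high panels containing it,
and proteins above 5% form the contributing set per contrast. The final
signature combines the differential list and the two contribution lists.
Because a plain three-way intersection of lists of size ~15/33/15 cannot
yield the reference outcome of 22, the default rule is the annotated
union with every membership pattern reported (a strict ≥ 2-lists rule is
provided); proteins present in all three lists are flagged as the top
tier.

# The synthetic cohort generator

`generate_cohort()` is the test bed: 5/10/7 patients; 126 detected
proteins drawn from a block-structured multivariate normal (blocks of 5,
compound-symmetric correlation 0.5, via a shared block factor, unit
marginal variance); 5 planted prognostic proteins placed in distinct
blocks with direction-consistent standardized shifts (long-term +1.0 SD
vs normal and +1.5 SD vs poor by default); missingness completely at
random at 5% (capped per protein so every detected protein passes the 0.8
filter by construction, and with an optional left-censoring mode); 201
monitored-but-undetected proteins emitted with >50% missingness; PFS
uniform within group-consistent ranges (0.5–3, 3.5–23, 24–44 months),
progression observed for poor and normal responders and censored with
probability 1/2 for long-term responders. Everything is reproducible from
a single seed via per-stage derived seeds.

What it does *not* emulate: the real cohort's unknown correlation
structure (the block design is a stand-in), intensity-dependent
missingness, peptide-level variation, and any relationship between
expression and PFS *within* a group. Passing tests therefore demonstrate
procedural correctness and calibration under a plausible generative
model, not clinical validity of any discovered signature.

# Problem sizes used in tests and the acceptance script

Simulation sizes are chosen to make the full suite a coffee-break run on
one core while keeping every stochastic check adequately powered: the
ensemble recovery check uses 50 cohorts at 10 × 10 trials; null AUC
calibration uses 100 random panels at 25 splits × 20 shuffles; the
acceptance script runs the full pipeline at 10 × 10 ensemble trials, 15
splits × 8 shuffles and a 3,000-panel cap, plus a 10-cohort recovery
benchmark at the 1.5 SD planted effect. The reference configuration
(100 × 100 trials; 100 × 50 panel cross-validation over all 23,478 panels
from 52 candidates) is the package default and is sized for an overnight
single-core run.

# Known limitations

* The rate-change cutoff is one defensible reading of a scheme whose
  original description is not available; both implemented variants are
  labeled and neither is claimed to match the original exactly.
* Candidate selection is anti-conservative at these sample sizes (chance
  correlation, above); rely on the corrected panel AUCs downstream.
* The ssGSEA score is unsigned; mixed-direction signatures weaken the
  patient ranking.
* With n = 22, every reported quantity downstream of the ensemble is a
  function of a single data draw; the package's seeds make runs
  reproducible, not the biology.
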
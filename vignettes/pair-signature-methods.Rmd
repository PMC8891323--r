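---
title: "Methods: rank-pair immune lncRNA signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-pair immune lncRNA signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `lncPairSig`, the
tunable parameters and their defaults, the generative model of the
synthetic cohorts, and the numerical and design decisions that an
analyst re-using or auditing the package should know about. No empirical
claim is made here beyond what the test suite and
`scripts/acceptance.R` compute.

## 1. The rank-pair feature model

For an ordered pair of lncRNAs (A, B) and a sample s, the feature is
$S_{AB,s} = \mathbf{1}\{x_{A,s} > x_{B,s}\}$. Exact ties score 0 — the
"otherwise" branch of the definition — which in practice only matters
for discretized input, since the generator samples continuous values.
Pairs are oriented canonically (gene ids sorted lexicographically, the
pair named `A|B`), so naming is deterministic and `B|A` never appears;
re-encoding with the reversed orientation flips every non-tie value.

Because $S$ depends only on the within-sample ordering, the encoding is
invariant to any strictly monotone per-sample transform — the property
that motivates pair signatures over expression signatures, and the one
asserted exactly (not approximately) in the test suite.

**Constancy filter.** A pair whose majority value exceeds 80% of tumour
samples is removed: it cannot separate risk groups of useful size. We
read "0 or 1 ratio greater than 80%" literally as *strictly greater*,
i.e. keep $0.2 \le \widehat{freq}(1) \le 0.8$ with both boundaries
inclusive; both bounds are arguments of `filter_pairs()` since the
boundary convention is not identifiable from the published counts.

## 2. Screening immune-related, differentially expressed lncRNAs

* Coexpression: Pearson correlation of `log2(x+1)` values between each
  lncRNA and each immune gene over tumour samples; retained if some
  immune gene has $|r| > 0.4$ and $p < 0.001$ (t approximation). We use
  the two-sided $|r|$ reading because negative immune regulation is
  biologically relevant and a one-sided reading is not stated; `signed =
  TRUE` restores $r > 0.4$. Correlation over tumour samples only matches
  the downstream use (the signature is built on tumours);
  `tumour_only = FALSE` is available.
* Differential expression: Welch t per gene on `log2(x+1)`,
  $\log_2 FC = \bar{x}_{tumour} - \bar{x}_{normal}$, BH adjustment over
  the tested set only, calls at $|log2FC| > 2$, $q < 0.05$. A moderated
  (limma-style) statistic is deliberately not re-implemented; with the
  planted effect sizes (|log2FC| = 3 against within-group sd ≈ 0.4–0.8)
  the Welch test is essentially at power 1 and the difference is
  immaterial. On real small-n cohorts limma's shrinkage would matter;
  that is a documented divergence.

## 3. Signature construction

Training/test split is 1:1, stratified on the event indicator (event
proportions of the halves differ by at most a few points), seeded.
Selection is a strict cascade, asserted as a nesting invariant
(final ⊆ Lasso survivors ⊆ univariate candidates):

1. univariate Cox per pair, Wald $p < 0.05$ (the univariate threshold is
   not published; 0.05 is the common choice and is configurable);
2. Lasso-Cox (`glmnet`), penalty at the CV-deviance minimum
   (`lambda.min`) with 10 seeded folds. The deviance-minimizing rule
   maximizes selection power at the cohort sizes used here;
   `lambda.1se` is selectable. An optional repeated-subsample mode
   (select pairs chosen in ≥ f of R subsample refits) is provided for
   users wanting a stability-selection variant;
3. bidirectional AIC-stepwise Cox from the full survivor model
   (`stats::step`); non-identifiable covariates are dropped first and
   the final AIC never exceeds the initial one. If the Lasso selects
   nothing, the pipeline falls back to the top-10 univariate pairs and
   records the fallback in the run manifest.

The risk score is the exact linear predictor
$\sum_i \hat\beta_i S_i$, uncentered, so scores are comparable across
samples scored with the same signature.

**Comparison baseline.** The conventional expression signature
(`baseline_expression_signature()`) screens `log2(x+1)` expression by
univariate Cox, keeps genes at $p < 0.001$ by default, steps by AIC, and
splits at the median training risk. On the desk-scale synthetic cohorts
(200 training samples) the expression signal induced by planted
*ordering* effects is indirect and the 0.001 screen is underpowered, so
the packaged comparison (acceptance tests) uses $p < 0.05$ for the
baseline — a choice favouring the competitor, made at design time.

## 4. Time-dependent ROC and the AIC cutoff

`td_roc()` implements the Kaplan–Meier estimator of time-dependent
sensitivity/specificity: with $\hat S$ the overall KM curve and
$\hat S(t \mid X > c)$ the KM curve within scores above c,

$$Se(c,t) = \frac{[1-\hat S(t\mid X>c)]\,P(X>c)}{1-\hat S(t)},\qquad
  Sp(c,t) = \frac{\hat S(t\mid X\le c)\,P(X\le c)}{\hat S(t)}.$$

This estimator is fully specified without a smoothing bandwidth (unlike
the nearest-neighbour variant) at the cost of local non-monotonicity;
estimates are clipped to [0, 1], and AUC is the trapezoid over the
(1−Sp, Se) polyline sorted by (FPR, TPR) with (0,0) and (1,1) appended.
Coordinates are snapped to 10 decimals before sorting so floating-point
noise cannot misorder tied vertices. When no censoring precedes the
horizon the estimator reduces *exactly* to the empirical ROC and the AUC
to the Mann–Whitney statistic — the strongest available correctness
check, asserted on random instances.

**"AIC of each point".** The cutoff rule this pipeline replicates
evaluates an AIC at each 1-year ROC point without a standard
definition. The only AIC definable at a
point is that of a model for the dichotomized score, so for each
candidate cutoff (midpoints of consecutive sorted unique scores) we fit
a one-covariate Cox model on $\mathbf{1}\{score > c\}$ over the *full*
follow-up and record $AIC = 2 - 2\log PL$; the chosen cutoff minimizes
this AIC, and the 1-year horizon fixes the ROC on which candidates are
reported (sensitivity, specificity and Youden index accompany each
candidate). "Maximum inflection point" is treated as descriptive
language for this optimum; `method = "youden"` provides the standard
alternative, and on cleanly separated bimodal scores the two rules
produce near-identical dichotomizations. Group assignment is strict
(`score > cutoff` → high; a score exactly at the cutoff is low), and the
training cutoff is reused unchanged for test and entire sets.

## 5. Consensus subtyping

`consensus_cluster()` is a self-contained Monti resampling
implementation: per repetition, 80% of samples are drawn and clustered
by average-linkage hierarchical agglomeration on Hamming distance of the
binary pair features (the natural metric for 0/1 data; the source
ecosystem's default inner clusterer is hclust as well); consensus(i, j)
is the co-clustering count over the co-sampling count. Final labels at
each k come from hclust on 1 − consensus. Defaults: `reps = 100`,
`item_fraction = 0.8`, `k_range = 2:6` — the customary defaults of
consensus-clustering software.

**Choosing k.** The delta-area rule is implemented in the conventional
form: $\Delta(2) = A(2)$ and $\Delta(k) = (A(k) - A(k-1))/A(k-1)$ for
k > 2, where A(k) is the area under the consensus CDF; k maximizes
$\Delta$. The proportion of ambiguous clustering
(PAC = CDF(0.9) − CDF(0.1)) is reported alongside as a diagnostic. The
replication profile fixes k = 3 (`run_config(fixed_k = 3)`), as the
subtype analysis asserts three clusters; `fixed_k = NULL` enables the
data-driven choice.

## 6. The synthetic cohort generator

`generate_cohort()` draws everything the pipeline consumes, with ground
truth attached. The generative model, and what each default emulates:

* **Expression.** Per-gene log2 values are Gaussian
  ($\mu_g \sim N(5, 1.5^2)$, $\sigma_g \sim U(0.4, 0.8)$),
  exponentiated to a linear scale for output — log-normal expression
  that matches the `log2(x+1)` convention of the tests. Planted pair
  members share $\mu$ and $\sigma$ so their ordering is balanced
  (freq(1) ≈ 0.5) and survives the constancy filter.
* **Coexpression** via a shared latent factor with loading $\sqrt r$ on
  both partners, giving Pearson correlation exactly r in closed form
  (default target 0.6).
* **Differential expression**: ±`de_log2fc` (default 3) added to tumour
  samples of the planted up/down sets; the default 81 up / 15 down
  mirrors the motivating cohort's split.
* **Survival**: exponential with hazard
  $h_0 \exp(\sum_i \beta_i S_i + \gamma (cluster-1))$ — the simplest
  model satisfying the proportional-hazards assumption of every Cox
  stage. The default $h_0 = 10^{-3}$/day (median OS ≈ 2 years at linear
  predictor 0) places all three clinical horizons (1/3/5 years) inside
  the informative follow-up range, so 1-year discrimination is estimated
  from a non-trivial number of events. Censoring is independent
  $U(0, m)$ with m solved from the closed form
  $E[(1-e^{-\lambda m})/(\lambda m)] = $ target (default 30%), so the
  realized censoring fraction is calibrated, not tuned.
* **Subtypes**: K balanced clusters (equal sizes, random membership).
  Cluster c shifts its "home" pairs' members by ±`cluster_sep` so the
  expected ordering flips between clusters — subtypes are recoverable
  from the pair features by construction, and balanced sizes give the
  delta-area rule a deterministic margin for the true k. A per-cluster
  log-hazard step `cluster_hazard` (default 0.5) plants the survival
  differences the cluster comparisons test for.
* **Covariates**: age, sex, grade, and an ordinal stage whose latent
  scale is mildly loaded on the true risk (`stage_assoc`, default 0.8),
  so the chi-square stage association the pipeline reports exists in
  truth. Infiltration scores (8 cell types × 3 methods), checkpoint-gene
  expression and drug IC50 (10 of 20 drugs) are linear in the
  standardized true risk plus noise; when the cohort is null (no pairs,
  no clusters) the linear predictor is constant and all of these are
  exactly null — the false-positive calibration checks rely on this.

What the generator does **not** emulate: negative-binomial count noise,
library-size and batch effects, competing risks, non-proportional
hazards, and correlated null pairs beyond shared-gene overlap. Passing
tests therefore demonstrate correctness of the pipeline's statistics
under its stated assumptions, not robustness to those violations.

## 7. Problem sizes and test design

The heavy properties run on cohorts of 400 tumour samples (recovery,
discrimination), 240 (subtyping) and 200 (null calibration), sizes at
which every check completes in seconds while keeping the Monte-Carlo
margins comfortable. A risk score built from four binary pairs with
|β| = 0.8 takes five values only; its population 1-year AUC is ≈ 0.74 —
near the discrimination bound being asserted — so the AUC check is made
on the mean over five seeded cohorts rather than per seed, where the
estimator's sampling noise (sd ≈ 0.03) would dominate. Planted-pair
recovery, sign agreement and the log-rank separation are asserted per
seed.

Two deliberate deviations from common phrasing are worth restating:
between-group comparisons of independent high/low groups use the
rank-sum (Mann–Whitney) test — a signed-rank test is inapplicable to
independent samples — and BH adjustment is always reported alongside raw
p so users can filter on either.

## 8. Known limitations

* The Cox stages assume proportional hazards; the generator satisfies
  this by construction and the package does not test it on user data.
* `td_roc`'s KM estimator can be locally non-monotone; the raw
  per-cutoff values are returned unaltered and only the integration
  sorts them.
* Stepwise-AIC selection inherits the usual post-selection optimism;
  training-set AUCs are optimistic, which is why test- and entire-set
  AUCs are always computed with the training-set cutoff.
* With very few distinct risk-score values (small signatures), the
  cutoff candidate grid is coarse; this is intrinsic to binary-pair
  scores, not an implementation limit.
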
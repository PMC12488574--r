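---
title: "Stage-salient biomarker mining and cascade classification: methods"
author: "stageSalience"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-salient biomarker mining and cascade classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stageSalience)
```

# Scope

`stageSalience` turns a stage-annotated log2 expression cohort into four
classifiers — cancer/normal screening, metastasis, molecular subtype and
histology — plus the biomarker mining that feeds them, and a late
integration of miRNA and methylation layers. This vignette documents the
statistical models, the tunable parameters, the synthetic-data generator
that the test suite is built on, the numerical choices, and the places
where the design was genuinely open.

# Stage-encoded differential expression

## Linear models and codings

Expression is modelled per gene by least squares on the sample's group
(control, stages I–IV), in two equivalent codings:

* *reference coding*: `y = α + Σ β_k X_k`, where `α` is the control
  baseline and `β_k` is the stage-k log2 fold-change (lfc) vs control;
* *cell-means coding*: `y = Σ β_k X_k` including the control indicator,
  so coefficients are group means and any contrast can be formed
  explicitly.

Both are computed from one limma cell-means fit; `fitStageModel` checks
the coding equivalence property (`β_k^{ref} = β_k^{cm} − β_0^{cm}`) in
the test suite to 1e-10. Gene-wise variances are moderated by
empirical-Bayes shrinkage (limma's `eBayes`); `moderate = FALSE` yields
ordinary t-tests, which the tests use to verify coefficients against a
direct group-mean oracle. P-values are BH-adjusted across genes *within*
each contrast family, never pooled across families.

Weighted fits are supported through observation weights from
`varianceStabilize`: the transform is the strictly monotone
`log2(x + 0.5)` (pseudo-count 0.5 avoids −∞ and matches the standard
variance-stabilizer's behaviour closely enough for rank-based use), and
weights come from a lowess trend of sqrt(residual sd) on mean log2
expression, inverted to the fourth power — the classic mean–variance
precision-weight construction. Library-size normalisation is deliberately
not applied: the pipeline's inputs are already normalised
(RSEM-normalised or equivalent), and the closed form keeps the transform
auditable (`x = 0 → −1`).

## The two-level contrast protocol

* **Level I** (stage vs control): gene *g* is stage-k *specific* iff
  `|lfc_k| > lfc_min` (default 2, strict) and adjusted `p_k < p_max`
  (default 0.001, strict). Sets may overlap across stages.
* **Level II** (inter-stage): the *salient* stage is the argmax of the
  absolute deviation from control; ties yield no call. A salience call is
  confirmed only when every pairwise contrast of the salient stage
  against the other three stages is significant at `contrast_p_max`
  (default 0.05, BH-adjusted) with consistently signed deviations. The
  reported contrast p is the worst (largest) of the three; per-stage
  lists truncate to the `n_top_per_stage` (default 10) most significant.

The salience rule is formalized here as argmax-deviation plus
all-pairwise significance because that formalization reproduces, from the
shipped 24-row reference coefficient table, every printed stage label and
direction (`assignSalientStage`; exercised in the tests and the
acceptance script). Whether level II should gate on raw or BH-adjusted
p-values was open; the default is BH-adjusted (the stricter, more
defensible choice), configurable via `contrast_p_max` applied to the
adjusted matrix.

## Monotonic and contra-regulated genes

A gene is *monotonic* when its four stage means are strictly increasing
or strictly decreasing (strict inequalities; assessed on means, not
medians). Flagged genes get a stage-ordinal fit (stages coded 1–4,
controls excluded — the reference intercepts are consistent with a
stage-anchored fit, and "across the cancer stages" reads most naturally
without controls), reporting intercept, slope, BH-adjusted slope p and
adjusted R².

*Contra-regulation* captures paradoxical trajectories of stage-specific
genes. The default taxonomy assigns pattern 1–3 to up-anchored genes
whose deviation peaks at stage I/II/III and then decays toward stage IV,
and patterns 4–6 to the mirrored down-anchored cases; trajectories whose
deviation keeps building toward stage IV yield no call. The strict
variant (`require_crossing = TRUE`) additionally demands that the decay
cross the control baseline. The permissive default is chosen because an
early-peaking, decaying profile that never crosses control is still
paradoxical with progression (the canonical stage-I example behaves this
way); the six templates are a documented, overridable default rather than
a fixed scientific claim.

# Preprocessing

* `filterLowVariance`: removes genes with sample sd strictly below
  `sigma_min` (default 1; the boundary is retained).
* `mergeSubstages`: AJCC sub-stages → macro stages I–IV; stage X, missing
  and unrecognized → NA; total and idempotent.
* `deriveMolecularSubtype`: triple-negative → TNBC; hormone-receptor
  negative, HER2+ → HER2; any hormone-receptor positivity → Luminal,
  split into A/B only when a Ki-67 labelling index is available
  (threshold 0.14). Missing IHC propagates to NA, never imputed.
* `stratifiedSplit`: per-stratum train counts are rounded and corrected
  by the largest-remainder rule so the total equals
  `round(n × train_fraction)`. The published cohort's 854/212 arithmetic
  is not exactly 80:20 of 1,066 under any single rounding rule, so the
  contract here is internal consistency (proportions within one sample
  per stratum), not replication of external rounding.
* `smoteBalance`: counting semantics of the classic R implementation —
  minority grows to `n_min × (1 + perc_over/100)` via convex
  combinations with one of `k` (default 5) minority nearest neighbours;
  the majority is downsampled to
  `(perc_under/100) × n_min × perc_over/100`, without replacement when
  possible. Defaults `perc_over = 1000`, `perc_under = 300` reproduce
  16 → 176 and 837 → 480; these are the only semantics consistent with
  those counts.
* `fsqnHarmonize`: per-gene rank mapping of a target matrix onto the
  empirical quantiles of a reference (feature-specific quantile
  normalization), used to harmonize microarray data onto an RNA-seq
  reference before inference. Ranks are preserved exactly; distributions
  match up to interpolation on the `(r − 0.5)/n` grid.

# Feature selection

Problem-specific base pools: screen = stage-salient ∪ top-n linear-model
genes; metastasis = rank-consensus of the metastatic contrast (top-50 by
lfc ∩ top-50 by significance, backfilled with the top 6 by significance)
∪ stage-salient; molecular subtype = top-10 per pairwise subtype
contrast; histology = all genes with `|lfc| > 2` in the ductal/lobular
contrast.

`borutaSelect` reimplements the shadow-feature scheme (it is part of the
pipeline's defined computation): each iteration appends permuted copies
of all features, ranks by random-forest impurity importance, and scores
a hit when a real feature beats the best shadow. Decisions use two-sided
binomial tests at `alpha` (default 0.01) with a Bonferroni correction
across the features still undecided, after a 5-iteration burn-in;
rejected features leave the pool. Tentative features are excluded by
default. `rfeSelect` performs cross-validated backward elimination on
forest importance and returns the smallest subset whose mean CV balanced
accuracy is within one standard error of the best — a rule that favours
the small panels this style of analysis reports (5–24 genes). Balanced
accuracy (not plain accuracy) is the RFE metric because the learning
problems are imbalanced. `consensusFeatures` intersects the two
selectors, falling back to the RFE set with a warning when the
intersection is empty (the typical case is nesting, RFE ⊂ Boruta).
Importance ties break by column order; all selectors are
seed-deterministic.

# Model zoo, nested selection and the cascade

Six families with compact default grids: random forest (250/500 trees,
mtry √p or p/3), RBF-SVM (cost 0.1/1/10), kNN (k 3/5/7/11, in-package
vote fractions so multiclass probabilities are available), single-hidden-
layer network (nnet, width 8/16/32, decay 0.01), two-hidden-layer
perceptron (in-package trainer: tanh units, softmax output, Adam,
early stopping on the training-loss plateau), and XGBoost (depth 2/4/6,
learning rate 0.05/0.3, 150 rounds). Features are standardized
(training-set center/sd) for the distance- and gradient-based families.
Raw model scores serve as probabilities; no recalibration, since the
readout reports prediction probabilities as-is.

`tuneModel` grid-searches by stratified 10-fold CV on balanced accuracy
and refits the winner on all training data; `nestedSelect` tunes each
family only on the training set, evaluates once on the holdout, and
ranks by holdout balanced accuracy (ties: MCC, then spec order). An
instrumentation hook records every sample identifier tuning touches, so
leakage onto the holdout is auditable (and asserted zero in the tests).
Multiclass metrics are macro one-vs-rest; MCC uses Gorodkin's R_K;
single-class truth yields AUROC = NA.

`ensembleVote` accepts a prediction only when all members agree
(probability = mean member probability) and abstains otherwise,
reporting coverage and accuracy over accepted samples. The cascade
(`predictSample`) screens first; only "cancer" calls reach the
metastasis, subtype and histology models. Confidence flags are "strong"
when a model's probability reaches its threshold — defaults 0.9 (screen),
0.75 (metastasis), 0.7 (subtype, histology), reflecting the probability
bands observed for correct predictions in the reference analysis — and a
weak level-1 cancer call is annotated, never overridden. Histology
abstentions propagate as "ambiguous" while other fields stay intact.

# Multi-omics late integration

miRNA salience reuses the identical two-level contrast on the miRNA
matrix. A regulator is *expression-concordant* with a target when their
directions are opposite; *temporal concordance* (evaluated only given
expression concordance, NA otherwise) requires the regulator's salient
stage to be at least as early as the target's. Methylation drivers
require Pearson r ≤ −0.3 with p < 0.001 against expression;
differential methylation uses Wilcoxon rank-sum tests (BH-adjusted
p < 0.05) with an absolute effect-size filter of 0.1 on the
group-mean-beta difference. Beta mixtures are fit by EM on the logit (M)
scale for numerical stability — whether the original analysis fit on the
beta or M scale is unstated, and the logit scale makes Gaussian
components defensible — with the component count (≤ 3) selected by BIC
and means reported back on the beta scale. Probe clustering cuts an
average-linkage tree on 1 − r at the smallest k for which every
within-cluster pair correlates above 0.7.

The "stage-informed models" whose consensus defines stage-salient
methylation are specified only by citation in the source material; here
they are implemented as the two-level contrast applied to (a)
probe-averaged betas, (b) logit M-values and (c) per-sample mixture
component means — documented as an interpretation. Consensus demands
stage agreement across all call sets and is monotone in the number of
agreeing sets. Methylation–expression temporal concordance requires the
repressive pairing (hyper + down, or hypo + up) and methylation salience
no later than the expression extremum; ties count as concordant by
default (configurable), which matters only for same-stage pairs.

# The synthetic cohort generator

`generateCohort` emulates the class structure of the cohort this
pipeline was designed around: 112 controls, 181/616/249/20 samples in
stages I–IV (metastatic disease is therefore rare — about 16:837 within
an 80% training split), subtype fractions 567:37:115
(Luminal:HER2:TNBC) and histology fractions 780:202 (IDC:ILC), allocated
exactly by largest remainder. Metastasis is stage IV by construction, so
the stage IV ⇔ metastatic invariant holds exactly.

Expression is Gaussian on the log2 scale (the pipeline consumes
variance-stabilized data, and the downstream mathematics is linear-model
based, so read-level count simulation would add nothing the tests can
use) with `noise_sd = 1` and baseline 6. Planted classes shift group
means: stage-salient genes get their full effect at the salient stage
and 0.6 of it elsewhere (mirroring the reference profiles, where
non-salient stages also deviate from control, just less); monotonic
genes get slope × stage; contra genes follow the six trajectory
templates; subtype/histology/metastasis markers shift the matching
samples. Default planted effects sit at the reference analysis's scale:
salient deviations 2.6–5.7 log2 units, monotonic slopes 0.62–0.89 per
stage, marker lfc 2.6–3.5. `n_genes` defaults to 600 — large enough for
stable BH behaviour and realistic null mass, small enough that the whole
suite runs in well under a minute; the real cohort's ~19k genes are not
a generative condition.

The miRNA layer gives each planted regulator its own stage-salient
profile plus an anti-coupling of strength 0.4 × the standardized target
residual, producing target correlations around −0.4 to −0.6 (the
realistic range for direct miRNA–target pairs) without letting the
target's stage profile overwhelm the regulator's own salience. The
methylation layer assigns samples to mixture components by expression
rank (inverted for negative coupling), so the planted correlation sign
and the planted component structure are both exact by construction.

One user seed fans out to independent per-layer substreams (expression,
labels, miRNA, methylation), so all three layers are reproducible
together and separately.

**What the generator does not emulate** — and hence what passing tests
do and do not show about real data: no read-level counts or
library-size effects, no batch effects, no gene–gene correlation beyond
the planted couplings, no heavy-tailed or bimodal expression within a
group, no mislabelled samples, and clinical labels that are exactly
consistent (real IHC and staging metadata are not). Recovery results on
this generator demonstrate that the *rules and estimators are implemented
correctly and have power at the stated effect sizes*; they do not
demonstrate clinical performance, which in the reference analysis
required external cohorts that are out of scope here.

# Numerical choices and degenerate inputs

Tie-breaks: salience argmax ties → no call; grid-search ties → first
grid row; importance ties → column order; ensemble tie (disagreement) →
abstain. Degenerate inputs: constant features are auto-rejected by
Boruta; zero-variance methylation yields NA correlation and no driver
call; all-tied Wilcoxon rows get p = 1; non-converged mixtures fall back
to fewer components with a warning; strata smaller than 2 go wholly to
training with a warning; a minority class smaller than k+1 reduces k
with a warning. The logit transform clips betas to [1e-4, 1 − 1e-4].

Problem sizes in the shipped tests: the default-structure cohort
(1178 × 600) for the salience/monotonic recovery checks; a 246-sample,
120-gene fixture for everything exercised repeatedly; 100 noise features
× 30 shadow iterations for the Boruta permutation null; 50 replicates of
n = 300 two-component mixtures for the BIC recovery rate; and a
200-gene end-to-end run (simulate → contrasts → selection → nested
training → cascade inference). These sizes are the package's own choice
of a desk-scale demonstration: large enough for the stated statistical
properties to hold with margin, small enough to run routinely.

# Known limitations

* The cascade does not discriminate stages I–III within non-metastatic
  cancer, and Luminal A/B are lumped (the A/B split needs Ki-67 or
  grade, which the reference cohort lacked).
* Variance moderation is limma's; the package does not attempt bit-exact
  replication of any external toolchain's internals.
* The contra-regulation taxonomy and the Averep/M-value/MethylMix-style
  consensus are documented interpretations with configurable defaults,
  not assertions about the original procedures.
* FSQN needs a per-gene reference distribution; genes absent from the
  reference pass through unharmonized (with a warning).
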
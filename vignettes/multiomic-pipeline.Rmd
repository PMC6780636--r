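---
title: "Methods: multi-group classification and cross-correlation of paired microbiome-metabolome profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-group classification and cross-correlation of paired microbiome-metabolome profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`micromet` implements an integrated analysis of paired gut-microbiome and
plasma-metabolome tables across several clinical groups (here: healthy
controls and four systemic autoimmune diseases — SLE, Sjögren's syndrome,
primary antiphospholipid syndrome and undifferentiated connective tissue
disease). This vignette is the package's account of the methods: what each
stage computes, which choices were genuinely open and how they were
resolved, and what the synthetic-data tests do and do not demonstrate.

## The data model

A cohort (`MultiOmicCohort`) holds three aligned tables over the same
samples: a genus-level relative-abundance matrix (rows sum to 1), a
metabolite peak-area matrix (non-negative), and per-sample metadata — the
clinical group, age in years, and three binary treatment flags
(hydroxychloroquine, prednisone above 5 mg/day, any immunosuppressant)
that later serve as confounders.

## The synthetic cohort generator

The study data the pipeline targets are not publicly deposited, so every
stage is exercised on a generator that emulates the study design: 114
subjects (HC 27, SLE 27, SjS 23, PAPS 11, UCTD 26), 130 genera, 254 peaks.
Ages are drawn per group from normal distributions matched to the clinical
table (e.g. SjS patients are on average two decades older than PAPS
patients) and treatment flags are Bernoulli draws with per-group rates from
the same table; controls are untreated. This makes confounder adjustment
consequential rather than decorative.

Feature intensities are log-normal: `log x = mu_f + group shift +
confounder term + block term + noise`. Specifics, with rationale:

* **Base distribution.** Per-feature baseline means `mu_f ~ N(0, 1.2^2)`
  for genera (log scale) reproduce the heavy right tail of genus tables;
  residual log-SD is 1, so the planted `effectSize` is a standardized mean
  shift. Genus intensities are closed (divided by the row total) to give
  compositional relative abundances; peaks stay unclosed, as raw areas.
* **Group effects.** Each planted feature receives a permuted graded
  contrast `effectSize * {-1, -0.5, 0, 0.5, 1}` across the five groups, so
  group pairs are separated by between 0.5 and 2 effect-size units and no
  single contrast dominates.
* **Zero inflation.** Structural absence is applied per genus before
  closure, with prevalence drawn from a Beta distribution around the
  configured mean; about 8% of genera are made rare (zero in over 92% of
  samples) so the `> 95%` zero-prevalence filter has something real to
  remove. Planted genera are capped at 10% absence and their baselines are
  drawn from the abundant range: a biomarker that the canonical `> 1%`
  mean-abundance filter deletes before the classifier runs would make
  recovery impossible *by construction*, which is not the property the
  tests are meant to probe.
* **Correlation blocks.** Each block couples 5 genera and 6 peaks through a
  latent per-sample factor. The loading is chosen in closed form so that
  two log-normal features sharing the factor have *raw-scale* Pearson
  correlation near the configured `blockCorr`
  (`lambda^2 = log((1 - rho) / (1 - rho e^{s^2}))` with reduced residual
  variance `s^2` for block members). Closure adds log-total noise to the
  genus side and attenuates the observed correlation; the genus-side
  loading is inflated by a fixed factor (1.6, calibrated once against the
  generator's own contract of `observed r ~ blockCorr`) to compensate.
  Negative `blockCorr` is supported but attenuates more, a known asymmetry
  of log-normal correlation.
* **Confounders.** Every feature receives random coefficients
  (`SD = confounderStrength`) on standardized age and the three flags, on
  the log scale.

Two caveats the generator makes explicit. First, because confounders act
log-linearly, their effect on the *raw* scale is nonlinear; linear
residualization cannot remove it completely, so a cohort with
`confounderStrength > 0` is *not* a complete null for the
cross-correlation — the permutation test correctly detects the residual
shared structure. Calibration checks therefore switch confounder effects
off. Second, group-specific demographics (age, drug rates) are themselves
group-informative; a classifier null additionally requires
`confounderStrength = 0` for the same reason. Both are properties of the
emulated design, not artifacts of the procedure.

What the generator does *not* emulate: read-level sequencing noise,
compositional artifacts of OTU picking, LC-MS retention drift or batch
effects. Passing tests show the pipeline recovers structure of the kind it
assumes; they cannot certify behavior under real-data pathologies outside
that model.

## Preprocessing

* Genus tables are filtered to genera with mean relative abundance
  strictly above 1% ("overall abundance" is read as the mean proportion,
  the usual convention for closed tables; for such tables the alternative
  reading — share of total signal — is numerically identical).
* Features zero in strictly more than 95% of samples are removed; in the
  classifier this filter is fitted per training fold.
* Peak areas are normalized by MSTUS — each sample divided by its summed
  intensity over the peaks detected in *every* sample (the common
  definition of "total useful signal"); if no peak is complete the divisor
  falls back to the sample total, with a warning. MSTUS is applied once,
  globally: it is a per-sample operation that uses no cross-sample
  statistics beyond the detection pattern, so fold-wise refitting would
  change nothing but the bookkeeping.
* Within each training fold, features are standardized, an isolation
  forest (500 trees by default, subsample 256) is fitted on the
  standardized data, exactly `floor(0.05 * n)` highest-scoring samples are
  removed, and location/scale are re-estimated on the retained samples.
  "5% of the outliers" is read as a contamination fraction with a floor
  count — the only reading consistent with fold sizes near 90. Constant
  features get unit scale with a warning. Test folds are transformed with
  training statistics and never trimmed.

## The classification engine

The evaluation design is a repeated (10x) stratified 5-fold outer
cross-validation; within each outer training set, a 5-fold inner
cross-validation drives feature and model selection. Stratification deals
each group's shuffled members round-robin into folds, starting each deal
from the currently smallest folds so remainders spread out; with 11 PAPS
samples every outer test fold holds at least two.

The model zoo is fixed: naive Bayes, adaptive boosting (500 rounds),
random forest (500 trees), extremely randomized trees (500 trees), and a
soft-voting average of the four. All emit class-probability scores.
Boosting is SAMME with depth-1 decision stumps (weighted-accuracy split
search in C++); forests come from `ranger`; naive Bayes from `e1071`.

**Fitness.** All selection is scored by the weighted one-vs-one balanced
accuracy. For each unordered class pair the evaluation set is restricted to
samples truly in the pair; sensitivity is the recall of the
lexicographically first class, specificity the recall of the second, and a
prediction outside the pair counts against whichever class it belongs to.
Pair weights are proportional to restricted sample counts. Inner-CV fitness
is computed on the *pooled* inner-fold predictions rather than as a mean of
per-fold values: with groups as small as 11, inner test folds routinely
lack one class of a pair, and per-fold means would be biased by which pairs
happen to be evaluable in which fold.

**Stochastic hill climbing.** The search state is a feature-inclusion bit
vector starting from the full set. Each iteration flips one uniformly
random feature and re-evaluates fitness with the currently selected
learner; a move is accepted if fitness strictly improves, or ties with a
strictly smaller subset (so plateaus shrink the model). The search stops
after `hillClimbBudget` consecutive rejections (default 200) or at a hard
cap of `10 * budget` total iterations, which bounds the worst-case cost
when many moves keep being accepted. The learner is re-selected from the
zoo every 25 accepted moves; ties in selection go to the first zoo entry
(naive Bayes). Every iteration is recorded in a trace.

**No leakage, by construction and by audit.** Filters, standardization,
outlier trimming, feature search and model selection all see only the
outer-training set; fold-wise preprocessing inside the inner CV is fitted
once per inner fold on the full feature set and candidate subsets index
its columns (exact for per-feature standardization; the outlier set is
deliberately held fixed across candidate subsets, which also makes the
search tractable). A test replaces outer-test rows with noise and verifies
bit-identical selected features, learner, trace and preprocessing
statistics.

**Reporting.** Outer-test predictions are pooled per repeat into one
one-vs-one metric set (BA, F1, AUROC as weighted pair means); headline
values are the mean and SD of these across repeats — the `0.73 +/- 0.03`
form. The consensus subset collects features selected in more than half of
the outer models; a single final search on all data is available by
running the search functions directly on the full cohort.

## Univariate screening

Selected features are screened by tie-corrected Kruskal-Wallis tests with
Benjamini-Hochberg correction across features at alpha 0.05 ("FDR
correction" without further qualification is taken to mean BH); flagged
features get Dunn's pairwise z-tests from pooled ranks with tie
correction. Dunn p-values are unadjusted across pairs by default — the
procedure is already gated by the KW+FDR screen — with a switch for
within-feature adjustment.

## Confounder-adjusted cross-correlation

For metabolite y (dependent), genus z (independent) and covariates X (age
plus the three drug flags), the partial correlation is the Pearson
correlation of the OLS residuals of y on [1, X] and z on [1, X]. Iterating
over all genus-metabolite pairs gives the G x M matrix; entries whose
residual vector is numerically zero (feature collinear with X) are NaN
with a note.

**Permutation correction.** Significance uses a step-down min-p
(Westfall-Young) procedure with B permutations (default 10,000). The null
is built by permuting the *rows of the metabolite block as a whole*
against fixed genera and covariates: this preserves the correlation
structure within the metabolome, which the min-p method's validity
(subset pivotality) relies on, and matches the reading of "permuting the
Y variable" with Y the metabolite block. Raw p-values use the
`(1 + count) / (B + 1)` convention. For the step-down pass, each
permutation's entry-level p-values are computed on the *same*
`(1 + count) / (B + 1)` scale with the permutation itself excluded from
its own count — so the attainable floor, `1 / (B + 1)`, matches the raw
p-value floor exactly. This alignment matters: mixing a `1/B`-scale null
with `1/(B+1)`-scale raw p-values makes the step-down count miss ties at
the floor and declares every extreme entry significant (family-wise error
near 1 in simulation); with aligned scales the procedure is valid and
mildly conservative. Adjusted p-values are enforced monotone in raw-p
order and never fall below the raw value. Note the granularity: with m
matrix entries, the smallest achievable adjusted p is about `(1 + m') /
(B + 1)` where `m'` counts permutations extreme for some entry, so B must
be large relative to m for any entry to clear alpha — with B = 10,000 and
a full-size matrix this is satisfied; small-B runs are for calibration
only.

**Highlighting** requires both adjusted p below alpha (0.05) and |partial
r| above 0.3; the corrected p is used because the procedure is explicitly
a multiple-testing correction.

**Bi-clustering and the simplified matrix.** Genera are clustered on the
rows of the partial-r matrix and metabolites on its columns (Euclidean
distance on r-profiles, Ward linkage via `ward.D2` — Ward assumes
Euclidean geometry, which the profiles provide). The tree is cut at an
explicit parameter, defaulting to 7 genus and 9 metabolite clusters: a
reproducible artifact cannot "inspect the tree manually", so the cut is a
declared setting. Per-sample centroids are means of *raw* relative
abundances and *raw* peak areas over each cluster's features, and the full
partial-correlation + min-p pipeline is rerun on the centroid tables.
With all-singleton clusters this reproduces the unaggregated matrix
entrywise, which is tested exactly.

## Diversity

Chao1 (bias-corrected: `S_obs + s1(s1-1) / (2(s2+1))`, finite when
doubletons are absent) and Shannon entropy (natural log, base switchable —
no base is canonical) are computed per sample; rarefaction curves
subsample without replacement at 10 evenly spaced depths up to a maximum
(matching the "10 subsampling points up to a fixed maximum" design) and
average the index over seeded Monte-Carlo draws. The mean rarefied
richness is validated against the closed-form hypergeometric expectation
(`vegan::rarefy`). UniFrac/PCoA beta diversity is out of scope — it
requires a phylogeny and external tooling.

## FreeViz projection

The projection is linear: embedding = standardized data x anchor matrix
(features x 2). Anchors start on the unit circle in seeded random order
and are updated by back-projected point forces: same-class pairs attract
proportionally to distance, different-class pairs repel proportionally to
1/distance (capped below 1e-3), following the original FreeViz force law;
the anchor matrix is rescaled to maximum row norm 1 after each step. The
iteration count is fixed (no convergence detection) for reproducibility,
and the average silhouette of the embedding is recorded each step.
Classes with a single sample are excluded from force computation.
Per-class mean and covariance are exported for confidence ellipses;
drawing is left to the caller. The silhouette is the standard Euclidean
one; singleton clusters score 0 by convention, and an all-singleton
labelling is an error.

## Problem sizes used by the tests and the acceptance script

The shipped checks run at deliberately reduced sizes chosen as the
smallest that still demonstrate each property: classifier calibration and
recovery use 100 trees/rounds, hill-climb budget 20 (cap 200), 10 repeats
for the null check and 3 for recovery; family-wise error calibration uses
100 null cohorts with a 20 x 30 matrix at B = 200; the power check uses 20
replicates of a 30 x 40 matrix at B = 1000 with 5 x 5 cluster cuts. The
acceptance script classifies the genus table with 3 repeats and the wider
peak table with 1 repeat (budget 8, cap 40) and runs the full
cross-correlation matrix at B = 1000 (reporting the raw-p highlight rule
alongside, since the adjusted-p floor grows with the entry count) and the
7 x 9 simplified matrix at the default B = 10,000. The analysis defaults (500 trees, budget 200, B = 10,000, 10
repeats) remain the package defaults.

## Known limitations

* The hill climb is a local search; with correlated features the selected
  subset is one of many near-equivalent optima, and the consensus subset
  should be read as "features the search keeps", not a unique signature.
* Westfall-Young adjustment is computed in memory (`B x entries`
  doubles); very large matrices at B = 10,000 need a few hundred MB.
* Partial correlation removes only linear covariate effects.
* The pooled one-vs-one AUROC of a fixed finite cohort has cohort-level
  variability around 0.5 under the null (a few hundredths at n = 114);
  calibration statements are about this band, not about exact equality.
* e1071's naive Bayes prediction dominates the per-iteration cost of the
  search on wide tables; the iteration cap keeps this bounded.
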
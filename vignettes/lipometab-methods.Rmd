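---
title: "Methods: multiblock metabo-lipidomics classification of HCV-related liver disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiblock metabo-lipidomics classification of HCV-related liver disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lipometab` implements a complete chemometrics workflow for
distinguishing hepatocellular carcinoma (HCC) from chronic HCV infection
and mixed cryoglobulinemia (MC) in plasma metabolomics and lipidomics
feature tables. This vignette is the package's account of the underlying
methods: the statistical models, their assumptions, the tunable
parameters and why the defaults are what they are, the numerical
conventions, and what the synthetic-data tests do and do not demonstrate
about real data.

## The data model

The pipeline's currency is a `feature_table`: a samples-by-features
abundance matrix with per-sample metadata (class ∈ {HCC, HCV, MC},
study vs pooled-QC status, AFP in ng/mL, age, gender) and per-feature
metadata (block, feature family, internal-standard mapping). Abundances
are non-negative ion intensities; `NA` marks a feature not detected in a
sample. Two blocks are analysed jointly: polar metabolites (HILIC-type
acquisition) and lipids (RP-type acquisition) measured on the same
samples.

## Preprocessing

Steps run in a fixed order; each appends a row to a report so the
feature bookkeeping is auditable.

1. **Missingness filter** (`filter_missing`). A feature is removed iff
   it is missing in *more than* 75 % of study samples **or** more than
   50 % of QC pools (both comparisons strict). The source description of
   this rule is grammatically ambiguous between AND- and OR-removal; we
   adopt OR because it is the conservative quality reading — a feature
   unreliable in either respect is dropped — and both thresholds are
   arguments.
2. **QC CV filter** (`filter_cv`). `CV% = 100·sd/mean` over a feature's
   observed QC values; features above 30 % are discarded, as are features
   whose CV is undefined (fewer than two QC observations, or a zero QC
   mean). The filter runs on raw intensities by default; whether it
   should see normalized intensities is not determinable from the source
   workflow, so the step is exposed separately and can be re-ordered by
   the user.
3. **Normalization** (`normalize_abundance`). Metabolomics:
   total-ion-sum — each sample row divided by its summed observed
   intensity, making observed row sums exactly 1 (within 1e-12).
   Lipidomics: internal-standard — each feature divided sample-wise by
   its class-specific IS feature, after which IS features are dropped.
   A zero row sum or a zero/missing IS value is an error naming the
   sample, not a silent repair.
4. **Imputation** (`impute_min_fraction`). Every missing *or zero* cell
   of feature *j* becomes `min observed positive value of j / 5`. Zeros
   must be treated as missing because log10 follows; they are counted
   separately in the report. The rule presumes missingness is
   left-censored (below the detection limit), which is exactly how the
   synthetic generator produces it.
5. **log10** and **autoscaling**. After imputation all values are
   strictly positive. Autoscaling divides by the *sample* SD (n − 1
   denominator; the source does not specify, and at these n the choice is
   immaterial). Constant columns cannot be autoscaled and are removed
   with a warning.

**Scaling and leakage.** The original workflow autoscales each full
block before splitting. The package supports that (`scaling = "global"`
in `run_workflow()`) but defaults to learning the centering/scaling
vectors on the training partition and applying them to test samples
(`"fit_on_train"`), because global scaling leaks test-set information
into the model. Both modes are tested; on the synthetic cohorts the
difference is negligible, which is itself informative about the sizes
involved.

## PCA, Hotelling ellipses, and SUM-PCA fusion

PCA is computed by SVD of the autoscaled matrix; scores are `U·S`,
eigenvalues `S²/(n−1)`. A deterministic sign convention — the
largest-magnitude element of each loading vector is positive — makes
scores reproducible across BLAS implementations. Requested components
beyond the numerical rank are truncated with a warning.

Score plots carry per-class Hotelling T² confidence ellipses at
95 %: `T²crit = 2(n−1)/(n−2)·F₀.₉₅(2, n−2)`, with the ellipse derived
from the eigendecomposition of the class score covariance scaled by
`T²crit`. The acceptance suite verifies ~95 % empirical coverage on
10,000 bivariate-normal scores.

**SUM-PCA** fuses blocks at low level: each autoscaled block is
multiplied by a block weight, blocks are concatenated column-wise, and
one PCA is fit on the fused matrix; its scores are the super scores
`T_sup`. The default weight is `1/√p_b` (p_b = number of variables in
block b), which equalizes every block's total sum of squares after
autoscaling — the standard SUM-PCA convention. The exact weighting used
in the original analysis is described only in supplementary material we
do not reproduce, so the weight is configurable (`"none"`,
`"sqrt_nvar"`, `"sqrt_eigen"`); with a single block every choice reduces
to plain PCA up to a scalar, which the tests assert.

## Kennard-Stone splitting

Training sets are chosen per class by the classic deterministic
Kennard-Stone maximin algorithm: start from the two most distant points,
then repeatedly add the candidate whose minimum distance to the selected
set is largest. All ties break toward the lowest sample index, so the
split is a pure function of the data. Three choices deserve comment:

- **Distances** are Euclidean on the first 3 SUM-PCA super-score
  columns of that class (autoscaled within class). The source does not
  state the dimensionality; 3 matches the three-component score plots
  used for exploration, and it is an argument (`fused_components`).
- **Training size** is `⌈0.7·n_class⌉`. The ceil rule is inferred from
  the published per-class performance denominators (49/17/7 training and
  20/6/3 test samples for classes of 69/23/10); it is exposed as
  `fraction`.
- **Initialization** is the classical farthest-pair start.

The greedy selection is verified against an exhaustive maximin oracle
for n ≤ 8 in the tests. One split is shared by both omics blocks and the
AFP benchmark so that all methods see identical partitions.

## PLS-DA

Class labels are one-hot coded; the response columns are centered and
NIPALS PLS2 runs with X- and Y-deflation. The fit stores weights `W`,
X-loadings `P`, Y-loadings `Q`, scores `T`, the implied regression
coefficients `B = W(PᵀW)⁻¹Qᵀ`, and the Y sum of squares explained per
component, `SS_a = (t_aᵀt_a)·‖q_a‖²`. With as many latent variables as
the rank of X, the coefficients coincide with multivariate least squares
on the one-hot response — an oracle equivalence asserted in the tests.
Prediction assigns the class with the largest predicted response
(argmax; exact ties go to the first class in sorted order, a
deterministic rule the tests pin down). No Bayesian threshold is
applied: argmax is the simplest rule consistent with three classes.

The number of latent variables is chosen by leave-one-out
cross-validation on the training partition only: for each candidate
count the left-out sample is classified by a model refit (including
re-autoscaling) on the remainder; the smallest count attaining the
minimum error wins, so ties favour parsimony. The NIPALS sequence is
nested in the component count, which lets one fit per left-out sample
serve all candidate counts.

**VIP scores.** `VIP_j = √(p·Σ_a SS_a·(w_aj/‖w_a‖)² / Σ_a SS_a)`. The
multi-response (PLS2) `SS_a` is used because the models are
three-class; the source does not specify the multi-response VIP
variant. Squared VIPs average to exactly 1, so `VIP > 1` marks
above-average influence; reduced models are refit from autoscaling
onward on the `VIP > 1` set or the top-20 ranked features (ties in the
ranking break by feature id).

## SIMCA

Each class gets its own autoscaled PCA submodel fit only on that class's
training rows. A new sample is judged by two statistics relative to the
submodel: Hotelling `T²` in the retained-score space with critical value
`k(n−1)/(n−k)·F₁₋α(k, n−k)`, and the squared orthogonal residual `Q`
with critical value from Box's scaled chi-square approximation on the
discarded eigenvalues (`g = θ₂/θ₁`, `h = θ₁²/θ₂`,
`Qcrit = g·χ²₁₋α(h)`). The combined reduced distance is
`d_c = √((T²/T²crit)² + (Q/Qcrit)²)`; class-modelling mode accepts class
c iff `d_c ≤ √2` (a sample may belong to several classes or none —
outlier status is expressible), and discriminant mode assigns
`argmin_c d_c`.

One calibration subtlety is worth stating plainly: each limit
individually accepts ≈ 95 % of self-generated samples at α = 0.05 — the
acceptance suite verifies both coverages within ±2 % — but the combined
`√2`-radius region strictly contains the joint acceptance box, so its
self-acceptance is ≈ 97 % asymptotically. That is a property of this
widely used convention, not a calibration error; the tests therefore
check the per-limit coverages (the well-defined 95 % claims) and that
the combined rule is at least as permissive as their conjunction.

## Metrics, ROC, and univariate statistics

Confusion matrices are true-by-predicted; per-class counts are standard
one-vs-rest (TP, FP, TN, FN), with `sensitivity = 100·TP/(TP+FN)` and
`specificity = 100·TN/(TN+FP)` reported to two decimals. The source's
prose definitions of TN/FP/FN are internally inconsistent (its "true
negatives" read as misclassified members of the class); the standard
definitions are used, which also reproduce the published percentage
patterns (e.g. 46/49 = 93.88 %).

ROC curves sweep every distinct score as a threshold; AUROC is the
trapezoid area, which equals the Mann-Whitney U statistic over
`n₊·n₋` with tied scores counting one half — verified against
brute-force pair counting for n ≤ 50. Multi-class problems reduce to
HCC-vs-rest, matching the clinical question (catching HCC, including
AFP-negative HCC).

Per-feature inference is a fixed-effects one-way ANOVA on the
preprocessed abundances (the source's lone mention of "N-way" ANOVA is
not actionable — no covariates are stated — and its result tables are
labelled one-way). Degenerate features (zero within-group variance) get
p = 1 when group means are equal and p = 0 otherwise, flagged. Raw
p-values are reported without multiplicity adjustment, matching the
source convention. The age audit reports the Pearson correlation of each
model-relevant feature with age and its two-sided t-test p-value.
Over-representation analysis is a generic upper-tail hypergeometric test
against user-supplied sets (GMT reader included); the original pathway
p-values depend on an external metabolite-set library and are out of
scope.

## Benchmarks and cohort statistics

The AFP rule calls a sample HCC-positive iff AFP > 20 ng/mL — the
boundary itself is negative, consistent with the clinical "≤ 20" bin —
and its accuracy is the percentage of HCC samples (with measured AFP)
called positive, per split partition. MC patients have no AFP
determination and are excluded. Cohort tables are compared with Pearson
chi-square (no continuity correction) for 2×3 tables and two-sided
Fisher exact for 2×2 tables; this mapping reproduces the published
cohort p-values exactly (0.3354, 0.0196, 0.266, 0.0071), whereas the
table footnote's "one-way ANOVA" cannot — the mapping is an inference
from numeric agreement, and both tests are exported directly. The
published AFP p-value (0.4973) is not reproducible from the printed
bins and presumably used the underlying continuous values; it is not a
package target.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` simulates the study design so every stage is
testable offline:

- class sizes 69/23/10 plus pooled QC replicates (`n_qc`, default 8;
  the true injection count is unpublished, so it is a free parameter);
- per-feature base abundances log-normal across features
  (`base_log10_mean = 5`, `base_log10_sd = 0.6` — typical ion-count
  magnitudes and dynamic range for annotated features);
- class effects as per-feature-family log10 offsets mirroring the
  reported differential biology: short/long-chain acylcarnitines and
  amino-acid derivatives up in HCC, medium-chain acylcarnitines up in
  HCV, LPC/LPC-O strongly down in HCC, PCs mildly up in HCC/HCV versus
  MC. Default offsets of 0.40–0.50 log10 against a within-group SD of
  0.12 log10 put the planted effects at ≥ 3 within-group SDs — clearly
  detectable at these sample sizes, as the reported compounds were;
- QC pools as the per-feature mean of all study samples with 10 %
  multiplicative noise, so ≥ 90 % of features show QC CV < 20 %
  (matching the reported platform stability) and QC rows carry no class
  effect by construction;
- left-censored missingness: cells below the pooled 15 % abundance
  quantile go missing with probability 0.35, concentrating missingness
  at low abundance exactly where the min/5 imputation rule is
  meaningful;
- internal standards as constant spikes (one per lipid family) with
  QC-level noise only;
- AFP from a two-component truncated log-normal mixture whose per-class
  exceedance of 20 ng/mL matches the published fractions (35/69, 1/23,
  0/10; MC recorded as not determined), and age/gender matching the
  published marginals.

These defaults are the study conditions of the package's tests and are
not adjusted per run. What the generator does **not** emulate: raw
spectra, retention/CCS dimensions and adducts, batch drift and run-order
effects, correlated feature families (features are conditionally
independent given class), annotation error, or any dependence between
omics signal and AFP status (they are simulated independently, which is
what makes the AFP-negative evaluation a clean construction). Passing
tests on this cohort therefore demonstrate algorithmic correctness and
sane statistical calibration — not that real plasma data will reach the
same accuracies; with conditionally independent features and 3-SD
effects, near-perfect synthetic classification is expected, and the
published real-data numbers (e.g. test accuracies of 94–100 % and
AUROCs of 0.83–0.94) are not desk-reproducible without the original
processed tables.

## Numerical conventions and degenerate inputs

- SVD sign convention as above; NIPALS inner-loop tolerance 1e-10, max
  500 iterations; X/Y residuals exhausted before the requested component
  count truncate the model with a warning.
- All ties (argmax class assignment, argmin SIMCA class, Kennard-Stone
  candidates, LOO component counts, VIP ranks) resolve
  deterministically toward the lowest index / first sorted label.
- Constant columns are removed (with a warning) before scaling;
  a reduced feature subset that is entirely constant is an error.
- A feature with no observed positive value cannot be imputed and is an
  error (it should have been filtered).
- Chi-square requires positive margins; Fisher is exact so no statistic
  or df is reported; hypergeometric p with zero overlap is 1 by
  definition.

## Problem sizes in the test suite

The packaged tests run the full pipeline on the default 102-sample,
two-block cohort (about 10 s), Monte-Carlo coverage checks on 10,000
bivariate-normal scores and 5,000 SIMCA self-samples, a 1,000-feature
ANOVA null, and oracle equivalences on small instances (n ≤ 50 for ROC,
n ≤ 8 for Kennard-Stone). These sizes give the coverage assertions
sampling error well inside their ±1–2 % bands while keeping the suite
fast enough to run habitually.

## Known limitations

- No batch/drift correction beyond QC monitoring (none was reported in
  the source workflow).
- No sparse or penalized PLS variants, and no class reweighting for the
  strong 69/23/10 imbalance.
- SIMCA component counts are selected with one shared count across
  classes in `select_components_loo()`; per-class counts can be passed
  to `fit_simca()` directly.
- The ORA is generic: biological conclusions require a curated
  metabolite-set library, which the package deliberately does not ship.
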
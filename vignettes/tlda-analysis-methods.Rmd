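---
title: "Methods: relative quantification and class analysis of TLDA miRNA profiles"
author: "tldaRQ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relative quantification and class analysis of TLDA miRNA profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tldaRQ)
```

# The data and the quantification model

A TaqMan low density array experiment produces one cycle-threshold (CT)
value per well: the PCR cycle at which the reporter fluorescence crosses
a fixed threshold. CT is a log2-scale abundance readout — one cycle is
one doubling, and lower CT means more template. The design this package
targets profiles 666 miRNA assays per specimen on two microfluidic cards
(panel A, 377 assays; panel B, 289), each card carrying the endogenous
control MammU6 in four replicate wells and one plant-derived
negative-control assay. Wells that never amplify are exported as
`Undetermined`.

`ct_matrix` stores this faithfully: one row per *well* (control
replicates keep distinct well indices), an explicit mask for
undetermined wells, per-sample batch labels, and control roles inferred
from assay-name patterns. The full assay identifier with its trailing
numeric assay ID (`hsa-miR-204-4373094`) is the primary key throughout:
mature and star (`*`) strand assays of the same miRNA would collide
under the bare name.

Quantification is the comparative-CT chain:

$$\Delta C_T(a,s) = C_T(a,s) - \overline{C_T}(\mathrm{MammU6}, s),
\qquad
\Delta\Delta C_T(a,s) = \Delta C_T(a,s) - \Delta C_T(a,\mathrm{cal}),
\qquad
\mathrm{FC} = 2^{-\Delta\Delta C_T}.$$

The control CT is the arithmetic mean of the unmasked MammU6 replicate
wells *per card* (per sample, per panel). Averaging per card rather than
across both cards of a specimen is deliberate: the two cards are
separate PCR runs and the control must absorb card-level offsets. The
subtraction makes every downstream quantity invariant to per-sample
additive CT shifts — pipetting, input amount, batch effects common to a
card — which is also a tested property of the pipeline.

Assumptions worth stating: amplification efficiency is taken as exactly 2
per cycle for all assays (no Pfaffl-type efficiency correction), and
MammU6 is taken as stably expressed. Within those assumptions the
calibrator sample has relative quantity exactly 1 everywhere, and
calibrating to sample *a* then to sample *b* gives reciprocal fold
changes — both enforced by tests at machine precision.

## Group fold changes, bins, intensities

Only per-sample fold changes are defined by the model, so a group-level
summary is a design choice. We use the ratio of geometric means of the
relative quantities, equivalently $2^{-(\overline{\Delta C_T}_1 -
\overline{\Delta C_T}_2)}$: it is the only aggregation under which the
log2 fold-change column is the difference of group means on the additive
CT scale, the calibrator cancels exactly, and the ratio of per-class
geometric mean *intensities* reproduces the fold change. Intensity is
defined as $2^{-\Delta C_T}$ so that larger means more abundant;
class-mean intensity columns in the report layouts are geometric means,
i.e. $2^{-\mathrm{mean}\,\Delta C_T}$. Fold-change bins are computed on
$\max(\mathrm{FC}, 1/\mathrm{FC})$ so up- and down-regulation bin
symmetrically (`FC 1.2-1.6`, `FC 1.6-2.0`, `FC 2.0-4.0`, `FC > 4`;
nothing below 1.2-fold is binned).

Masked wells are excluded from all means rather than imputed; an
optional censoring policy (`apply_ct_ceiling()`, default 40 cycles)
substitutes a ceiling CT instead, which treats non-amplification as
"at least this dilute". The default keeps masking because imputing at
the ceiling biases low-expression fold changes toward the ceiling
difference.

# Class comparison statistics

Two parallel analysis modes mirror the two normalization routes:

* **Mode I** works on log2 relative quantities ($-\Delta\Delta C_T$) and
  uses the plain pooled-variance two-sample t-test. Statistics are
  computed on the additive log scale, never on raw fold changes.
* **Mode II** works on MammU6-normalised CT (log2 intensity,
  $-\Delta C_T$) and uses the random-variance moderated t by default.

With 666 assays and 3–10 samples per class, per-assay variance estimates
are noisy. The random variance model assumes per-assay precisions
$1/\sigma^2_g \sim \Gamma(a, b)$, under which the observed residual
variance $v_g$ with $d_g$ degrees of freedom satisfies $v_g\,a\,b \sim
F(d_g, 2a)$. `fit_rvm()` maximises this F likelihood over $(\log a,
\log b)$ from several moment-based starts (L-BFGS-B, bounded to keep the
likelihood finite; homogeneous variance sets correctly drive $a$ to the
full-shrinkage limit). The moderated statistic replaces $v_g$ with
$\tilde v_g = (d_g v_g + 2/b)/(d_g + 2a)$ and tests on $d_g + 2a$
degrees of freedom. Parameter recovery (within 10% on 5000
model-simulated variances) and type-I calibration (rejection rate within
[0.045, 0.055] at $\alpha = 0.05$ on 20 000 model-conform null assays)
are part of the test suite.

Degenerate assays — zero residual variance, or fewer than two unmasked
values in a class — are *flagged with p = 1*, not dropped, so the
666-assay multiple-testing universe stays intact for FDR computations.

## Permutation machinery

Three permutation procedures share one vectorised row-statistic kernel:

* **Per-assay permutation p** — two-sided; when the number of distinct
  label assignments $\binom{n}{n_1}$ is at most the permutation budget,
  the exact exhaustive distribution is enumerated (for 3 vs 3 the
  attainable two-sided minimum is 2/20 = 0.1); otherwise Monte-Carlo
  permutations with the add-one convention $(1+k)/(1+B)$, so no p-value
  is zero.
* **Global test** — the proportion of permutations yielding at least as
  many assays significant at $\alpha = 0.001$ as the observed labelling
  (plain proportion; with $B = 1$ it is 0 or 1 by the count convention).
* **Multivariate selection** — selects assays so that, with 90%
  confidence over the permutation distribution, the false discovery
  proportion is below 10%. Candidate cutoffs are the ordered observed
  p-values; for each, the confidence-quantile of the permuted count of
  p-values under the cutoff bounds the false discoveries; the largest
  admissible cutoff wins. Two details matter for correctness. First, the
  observed labelling is included in the permutation set, as in standard
  permutation inference. Second, selection is gated on a permutation
  min-p test of the global null at level $1 - \text{confidence}$:
  scanning many cutoffs is by itself slightly anti-conservative, and the
  gate restores the exact guarantee that under a complete null the
  selection is empty with the stated confidence. With
  `confidence = 0` the rule degenerates to bounding the *expected*
  false-discovery count. Hyperparameters of the moderated t are fitted
  once on the observed data and reused across permutations: the variance
  prior describes the assay set, not the labelling, and refitting per
  permutation multiplies cost roughly a hundredfold without changing the
  observed statistics.

Multi-class contrasts (e.g. node-positive/negative by age group) use a
row-wise one-way ANOVA F. Classes reduced to one member still contribute
to the between-class term; degrees of freedom adapt per row to the
classes actually observed after masking.

# Unsupervised analysis

For the sample embedding, each sample is centered by its mean and
standardised by the Euclidean norm of the centered vector (an idempotent
transform), and the samples are then embedded by their principal
components — with Euclidean distances, classical multidimensional
scaling and PCA coincide, so the first three component scores are
reported together with the variance fraction each explains. The mean
sample profile is removed before the decomposition; pairwise distances
are unchanged by that translation, and it is exactly what makes the
axes the classical-MDS axes (verified against `cmdscale` to 1e-8).
Assays with any masked value are excluded row-wise before embedding,
since a Euclidean geometry over incomplete vectors is not well defined.

Hierarchical clustering uses the Eisen heat-map defaults — centered
Pearson correlation distance ($1 - r$) with average linkage — with
metric and linkage as configuration knobs and a Euclidean option.
Constant profiles, whose correlation is undefined, are assigned the
maximal distance (2) and flagged. The output is data (trees, leaf
orders, the clustered matrix), with Newick export; rendering is left to
plotting adapters so the testable core stays image-free.

# Class prediction

Seven two-class classifiers share one training interface: compound
covariate predictor (t-weighted sum of selected features, threshold
midway between class mean scores), diagonal linear discriminant
analysis (pooled per-feature variances), nearest neighbour with k = 1
and k = 3 (Euclidean; k = 3 vote ties break to the nearest neighbour's
label), nearest centroid, a linear-kernel SVM (unit cost, no rescaling,
fixed solver settings for determinism), and a Bayesian compound
covariate (Gaussian class-conditional posteriors with equal priors and a
pooled score variance over the CCP score).

The error estimate is leave-one-out cross-validation in which the
*entire* model-building process — feature selection at $\alpha = 0.001$
by the moderated t, hyperparameter fitting included — is repeated inside
every fold. The stored per-fold feature lists are tested to equal an
independent recomputation from the training subset, and a leak-canary
dataset (each feature informative about exactly one sample) confirms
chance-level error. When a fold selects nothing — the expected outcome
on null data at $\alpha = 0.001$ — the fold predicts the training
majority class and is flagged. This makes the *permutation* behaviour of
LOOCV worth knowing: under permuted labels with balanced classes, the
majority model predicts every left-out sample wrong (error 1.0, a
well-known LOOCV artifact), so chance-level behaviour is assessed with a
permissive selection threshold that lets noise features through.
Significance of an observed error rate is the plain proportion of label
permutations whose cross-validated error is no greater.

# The synthetic generator

`generate_dataset()` draws
$$C_T(a,s) = \mu_a + u_s + w_{b(s)} - e(a, \mathrm{group}(s)) + \varepsilon$$
with per-assay baselines $\mu_a \sim U(22, 34)$ cycles, per-sample
offsets $u_s$ (sd 1.0), per-batch offsets $w_b$ (sd 0.3), planted
effects $e$ on the CT scale (one cycle per log2 unit, matching the
$2^{-\Delta\Delta C_T}$ model exactly), and technical noise (sd 0.5
cycles). Control wells (mean 20, replicate sd 0.15) share the sample and
batch offsets so normalization removes them exactly. Censoring to
`Undetermined` above 38 cycles is applied *after* noise, so masking
correlates with low expression as on real cards. All draws are standard
normals scaled afterwards, which keeps the random stream aligned when an
sd parameter changes (including sd = 0) — that is what makes the
shift-invariance property testable as an exact identity. The default
design mirrors the study: 10 + 10 melanoma and 3 + 3 nevus samples in
three batches, a single global calibrator in the first nevus group
("PN1"-style), with an optional calibrator-per-batch mode.

The defaults for noise magnitudes are choices a qPCR practitioner would
call typical for FFPE-derived TLDA data: replicate noise of half a
cycle, sample-loading offsets of a cycle, batch offsets a third of a
cycle. What the generator does *not* emulate: amplification-efficiency
variation between assays, correlated co-regulation between miRNAs,
panel-specific chemistry differences, or heavy-tailed outliers from
degraded FFPE RNA. Passing tests therefore validate the statistical
machinery under its own model assumptions; they do not certify
performance on real degraded-specimen data.

# Numerical and design choices

* Problem sizes in the validation suite are chosen to keep Monte-Carlo
  error meaningfully below the tested bands: 20 000 assays for type-I
  calibration, 5000 variances for hyperparameter recovery, 200 null and
  50 planted replicates (B = 100 permutations each) for the
  false-discovery control checks.
* Every stochastic operation takes an explicit seed; the pipeline writes
  seeds, versions and artifact checksums into its run log and manifest,
  and identical configurations reproduce identical artifacts.
* The pipeline surface is the exported functions plus `run_pipeline()`
  over a config list or YAML file; report layouts follow the standard
  column orders (`miR`, `FC`, `Log2(FC)`, `p value`, `FDR (BH)`,
  `FC Bin`; intensity layouts with per-class geometric means; per-class
  sensitivity/specificity/PPV/NPV).
* Known limitations: two-class prediction only; no efficiency
  correction; the cluster-significance test against a single
  multivariate-Gaussian null is out of scope; ingesting a given
  instrument export may need dialect options (`format_options`) since
  export layouts vary between software versions.
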
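---
title: "From voxelwise morphometry to an interpretable classification index: methods"
author: "vicindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From voxelwise morphometry to an interpretable classification index: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`vicindex` implements a complete case-control gray-matter-volume (GMV)
analysis: mass-univariate group statistics with cluster-extent
family-wise-error (FWE) control, supervised classification on the
suprathreshold voxels, Shapley-value attribution of the fitted
classifier, construction of a *volumetric integrated classification
index* (VICI) from those attributions, and association of the regional
VICI abnormality pattern with multi-donor gene expression. Because the
clinical populations such analyses target (here, an elderly, largely
male PTSD cohort contrasted with healthy controls) are behind
restricted-access archives, the package ships a seeded synthetic-cohort
generator with planted effects so that every stage is exercisable,
testable and reproducible from a clean checkout.

The pipeline ingests already-preprocessed data: modulated, spatially
normalized GMV maps. Segmentation, registration, bias correction and
modulation are upstream concerns of dedicated toolchains and are out of
scope; the 8 mm full-width-at-half-maximum (FWHM) Gaussian smoothing
that conventionally follows them *is* in scope and is applied by the
generator (and available as `smoothGaussian()`).

# The voxelwise model

At every voxel $v$ inside the analysis mask, GMV is modeled by ordinary
least squares as

$$ y_v = \beta_0 + \beta_g \, \mathbb{1}[\text{patient}] +
   \beta_a \,\text{age} + \beta_t \,\text{TIV} + \varepsilon, $$

with age (years) and total intracranial volume (TIV, mL) as nuisance
covariates. The group contrast $t_v = \hat\beta_g / \mathrm{SE}$ with
$\mathrm{df} = n - \mathrm{rank}(X)$ reduces exactly to the classical
pooled two-sample t-test when no covariates are requested — an identity
the test suite asserts to $10^{-10}$. The analysis mask keeps voxels
whose across-subject mean exceeds 10% of the global mean (a common
heuristic; the threshold is a parameter), and excludes voxels with
degenerate residual variance so that $t$ is finite everywhere it is
reported.

Voxelwise thresholding uses two-sided $p < 0.001$ (uncorrected), and
suprathreshold voxels are clustered under 26-connectivity (faces,
edges, corners), separately for each contrast sign so that hypo- and
hyper-volume effects never merge. Cluster labels are deterministic:
decreasing extent, ties broken by the smallest linear voxel index.

## Cluster-extent FWE by permutation

Classical random-field-theory cluster correction assumes smooth
Gaussian fields and known smoothness. This package instead builds the
null distribution of the *maximum cluster extent* by refitting the GLM
under random permutations of the group labels with covariates kept
attached to their subjects, and assigns each observed cluster

$$ p_{\mathrm{FWE}} = \frac{1 + \#\{b : \max\text{-extent}_b \ge k\}}
   {B + 1}, $$

the add-one estimator, which is never exactly zero and is valid at any
$B$. Defaults echo the conventions of the field: voxel $p < 0.001$,
cluster $\alpha = 0.05$, $B = 1000$. Permutation of group labels is
exchangeable under the null of no group effect given that covariates
are unrelated to group assignment — the design the generator
instantiates. The suite verifies calibration directly: over 200 null
cohorts the family-wise false-positive rate at $\alpha = 0.05$ fell
inside the binomial band (observed 0.045 in development runs).

# Classification

Features are the GMV values at every voxel inside the FWE-significant
clusters, one column per voxel in linear-index order (the voxel index
travels with the matrix so attributions can be projected back into
volume space). Six families are benchmarked, mirroring common MRI
case-control practice: linear- and RBF-kernel SVM, random forest,
ridge-regularized logistic regression, a single decision tree, and
gradient-boosted trees. The protocol is a stratified 9:1 train/test
split, hyperparameter selection by stratified tenfold cross-validation
maximizing ROC-AUC on the training set only, and held-out evaluation of
accuracy, sensitivity (patient class positive), specificity and
rank-based AUC with midrank tie handling. Features are z-scored with
training-set statistics only.

Hyperparameter grids are deliberately small and fixed (SVM cost
$\{0.1, 1, 10\}$; RBF $\gamma \in \{1/d, 0.01\}$; forest size
$\{200, 500\}$ with depth $\{\infty, 8\}$; ridge $\lambda \in
\{0.01, 0.1, 1\}$; tree complexity $\{0.01, 0.001\}$ with depth
$\{30, 8\}$; boosting depth $\{2, 3\}$ with learning rate
$\{0.1, 0.3\}$ at 100 rounds): the goal is a reproducible benchmark,
not an exhaustive search. Plain maximum-likelihood logistic regression
is unusable at voxel dimensionality ($p \gg n$), so the logistic family
is ridge-penalized — the same remedy scikit-learn applies by default.

Significance of held-out performance uses label permutation: labels are
shuffled *before* the split, the entire split-tune-evaluate procedure
is rerun, and the add-one p-value compares the observed held-out AUC
with the permuted ones (1000 permutations by default). AUC was chosen
as the permutation statistic because it is threshold-free; accuracy is
reported alongside.

## Selection leakage is measurable, not hidden

Selecting features from a group contrast computed on *all* subjects
before splitting — standard in the literature this pipeline models —
leaks test-set information into the features. The package treats that
as an object of study: `selection_mode = "pooled"` reproduces the
leaky protocol, `selection_mode = "trainonly"` recomputes the
feature-selecting contrast on training subjects only, and the test
suite demonstrates on null data that pooled selection is optimistically
biased while train-only selection is not. Results obtained with pooled
selection should be read accordingly.

A related granularity caveat: with a 0.1 test fraction, cohorts of
~50 subjects leave 5 held-out subjects, and a permutation can tie a
perfect AUC with probability $2!\,3!/5! = 0.1$, placing a hard floor
near 0.1 on the permutation p-value. Permutation significance is
therefore only meaningful at cohort sizes whose held-out sets make the
AUC reasonably fine-grained — about 100 subjects (10 held out, tie
probability 1/210) in the configurations the suite exercises.

# Shapley attribution and the VICI

The model output attributed is the positive-class (patient)
probability. Coalition values are *interventional*:

$$ v(S) = \frac{1}{|B|}\sum_{b \in B} f(x_S, b_{\bar S}), $$

features outside the coalition are replaced by values from a background
set $B$ (a seeded 50-row training subsample by default). Two estimators
are provided:

* `shapleyExact()` enumerates all $2^{d}$ coalitions (guarded at
  $d \le 12$) and is the oracle: efficiency, symmetry and dummy hold to
  $10^{-10}$.
* `shapleyMonteCarlo()` is the permutation-sampling estimator: for each
  of $m$ draws, a random feature order and a random background row;
  features switch from background to subject values in order, and the
  output change when feature $j$ switches is one sample of $\phi_j$.
  The estimator is unbiased, seeded, and returns per-feature Monte
  Carlo standard errors; the suite checks convergence to the exact
  values within 3 SE at $m = 2000$.

The VICI collapses a subject's attributions $\phi_{ij}$ into a scalar
$\mathrm{VICI}_i = \sum_j w_j \phi_{ij}$ and a voxel map (the weighted
attributions back-projected through the feature index; mass is
conserved exactly). Two weighting schemes formalize the "weighted
summation" idea:

* **unit** (default): $w_j = 1$. Then $\mathrm{VICI}_i = f(x_i) -
  \text{base}$ exactly, so the index is an affine transform of the
  model output and *provably* ROC-equivalent to the classifier — the
  checkable form of the claim that the index classifies as well as the
  model it summarizes. This is why it is the default.
* **importance**: $w_j \propto \overline{|\phi_{\cdot j}|}$, normalized
  to sum 1 — the literal weighted reading, emphasizing globally
  important voxels. Its AUC tracks the model's closely on
  planted-effect cohorts but equality is not guaranteed.

VICI group-difference maps reuse the identical voxelwise GLM and
permutation FWE machinery (same thresholds, same conventions) on the
per-subject VICI maps, restricted to feature voxels with
non-degenerate variance. Spatial coupling between the VICI and GMV
abnormality patterns is the Spearman correlation of their $|t|$
fields, voxelwise or region-averaged. Clinical correlations
(CAPS, MMSE, MoCA, GDS) are computed within the patient group by
default: pooled two-group correlations would conflate group separation
of the index with severity scaling among patients.

# Imaging transcriptomics

The pipeline ingests a donor × region × gene expression array (the
probe-level curation that produces such arrays from raw microarray
atlases is upstream and out of scope). Within each donor, expression
is normalized with the scaled robust sigmoid — a logistic standardized
by median and IQR ($\mathrm{IQR}/1.35$ approximates the SD of a
normal), rescaled to $[0,1]$ — first across genes within each sample
region, then across regions within each gene. Zero-IQR axes fall back
to rank scaling and are flagged.

Differential stability,
$\mathrm{DS}(g) = \binom{D}{2}^{-1}\sum_{d<d'}
\rho_S\!\left(x^{(d)}_{\cdot g},\, x^{(d')}_{\cdot g}\right)$,
scores the cross-donor reproducibility of a gene's regional profile
and is invariant to monotone per-donor transforms; the top 50% of
genes are retained by default. Association then correlates
(Spearman) the donor-averaged normalized expression of each requested
risk gene with the regional mean $t$ of the VICI group map, Bonferroni
corrected over the genes actually tested at $\alpha = 0.05$. Risk
genes dropped by the stability filter are reported as missing, never
silently discarded. Signed regional $t$ is the default ("mean t" is
read literally); an absolute-value mode is a flag.

# The synthetic cohort generator

The generator's defaults are the study conditions the rest of the
package assumes: 40 controls and 62 patients aged 60–80, a
40×48×40 grid of 4 mm voxels, 8 mm FWHM smoothing, additive voxel
noise, and a CAPS-like severity score elevated in patients but — by
default — statistically independent of the voxel data, so that
clinical correlations are null by design (coupling is a config knob).
Design choices worth stating explicitly:

* **Baseline template** — a smooth radial gradient (bright center,
  0.7 → 0.15 range in modulated-GMV-like units) rather than a bundled
  brain template, keeping the package download-free. Nothing
  downstream depends on anatomy, only on smooth spatial structure.
* **Effects** — spheres in voxel space, multiplicative on the
  baseline (`baseline * (1 + magnitude)`), planted before noise and
  smoothing, mirroring the order of real pipelines. Spheres give
  analytically checkable truth masks. The default radii (14 and
  11 mm, about the volume scale of frontal clusters reported in
  elderly PTSD morphometry) are chosen large relative to the 8 mm
  smoothing kernel: at the default signal-to-noise the detection halo
  extends roughly 5 mm beyond a sharp effect boundary, and planted
  spheres much below ~13 mm radius cannot reach a truth-mask Dice of
  0.5 no matter how exact the statistics are. Recoverability
  (median Dice ≥ 0.5 over seeds) is asserted by the suite.
* **Covariates** — age uniform over the range, TIV Gaussian
  (1450 ± 120 mL), each contributing a small linear trend at every
  voxel; the GLM removes them.
* **Expression arrays** — every gene has a latent regional profile
  shared across donors and observed with donor-level noise. Coupled
  genes mix the normal-scores transform of a supplied regional signal
  into their latent profile with weight
  $\lambda = 2\sin(\pi\rho_S/6)$, the Gaussian-copula mapping that
  targets a chosen Spearman correlation; at $\rho_S = 1$, noiseless,
  the profile is an exact monotone transform of the signal. Uncoupled
  genes get per-gene inflated donor noise (1–3× the base SD),
  emulating the broad reliability spread of microarray probes; this
  also makes coupled genes differentially stable, so they survive the
  DS filter, as strongly spatially patterned genes do in real atlases.

What the generator does *not* emulate: anatomy and tissue boundaries,
spatially correlated (non-white) noise before smoothing, scanner- or
site-level batch structure, nonlinear covariate effects, and any
genuine biological link between expression and atrophy — the coupling
is statistical by construction. Passing tests therefore demonstrate
the *statistical* correctness and calibration of the machinery, not
that the pipeline would reach the same biological conclusions on real
cohorts.

# Numerical and reproducibility choices

* Smoothing uses half-sample mirror boundaries, under which a
  normalized kernel preserves the image sum exactly; the per-axis
  kernel is truncated at $4\sigma$.
* Permutation p-values use the add-one estimator everywhere, so
  reported values are bounded below by $1/(B+1)$.
* One master seed fans out to stage seeds via the fixed affine map
  `deriveSeed(master, stage)`; identical configuration and seed give
  bit-identical outputs, including on-disk artifacts.
* p-values are floored at the smallest positive double to keep
  $p \in (0, 1]$ inside masks.
* Cluster tables, metric tables and gene tables are TSV (locale-safe);
  volumes are single-file NIfTI-1 `.nii.gz` with the affine stored in
  both qform and sform.
* The test suite and the acceptance script run at reduced problem
  sizes chosen to keep full runs in the tens of minutes on one CPU:
  null-calibration cohorts of 15+15 subjects on 20×24×20 grids with
  199 permutations, recovery cohorts at the full default geometry with
  99 permutations, classifier nulls at 99 permutations, and
  expression arrays of 200 genes × 118 regions × 6 donors. These
  sizes are stated here as the package's own validation conditions.

# Known limitations

* Random-field-theory cluster correction is not implemented;
  permutation is the only FWE route.
* The Monte-Carlo Shapley estimator scales linearly in features ×
  samples × subjects and is the pipeline's cost center at voxel
  dimensionality; exact enumeration is capped at 12 features.
* Probability outputs of SVMs rely on Platt scaling, which is itself
  fitted by internal cross-validation; ROC-based conclusions are
  unaffected (the decision values are monotone in the fitted
  probabilities), but absolute probabilities from tiny training sets
  are noisy.
* `simulateCohort` holds the full subject × voxel matrix in memory;
  the default grid with ~100 subjects needs on the order of a few
  hundred MB.
* The generator omits a sex covariate (the emulated cohort is
  single-sex); adding one would be a config extension, not a redesign.
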
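---
title: "Multivariate SVR lesion-symptom mapping: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate SVR lesion-symptom mapping: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svrlsm)
```

## The problem

Lesion-symptom mapping asks which locations of brain damage account for a
behavioral deficit across a cohort of patients. The mass-univariate
approach tests each voxel separately and inherits the spatial biases of
lesion anatomy; the multivariate approach taken here enters *all* covered
voxels into one predictive model of behavior — an epsilon-insensitive
support vector regression (SVR) with a radial basis function kernel — and
assigns voxel-level statistics by permutation. The package implements the
full pipeline for a working-memory study design in acute stroke:
psychometric scoring of two span tasks and a picture–word matching task,
covariate residualization, lesion-matrix construction, SVR fitting with
permutation-based hyperparameter selection, and per-patch permutation
inference, together with a seeded simulator that generates cohorts with
the statistical structure the analysis assumes.

## Behavioral scoring

**Interpolated span.** Span tasks administer increasing list lengths
(digit matching: 2–6 items with 6, 8, 6, 8, 10 trials; category probe:
1–4 items with 8, 8, 12, 16 trials) and stop once accuracy falls below
75%. The span is the list length at which accuracy crosses the criterion,
linearly interpolated between the two lengths spanning 75%:

$$ S = L + \frac{a_L - 75}{a_L - a_{L+1}} $$

with accuracies in percentage points, $L$ the last length at or above
criterion. Two edge rules close the scale: if even the shortest list is
below criterion, a virtual one-item-shorter length at 100% accuracy
anchors the interpolation; if the longest administered list is still at
or above criterion, a virtual one-item-longer length at 50% anchors it.
The ceiling rule is stated for the digit task (7 items at 50%); we
generalize both rules symmetrically to the category probe (virtual 0-item
length at 100%, 5-item length at 50%), which keeps scores positive,
reproduces the observed task maxima (6.50 and 4.50), and treats the two
tasks identically, as their shared scoring procedure implies. Accuracies
are handled internally as proportions; the interpolation ratio is
invariant to that choice of units. List lengths missing after the stop
rule are *not administered*, never 0% accuracy.

**Signal detection.** Picture–word matching presents 17 match trials and
17 foils per condition; discriminability is $d' = \Phi^{-1}(H) -
\Phi^{-1}(F)$. Extreme rates are corrected by the half-trial rule
($0 \mapsto 1/(2N)$, $1 \mapsto 1 - 1/(2N)$), exposed as a parameter.
This rule is adopted because it reproduces the observed ceiling of 3.78
exactly at $N = 17$: $2\,\Phi^{-1}(33/34) = 3.779$. The two d′ scores are
assumed to share the 17 match trials across foil conditions.

**Input-processing composite.** The two d′ scores are standardized and
summarized by the first principal component of their $2\times 2$
correlation matrix. For two standardized variables at correlation $r$,
the first eigenvalue is $1+r$, so the explained variance is $(1+r)/2$ and
both loadings are $\sqrt{(1+r)/2}$ — at $r = 0.69$, 84.5% and 0.92. The
component sign is fixed so loadings are positive (higher composite =
better input processing); the source procedure leaves the sign
convention open.

**Residualization.** Each working-memory score is residualized in a
*single* multiple regression on lesion size, the input-processing
composite and the opposing working-memory score simultaneously (not
sequentially), then min–max scaled to $[0,1]$. The scaled dependent
variable is invariant to affine rescaling of the raw score.

## The lesion design matrix

Masks are binary volumes on a common template grid. Voxels lesioned in
fewer than `min_subjects` patients (default 5, i.e. >5% of a 94-patient
cohort) are removed; lesion volume is always computed on the unfiltered
mask, so the lesion-size covariate does not depend on the filter.
Because the voxel grid used for counting is the working grid, the
lesion-size covariate is expressed in voxels of that grid.

Voxels with identical lesion patterns across all subjects are
indistinguishable to any across-subject model, and are compressed into
*patches*. The compression is exactly lossless for the SVR because the
kernel uses patch multiplicities:

$$ k(u, v) = \exp\!\Big(-\gamma \sum_j m_j (u_j - v_j)^2\Big), $$

where $m_j$ is the number of voxels in patch $j$; this equals the plain
RBF kernel on the expanded voxel matrix, which the test suite verifies to
$10^{-10}$. Patches are ordered by their smallest member's linear grid
index, making all outputs deterministic. Voxel indices are 0-based
internally; reported coordinates are template-space mm through the
affine.

## Model fitting and inference

**Solver.** The epsilon-SVR dual is solved by a second-order SMO working
on a *precomputed* kernel matrix (`src/smo.cpp`). The kernel is fixed
across the thousands of permutation refits the pipeline performs, so
precomputing it once per gamma and re-solving the dual dominates every
alternative; the solver is validated against libsvm (through e1071) to
prediction agreement better than $10^{-3}$ on random problems. The
convergence tolerance defaults to $10^{-3}$ (the libsvm default) with an
iteration cap of $2\times 10^5$; the epsilon tube defaults to 0.1, the
long-standing default of the software lineage this method descends from.

**Hyperparameter selection.** A grid over cost $[10^{-2}, 10^9]$ and
gamma $[10^{-9}, 10^3]$ (decade steps by default; the discretization is a
package choice, as only the ranges are stated) is scored by 5-fold
cross-validated MSE, and each pair's significance is the permutation rank
of its real MSE among `n_perm` fits to shuffled dependent scores:
$p = (1 + \#\{\mathrm{MSE}_{perm} \le \mathrm{MSE}_{real}\})/(n_{perm}+1)$.
The same fold partition and the same permutation set are applied to every
pair so that pairs are compared on identical resamples. The pair with the
lowest $p$ wins, and its $p$ is reported as the model significance — note
this is the grid minimum and is not re-validated out of sample, a
selection-bias caveat inherited from the procedure itself.

Ties on the minimal $p$ are common once many pairs saturate the
permutation resolution ($p = 1/(n_{perm}+1)$). We break ties toward the
most regularized pair — smallest cost, then smallest gamma. We initially
broke ties by the lowest real cross-validated MSE, but simulation showed
that rule selects high-variance pairs whose beta maps fail to localize
ground truth (in one cohort, Dice 0.00 against ground truth versus 0.61
for the most-regularized tied pair); among pairs the permutation test
cannot distinguish, the smoothest model yields the most stable
sensitivity map, so maximal regularization is the package's tie rule.

**Beta map.** How the per-feature weights of the RBF model are formed is
not specified by the procedure we follow; we adopt the established
SVR-LSM convention of dual-coefficient back-projection,
$\beta_j = \sum_i \alpha_i x_{ij}$ over support vectors, whose ranking is
what the permutation inference consumes. An analytic kernel-gradient
sensitivity map is available behind `beta_map(fit, method = "gradient")`.

**Patch inference.** The model is refit to `n_perm` shuffles of the
dependent variable; each patch's p-value is the lower-tail rank
$p_j = (1 + \#\{\beta_j^{perm} \le \beta_j\})/(n_{perm}+1)$. Damage is
expected to *lower* performance, so only negative betas are interpreted:
a patch is significant when $p_j < \alpha$ (default 0.05) and
$\beta_j < 0$. The add-one estimator avoids zero p-values and counts ties
as extreme, our resolution of the ambiguity in "rank among random
models". P-values are *not* corrected across patches, faithfully to the
original procedure; a Benjamini–Hochberg option exists behind
`fdr = TRUE` but is off by default. Permutations for inference are drawn
from a fresh substream by default (`reuse_selection_permutations = TRUE`
reuses the selection stream). A failed permutation fit is resampled and
counted. No feature normalization is applied beyond the binary lesion
indicators: lesion volume is controlled by residualizing the behavior,
not by scaling lesion vectors.

All randomness flows from one master seed through named substreams
(lesion simulation, behavior simulation, CV folds, selection
permutations, inference permutations), so identical configurations give
bit-identical results and each stage is independently reproducible.

## The synthetic cohort generator

No patient data accompany the design this package implements, so the
simulator is the test bed: it generates cohorts with the statistical
structure the analysis assumes, and every default was fixed once, before
the validation suite was finalized.

* **Grid.** 24×24×18 voxels of 3 mm (279 936 mm³). The 3 mm voxel is
  deliberate: the target lesion-volume distribution (mean 14 098 mm³, SD
  18 641 mm³, range 135–104 243 mm³) must fit inside the working grid,
  and at 1 mm it cannot. Volumes are drawn from a lognormal
  moment-matched to that mean and SD and clipped to the printed range.
* **Lesion shapes.** Each lesion is the set of $v$ voxels nearest a seed
  center under a random anisotropic positive-definite metric — a level
  set of a convex quadratic, hence connected (verified by a
  flood-fill oracle in the tests). Seed centers cluster over the two
  ground-truth regions and the territory between them, giving the
  overlapping, spatially clustered coverage the coverage filter expects;
  cohorts that fail to reach the 5-subject overlap in a truth region are
  partially resampled (logged).
* **Ground truth.** Two disjoint spheres of radius 3.5 voxels
  (≈4 800 mm³, the scale of the significant clusters such analyses
  report). Damage to region A lowers the phonological latent, region B
  the semantic latent; log lesion volume lowers both; a shared factor
  induces the target cross-score correlation of 0.51. A second pair of
  latents with its own shared factor drives the picture–word matching
  performance at target correlation 0.69.
* **Trial-level expression.** Latents are expressed at the *trial* level
  — per list length, `n_correct ~ Binomial(n, plogis(intercept + latent -
  slope·(L - min)))` honoring the stop rule, and detection counts from
  one shared set of 17 match trials plus 17 foils per condition — so span
  scoring, stop rules and d′ corrections are exercised end to end. The
  intercepts, slopes and variance shares were calibrated once so the
  scored cohort reproduces the target correlations (0.51, 0.69) and
  score distributions, and the tests assert those targets within ±0.1.

What the simulator does **not** emulate: vascular-territory anatomy,
hemispheric asymmetry beyond clustered seeding, registration error, CT
artifacts, or any longitudinal structure. Passing recovery tests
therefore show that the pipeline recovers focal, region-driven deficits
under its own generative assumptions — not that it is unbiased on real
stroke anatomy, where lesion correlation structure is far less benign.

## Validation problem sizes

The suite validates the span/d′/composite arithmetic exactly; solver
fidelity against libsvm on random problems; patch/voxel equivalence to
$10^{-10}$ on 20×500 matrices; permutation calibration with 100
global-null cohorts of 50 subjects at 199 permutations (per-patch
significant fraction within two Monte-Carlo standard errors of
$\alpha$); agreement with the exhaustive 720-permutation law at
$n = 6$; and ground-truth recovery on five default cohorts with a 4×4
decade grid at 199 permutations, requiring mean Dice above 0.3 with mean
voxelwise false-positive rate below 0.05 per score and correct
region-to-score assignment in at least 4 of 5 seeds. These sizes keep the
whole suite at desk scale while leaving every statistical claim backed by
a computed check; the full 12×13 grid and 1000 permutations remain the
defaults for real analyses.

## Known limitations

* The reported model p-value is the grid minimum (selection bias; see
  above).
* Per-patch p-values are uncorrected across patches by design fidelity;
  interpret patch maps at the region level or enable the FDR option.
* Patch significance inherits the spatial correlation of lesion
  anatomy: neighbors of a truly causal region are partially significant
  ("smearing"), which is what bounds the recovery Dice well below 1.
* The simulator's generative constants are stand-ins calibrated to
  printed summary statistics, not estimates from any patient data.
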
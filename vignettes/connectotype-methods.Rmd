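---
title: "Individual-specific connectomes: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-specific connectomes: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectotype)
```

## The problem

Group-level cortical atlases assign every subject the same functional
region boundaries, but the size and position of functional regions vary
substantially across individuals, especially in association cortex. When
region boundaries are mislocalized, the time series averaged within an
"ROI" mixes signals from neighboring regions, between-network correlations
are inflated toward within-network values, and the association between
connectivity and behavioral symptoms is diluted. `connectotype` implements
the full analysis chain for studying this phenomenon and exploiting its
remedy: per-subject network parcellation initialized by a population
atlas, homologous ROI identification by template matching,
within/between-network connectivity decomposition, inter-individual
variability profiling, and genotype-stratified machine-learning prediction
of clinical group and symptom severity from connection features.

Everything runs on synthetic cortical-surface cohorts with planted ground
truth, so each stage is testable end to end without restricted clinical
data. The synthetic generator is first-class, tested code: its defaults
define the study conditions that the test suite and the acceptance script
exercise.

## The synthetic cohort model

**Surface and atlas.** A single-hemisphere cortical sheet is modeled as a
triangulated mesh (icosphere or planar grid); geodesic distance is the
shortest path over mesh edges with Euclidean weights. The population atlas
partitions the mesh into `n_rois` connected patches (geodesic Voronoi
cells of farthest-point-sampled seeds, repaired to stay connected with at
least 4 vertices each). ROI $i$ belongs to fine network
$((i-1) \bmod n_{net})+1$; this interleaving distributes each network over
the sheet the way large-scale functional networks tile the cortex. Fine
networks map onto 7 canonical networks the same way. Defaults are 2562
vertices, 116 ROIs, 18 networks — the full-scale condition — while tests
run on 642-, 324- and 162-vertex meshes (see *Problem sizes* below).

**Individual topography.** A subject's true parcellation perturbs the
atlas at its ROI boundaries: over `ceiling(shift_sd)` rounds, each
boundary vertex moves to a geodesically adjacent ROI with probability
`0.5 * shift_sd / ceiling(shift_sd)`. Moves that would empty, shrink below
two vertices, or disconnect an ROI are skipped, so regions stay contiguous
— the premise of the matching step. `shift_sd = 0` is the identity; the
default is 1 edge length, which displaces roughly a quarter to a half of
boundary vertices.

**Signals.** Every ROI has one latent time series with unit variance;
latents of distinct ROIs covary as `network_cov[net(i), net(j)]` (diagonal
0.6 = within-network covariance, off-diagonal 0.2 by default). A vertex
carries its ROI latent plus iid Gaussian noise of SD `vertex_noise_sd`
(default 0.5, i.e. vertex-level SNR of about 2). Planted
connection-specific covariance shifts are added per subject before the
Cholesky draw, with eigenvalue clipping to keep the matrix positive
semi-definite. Nuisance structure is mixed in explicitly: six random-walk
motion parameters, AR(1) white-matter and ventricle proxies (coupling
0.3), and large-amplitude spikes confined to motion-outlier frames.

**Motion and scores.** FD and DVARS baselines stay below the 0.2 mm / 50
censoring thresholds; a Bernoulli(`outlier_rate` = 0.05) subset of frames
exceeds them. Symptom scores follow
$s = b_0 + \sum_k \beta_k\, c_{i_k j_k} + \gamma_{age}\,a + \gamma_{sex}\,x + \varepsilon$
computed from the *generative* connectivity at 3 planted between-network
connections per genotype group (disjoint between groups), with clinical
group encoded as connectivity mean shifts of 0 / −0.12 / −0.3 (healthy
aging / MCI-like / AD-like), $\beta = 8$, noise SD 1.5 (MMSE-like, clamped
to [0, 30]) and 2.5 (LIMM-like, clamped to [0, 25]). With these values the
group means land near 29 / 26 / 22 on the MMSE-like scale — the ordering
and spread of the cohort the generator emulates. Cohort cells default to
42/39/39 carriers and 43/39/33 noncarriers (235 subjects). All randomness
derives from one seed through `derive_seed(seed, subject)`, so adding
subjects never reshuffles existing ones.

What the generator deliberately does not emulate: volumetric acquisition,
hemodynamics, spatial autocorrelation of noise, realistic artifact
spectra, atrophy. Group effects exist only in connectivity, because
connectivity is all the pipeline sees. Passing tests therefore demonstrate
the *pipeline's* correctness and the qualitative mechanism (boundary
mislocalization dilutes brain–behavior association), not performance on
real fMRI.

## Signal quality control

The stage order is fixed: censor → nuisance regression → interpolation →
band-pass; censored frames stay excluded from every later correlation —
interpolation exists only to make the band-pass well-posed.

* **Censoring.** Frames with FD > 0.2 mm or DVARS > 50 are outliers; one
  frame before and two after are also censored; kept runs shorter than 5
  frames are removed; a subject with more than half its frames censored is
  excluded. All five numbers are config parameters. The exclusion rule is
  read at run/subject level: a single volume cannot itself contain
  multiple censored frames, so the fraction-based reading is the only one
  that parses.
* **Nuisance regression.** 18 columns: intercept, linear trend, six motion
  parameters, mean white-matter and ventricle proxies, and backward
  differences of those eight. OLS is fitted on kept frames only and
  subtracted everywhere; collinear columns are dropped with a warning.
* **Interpolation.** Kept residuals are fitted with an intercept plus
  sine/cosine pairs on the linear grid $m/(T \cdot TR)$. Two numerical
  choices matter. First, the grid is truncated so the kept-frame system is
  overdetermined ($2 n_{freq} \le \tfrac{2}{3} n_{kept}$) — this keeps the
  fit well-conditioned and still covers the 0.009–0.08 Hz band retained
  downstream by a wide margin. Second, the system is solved by truncated
  SVD (relative tolerance 0.1): singular directions that are nearly
  invisible on the kept frames oscillate without constraint inside
  multi-frame censoring gaps, and inverting them produces reconstructions
  hundreds of times larger than the signal. Dropping them bounds the
  reconstruction while leaving grid sinusoids under scattered censoring
  reconstructed to machine precision (both behaviors are asserted in the
  test suite).
* **Band-pass.** A zero-phase FFT mask retaining 0.009–0.08 Hz (TR = 3 s,
  Nyquist 0.167 Hz). DC is rejected exactly; band edges are validated
  against Nyquist before any compute.

## Parcellation and template matching

Iteration $t$ of the individual network mapping scores every vertex
against every network:
$\mathrm{score}(v,k) = \mathrm{corr}(x_v, \bar x_k) + \lambda_t(v)\,\mathbf 1[\mathrm{atlas}(v)=k]$,
where $\bar x_k$ is the SNR-weighted mean series of the network's current
members and
$\lambda_t(v) = \alpha_t (1-\mathrm{variability}(v))(1-\mathrm{snr}(v))$.
The prior weight $\alpha_t = (n_{iter}-t)/n_{iter}$ decays linearly to
zero, so the final map is driven by the subject's own data; the prior is
weakest where inter-individual variability or SNR is high. Iteration stops
at 10 rounds or when fewer than 0.1% of labels change; an emptied network
is reseeded from its atlas vertices. For synthetic cohorts the two maps
come from generator truth (boundary-adjacent vertices get variability 0.8
vs 0.2; SNR $1/(1+\sigma^2_{noise})$); for other data they are
user-supplied, defaulting to 0.5. The blend form, the $\lambda$ weighting
and the linear schedule are this package's fully specified realization of
atlas-guided iterative parcellation; they preserve the qualitative
contract (prior influence shaped by variability and SNR, vanishing over
iterations) while being exactly testable: with noise-free signals the true
topography is a fixed point, and with an overwhelming $\alpha$ the atlas
is returned regardless of data.

Network label maps are cut into patches (connected components). A smoothed
support is computed per patch (geodesic Gaussian of the patch indicator,
threshold 0.5, $\sigma$ = half the mean edge length) and stored; the
original vertex set is never altered. Matching to the atlas ROIs of the
patch's own network then applies three rules: (1) a patch overlapping
exactly one ROI by more than `overlap_min` vertices inherits its identity;
(2) a patch overlapping several ROIs is split — overlap vertices become
centers keeping their atlas identity, remaining vertices join the
geodesically nearest center, ties toward the lower ROI id; (3) a
non-overlapping patch joins its nearest same-network ROI if the gap is
smaller than that ROI's internal mean pairwise geodesic distance, else its
vertices are "unrecognized". Each vertex records which rule labeled it.

Three open choices were resolved as follows. Overlap counts use the
*original* patch support: on desk-scale meshes, ROIs span only a handful
of vertices and support erosion by smoothing breaks the exact
zero-perturbation closure, whereas on mm-scale surfaces the distinction is
immaterial; the smoothed support is retained as metadata. The rule-1
threshold of 20 vertices is calibrated to a 5124-vertex bilateral surface
and is scaled by `n_vertices / 5124` with a floor of 3. The rule-3
threshold distance is geodesic (a flag switches to Euclidean).

## Connectivity, variability, prediction

**Connectome.** ROI series are unweighted vertex means over kept frames;
connectivity is plain Pearson correlation (no Fisher z by default — a flag
enables it for sensitivity analyses), giving a symmetric unit-diagonal
matrix with unmatched ROIs masked. Features are the strict upper triangle
in row-major order: 116 ROIs give 6670 connections. Per network, the
within value averages pairs with both ROIs inside; the between value
averages pairs with exactly one ROI inside. The individual-vs-atlas
between-network shift is reported as percent change against the signed
atlas baseline with paired t-tests, Bonferroni-adjusted over networks.

**Variability.** ROI size variability is the across-subject sample SD
(ddof = 1) of matched vertex counts (unmatched = 0). Position uses the
geodesic medoid as the ROI center — it stays on the mesh and is
deterministic, unlike a Euclidean centroid projection (available behind a
flag) — and averages pairwise center distances across subjects.
Vertex-wise variability correlates each vertex's profile against a
fixed basis (the subject's atlas-ROI mean series) and averages
$1-r$ over subject pairs; a full vertex-by-vertex profile basis is not
desk-scale, and this length-`n_rois` reduction is flagged as the package's
definition of the quantity. ROI connectivity variability is the mean of
the across-subject connection SDs over each ROI's incident connections.

**Prediction.** Classification: stratified k-fold (default 5;
configurable to 10) RBF-SVM (`e1071`, C = 1, kernel width $1/p$ after
standardization) with per-fold confound residualization and two-sample
t-test selection at p < 0.001 (uncorrected, as for classification).
Symptom estimation: leave-one-out linear L2-regularized L2-loss SVR
(C = 1, $\epsilon$ = 0.1; hyperparameters fixed in config). Inside every
fold, age and sex are regressed out of features and scores on the training
rows and the training coefficients are applied to the held-out subject;
features are selected by correlation p-value, Bonferroni-corrected over
the tested features (an uncorrected mode exists, and an always-active
fallback keeps the 10 smallest-p features when nothing survives). The SVR
is authored in the package: the objective is smooth, it is optimized by
L-BFGS-B with an analytic gradient, and for wide feature blocks it is
solved exactly in the span of the training rows (any weight component
orthogonal to that span only inflates the penalty). Fold weights are
expanded with zeros at unselected features; significance uses permutation
of scores with the whole pipeline re-run per permutation and the add-one
estimator $p = (1+\#\{r_{perm} \ge r_{obs}\})/(1+n_{perm})$ (raw
percentage available by flag). Contributions: mean weight per connection
across folds; the top set exceeds the 90th percentile of |mean weight|
over ever-selected connections (matching reported top-set sizes far below
$0.1 \times 6670$; an all-features mode exists, and the set is never
empty); ROI contribution sums |mean weight| over incident connections;
canonical-network tables split top connections into within and between.

A caution established while validating the null behavior: with the
fallback selection always active, the LOOCV observed-vs-predicted
correlation under shuffled scores is *not* tightly concentrated — nested
selection at n ≈ 120 produces excursions beyond |r| = 0.3, predominantly
negative, and an independent ridge regression under the same selection
reproduces them. Permutation p-values remain correctly calibrated
(uniform under the null) because the permuted replicates overfit the same
way; single null r values should not be over-interpreted.

## Problem sizes

Full-scale defaults (2562 vertices, 235 subjects, 1000 permutations) are
what a real analysis would use. The test suite and the acceptance script
run the same code at sizes chosen for a desktop run: 642-vertex icosphere
with all 116 ROIs for closure and recovery checks (10–20 subjects), a
324-vertex grid with 58 ROIs / 12 networks for replicate cohorts of 120
subjects (5.6 vertices per ROI, the same ROI granularity as the 642/116
configuration), 162-vertex meshes for algebraic checks, and 99–199
permutations where a significance value is needed. ROI granularity is the
binding constraint for matching quality: below roughly 5 vertices per ROI
a one-edge boundary shift exceeds the region scale and template matching
degrades, so replicate cohorts are not run on the 162-vertex mesh.

## Known limitations

* Geodesics are graph shortest paths, not exact polyhedral geodesics;
  fine for label geometry at these resolutions.
* The generator's latent model makes all vertices of an ROI exchangeable;
  there is no within-ROI gradient structure, so rule-2 splits are easier
  than on real data.
* Subjects are independent draws; no site, scanner, or family structure.
* The iterative parcellation is a compact re-specification, not a
  re-implementation of any published codebase, and population variability
  maps are synthetic stand-ins.
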
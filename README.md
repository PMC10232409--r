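# connectotype

Individual-specific functional connectome analysis on cortical surface
meshes, for researchers studying how inter-individual variability in
functional brain topography affects connectivity-based prediction of
clinical status and symptom severity.

Group-level atlases give every subject identical region boundaries, but
the size and position of functional regions differ across people. When a
region is mislocalized, its mean time series mixes neighboring regions,
between-network correlations are inflated, and the association between
connectivity and behavior is diluted. `connectotype` implements the full
chain for quantifying and overcoming this:

1. **Synthetic cohorts with planted truth** — triangulated meshes,
   population atlases (116 ROIs in 18 networks under 7 canonical networks
   by default), subject-specific boundary shifts, network-structured
   signals with controllable SNR, motion traces, and symptom scores
   generated from a small set of planted between-network connections plus
   age/sex confounds.
2. **Signal QC** — frame censoring (FD > 0.2 mm or DVARS > 50, dilated
   1-before/2-after, minimum run 5, subject exclusion above 50%
   censoring), 18-column nuisance regression, spectral interpolation of
   censored frames, zero-phase 0.009–0.08 Hz band-pass.
3. **Individual parcellation** — iterative atlas-guided network mapping,
   `score(v,k) = corr(x_v, ref_k) + α_t (1−variability_v)(1−snr_v) 1[atlas(v)=k]`
   with the prior decaying to zero, then patch extraction and three-rule
   template matching (overlap / split / nearest-else-unrecognized) onto
   the homologous atlas ROIs.
4. **Connectomes** — Pearson ROI×ROI matrices on the individual and atlas
   bases, upper-triangle feature vectors (116 ROIs → 6670 connections),
   within/between-network decomposition, individual-vs-atlas
   between-network shift with paired tests.
5. **Variability** — per-ROI size, position (geodesic medoid), vertex-wise
   profile, and ROI connectivity variability, with cross-profile
   correlations.
6. **Prediction** — genotype-stratified RBF-SVM classification
   (stratified k-fold, t-test feature selection at p = 0.001) and
   leave-one-out linear L2-regularized L2-loss SVR symptom estimation
   with train-only confound residualization and Bonferroni-corrected
   correlation selection, permutation significance, and
   connection/ROI/network contribution analysis (top decile of
   fold-averaged absolute weights).

## Worked example

A 120-subject cohort (60 genotype-positive "carriers", 60 noncarriers; 20
each of healthy-aging, MCI-like, and AD-like subjects) on a 324-vertex
mesh with 58 ROIs in 12 networks. Carrier symptom scores are driven by
three planted between-network connections (ROI pairs 1–5, 6–10, 11–15).

```r
library(connectotype)

mesh  <- make_mesh(324, "grid")
atlas <- make_atlas(mesh, n_networks = 12, n_rois = 58, seed = 99)
cfg <- cohort_config(n_vertices = 324, n_networks = 12, n_rois = 58,
                     timepoints = 196,
                     group_counts = rbind(carrier    = c(20, 20, 20),
                                          noncarrier = c(20, 20, 20)),
                     seed = 42)
cohort   <- make_cohort(cfg, mesh, atlas)
analysis <- analyze_cohort(cohort)   # QC -> parcellation -> connectomes

ind <- predict_symptoms(analysis, score = "mmse_like",
                        genotype = "carrier", basis = "individual",
                        n_perm = 99, seed = 1)
atl <- predict_symptoms(analysis, score = "mmse_like",
                        genotype = "carrier", basis = "atlas")
ind$report
#> prediction_report: n = 60, observed-vs-predicted r = 0.611, permutation p = 0.01
atl$report
#> prediction_report: n = 60, observed-vs-predicted r = 0.283
ind$contribution
#> contribution_report: 1 top connections (100% between-network)
head(ind$contribution$top_connections[, c("roi_i", "roi_j", "mean_weight", "type")])
#>       roi_i roi_j mean_weight    type
#> roi_i     1     5    7.881456 between
```

Symptoms estimated from individual-specific connectivity correlate with
the observed scores (r = 0.61, permutation p = 0.01) far better than the
atlas-based estimate of the *same* subjects (r = 0.28), and the single
top-decile connection is one of the planted effect connections (ROI pair
1–5, a between-network connection). The between-network shift mirrors the
mechanism:

```r
ni <- lapply(analysis$matrices_individual, network_connectivity,
             roi_network = atlas$roi_network)
na <- lapply(analysis$matrices_atlas, network_connectivity,
             roi_network = atlas$roi_network)
shift <- between_network_shift(ni, na)
attr(shift, "mean_pct_change")
#> [1] -40.46965
```

Between-network connectivity is substantially lower — i.e. measured more
cleanly, with less spill-over from neighboring regions — once ROIs are
localized per subject (significant in 12/12 networks after Bonferroni).

`run_pipeline()` wraps the same stages behind a validated (YAML-able)
config, writes TSV/JSON stage outputs, and returns a manifest with MD5
checksums that reproduce exactly under a fixed seed; `summarize_run()`
tabulates the results.

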
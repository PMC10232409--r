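# End-to-end orchestration: simulate -> qc -> parcellate -> connectome ->
# variability -> predict, with config validation, derived seeds, output
# files and a manifest of checksums. The stage order is fixed; the
# orchestrator exposes no way to permute it.

#' Analyze a cohort end to end (in memory)
#'
#' For every non-excluded subject: signal QC (censoring, nuisance
#' regression, spectral interpolation, band-pass), individual-specific
#' parcellation with template matching, ROI time series on both the
#' individual and the atlas parcellation (censored frames excluded), and
#' the two connectivity matrices.
#'
#' @param cohort a `synthetic_cohort` (or a compatible list of subject
#'   records with `mesh` and `atlas`).
#' @param qc run the signal QC stage (default `TRUE`; `FALSE` uses the raw
#'   signals, for noise-free closures).
#' @param n_iter parcellation iterations (default 10).
#' @param geodesic optional precomputed geodesic matrix (computed once
#'   when `NULL`).
#' @param fisher_z passed to [connectivity_matrix()].
#' @return a `cohort_analysis` list: `phenotypes` (data frame),
#'   `parcellations`, `matrices_individual`, `matrices_atlas`,
#'   `features_individual`, `features_atlas` (subject x connection),
#'   `feature_table`, `clean_signals`, `masks`, `excluded` (ids), `mesh`,
#'   `atlas`.
#' @export
analyze_cohort <- function(cohort, qc = TRUE, n_iter = 10L, geodesic = NULL,
                           fisher_z = FALSE) {
  mesh <- cohort$mesh; atlas <- cohort$atlas
  if (is.null(geodesic)) geodesic <- geodesic_distances(mesh)
  tr_s <- cohort$config$tr_s %||% 3
  parcellations <- list(); mats_i <- list(); mats_a <- list()
  masks <- list(); signals_clean <- list()
  keep_rows <- list(); excluded <- integer(0)
  idx <- feature_index(atlas$n_rois)
  feats_i <- NULL; feats_a <- NULL
  for (subj in cohort$subjects) {
    if (qc) {
      design <- nuisance_design(subj$motion_params, subj$wm, subj$vent)
      res <- qc_pipeline(subj$signals, subj$fd, subj$dvars, design,
                         frame_interval_s = tr_s)
      if (res$excluded) {
        excluded <- c(excluded, subj$id)
        next
      }
      sig <- res$signals; mask <- res$mask
    } else {
      sig <- subj$signals
      mask <- censor_mask(rep(0, ncol(sig)), rep(0, ncol(sig)))
    }
    parc <- parcellate_subject(sig, atlas, mesh,
                               variability_map = cohort$variability_map,
                               snr_map = cohort$snr_map, mask = mask,
                               n_iter = n_iter, geodesic = geodesic)
    ts_i <- roi_timeseries(sig, parc, mask, n_rois = atlas$n_rois)
    ts_a <- roi_timeseries(sig, atlas, mask, n_rois = atlas$n_rois)
    m_i <- connectivity_matrix(ts_i$ts, fisher_z, basis = "individual")
    m_a <- connectivity_matrix(ts_a$ts, fisher_z, basis = "atlas")
    sid <- as.character(subj$id)
    parcellations[[sid]] <- parc
    mats_i[[sid]] <- m_i; mats_a[[sid]] <- m_a
    masks[[sid]] <- mask
    signals_clean[[sid]] <- sig[, mask$keep, drop = FALSE]
    feats_i <- rbind(feats_i, unclass(m_i)[idx])
    feats_a <- rbind(feats_a, unclass(m_a)[idx])
    keep_rows[[sid]] <- subj
  }
  if (length(keep_rows) == 0L) stop_validation("all subjects excluded")
  phen <- do.call(rbind, lapply(keep_rows, function(s)
    data.frame(id = s$id, genotype = s$genotype, group = s$group,
               age = s$age, sex = s$sex,
               mmse_like = s$scores[["mmse_like"]],
               limm_like = s$scores[["limm_like"]])))
  rownames(phen) <- NULL
  # masked connections imputed with the cohort mean inside the feature
  # blocks only (summaries elsewhere never see imputed values)
  impute <- function(f) {
    mu <- colMeans(f, na.rm = TRUE)
    mu[is.na(mu)] <- 0
    bad <- which(is.na(f), arr.ind = TRUE)
    if (nrow(bad) > 0) f[bad] <- mu[bad[, 2]]
    f
  }
  structure(list(phenotypes = phen, parcellations = parcellations,
                 matrices_individual = mats_i, matrices_atlas = mats_a,
                 features_individual = impute(feats_i),
                 features_atlas = impute(feats_a),
                 feature_table = idx, clean_signals = signals_clean,
                 masks = masks, excluded = excluded,
                 mesh = mesh, atlas = atlas, geodesic = geodesic),
            class = "cohort_analysis")
}

#' Genotype-stratified symptom prediction on an analyzed cohort
#'
#' Runs the LOOCV SVR (optionally with a permutation test) on one genotype
#' group and one connectivity basis, followed by the contribution
#' analysis.
#'
#' @param analysis a [analyze_cohort()] result.
#' @param score `"mmse_like"` or `"limm_like"`.
#' @param genotype `"carrier"`, `"noncarrier"`, or `"all"` (merged).
#' @param basis `"individual"` or `"atlas"`.
#' @param n_perm permutations for the significance test (0 skips it).
#' @param seed permutation seed.
#' @param ... passed to [predict_svr_loocv()] / [permutation_test()].
#' @return a list with `report` (a `prediction_report`) and
#'   `contribution` (a `contribution_report`).
#' @export
predict_symptoms <- function(analysis, score = "mmse_like",
                             genotype = "carrier",
                             basis = c("individual", "atlas"),
                             n_perm = 0L, seed = 1L, ...) {
  basis <- match.arg(basis)
  phen <- analysis$phenotypes
  rows <- if (genotype == "all") seq_len(nrow(phen))
  else which(phen$genotype == genotype)
  feats <- if (basis == "individual") analysis$features_individual
  else analysis$features_atlas
  feats <- feats[rows, , drop = FALSE]
  scores <- phen[[score]][rows]
  conf <- cbind(age = phen$age, sex = phen$sex)[rows, , drop = FALSE]
  report <- if (n_perm > 0L)
    permutation_test(feats, scores, conf, n_perm = n_perm, seed = seed, ...)
  else predict_svr_loocv(feats, scores, conf, ...)
  contrib <- contribution_analysis(report$fold_weights,
                                   analysis$feature_table,
                                   analysis$atlas$roi_network,
                                   analysis$atlas$canonical_map)
  list(report = report, contribution = contrib)
}

#' Validate a pipeline configuration
#'
#' Checks a configuration list (or YAML file) before any compute: schema
#' version, positive counts, feasible atlas sizes, and a valid band-pass
#' band against the Nyquist frequency.
#'
#' @param config a list or path to a YAML file.
#' @return the validated config list (with `cohort` coerced to
#'   `cohort_config`), invisibly classed `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_config("config must be a list or YAML path")
  cohort_args <- config$cohort %||% list()
  cfg <- do.call(cohort_config, cohort_args)
  qc <- config$qc %||% list()
  low <- qc$low %||% 0.009
  high <- qc$high %||% 0.08
  if (high <= low || high >= 1 / (2 * cfg$tr_s))
    stop_config("config field qc.high: invalid band [", low, ", ", high,
                "] for TR = ", cfg$tr_s, " s")
  predict <- config$predict %||% list()
  n_perm <- predict$n_perm %||% 0L
  if (n_perm < 0) stop_config("config field predict.n_perm must be >= 0")
  structure(list(cohort = cfg, qc = list(low = low, high = high),
                 predict = list(n_perm = n_perm,
                                scores = predict$scores %||% "mmse_like",
                                genotypes = predict$genotypes %||%
                                  rownames(cfg$group_counts)),
                 out_dir = config$out_dir),
            class = "pipeline_config")
}

#' Run the full pipeline and write a manifest
#'
#' Executes the fixed stage order simulate -> qc -> parcellate ->
#' connectome -> variability -> predict, writes stage outputs (labels and
#' matrices as TSV, reports as JSON) under `out_dir`, and returns a run
#' manifest listing every output file with its MD5 checksum. Re-running
#' with the same config reproduces identical checksums.
#'
#' @param config a list, `pipeline_config`, or YAML path (see
#'   [validate_config()]).
#' @param out_dir output directory (overrides the config's; default a
#'   fresh temporary directory).
#' @return a `run_manifest` list: `config`, `seed`, `files` (data frame
#'   path/md5), `excluded`, `predictions`, `variability`, `shift`,
#'   `version`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out_dir <- out_dir %||% config$out_dir %||%
    file.path(tempdir(), paste0("connectotype_run_",
                                config$cohort$seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- make_cohort(config$cohort)
  analysis <- analyze_cohort(cohort)
  write_labels_tsv(cohort$atlas$roi_of_vertex,
                   file.path(out_dir, "atlas_roi_labels.tsv"))
  # variability stage
  vprof <- variability_profile(analysis$parcellations,
                               analysis$matrices_individual,
                               analysis$matrices_atlas,
                               analysis$mesh, analysis$atlas,
                               signal_list = analysis$clean_signals,
                               geodesic = analysis$geodesic)
  utils::write.table(format(vprof, digits = 12),
                     file.path(out_dir, "variability_profile.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  # between-network shift stage
  net_i <- lapply(analysis$matrices_individual, network_connectivity,
                  roi_network = analysis$atlas$roi_network)
  net_a <- lapply(analysis$matrices_atlas, network_connectivity,
                  roi_network = analysis$atlas$roi_network)
  shift <- between_network_shift(net_i, net_a)
  utils::write.table(format(shift, digits = 12),
                     file.path(out_dir, "between_network_shift.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  # prediction stage
  predictions <- list()
  for (sc in config$predict$scores) {
    for (g in config$predict$genotypes) {
      for (basis in c("individual", "atlas")) {
        key <- paste(sc, g, basis, sep = ".")
        pr <- predict_symptoms(analysis, score = sc, genotype = g,
                               basis = basis,
                               n_perm = config$predict$n_perm,
                               seed = derive_seed(config$cohort$seed, 1000))
        predictions[[key]] <- list(
          r = pr$report$r, permutation_p = pr$report$permutation_p,
          n = length(pr$report$observed),
          frac_top_between = pr$contribution$frac_top_between,
          top_connections = pr$contribution$top_connections)
      }
    }
  }
  pred_json <- lapply(predictions, function(p)
    list(r = p$r, permutation_p = p$permutation_p, n = p$n,
         frac_top_between = p$frac_top_between))
  jsonlite::write_json(pred_json, file.path(out_dir, "predictions.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- structure(list(
    config = config, seed = config$cohort$seed,
    files = data.frame(path = files,
                       md5 = unname(tools::md5sum(files))),
    excluded = analysis$excluded,
    predictions = predictions, variability = vprof, shift = shift,
    version = as.character(utils::packageVersion("connectotype"))),
    class = "run_manifest")
  jsonlite::write_json(
    list(seed = manifest$seed, version = manifest$version,
         excluded = manifest$excluded,
         files = manifest$files),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Summarize a pipeline run
#'
#' Human-readable tables mirroring the analysis reporting shape: one row
#' per prediction contrast with r, permutation p, and the between-network
#' share of the top connections, plus the per-network between-network
#' shift.
#'
#' @param manifest a [run_pipeline()] result.
#' @return a list with `prediction_table` and `shift_table` data frames,
#'   printed on request.
#' @export
summarize_run <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  pt <- if (length(manifest$predictions) == 0L) {
    data.frame(contrast = "not run")
  } else {
    do.call(rbind, lapply(names(manifest$predictions), function(k) {
      p <- manifest$predictions[[k]]
      data.frame(contrast = k, n = p$n, r = p$r,
                 permutation_p = p$permutation_p %||% NA_real_,
                 frac_top_between = p$frac_top_between)
    }))
  }
  list(prediction_table = pt, shift_table = manifest$shift)
}
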
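# Synthetic cohort generator: subject-specific functional topography
# (boundary-perturbed atlas labels), network-structured vertex time series
# with controllable SNR, motion traces with outlier frames, and symptom
# scores generated as a linear function of a small planted set of
# between-network connections plus age/sex confounding and noise.
#
# Every operation is a pure function of its arguments and seed; all cohort
# randomness derives from the config seed through per-subject child seeds.

#' Perturb atlas topography into a subject-specific parcellation
#'
#' Emulates inter-individual variability in the size and position of
#' functional regions: in each of `ceiling(shift_sd)` rounds, every vertex
#' on an ROI boundary is reassigned, with probability
#' `min(1, 0.5 * shift_sd / ceiling(shift_sd))`, to the ROI of one of its
#' geodesic neighbors. A move that would empty an ROI, shrink it below
#' `min_roi_size`, or disconnect it is skipped, so all ROIs remain nonempty
#' connected patches. `boundary_shift_sd = 0` returns the atlas unchanged.
#'
#' @param atlas a `cortical_atlas`.
#' @param mesh the `surface_mesh` the atlas lives on.
#' @param boundary_shift_sd non-negative perturbation magnitude in mesh
#'   edge-length units; larger values displace boundaries further.
#' @param seed integer RNG seed.
#' @param min_roi_size smallest ROI size preserved (default 2).
#' @return a list with `roi_of_vertex`, `network_of_vertex` (implied by the
#'   perturbed ROI labels) and `n_moved`, the number of reassigned vertices.
#' @export
perturb_topography <- function(atlas, mesh, boundary_shift_sd, seed,
                               min_roi_size = 2L) {
  stopifnot(inherits(atlas, "cortical_atlas"), inherits(mesh, "surface_mesh"))
  if (boundary_shift_sd < 0) stop_config("boundary_shift_sd must be >= 0")
  roi <- atlas$roi_of_vertex
  if (boundary_shift_sd == 0) {
    return(list(roi_of_vertex = roi,
                network_of_vertex = atlas$roi_network[roi],
                n_moved = 0L))
  }
  adj <- mesh_adjacency(mesh)
  rounds <- as.integer(ceiling(boundary_shift_sd))
  p_flip <- min(1, 0.5 * boundary_shift_sd / rounds)
  n_moved <- 0L
  withr::with_seed(seed, {
    for (r in seq_len(rounds)) {
      boundary <- which(vapply(seq_along(adj), function(v)
        any(roi[adj[[v]]] != roi[v]), logical(1)))
      boundary <- sample(boundary)           # randomized sweep order
      flip <- stats::runif(length(boundary)) < p_flip
      for (v in boundary[flip]) {
        old <- roi[v]
        members <- which(roi == old)
        if (length(members) <= min_roi_size) next
        if (length(vertex_components(setdiff(members, v), adj)) != 1L) next
        cand <- setdiff(unique(roi[adj[[v]]]), old)
        if (length(cand) == 0L) next
        roi[v] <- if (length(cand) == 1L) cand else sample(cand, 1L)
        n_moved <- n_moved + 1L
      }
    }
  })
  list(roi_of_vertex = roi,
       network_of_vertex = atlas$roi_network[roi],
       n_moved = n_moved)
}

# ROI-level covariance implied by a network-level covariance: distinct ROIs
# i != j covary as network_cov[net(i), net(j)] (the diagonal of network_cov
# is the within-network ROI-to-ROI covariance) and every ROI latent has unit
# variance. Optional per-pair additions plant subject-specific connectivity.
roi_covariance <- function(network_cov, roi_network, pair_shift = NULL) {
  k <- nrow(network_cov)
  sigma <- network_cov[roi_network, roi_network]
  diag(sigma) <- 1
  if (!is.null(pair_shift) && nrow(pair_shift) > 0) {
    for (e in seq_len(nrow(pair_shift))) {
      i <- pair_shift[e, 1]; j <- pair_shift[e, 2]; d <- pair_shift[e, 3]
      sigma[i, j] <- sigma[i, j] + d
      sigma[j, i] <- sigma[i, j]
    }
  }
  # clip eigenvalues so planted shifts cannot make the matrix indefinite
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < 1e-10) {
    vals <- pmax(ev$values, 1e-10)
    sigma <- ev$vectors %*% (vals * t(ev$vectors))
    sigma <- stats::cov2cor(sigma)
  }
  sigma
}

#' Simulate network-structured vertex time series
#'
#' Every ROI of the (true, subject-specific) parcellation has one latent
#' time series; latents of distinct ROIs covary as
#' `network_cov[net(i), net(j)]` (the diagonal giving the within-network
#' ROI-to-ROI covariance) and each latent has unit variance. A vertex
#' signal is its ROI latent plus independent Gaussian noise with standard
#' deviation `vertex_noise_sd`, so low values emulate high SNR.
#'
#' @param true_parcellation list with `roi_of_vertex` (e.g. from
#'   [perturb_topography()]) covering all mesh vertices.
#' @param mesh the `surface_mesh` (used only for the vertex count).
#' @param timepoints number of frames (>= 20).
#' @param network_cov symmetric positive semi-definite network-by-network
#'   covariance.
#' @param vertex_noise_sd scalar or per-vertex noise SD (>= 0).
#' @param seed integer RNG seed.
#' @param roi_network ROI -> network map; required when
#'   `true_parcellation` does not carry one.
#' @param pair_shift optional 3-column matrix `(roi_i, roi_j, delta)` of
#'   covariance additions planting subject-specific connectivity.
#' @return a list: `signals` (vertex x time), `latents` (time x ROI),
#'   `roi_cov` (the ROI covariance actually used, after PSD clipping).
#' @export
simulate_timeseries <- function(true_parcellation, mesh, timepoints,
                                network_cov, vertex_noise_sd, seed,
                                roi_network = NULL, pair_shift = NULL) {
  if (timepoints < 20) stop_config("timepoints must be >= 20")
  network_cov <- as.matrix(network_cov)
  if (!isSymmetric(unname(network_cov), tol = 1e-8))
    stop_validation("network_cov must be symmetric")
  ev <- eigen(network_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_validation("network_cov must be positive semi-definite")
  roi <- true_parcellation$roi_of_vertex
  nv <- length(roi)
  if (nv != mesh$n_vertices)
    stop_validation("parcellation does not cover the mesh")
  roi_network <- roi_network %||% true_parcellation$roi_network
  if (is.null(roi_network))
    roi_network <- rep(1L, max(roi))
  sigma <- roi_covariance(network_cov, roi_network, pair_shift)
  nr <- nrow(sigma)
  if (length(vertex_noise_sd) == 1L)
    vertex_noise_sd <- rep(vertex_noise_sd, nv)
  withr::with_seed(seed, {
    z <- matrix(stats::rnorm(timepoints * nr), timepoints, nr)
    latents <- z %*% chol(sigma + diag(1e-10, nr))
    noise <- matrix(stats::rnorm(nv * timepoints), nv, timepoints) *
      vertex_noise_sd
  })
  signals <- t(latents)[roi, , drop = FALSE] + noise
  list(signals = signals, latents = latents, roi_cov = sigma)
}

#' Simulate framewise displacement and DVARS traces
#'
#' Baseline FD stays below 0.2 mm and baseline DVARS below 50; a
#' Bernoulli(`outlier_rate`) subset of frames receives an FD and/or DVARS
#' excursion above the corresponding threshold, so the expected raw outlier
#' count is `outlier_rate * timepoints`.
#'
#' @param timepoints number of frames.
#' @param outlier_rate per-frame outlier probability in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return a list with numeric `fd` (mm), `dvars`, and the logical
#'   `outlier` indicator actually drawn.
#' @export
simulate_motion <- function(timepoints, outlier_rate, seed) {
  if (outlier_rate < 0 || outlier_rate > 1)
    stop_config("outlier_rate must be in [0, 1]")
  withr::with_seed(seed, {
    fd <- pmin(abs(stats::rnorm(timepoints, 0.08, 0.03)), 0.19)
    dvars <- pmin(pmax(stats::rnorm(timepoints, 30, 5), 5), 48)
    outlier <- stats::runif(timepoints) < outlier_rate
    if (any(outlier)) {
      kind <- sample(3L, sum(outlier), replace = TRUE)  # fd / dvars / both
      fd_hit <- outlier
      fd_hit[outlier] <- kind != 2L
      dv_hit <- outlier
      dv_hit[outlier] <- kind != 1L
      fd[fd_hit] <- 0.21 + stats::rexp(sum(fd_hit), 5)
      dvars[dv_hit] <- 52 + stats::rexp(sum(dv_hit), 0.2)
    }
  })
  list(fd = fd, dvars = dvars, outlier = outlier)
}

#' Simulate symptom scores from planted connections
#'
#' `score = sum_k beta_k * conn(i_k, j_k) + gamma_age * age +
#' gamma_sex * sex + baseline + Normal(0, noise_sd)`, optionally clamped to
#' an instrument range.
#'
#' @param true_connectivity ROI x ROI connectivity matrix (the generative
#'   truth, not a measured matrix).
#' @param effect_connections matrix with columns `roi_i`, `roi_j`, `beta`.
#' @param age,sex scalar confound values (sex coded 0/1).
#' @param gamma_age,gamma_sex confound coefficients (default 0).
#' @param baseline intercept (default 0).
#' @param noise_sd Gaussian noise SD (default 0).
#' @param range optional length-2 clamping interval, e.g. `c(0, 30)` for an
#'   MMSE-like instrument; `NULL` (default) leaves scores unclamped.
#' @param seed integer RNG seed (only used when `noise_sd > 0`).
#' @return a single numeric score.
#' @export
simulate_symptoms <- function(true_connectivity, effect_connections,
                              age = 0, sex = 0, gamma_age = 0, gamma_sex = 0,
                              baseline = 0, noise_sd = 0, range = NULL,
                              seed = 1L) {
  eff <- as.matrix(effect_connections)
  nr <- nrow(true_connectivity)
  if (nrow(eff) > 0 && (any(eff[, 1:2] < 1) || any(eff[, 1:2] > nr)))
    stop_validation("effect connections reference invalid ROI pairs")
  signal <- if (nrow(eff) == 0) 0 else
    sum(eff[, 3] * true_connectivity[cbind(eff[, 1], eff[, 2])])
  eps <- if (noise_sd > 0)
    withr::with_seed(seed, stats::rnorm(1, 0, noise_sd)) else 0
  score <- baseline + signal + gamma_age * age + gamma_sex * sex + eps
  if (!is.null(range)) score <- min(max(score, range[1]), range[2])
  score
}

#' Configuration for a synthetic cohort
#'
#' Defaults mirror the study conditions the generator emulates: two
#' genotype cohorts of 120 (carriers) and 115 (noncarriers) subjects in
#' three clinical subgroups (42/39/39 and 43/39/33), a 2562-vertex
#' single-hemisphere mesh carrying 116 ROIs in 18 fine networks under 7
#' canonical networks, 196 frames at TR = 3 s, boundary shifts of 1 edge
#' length, vertex noise SD 0.5 (vertex SNR about 2), and MMSE-like /
#' LIMM-like scores clamped to `[0, 30]` / `[0, 25]` whose group structure
#' follows the planted connection shifts (deviations ordered AD > MCI > NA).
#' Each genotype group carries its own planted effect-connection map.
#'
#' @param n_vertices mesh size (default 2562; use 642 or 162 for desk-scale
#'   runs).
#' @param n_networks,n_rois atlas sizes (defaults 18 and 116).
#' @param timepoints frames per subject (default 196).
#' @param tr_s frame interval in seconds (default 3).
#' @param group_counts 2 x 3 matrix of subject counts, rows = genotype
#'   (carrier, noncarrier), columns = group (NA, MCI, AD).
#' @param boundary_shift_sd topography perturbation (default 1 edge).
#' @param vertex_noise_sd vertex noise SD (default 0.5).
#' @param within_network_cov,between_network_cov entries of the network
#'   covariance (defaults 0.6 and 0.2).
#' @param effect_connections named list (`carrier`, `noncarrier`) of
#'   3-column matrices `(roi_i, roi_j, beta)`; `NULL` plants 3 distinct
#'   between-network connections per genotype with the default betas.
#' @param group_conn_shift named connectivity mean shifts per clinical
#'   group applied to the planted connections (default NA 0, MCI -0.12,
#'   AD -0.3).
#' @param effect_conn_sd subject-level SD of the planted connectivity
#'   deviations (default 0.1).
#' @param symptom_noise_sd named noise SDs for `mmse_like` and `limm_like`
#'   (defaults 1.5 and 2.5, in the range of the within-subgroup score SDs
#'   the generator emulates).
#' @param gamma_age,gamma_sex confound coefficients (defaults -0.05 and
#'   0.3).
#' @param outlier_rate motion outlier rate (default 0.05).
#' @param nuisance_coupling amplitude of the motion/tissue nuisance
#'   components mixed into the signals (default 0.3).
#' @param atlas_seed,seed integer seeds; `seed` drives all per-subject
#'   randomness through [derive_seed()].
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_vertices = 2562, n_networks = 18, n_rois = 116,
                          timepoints = 196, tr_s = 3,
                          group_counts = rbind(carrier = c(42, 39, 39),
                                               noncarrier = c(43, 39, 33)),
                          boundary_shift_sd = 1, vertex_noise_sd = 0.5,
                          within_network_cov = 0.6, between_network_cov = 0.2,
                          effect_connections = NULL,
                          group_conn_shift = c("NA" = 0, MCI = -0.12,
                                               AD = -0.3),
                          effect_conn_sd = 0.1,
                          symptom_noise_sd = c(mmse_like = 1.5,
                                               limm_like = 2.5),
                          gamma_age = -0.05, gamma_sex = 0.3,
                          outlier_rate = 0.05, nuisance_coupling = 0.3,
                          atlas_seed = 99, seed = 1) {
  group_counts <- as.matrix(group_counts)
  if (any(group_counts <= 0)) stop_config("all group counts must be positive")
  if (is.null(rownames(group_counts)))
    rownames(group_counts) <- c("carrier", "noncarrier")
  colnames(group_counts) <- c("NA", "MCI", "AD")
  roi_network <- ((seq_len(n_rois) - 1L) %% n_networks) + 1L
  if (is.null(effect_connections)) {
    # one deterministic scan, split in two, so the genotype maps never share
    # a connection
    all_pairs <- choose_effect_connections(n_rois, roi_network, 6L, beta = 8)
    effect_connections <- list(carrier = all_pairs[1:3, , drop = FALSE],
                               noncarrier = all_pairs[4:6, , drop = FALSE])
  }
  for (g in names(effect_connections)) {
    eff <- effect_connections[[g]]
    if (any(eff[, 1:2] < 1) || any(eff[, 1:2] > n_rois) ||
        any(eff[, 1] == eff[, 2]))
      stop_config("effect connections reference invalid ROI pairs")
  }
  structure(list(
    n_vertices = n_vertices, n_networks = n_networks, n_rois = n_rois,
    timepoints = timepoints, tr_s = tr_s, group_counts = group_counts,
    boundary_shift_sd = boundary_shift_sd, vertex_noise_sd = vertex_noise_sd,
    within_network_cov = within_network_cov,
    between_network_cov = between_network_cov,
    effect_connections = effect_connections,
    group_conn_shift = group_conn_shift, effect_conn_sd = effect_conn_sd,
    symptom_noise_sd = symptom_noise_sd,
    gamma_age = gamma_age, gamma_sex = gamma_sex,
    score_baseline = c(mmse_like = 24.4, limm_like = 8),
    score_range = list(mmse_like = c(0, 30), limm_like = c(0, 25)),
    outlier_rate = outlier_rate, nuisance_coupling = nuisance_coupling,
    atlas_seed = atlas_seed, seed = seed,
    schema_version = "1"), class = "cohort_config")
}

# Deterministic scan for n_pairs distinct between-network ROI pairs.
choose_effect_connections <- function(n_rois, roi_network, n_pairs,
                                      offset = 0L, beta = 8) {
  stopifnot(n_rois >= 2 * n_pairs)
  pairs <- matrix(0, 0, 3, dimnames = list(NULL, c("roi_i", "roi_j", "beta")))
  i <- 1L + offset
  step <- max(2L, n_rois %/% (2L * n_pairs))
  while (nrow(pairs) < n_pairs) {
    a <- (i - 1L) %% n_rois + 1L
    b <- (i - 1L + step) %% n_rois + 1L
    i <- i + step + 1L
    if (a == b || roi_network[a] == roi_network[b]) next
    key_new <- paste(min(a, b), max(a, b))
    keys <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    if (key_new %in% keys) next
    pairs <- rbind(pairs, c(a, b, beta))
  }
  pairs
}

#' Generate a synthetic cohort
#'
#' For every subject: perturbed topography, network-structured time series
#' with the subject's planted connectivity deviations, nuisance components
#' (six motion parameters, white-matter and ventricle proxies) mixed into
#' the signals, FD/DVARS traces with outlier frames and matching signal
#' spikes, and MMSE-like / LIMM-like symptom scores computed from the true
#' (generative) connectivity at the genotype's planted connections plus
#' age/sex confounding and noise. Clinical group differences are encoded as
#' connectivity mean shifts (|deviation| ordered AD > MCI > NA).
#'
#' @param config a [cohort_config()].
#' @param mesh,atlas optionally precomputed mesh/atlas (rebuilt from the
#'   config when `NULL`).
#' @return an object of class `synthetic_cohort`: `config`, `mesh`,
#'   `atlas`, `variability_map` and `snr_map` (per-vertex priors exposed to
#'   the parcellation), and `subjects`, a list of subject records each with
#'   `id`, `genotype`, `group`, `age`, `sex`, `signals`, `fd`, `dvars`,
#'   `motion_params`, `wm`, `vent`, `scores`, and `truth` (true
#'   parcellation, ROI covariance, true connectivity, planted connections).
#' @export
make_cohort <- function(config, mesh = NULL, atlas = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  mesh <- mesh %||% make_mesh(config$n_vertices, "icosphere")
  atlas <- atlas %||% make_atlas(mesh, config$n_networks, config$n_rois,
                                 seed = config$atlas_seed)
  k <- config$n_networks
  network_cov <- matrix(config$between_network_cov, k, k)
  diag(network_cov) <- config$within_network_cov
  adj <- mesh_adjacency(mesh)
  net_of_v <- atlas$network_of_vertex
  boundary <- vapply(seq_along(adj), function(v)
    any(net_of_v[adj[[v]]] != net_of_v[v]), logical(1))
  variability_map <- ifelse(boundary, 0.8, 0.2)
  snr_map <- rep(1 / (1 + mean(config$vertex_noise_sd)^2), mesh$n_vertices)
  subjects <- list()
  idx <- 0L
  for (g in rownames(config$group_counts)) {
    eff <- config$effect_connections[[g]]
    for (grp in colnames(config$group_counts)) {
      for (s in seq_len(config$group_counts[g, grp])) {
        idx <- idx + 1L
        subjects[[idx]] <- simulate_subject(idx, g, grp, eff, config,
                                            mesh, atlas, network_cov)
      }
    }
  }
  structure(list(config = config, mesh = mesh, atlas = atlas,
                 variability_map = variability_map, snr_map = snr_map,
                 subjects = subjects),
            class = "synthetic_cohort")
}

simulate_subject <- function(idx, genotype, group, eff, config, mesh, atlas,
                             network_cov) {
  base_seed <- derive_seed(config$seed, idx)
  truth_parc <- perturb_topography(atlas, mesh, config$boundary_shift_sd,
                                   seed = derive_seed(base_seed, 1L))
  truth_parc$roi_network <- atlas$roi_network
  demo <- withr::with_seed(derive_seed(base_seed, 2L), {
    list(age = min(max(stats::rnorm(1, 72, 7), 55), 95),
         sex = stats::rbinom(1, 1, 0.5),
         delta = config$group_conn_shift[[group]] +
           stats::rnorm(nrow(eff), 0, config$effect_conn_sd))
  })
  pair_shift <- cbind(eff[, 1], eff[, 2], demo$delta)
  ts <- simulate_timeseries(truth_parc, mesh, config$timepoints,
                            network_cov, config$vertex_noise_sd,
                            seed = derive_seed(base_seed, 3L),
                            roi_network = atlas$roi_network,
                            pair_shift = pair_shift)
  true_conn <- stats::cov2cor(ts$roi_cov)
  motion <- simulate_motion(config$timepoints, config$outlier_rate,
                            seed = derive_seed(base_seed, 4L))
  nuis <- withr::with_seed(derive_seed(base_seed, 5L), {
    tt <- config$timepoints
    mp <- apply(matrix(stats::rnorm(tt * 6, 0, 0.02), tt, 6), 2, cumsum)
    wm <- as.numeric(stats::filter(stats::rnorm(tt), 0.8,
                                   method = "recursive"))
    vent <- as.numeric(stats::filter(stats::rnorm(tt), 0.8,
                                     method = "recursive"))
    load <- matrix(stats::rnorm(mesh$n_vertices * 8, 0, 1),
                   mesh$n_vertices, 8)
    spike <- matrix(stats::rnorm(mesh$n_vertices * tt, 0, 3),
                    mesh$n_vertices, tt)
    list(mp = mp, wm = wm, vent = vent, load = load, spike = spike)
  })
  signals <- ts$signals +
    config$nuisance_coupling *
      (nuis$load %*% t(cbind(scale(nuis$mp), scale(nuis$wm),
                             scale(nuis$vent))))
  signals[, motion$outlier] <- signals[, motion$outlier] +
    nuis$spike[, motion$outlier, drop = FALSE]
  scores <- c(
    mmse_like = simulate_symptoms(true_conn, eff,
                                  age = demo$age - 72, sex = demo$sex,
                                  gamma_age = config$gamma_age,
                                  gamma_sex = config$gamma_sex,
                                  baseline = config$score_baseline[["mmse_like"]],
                                  noise_sd = config$symptom_noise_sd[["mmse_like"]],
                                  range = config$score_range$mmse_like,
                                  seed = derive_seed(base_seed, 6L)),
    limm_like = simulate_symptoms(true_conn,
                                  cbind(eff[, 1], eff[, 2], 11),
                                  age = demo$age - 72, sex = demo$sex,
                                  gamma_age = config$gamma_age,
                                  gamma_sex = config$gamma_sex,
                                  baseline = config$score_baseline[["limm_like"]],
                                  noise_sd = config$symptom_noise_sd[["limm_like"]],
                                  range = config$score_range$limm_like,
                                  seed = derive_seed(base_seed, 7L)))
  list(id = idx, genotype = genotype, group = group,
       age = demo$age, sex = demo$sex,
       signals = signals, fd = motion$fd, dvars = motion$dvars,
       motion_params = nuis$mp, wm = nuis$wm, vent = nuis$vent,
       scores = scores,
       truth = list(parcellation = truth_parc, roi_cov = ts$roi_cov,
                    true_connectivity = true_conn,
                    effect_connections = eff, conn_delta = demo$delta))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(genotype = vapply(x$subjects, `[[`, "", "genotype"),
               group = vapply(x$subjects, `[[`, "", "group"))
  cat(sprintf("synthetic_cohort: %d subjects on %d-vertex mesh (%d ROIs)\n",
              length(x$subjects), x$mesh$n_vertices, x$atlas$n_rois))
  print(tab)
  invisible(x)
}
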
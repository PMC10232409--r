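test_that("zero boundary shift returns the atlas unchanged", {
  mesh <- test_mesh_162(); atlas <- test_atlas_162()
  p <- perturb_topography(atlas, mesh, 0, seed = 3)
  expect_identical(p$roi_of_vertex, atlas$roi_of_vertex)
  expect_identical(p$n_moved, 0L)
})

test_that("boundary perturbation moves boundaries but keeps ROIs connected", {
  mesh <- test_mesh_162(); atlas <- test_atlas_162()
  p1 <- perturb_topography(atlas, mesh, 1, seed = 3)
  p2 <- perturb_topography(atlas, mesh, 1, seed = 4)
  d1 <- dice_per_roi(p1$roi_of_vertex, atlas$roi_of_vertex, 24)
  expect_true(any(d1 < 1))
  expect_false(identical(p1$roi_of_vertex, p2$roi_of_vertex))
  for (r in seq_len(24)) {
    members <- which(p1$roi_of_vertex == r)
    expect_gt(length(members), 0)
    expect_equal(oracle_component_count(members, mesh), 1L)
  }
})

test_that("mean Dice with the atlas is non-increasing in the shift", {
  mesh <- test_mesh_162(); atlas <- test_atlas_162()
  mean_dice <- vapply(c(0.5, 2.0), function(sd_) {
    mean(vapply(1:20, function(s) {
      p <- perturb_topography(atlas, mesh, sd_, seed = 100 + s)
      mean(dice_per_roi(p$roi_of_vertex, atlas$roi_of_vertex, 24))
    }, numeric(1)))
  }, numeric(1))
  expect_lte(mean_dice[2], mean_dice[1])
})

test_that("simulated signals follow the planted ROI/network structure", {
  mesh <- test_mesh_162(); atlas <- test_atlas_162()
  parc <- perturb_topography(atlas, mesh, 1, seed = 9)
  # noise-free: every vertex in an ROI carries the ROI latent exactly
  ts0 <- simulate_timeseries(parc, mesh, 40, default_network_cov(6), 0,
                             seed = 5, roi_network = atlas$roi_network)
  vs <- which(parc$roi_of_vertex == 3)
  expect_equal(max(abs(sweep(ts0$signals[vs, ], 2,
                             ts0$signals[vs[1], ]))), 0)
  # identity network covariance: between-network latents uncorrelated
  ts1 <- simulate_timeseries(parc, mesh, 2000, diag(6), 0, seed = 6,
                             roi_network = atlas$roi_network)
  cc <- cor(ts1$latents)
  between <- abs(cc[atlas$roi_network[row(cc)] != atlas$roi_network[col(cc)]])
  expect_lt(max(between), 0.1)
  # determinism
  ts2 <- simulate_timeseries(parc, mesh, 40, default_network_cov(6), 0.3,
                             seed = 5, roi_network = atlas$roi_network)
  ts3 <- simulate_timeseries(parc, mesh, 40, default_network_cov(6), 0.3,
                             seed = 5, roi_network = atlas$roi_network)
  expect_identical(ts2$signals, ts3$signals)
  expect_error(simulate_timeseries(parc, mesh, 40, matrix(c(1, 2, 0, 1),
                                                          2, 2), 0, seed = 1),
               class = "connectotype_validation_error")
  expect_error(simulate_timeseries(parc, mesh, 40,
                                   matrix(c(1, 2, 2, 1), 2, 2), 0, seed = 1),
               class = "connectotype_validation_error")
})

test_that("motion traces hit the censoring thresholds at the planted rate", {
  none <- simulate_motion(20, 0, seed = 1)
  expect_false(any(none$fd > 0.2 | none$dvars > 50))
  all_out <- simulate_motion(20, 1, seed = 1)
  expect_true(all(all_out$fd > 0.2 | all_out$dvars > 50))
  counts <- vapply(1:50, function(s) {
    m <- simulate_motion(500, 0.1, seed = s)
    sum(m$fd > 0.2 | m$dvars > 50)
  }, numeric(1))
  expect_gte(mean(counts), 40)
  expect_lte(mean(counts), 60)
})

test_that("symptom scores are the planted linear map of connectivity", {
  sigma <- default_network_cov(4, 0.6, 0.2)
  tc <- sigma[c(1, 2, 3, 4, 1, 2), c(1, 2, 3, 4, 1, 2)]
  diag(tc) <- 1
  s <- simulate_symptoms(tc, cbind(2, 5, 1))
  expect_equal(s, tc[2, 5])
  # effect monotonicity: larger beta, stronger score-connection coupling
  conns <- vapply(1:500, function(i) {
    cov_i <- connectotype:::roi_covariance(sigma, c(1, 2, 3, 4, 1, 2),
                                           cbind(1, 4, rnorm(1, 0, 0.2)))
    stats::cov2cor(cov_i)[1, 4]
  }, numeric(1))
  score_of <- function(beta) vapply(seq_along(conns), function(i) {
    m <- diag(6); m[1, 4] <- m[4, 1] <- conns[i]
    simulate_symptoms(m, cbind(1, 4, beta), noise_sd = 1, seed = 900 + i)
  }, numeric(1))
  r_small <- cor(conns, score_of(0.5))
  r_large <- cor(conns, score_of(4))
  expect_gt(r_large, r_small)
  # null: no planted effect, scores uncorrelated with candidate connections
  null_scores <- score_of(0)
  expect_lt(abs(cor(conns, null_scores)), 0.2)
  # clamping respects the instrument range
  expect_equal(simulate_symptoms(tc, cbind(2, 5, 1000), range = c(0, 30)), 30)
})

test_that("cohorts are deterministic with the configured cell structure", {
  cfg <- cohort_config(n_vertices = 162, n_networks = 6, n_rois = 24,
                       timepoints = 40,
                       group_counts = rbind(carrier = c(2, 1, 1),
                                            noncarrier = c(1, 1, 1)),
                       boundary_shift_sd = 0, vertex_noise_sd = 0,
                       outlier_rate = 0, seed = 21)
  mesh <- test_mesh_162()
  atlas <- make_atlas(mesh, 6, 24, seed = cfg$atlas_seed)
  cohort <- make_cohort(cfg, mesh, atlas)
  expect_length(cohort$subjects, 7)
  tab <- table(vapply(cohort$subjects, `[[`, "", "genotype"),
               vapply(cohort$subjects, `[[`, "", "group"))
  expect_equal(unname(tab["carrier", "NA"]), 2)
  expect_equal(unname(tab["noncarrier", "AD"]), 1)
  # zero shift: every true parcellation is the atlas
  for (s in cohort$subjects)
    expect_identical(s$truth$parcellation$roi_of_vertex,
                     atlas$roi_of_vertex)
  cohort2 <- make_cohort(cfg, mesh, atlas)
  expect_identical(vapply(cohort$subjects, function(s) s$scores, numeric(2)),
                   vapply(cohort2$subjects, function(s) s$scores,
                          numeric(2)))
  # genotype effect maps are disjoint by construction
  eff <- cfg$effect_connections
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  expect_length(intersect(key(eff$carrier), key(eff$noncarrier)), 0)
})
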
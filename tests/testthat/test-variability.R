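test_that("size variability matches the hand formula", {
  pA <- list(roi_of_vertex = c(rep(1L, 10), rep(2L, 6)))
  pB <- list(roi_of_vertex = c(rep(1L, 14), rep(2L, 2)))
  expect_equal(size_variability(list(pA, pB), 2),
               c(sqrt(8), sqrt(8)), tolerance = 1e-10)
  three <- list(list(roi_of_vertex = rep(1L, 8)),
                list(roi_of_vertex = rep(1L, 10)),
                list(roi_of_vertex = rep(1L, 12)))
  expect_equal(size_variability(three, 1), 2, tolerance = 1e-10)
  # an unmatched ROI counts as size zero
  pC <- list(roi_of_vertex = rep(1L, 10))
  sv <- size_variability(list(pA, pC), 2)
  expect_equal(sv[2], stats::sd(c(6, 0)))
})

test_that("position variability is the mean pairwise center distance", {
  mesh <- make_mesh(100, "grid")
  geo <- geodesic_distances(mesh)
  # two single-vertex ROIs three unit edges apart along a grid row
  pA <- list(roi_of_vertex = c(1L, rep(NA_integer_, 99)))
  pB <- list(roi_of_vertex = c(rep(NA_integer_, 3), 1L,
                               rep(NA_integer_, 96)))
  expect_equal(position_variability(list(pA, pB), mesh, 1, geo), 3)
  # three centers at column offsets 0, 1, 3: pair distances 1, 3, 2
  pC <- list(roi_of_vertex = c(NA_integer_, 1L, rep(NA_integer_, 98)))
  expect_equal(position_variability(list(pA, pC, pB), mesh, 1, geo), 2)
  # identical parcellations give zero everywhere
  expect_equal(position_variability(list(pA, pA), mesh, 1, geo), 0)
})

test_that("position variability scales exactly with the mesh coordinates", {
  mesh <- test_mesh_162()
  atlas <- test_atlas_162()
  parcs <- lapply(1:3, function(s)
    perturb_topography(atlas, mesh, 1, seed = 50 + s))
  pv <- position_variability(parcs, mesh, 24)
  scaled <- connectotype:::finish_mesh(mesh$vertices * 2.5, mesh$triangles)
  pv2 <- position_variability(parcs, scaled, 24)
  expect_equal(pv2, 2.5 * pv, tolerance = 1e-10)
  # size variability is scale-invariant by construction
  expect_identical(size_variability(parcs, 24),
                   size_variability(parcs, 24))
})

test_that("connectivity variability is zero for identical subjects and matches hand math", {
  set.seed(52)
  base <- oracle_connectivity(matrix(rnorm(6 * 40), 6, 40))
  expect_equal(roi_connectivity_variability(list(base, base, base)),
               rep(0, 6))
  # one connection varying +/- d around its mean across two subjects
  d <- 0.2
  m1 <- base; m2 <- base
  m1[2, 5] <- m1[5, 2] <- base[2, 5] + d
  m2[2, 5] <- m2[5, 2] <- base[2, 5] - d
  v <- roi_connectivity_variability(list(m1, m2))
  sd_conn <- stats::sd(c(base[2, 5] + d, base[2, 5] - d))
  expect_equal(v[2], sd_conn / 5)       # mean over the 5 incident pairs
  expect_equal(v[5], sd_conn / 5)
  expect_equal(v[1], 0)
  # invariance to subject order
  expect_equal(roi_connectivity_variability(list(m2, m1)), v)
})

test_that("vertex-wise variability is zero for identical subjects and detects planted contrast", {
  mesh <- test_mesh_162(); atlas <- test_atlas_162()
  ts <- simulate_timeseries(list(roi_of_vertex = atlas$roi_of_vertex),
                            mesh, 80, default_network_cov(6), 0.2,
                            seed = 53, roi_network = atlas$roi_network)
  same <- vertex_variability(list(ts$signals, ts$signals), atlas)
  expect_lt(max(same$per_vertex, na.rm = TRUE), 1e-10)
  # subjects whose topography differs only inside networks 1-3 show more
  # profile variability on those networks' vertices
  perturb_some <- function(seed) {
    p <- perturb_topography(atlas, mesh, 1.5, seed = seed)
    frozen <- atlas$roi_network[atlas$roi_of_vertex] > 3 |
      atlas$roi_network[p$roi_of_vertex] > 3
    p$roi_of_vertex[frozen] <- atlas$roi_of_vertex[frozen]
    p
  }
  sigs <- lapply(1:6, function(s) {
    p <- perturb_some(60 + s)
    simulate_timeseries(p, mesh, 80, default_network_cov(6), 0.1,
                        seed = 70 + s,
                        roi_network = atlas$roi_network)$signals
  })
  vv <- vertex_variability(sigs, atlas)
  hot <- atlas$network_of_vertex <= 3
  expect_gt(mean(vv$per_vertex[hot]), mean(vv$per_vertex[!hot]))
})

test_that("profile correlations behave and the full profile assembles", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(correlate_profiles(a, a)$r, 1)
  expect_equal(correlate_profiles(a, -a)$r, -1)
  expect_true(is.na(correlate_profiles(a, rep(1, 5))$r))
  expect_error(correlate_profiles(a, a[1:3]),
               class = "connectotype_validation_error")
  # on a shift-0 noise-0 cohort all four profiles are identically zero
  mesh <- test_mesh_162()
  atlas <- test_atlas_162()
  parc0 <- list(roi_of_vertex = atlas$roi_of_vertex)
  mats <- lapply(1:3, function(s) {
    ts <- simulate_timeseries(parc0, mesh, 60, default_network_cov(6), 0,
                              seed = 80, roi_network = atlas$roi_network)
    unclass(connectivity_matrix(roi_timeseries(ts$signals, atlas)$ts))
  })
  prof <- variability_profile(list(atlas, atlas, atlas), mats, mats,
                              mesh, atlas, geodesic = test_geo_162())
  expect_true(all(prof$size_var == 0))
  expect_true(all(prof$position_var == 0))
  expect_true(all(prof$indiv_conn_var == 0))
  expect_true(all(prof$atlas_conn_var == 0))
})
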
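grid10 <- function() fixture("grid10", function() make_mesh(100, "grid"))
gidx <- function(x, y) y * 10 + x + 1   # grid vertex index from 0-based coords

# hand-built atlas on the 10x10 grid: ROI 1 and 2 in network 1 (two small
# blocks), everything else ROI 3 in network 2
grid_atlas <- function() fixture("grid_atlas", function() {
  roi <- rep(3L, 100)
  for (x in 0:2) for (y in 0:2) roi[gidx(x, y)] <- 1L
  for (x in 6:8) for (y in 0:2) roi[gidx(x, y)] <- 2L
  structure(list(roi_of_vertex = roi,
                 network_of_vertex = c(1L, 1L, 2L)[roi],
                 roi_network = c(1L, 1L, 2L),
                 canonical_map = c(1L, 2L),
                 n_networks = 2L, n_rois = 3L, n_canonical = 2L),
            class = "cortical_atlas")
})

test_that("noise-free atlas topography is a fixed point of the parcellation", {
  mesh <- test_mesh_162(); atlas <- test_atlas_162()
  parc0 <- list(roi_of_vertex = atlas$roi_of_vertex)
  ts <- simulate_timeseries(parc0, mesh, 60, default_network_cov(6), 0,
                            seed = 31, roi_network = atlas$roi_network)
  labels <- iterative_parcellation(ts$signals, atlas,
                                   snr_map = rep(1, 162))
  expect_identical(labels, atlas$network_of_vertex)
  ip <- parcellate_subject(ts$signals, atlas, mesh,
                           snr_map = rep(1, 162),
                           geodesic = test_geo_162())
  expect_identical(ip$roi_of_vertex, atlas$roi_of_vertex)
})

test_that("noise-free perturbed topography is recovered exactly at network level", {
  mesh <- test_mesh_642(); atlas <- test_atlas_642()
  truth <- perturb_topography(atlas, mesh, 1, seed = 17)
  ts <- simulate_timeseries(truth, mesh, 60, default_network_cov(18), 0,
                            seed = 32, roi_network = atlas$roi_network)
  labels <- iterative_parcellation(ts$signals, atlas,
                                   snr_map = rep(1, 642))
  expect_identical(labels, truth$network_of_vertex)
})

test_that("a dominant atlas prior reproduces the atlas regardless of signals", {
  mesh <- test_mesh_162(); atlas <- test_atlas_162()
  set.seed(33)
  noise <- matrix(rnorm(162 * 50), 162, 50)
  labels <- iterative_parcellation(noise, atlas,
                                   variability_map = rep(0.5, 162),
                                   snr_map = rep(0.5, 162),
                                   alpha = rep(1e6, 10))
  expect_identical(labels, atlas$network_of_vertex)
})

test_that("patches are connected components and smoothing keeps them intact", {
  mesh <- grid10()
  labels <- rep(1L, 100)
  blob2 <- c(gidx(8, 8), gidx(9, 8), gidx(8, 9), gidx(9, 9))
  labels[blob2] <- 2L
  labels[gidx(0, 9)] <- 2L            # second, disjoint blob of network 2
  patches <- extract_patches(labels, mesh,
                             smoothing_sigma = 0.5)
  nets <- vapply(patches, `[[`, integer(1), "network")
  expect_equal(sum(nets == 2), 2)
  # original vertex sets are exactly the flood-fill components
  for (p in patches) {
    expect_equal(oracle_component_count(p$vertices, mesh), 1L)
    expect_true(all(labels[p$vertices] == p$network))
  }
  expect_setequal(unlist(lapply(patches, `[[`, "vertices")), 1:100)
  # a random label map has as many patches as brute-force components
  set.seed(34)
  rand <- sample(1:3, 100, replace = TRUE)
  patches2 <- extract_patches(rand, mesh)
  n_oracle <- sum(vapply(1:3, function(k) {
    members <- which(rand == k)
    oracle_component_count(members, mesh)
  }, integer(1)))
  expect_length(patches2, n_oracle)
})

test_that("template matching follows the overlap / split / nearest rules", {
  mesh <- grid10(); atlas <- grid_atlas()
  geo <- geodesic_distances(mesh)
  # rule 1: a patch identical to ROI 1
  p_roi1 <- list(vertices = which(atlas$roi_of_vertex == 1L), network = 1L)
  ip <- match_patches(list(p_roi1), atlas, mesh, geodesic = geo)
  expect_true(all(ip$roi_of_vertex[p_roi1$vertices] == 1L))
  expect_true(all(ip$provenance[p_roi1$vertices] == "rule1"))
  # rule 2: a patch straddling ROIs 1 and 2 plus a connecting strip
  strip <- c(gidx(3, 1), gidx(4, 1), gidx(5, 1))
  straddle <- sort(c(which(atlas$roi_of_vertex %in% 1:2), strip))
  ip2 <- match_patches(list(list(vertices = straddle, network = 1L)),
                       atlas, mesh, geodesic = geo)
  expect_true(all(ip2$provenance[straddle] == "rule2"))
  # each strip vertex joins the geodesically nearest center (oracle:
  # Floyd-Warshall distances; ties break toward the lower ROI id)
  fw <- oracle_floyd_warshall(mesh)
  for (v in strip) {
    d1 <- min(fw[v, which(atlas$roi_of_vertex == 1L)])
    d2 <- min(fw[v, which(atlas$roi_of_vertex == 2L)])
    expected <- if (d1 <= d2) 1L else 2L
    expect_identical(ip2$roi_of_vertex[v], expected)
  }
  # rule 3, assignable: a small patch one edge away from ROI 1
  near <- c(gidx(3, 0), gidx(3, 1))
  ip3 <- match_patches(list(list(vertices = near, network = 1L)),
                       atlas, mesh, geodesic = geo)
  expect_true(all(ip3$roi_of_vertex[near] == 1L))
  expect_true(all(ip3$provenance[near] == "rule3"))
  # rule 3, too far: distance to both network-1 ROIs exceeds their
  # internal mean pairwise distance (hand check), so unrecognized
  far <- c(gidx(8, 8), gidx(9, 8), gidx(8, 9), gidx(9, 9))
  roi1 <- which(atlas$roi_of_vertex == 1L)
  thr1 <- mean(fw[roi1, roi1][upper.tri(fw[roi1, roi1])])
  expect_gt(min(fw[far, roi1]), thr1)
  ip4 <- match_patches(list(list(vertices = far, network = 1L)),
                       atlas, mesh, geodesic = geo)
  expect_true(all(is.na(ip4$roi_of_vertex[far])))
  expect_true(all(ip4$provenance[far] == "unrecognized"))
  # rule coverage: every patch vertex got exactly one provenance tag
  expect_equal(sum(ip4$rule_counts), length(far))
})

test_that("ROI time series equal the naive per-frame mean", {
  mesh <- grid10(); atlas <- grid_atlas()
  set.seed(35)
  sig <- matrix(rnorm(100 * 30), 100, 30)
  out <- roi_timeseries(sig, atlas)
  # loop oracle
  for (r in 1:3) {
    vs <- which(atlas$roi_of_vertex == r)
    for (t in c(1, 15, 30))
      expect_equal(out$ts[r, t], mean(sig[vs, t]), tolerance = 1e-12)
  }
  # single-vertex ROI passes its series through
  parc1 <- list(roi_of_vertex = c(1L, rep(NA_integer_, 99)), n_rois = 2L)
  out1 <- roi_timeseries(sig, parc1)
  expect_equal(out1$ts[1, ], sig[1, ])
  expect_true(all(is.na(out1$ts[2, ])))
  expect_equal(out1$n_vertices, c(1L, 0L))
  # duplicating a vertex's signal across an ROI keeps the mean
  sig2 <- sig
  vs <- which(atlas$roi_of_vertex == 1)
  sig2[vs, ] <- rep(sig[vs[1], ], each = length(vs))
  out2 <- roi_timeseries(sig2, atlas)
  expect_equal(out2$ts[1, ], sig[vs[1], ])
  # censored frames are excluded
  fd <- rep(0.1, 30); fd[12] <- 0.9
  cm <- censor_mask(fd, rep(10, 30))
  out3 <- roi_timeseries(sig, atlas, mask = cm)
  expect_equal(ncol(out3$ts), sum(cm$keep))
})
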
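# Inter-individual variability of the functional topography and
# connectome: per-ROI variability in region size and position, vertex-wise
# connectivity-profile variability, and ROI-based connectivity variability,
# plus the cross-profile correlations relating them.

#' Per-ROI size variability across subjects
#'
#' Sample standard deviation (ddof = 1) of the matched vertex count of each
#' ROI across subjects; an ROI unmatched in a subject counts as size 0 for
#' that subject.
#'
#' @param parcellations list of per-subject parcellations (any objects with
#'   `roi_of_vertex`).
#' @param n_rois number of ROIs.
#' @return numeric vector of length `n_rois`.
#' @export
size_variability <- function(parcellations, n_rois) {
  if (length(parcellations) < 2L) stop_validation("need >= 2 subjects")
  sizes <- vapply(parcellations, function(p) {
    roi <- p$roi_of_vertex
    tabulate(roi[!is.na(roi)], n_rois)
  }, integer(n_rois))
  sizes <- matrix(sizes, nrow = n_rois)
  apply(sizes, 1, stats::sd)
}

#' Per-ROI position variability across subjects
#'
#' The position of an ROI is its geodesic medoid: the member vertex
#' minimizing the summed geodesic distance to all member vertices (a
#' discrete, on-mesh stand-in for the center of mass; ties break toward
#' the lower vertex index). Position variability is the mean geodesic
#' distance between the ROI's centers over all unordered subject pairs;
#' subjects lacking the ROI are omitted from its pairs.
#'
#' @inheritParams size_variability
#' @param mesh the `surface_mesh`.
#' @param geodesic optional precomputed full geodesic distance matrix.
#' @return numeric vector of length `n_rois` (`NA` when fewer than two
#'   subjects carry the ROI).
#' @export
position_variability <- function(parcellations, mesh, n_rois,
                                 geodesic = NULL) {
  if (length(parcellations) < 2L) stop_validation("need >= 2 subjects")
  if (is.null(geodesic)) geodesic <- geodesic_distances(mesh)
  centers <- vapply(parcellations, function(p) {
    vapply(seq_len(n_rois), function(r) {
      vs <- which(p$roi_of_vertex == r)
      if (length(vs) == 0L) return(NA_integer_)
      vs[which.min(rowSums(geodesic[vs, vs, drop = FALSE]))]
    }, integer(1))
  }, integer(n_rois))
  centers <- matrix(centers, nrow = n_rois)
  vapply(seq_len(n_rois), function(r) {
    cs <- centers[r, ]
    cs <- cs[!is.na(cs)]
    if (length(cs) < 2L) return(NA_real_)
    d <- geodesic[cs, cs, drop = FALSE]
    mean(d[upper.tri(d)])
  }, numeric(1))
}

#' Vertex-wise connectivity-profile variability
#'
#' The profile of vertex `v` in a subject is the vector of correlations
#' from `v`'s time series to a fixed basis shared across subjects — the
#' subject's atlas-ROI mean time series. The variability at `v` is the
#' mean, over all unordered subject pairs, of `1 - r` between the two
#' subjects' profiles at `v`; the per-ROI value averages over the atlas
#' ROI's vertices.
#'
#' @param signal_list list of per-subject cleaned vertex x time matrices
#'   (kept frames only).
#' @param atlas the `cortical_atlas` providing the common profile basis.
#' @return a list with `per_vertex` and `per_roi` variability vectors.
#' @export
vertex_variability <- function(signal_list, atlas) {
  ns <- length(signal_list)
  if (ns < 2L) stop_validation("need >= 2 subjects")
  profiles <- lapply(signal_list, function(sig) {
    basis <- roi_timeseries(sig, atlas, n_rois = atlas$n_rois)$ts
    cor_cols(t(sig), t(basis))               # vertex x roi
  })
  nv <- nrow(profiles[[1]])
  acc <- numeric(nv)
  npair <- 0L
  for (a in seq_len(ns - 1L)) for (b in (a + 1L):ns) {
    pa <- profiles[[a]]; pb <- profiles[[b]]
    r <- row_cor(pa, pb)
    acc <- acc + (1 - r)
    npair <- npair + 1L
  }
  per_vertex <- acc / npair
  per_roi <- vapply(seq_len(atlas$n_rois), function(r)
    mean(per_vertex[atlas$roi_of_vertex == r], na.rm = TRUE), numeric(1))
  list(per_vertex = per_vertex, per_roi = per_roi)
}

# Row-wise Pearson correlation between two matrices of equal shape.
row_cor <- function(a, b) {
  a <- a - rowMeans(a, na.rm = TRUE)
  b <- b - rowMeans(b, na.rm = TRUE)
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a^2) * rowSums(b^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Per-ROI connectivity variability across subjects
#'
#' Per connection, the sample SD across subjects; per ROI, the mean of the
#' SDs over its incident connections (115 of them for 116 ROIs). Masked
#' connections are excluded pairwise.
#'
#' @param matrices list of per-subject ROI x ROI connectivity matrices
#'   (all of the same basis, individual or atlas).
#' @return numeric per-ROI vector.
#' @export
roi_connectivity_variability <- function(matrices) {
  ns <- length(matrices)
  if (ns < 2L) stop_validation("need >= 2 subjects")
  n <- nrow(matrices[[1]])
  idx <- feature_index(n)
  feats <- vapply(matrices, function(m) unclass(as.matrix(m))[idx],
                  numeric(nrow(idx)))
  conn_sd <- apply(feats, 1, stats::sd, na.rm = TRUE)
  vapply(seq_len(n), function(r) {
    inc <- idx[, 1] == r | idx[, 2] == r
    mean(conn_sd[inc], na.rm = TRUE)
  }, numeric(1))
}

#' Correlate two per-ROI variability profiles
#'
#' Pearson correlation and two-sided p-value across ROIs (e.g. size
#' variability against connectivity variability, N = 116 ROIs).
#'
#' @param a,b numeric per-ROI vectors of equal length >= 3.
#' @return list with `r` and `p` (`NA` for constant input).
#' @export
correlate_profiles <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L)
    stop_validation("profiles must have equal length >= 3")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
    return(list(r = NA_real_, p = NA_real_))
  ht <- stats::cor.test(a[ok], b[ok])
  list(r = unname(ht$estimate), p = ht$p.value)
}

#' Full variability profile of a cohort
#'
#' Convenience wrapper assembling size, position, vertex-wise, and ROI
#' connectivity variability into one table.
#'
#' @param parcellations list of per-subject individual parcellations.
#' @param indiv_matrices,atlas_matrices lists of per-subject connectivity
#'   matrices on the individual and atlas bases.
#' @param signal_list per-subject cleaned signals (for the vertex-wise
#'   component); `NULL` skips it.
#' @param mesh,atlas the mesh and atlas.
#' @param geodesic optional precomputed geodesic distance matrix.
#' @return a data frame with one row per ROI: `roi`, `size_var`,
#'   `position_var`, `indiv_conn_var`, `atlas_conn_var`, and (if computed)
#'   `vertex_conn_var`.
#' @export
variability_profile <- function(parcellations, indiv_matrices,
                                atlas_matrices, mesh, atlas,
                                signal_list = NULL, geodesic = NULL) {
  n_rois <- atlas$n_rois
  out <- data.frame(
    roi = seq_len(n_rois),
    size_var = size_variability(parcellations, n_rois),
    position_var = position_variability(parcellations, mesh, n_rois,
                                        geodesic),
    indiv_conn_var = roi_connectivity_variability(indiv_matrices),
    atlas_conn_var = roi_connectivity_variability(atlas_matrices))
  if (!is.null(signal_list))
    out$vertex_conn_var <- vertex_variability(signal_list, atlas)$per_roi
  out
}
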
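# Population-level atlas: per-vertex network and ROI labels on a mesh.
# ROIs are connected patches grown by geodesic distance from well-spread
# seed vertices; each ROI belongs to exactly one network, and fine networks
# map onto 7 canonical networks.

#' Build a population-level atlas on a mesh
#'
#' ROI seed vertices are chosen by deterministic farthest-point sampling
#' (initialized from `seed`), and ROIs are the geodesic Voronoi cells of
#' those seeds, repaired so that every cell is a connected patch with at
#' least `min_roi_size` vertices. ROI `i` is assigned to fine network
#' `((i - 1) mod n_networks) + 1`, which distributes each network over the
#' mesh the way large-scale functional networks are distributed over the
#' cortex, and fine network `k` maps to canonical network
#' `((k - 1) mod 7) + 1`.
#'
#' @param mesh a `surface_mesh`.
#' @param n_networks number of fine networks (default 18).
#' @param n_rois number of ROIs (default 116); must satisfy
#'   `n_networks <= n_rois <= n_vertices / 4`.
#' @param seed integer RNG seed; the same seed always yields the same atlas.
#' @param n_canonical number of canonical networks (default 7).
#' @param min_roi_size smallest admissible ROI (default 4 vertices).
#' @return an object of class `cortical_atlas`: `network_of_vertex`,
#'   `roi_of_vertex`, `roi_network` (ROI -> network), `canonical_map`
#'   (network -> canonical network), plus the size parameters.
#' @examples
#' mesh <- make_mesh(162, "icosphere")
#' atlas <- make_atlas(mesh, n_networks = 6, n_rois = 24, seed = 1)
#' table(atlas$roi_network)
#' @export
make_atlas <- function(mesh, n_networks = 18L, n_rois = 116L, seed = 1L,
                       n_canonical = 7L, min_roi_size = 4L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  n_networks <- as.integer(n_networks); n_rois <- as.integer(n_rois)
  if (n_rois < n_networks)
    stop_config("n_rois must be >= n_networks")
  if (n_rois * min_roi_size > mesh$n_vertices)
    stop_config("infeasible sizes: each of the ", n_rois,
                " ROIs needs >= ", min_roi_size, " of ", mesh$n_vertices,
                " vertices")
  nv <- mesh$n_vertices
  if (n_rois == 1L) {
    roi <- rep(1L, nv)
  } else {
    seeds <- withr::with_seed(seed, farthest_point_seeds(mesh, n_rois))
    d <- geodesic_distances(mesh, from = seeds)
    roi <- apply(d, 2, which.min)          # ties -> lowest seed index
    roi <- repair_label_connectivity(roi, mesh)
    roi <- enforce_min_size(roi, mesh, min_roi_size)
  }
  roi_network <- ((seq_len(n_rois) - 1L) %% n_networks) + 1L
  canonical_map <- ((seq_len(n_networks) - 1L) %% n_canonical) + 1L
  structure(list(network_of_vertex = roi_network[roi],
                 roi_of_vertex = as.integer(roi),
                 roi_network = roi_network,
                 canonical_map = canonical_map,
                 n_networks = n_networks, n_rois = n_rois,
                 n_canonical = as.integer(n_canonical)),
            class = "cortical_atlas")
}

#' @export
print.cortical_atlas <- function(x, ...) {
  cat(sprintf("cortical_atlas: %d vertices, %d ROIs in %d networks (%d canonical)\n",
              length(x$roi_of_vertex), x$n_rois, x$n_networks, x$n_canonical))
  invisible(x)
}

# Farthest-point sampling of k seed vertices; the first seed is random
# (current RNG), subsequent seeds maximize geodesic distance to the set.
farthest_point_seeds <- function(mesh, k) {
  nv <- mesh$n_vertices
  seeds <- integer(k)
  seeds[1] <- sample.int(nv, 1L)
  mind <- as.numeric(geodesic_distances(mesh, from = seeds[1]))
  if (k > 1) for (i in 2:k) {
    seeds[i] <- which.max(mind)
    mind <- pmin(mind, as.numeric(geodesic_distances(mesh, from = seeds[i])))
  }
  seeds
}

# Split any disconnected label cell: keep its largest component, push the
# rest to an adjacent label (mode of neighboring labels). Iterates to a
# fixed point; geodesic Voronoi cells on a graph are connected except for
# rare tie configurations, so this converges almost immediately.
repair_label_connectivity <- function(labels, mesh) {
  adj <- mesh_adjacency(mesh)
  for (pass in 1:20) {
    changed <- FALSE
    for (lab in sort(unique(labels))) {
      members <- which(labels == lab)
      comps <- vertex_components(members, adj)
      if (length(comps) <= 1L) next
      sizes <- lengths(comps)
      for (ci in seq_along(comps)[-which.max(sizes)]) {
        frag <- comps[[ci]]
        nb_labels <- setdiff(unique(labels[unlist(adj[frag])]), lab)
        if (length(nb_labels) == 0L) next
        counts <- table(factor(labels[unlist(adj[frag])],
                               levels = nb_labels))
        labels[frag] <- as.integer(names(counts)[which.max(counts)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  labels
}

# Grow any label below min_size by annexing the nearest adjacent vertex
# whose donor label stays connected and above min_size.
enforce_min_size <- function(labels, mesh, min_size) {
  adj <- mesh_adjacency(mesh)
  for (pass in 1:200) {
    sizes <- tabulate(labels, max(labels))
    small <- which(sizes < min_size)
    if (length(small) == 0L) break
    lab <- small[1]
    members <- which(labels == lab)
    ring <- setdiff(unique(unlist(adj[members])), members)
    ring <- ring[order(labels[ring], ring)]
    moved <- FALSE
    for (v in ring) {
      donor <- labels[v]
      if (sizes[donor] <= min_size) next
      rest <- setdiff(which(labels == donor), v)
      if (length(vertex_components(rest, adj)) == 1L) {
        labels[v] <- lab
        moved <- TRUE
        break
      }
    }
    if (!moved) break
  }
  labels
}

# Connected components of a vertex subset under the mesh adjacency,
# returned as a list of integer vectors (flood fill).
vertex_components <- function(members, adj) {
  if (length(members) == 0L) return(list())
  in_set <- logical(length(adj))
  in_set[members] <- TRUE
  seen <- logical(length(adj))
  comps <- list()
  for (start in members) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    comp <- integer(0)
    while (length(queue) > 0L) {
      v <- queue[[1]]
      queue <- queue[-1]
      comp <- c(comp, v)
      nb <- adj[[v]]
      nb <- nb[in_set[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# Vertices of one ROI.
roi_vertices <- function(atlas_or_parc, roi) {
  which(atlas_or_parc$roi_of_vertex == roi)
}

#' Write / read per-vertex labels as two-column TSV
#'
#' @param labels integer vector of per-vertex labels (NA allowed).
#' @param path file path; columns `vertex_id` (1-based) and `label`.
#' @return `write_labels_tsv` returns `path` invisibly; `read_labels_tsv`
#'   returns an integer vector ordered by vertex id.
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(data.frame(vertex_id = seq_along(labels), label = labels),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels_tsv
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.delim(path)
  out <- df$label[order(df$vertex_id)]
  as.integer(out)
}
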
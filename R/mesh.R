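# Triangulated surface meshes: the substrate for geodesic distances,
# connected components and region growing. Meshes stand in for a single
# cortical hemisphere surface; the default test mesh is a 642-vertex
# icosphere and the default full-scale mesh has 2562 vertices.

#' Build a triangulated surface mesh
#'
#' Constructs a connected triangulated mesh with approximately `n_vertices`
#' vertices. Two topologies are supported: `"icosphere"` (a subdivided
#' icosahedron projected onto the unit sphere, vertex counts 12, 42, 162,
#' 642, 2562, ...) and `"grid"` (an m-by-m planar grid with the standard
#' diagonal split, so every interior vertex has degree 6).
#'
#' @param n_vertices requested vertex count (>= 12 for icosphere, >= 4 for
#'   grid); the smallest mesh with at least this many vertices is returned
#'   for icospheres, and `round(sqrt(n_vertices))^2` for grids.
#' @param topology `"icosphere"` or `"grid"`.
#' @return an object of class `surface_mesh`: a list with `vertices`
#'   (n x 3 coordinates), `triangles` (m x 3 vertex indices), `edges`
#'   (e x 2, each row sorted), `edge_lengths`, `n_vertices`, and `graph`
#'   (an \pkg{igraph} graph weighted by Euclidean edge length).
#' @examples
#' mesh <- make_mesh(42, "icosphere")
#' mesh$n_vertices
#' @export
make_mesh <- function(n_vertices, topology = c("icosphere", "grid")) {
  if (!is.character(topology))
    stop_config("topology must be a character name")
  topology <- tryCatch(match.arg(topology),
                       error = function(e)
                         stop_config("unsupported topology: ", topology[1]))
  if (topology == "icosphere") {
    if (n_vertices < 12) stop_config("icosphere needs n_vertices >= 12")
    mesh <- icosahedron()
    while (nrow(mesh$vertices) < n_vertices) mesh <- subdivide_sphere(mesh)
    finish_mesh(mesh$vertices, mesh$triangles)
  } else {
    if (n_vertices < 4) stop_config("grid needs n_vertices >= 4")
    m <- max(2L, as.integer(round(sqrt(n_vertices))))
    idx <- function(i, j) (j - 1L) * m + i
    verts <- cbind(rep(seq_len(m), m) - 1, rep(seq_len(m), each = m) - 1, 0)
    tri <- matrix(0L, 0L, 3L)
    for (j in seq_len(m - 1L)) {
      for (i in seq_len(m - 1L)) {
        v00 <- idx(i, j); v10 <- idx(i + 1L, j)
        v01 <- idx(i, j + 1L); v11 <- idx(i + 1L, j + 1L)
        tri <- rbind(tri, c(v00, v10, v11), c(v00, v11, v01))
      }
    }
    finish_mesh(verts, tri)
  }
}

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  tri <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, triangles = tri)
}

subdivide_sphere <- function(mesh) {
  v <- mesh$vertices
  tri <- mesh$triangles
  midpoint_cache <- new.env(hash = TRUE)
  get_mid <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    hit <- midpoint_cache[[key]]
    if (!is.null(hit)) return(hit)
    mid <- (v[a, ] + v[b, ]) / 2
    mid <- mid / sqrt(sum(mid^2))
    v <<- rbind(v, mid)
    id <- nrow(v)
    midpoint_cache[[key]] <- id
    id
  }
  out <- matrix(0L, 0L, 3L)
  for (t in seq_len(nrow(tri))) {
    a <- tri[t, 1]; b <- tri[t, 2]; c <- tri[t, 3]
    ab <- get_mid(a, b); bc <- get_mid(b, c); ca <- get_mid(c, a)
    out <- rbind(out, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
  }
  list(vertices = v, triangles = out)
}

finish_mesh <- function(vertices, triangles) {
  vertices <- unname(as.matrix(vertices))
  triangles <- unname(as.matrix(triangles))
  storage.mode(triangles) <- "integer"
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  len <- sqrt(rowSums((vertices[e[, 1], , drop = FALSE] -
                         vertices[e[, 2], , drop = FALSE])^2))
  if (any(len <= 0)) stop_validation("mesh contains a zero-length edge")
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- len
  if (!igraph::is_connected(g)) stop_validation("mesh graph is not connected")
  structure(list(vertices = vertices, triangles = triangles, edges = e,
                 edge_lengths = len, n_vertices = nrow(vertices), graph = g),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles, %d edges (mean edge %.3f)\n",
              x$n_vertices, nrow(x$triangles), nrow(x$edges),
              mean(x$edge_lengths)))
  invisible(x)
}

#' Geodesic distances on a mesh
#'
#' Shortest-path distances over mesh edges with Euclidean edge weights
#' (the standard discrete geodesic).
#'
#' @param mesh a `surface_mesh`.
#' @param from,to optional vertex index vectors (default: all vertices).
#' @return a `length(from)` x `length(to)` distance matrix.
#' @export
geodesic_distances <- function(mesh, from = NULL, to = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  from <- from %||% seq_len(mesh$n_vertices)
  to <- to %||% seq_len(mesh$n_vertices)
  igraph::distances(mesh$graph, v = from, to = to,
                    algorithm = "dijkstra")
}

# Adjacency list of the mesh graph (list of integer neighbor vectors).
mesh_adjacency <- function(mesh) {
  adj <- igraph::as_adj_list(mesh$graph, mode = "all")
  lapply(adj, as.integer)
}

# Vertex degrees of the mesh graph.
mesh_degrees <- function(mesh) igraph::degree(mesh$graph)

#' Write / read a mesh in OFF format
#'
#' Plain-text OFF polygon files, readable by standard mesh viewers.
#'
#' @param mesh a `surface_mesh`.
#' @param path output file path.
#' @return `write_mesh_off` returns `path` invisibly; `read_mesh_off`
#'   returns a `surface_mesh`.
#' @export
write_mesh_off <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", mesh$n_vertices, nrow(mesh$triangles)), con)
  utils::write.table(format(mesh$vertices, digits = 12, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mesh_off
#' @export
read_mesh_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (toupper(trimws(lines[1])) != "OFF") stop_validation("not an OFF file")
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vert <- do.call(rbind, lapply(lines[3:(2 + nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  tri <- do.call(rbind, lapply(lines[(3 + nv):(2 + nv + nf)], function(l) {
    f <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    f[2:4] + 1L
  }))
  finish_mesh(vert, tri)
}
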
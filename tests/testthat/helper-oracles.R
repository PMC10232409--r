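# Independent oracles and shared fixtures. The oracles deliberately use
# naive, literal implementations (frame-by-frame loops, Floyd-Warshall,
# flood fill) so they share no code path with the package internals they
# check.

# --- brute-force censoring oracle -----------------------------------------
# Literal rule application: flag, dilate frame by frame, then censor every
# kept run shorter than min_run by scanning runs explicitly.
oracle_censor <- function(fd, dvars, fd_thresh = 0.2, dvars_thresh = 50,
                          pre = 1, post = 2, min_run = 5,
                          exclusion_fraction = 0.5) {
  n <- length(fd)
  bad <- logical(n)
  for (i in seq_len(n)) {
    if (fd[i] > fd_thresh || dvars[i] > dvars_thresh) {
      for (j in seq(i - pre, i + post)) {
        if (j >= 1 && j <= n) bad[j] <- TRUE
      }
    }
  }
  i <- 1
  while (i <= n) {
    if (!bad[i]) {
      j <- i
      while (j <= n && !bad[j]) j <- j + 1
      if ((j - i) < min_run) bad[i:(j - 1)] <- TRUE
      i <- j
    } else i <- i + 1
  }
  list(keep = !bad, excluded = mean(bad) > exclusion_fraction)
}

# --- Floyd-Warshall geodesic oracle ---------------------------------------
oracle_floyd_warshall <- function(mesh) {
  n <- mesh$n_vertices
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (e in seq_len(nrow(mesh$edges))) {
    i <- mesh$edges[e, 1]; j <- mesh$edges[e, 2]
    d[i, j] <- d[j, i] <- mesh$edge_lengths[e]
  }
  for (k in seq_len(n)) {
    dk <- d[, k]
    cand <- outer(dk, d[k, ], "+")
    d <- pmin(d, cand)
  }
  d
}

# --- flood-fill component counter -----------------------------------------
oracle_component_count <- function(members, mesh) {
  if (length(members) == 0) return(0L)
  adj_from_edges <- function() {
    a <- vector("list", mesh$n_vertices)
    for (e in seq_len(nrow(mesh$edges))) {
      i <- mesh$edges[e, 1]; j <- mesh$edges[e, 2]
      a[[i]] <- c(a[[i]], j); a[[j]] <- c(a[[j]], i)
    }
    a
  }
  adj <- adj_from_edges()
  seen <- logical(mesh$n_vertices)
  count <- 0L
  for (s in members) {
    if (seen[s]) next
    count <- count + 1L
    stack <- s
    seen[s] <- TRUE
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      for (w in adj[[v]]) {
        if (w %in% members && !seen[w]) {
          seen[w] <- TRUE
          stack <- c(stack, w)
        }
      }
    }
  }
  count
}

# --- per-frame Pearson connectivity oracle --------------------------------
oracle_connectivity <- function(ts) {
  n <- nrow(ts)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    xi <- ts[i, ] - mean(ts[i, ]); xj <- ts[j, ] - mean(ts[j, ])
    out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  out
}

# --- shared fixtures (built once per test run) ----------------------------
.fixture_env <- new.env()

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

test_mesh_162 <- function() fixture("mesh162", function()
  make_mesh(162, "icosphere"))
test_mesh_642 <- function() fixture("mesh642", function()
  make_mesh(642, "icosphere"))
test_atlas_162 <- function() fixture("atlas162", function()
  make_atlas(test_mesh_162(), n_networks = 6, n_rois = 24, seed = 2))
test_atlas_642 <- function() fixture("atlas642", function()
  make_atlas(test_mesh_642(), n_networks = 18, n_rois = 116, seed = 99))
test_geo_162 <- function() fixture("geo162", function()
  geodesic_distances(test_mesh_162()))
test_geo_642 <- function() fixture("geo642", function()
  geodesic_distances(test_mesh_642()))

default_network_cov <- function(k, within = 0.6, between = 0.2) {
  m <- matrix(between, k, k)
  diag(m) <- within
  m
}

# Per-ROI Dice between two label maps.
dice_per_roi <- function(labels_a, labels_b, n_rois) {
  vapply(seq_len(n_rois), function(r)
    dice_overlap(which(labels_a == r), which(labels_b == r)), numeric(1))
}
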
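# ROI-to-ROI connectivity matrices (Pearson correlation over kept frames),
# their vectorization into connection features, and within-/between-network
# aggregation. No Fisher z-transform is applied by default: connectivity is
# reported on the correlation scale, with an optional z-transform flag for
# sensitivity analyses.

#' ROI-to-ROI connectivity matrix
#'
#' Pairwise Pearson correlation between ROI time series over kept frames.
#' The matrix is symmetric with unit diagonal; ROIs whose series are
#' missing or have zero variance are fully masked with `NA` (zero-variance
#' with a warning).
#'
#' @param roi_ts ROI x time matrix (e.g. `roi_timeseries()$ts`), already
#'   restricted to kept frames.
#' @param fisher_z apply the Fisher z-transform to off-diagonal entries
#'   (default `FALSE`).
#' @param basis `"individual"` or `"atlas"`, recorded as an attribute.
#' @return an ROI x ROI `connectivity_matrix` with attributes `basis` and
#'   `missing` (logical per-ROI mask).
#' @export
connectivity_matrix <- function(roi_ts, fisher_z = FALSE,
                                basis = c("individual", "atlas")) {
  basis <- match.arg(basis)
  roi_ts <- as.matrix(roi_ts)
  if (ncol(roi_ts) < 3L) stop_validation("need >= 3 kept frames")
  missing_roi <- apply(roi_ts, 1, function(x) any(is.na(x)))
  sds <- apply(roi_ts, 1, stats::sd)
  zero_var <- !missing_roi & (is.na(sds) | sds == 0)
  if (any(zero_var))
    warning("masking ", sum(zero_var), " zero-variance ROI series")
  bad <- missing_roi | zero_var
  if (sum(!bad) < 2L) stop_validation("need >= 2 usable ROI series")
  r <- suppressWarnings(stats::cor(t(roi_ts)))
  r[bad, ] <- NA_real_
  r[, bad] <- NA_real_
  diag(r)[!bad] <- 1
  if (fisher_z) {
    off <- row(r) != col(r)
    r[off] <- atanh(pmin(pmax(r[off], -1 + 1e-12), 1 - 1e-12))
  }
  structure(r, basis = basis, missing = bad, class = c("connectivity_matrix",
                                                       class(r)))
}

#' Vectorize a symmetric connectivity matrix into connection features
#'
#' Strict upper-triangle entries in row-major order, i.e. pairs
#' (1,2), (1,3), ..., (1,n), (2,3), ...; a 116-ROI matrix yields 6670
#' features.
#'
#' @param matrix symmetric ROI x ROI matrix.
#' @param tol asymmetry tolerance (default 1e-10).
#' @return a numeric feature vector with attribute `index`, a 2-column
#'   `(roi_i, roi_j)` table aligning features to ROI pairs.
#' @export
feature_vector <- function(matrix, tol = 1e-10) {
  m <- unclass(as.matrix(matrix))
  if (nrow(m) != ncol(m) ||
      max(abs(m - t(m)), na.rm = TRUE) > tol)
    stop_validation("connectivity matrix must be symmetric")
  idx <- feature_index(nrow(m))
  structure(m[idx], index = idx)
}

#' Feature index table for n ROIs
#'
#' @param n number of ROIs.
#' @return `choose(n, 2)` x 2 integer matrix of (roi_i, roi_j) pairs in
#'   row-major upper-triangle order.
#' @export
feature_index <- function(n) {
  idx <- t(utils::combn(n, 2L))
  colnames(idx) <- c("roi_i", "roi_j")
  idx
}

#' Rebuild a symmetric matrix from a feature vector
#'
#' Inverse of [feature_vector()] (diagonal set to 1).
#'
#' @param features numeric feature vector of length `choose(n, 2)`.
#' @param n number of ROIs.
#' @return an n x n symmetric matrix.
#' @export
feature_to_matrix <- function(features, n) {
  idx <- feature_index(n)
  m <- diag(1, n)
  m[idx] <- features
  m[idx[, c(2, 1)]] <- features
  m
}

#' Within- and between-network connectivity summary
#'
#' For each network `k`: the within value is the mean connectivity over
#' ROI pairs with both ROIs in `k`, and the between value is the mean over
#' pairs with exactly one ROI in `k`. Masked pairs are excluded. A network
#' with a single ROI has no within pairs and reports `NA`.
#'
#' @param matrix an ROI x ROI connectivity matrix.
#' @param roi_network ROI -> network id map (fine or canonical).
#' @return a `network_connectivity` list: `within`, `between` (per-network
#'   vectors), `global_within`, `global_between`, `global_mean`.
#' @export
network_connectivity <- function(matrix, roi_network) {
  m <- unclass(as.matrix(matrix))
  n <- nrow(m)
  if (length(roi_network) != n)
    stop_validation("every ROI must be mapped to a network")
  idx <- feature_index(n)
  vals <- m[idx]
  net_i <- roi_network[idx[, 1]]
  net_j <- roi_network[idx[, 2]]
  same <- net_i == net_j
  nets <- sort(unique(roi_network))
  within <- vapply(nets, function(k) {
    sel <- same & net_i == k & !is.na(vals)
    if (!any(sel)) NA_real_ else mean(vals[sel])
  }, numeric(1))
  between <- vapply(nets, function(k) {
    sel <- !same & (net_i == k | net_j == k) & !is.na(vals)
    if (!any(sel)) NA_real_ else mean(vals[sel])
  }, numeric(1))
  names(within) <- names(between) <- nets
  list(within = within, between = between,
       global_within = mean(vals[same], na.rm = TRUE),
       global_between = mean(vals[!same], na.rm = TRUE),
       global_mean = mean(vals, na.rm = TRUE))
}

#' Individual-vs-atlas between-network connectivity shift
#'
#' Per network: the percent change of mean between-network connectivity
#' when ROIs are individual-specific relative to atlas-based,
#' `100 * (mean_ind - mean_atlas) / mean_atlas` (signed baseline, so a
#' uniform scaling of connectivity strength by 0.9 reads -10% whatever the
#' sign of the baseline), with a paired t-test
#' across subjects and Bonferroni adjustment over networks.
#'
#' @param individual_summaries,atlas_summaries lists (one element per
#'   subject, same order) of [network_connectivity()] results.
#' @return a data frame with one row per network: `network`, `pct_change`,
#'   `t`, `p`, `p_bonferroni`, plus the overall mean percent change as
#'   attribute `mean_pct_change`.
#' @export
between_network_shift <- function(individual_summaries, atlas_summaries) {
  ns <- length(individual_summaries)
  if (ns != length(atlas_summaries))
    stop_validation("summary lists must cover the same subjects")
  if (ns < 3L) stop_validation("need >= 3 subjects for a paired test")
  ind <- do.call(rbind, lapply(individual_summaries, `[[`, "between"))
  atl <- do.call(rbind, lapply(atlas_summaries, `[[`, "between"))
  k <- ncol(ind)
  res <- lapply(seq_len(k), function(j) {
    ok <- stats::complete.cases(ind[, j], atl[, j])
    d <- ind[ok, j] - atl[ok, j]
    pct <- 100 * (mean(ind[ok, j]) - mean(atl[ok, j])) / mean(atl[ok, j])
    if (length(d) < 3L || stats::sd(d) == 0) {
      tt <- 0; p <- 1
    } else {
      ht <- stats::t.test(ind[ok, j], atl[ok, j], paired = TRUE)
      tt <- unname(ht$statistic); p <- ht$p.value
    }
    data.frame(network = colnames(ind)[j] %||% j, pct_change = pct,
               t = tt, p = p)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(out$p * k, 1)
  attr(out, "mean_pct_change") <- mean(out$pct_change)
  out
}

#' Write / read a matrix as TSV with row and column names
#'
#' @param m a matrix.
#' @param path file path.
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   returns a numeric matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  m <- as.matrix(m)
  df <- data.frame(id = rownames(m) %||% seq_len(nrow(m)),
                   signif(unclass(m), 12), check.names = FALSE)
  colnames(df) <- c("id", colnames(m) %||% seq_len(ncol(m)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
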
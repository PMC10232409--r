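# Internal helpers shared across modules.

#' Derive a child RNG seed from a parent seed and an index
#'
#' Uses a Lehmer-style mixing so that changing the cohort size does not
#' reshuffle the seeds of already-existing subjects, and all derived seeds
#' stay below 2^31.
#'
#' @param seed parent integer seed.
#' @param index non-negative integer stream index.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(index), length(index) == 1L)
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(index) * 16807 + 1) %%
               2147483647)
}

#' Dice overlap between two vertex sets
#'
#' `2 |A n B| / (|A| + |B|)`; the standard overlap score used to compare a
#' matched individual region with its ground-truth counterpart.
#'
#' @param a,b integer vectors of vertex indices.
#' @return Dice coefficient in `[0, 1]`; `NaN` when both sets are empty.
#' @export
dice_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) + length(b) == 0L) return(NaN)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("connectotype_config_error",
                                             "error", "condition")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("connectotype_validation_error",
                                             "error", "condition")))
}

# Pearson correlation between the columns of x and the columns of y,
# returned as an ncol(x) x ncol(y) matrix. Zero-variance columns give NA
# without warnings.
cor_cols <- function(x, y) {
  x <- scale(x); y <- scale(y)
  x[!is.finite(x)] <- NA_real_
  y[!is.finite(y)] <- NA_real_
  suppressWarnings(crossprod(x, y) / (nrow(x) - 1))
}

# Two-sided p-value for a Pearson correlation with m observations.
cor_pvalue <- function(r, m) {
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((m - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tt), df = m - 2)
}
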
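# Frame censoring, nuisance regression, spectral interpolation of censored
# frames, and band-pass filtering of vertex-by-time signals. The pipeline
# order is fixed (regress -> interpolate -> band-pass) and censored frames
# remain excluded from all downstream correlation computations; the
# interpolation only exists to make the band-pass well-posed.

#' Motion-based frame censoring mask
#'
#' Frames with `fd > fd_thresh` or `dvars > dvars_thresh` are marked as raw
#' outliers; each outlier is dilated by `pre` frames before and `post`
#' frames after (clipped at the series ends); any maximal surviving run of
#' kept frames shorter than `min_run` is censored as well. A run/subject
#' whose censored-frame fraction exceeds `exclusion_fraction` is flagged
#' for exclusion.
#'
#' @param fd per-frame framewise displacement (mm).
#' @param dvars per-frame DVARS, same length as `fd`.
#' @param fd_thresh FD threshold (default 0.2 mm).
#' @param dvars_thresh DVARS threshold (default 50).
#' @param pre,post dilation widths in frames (defaults 1 and 2).
#' @param min_run shortest kept run retained (default 5).
#' @param exclusion_fraction censored fraction above which the subject is
#'   excluded (default 0.5).
#' @return an object of class `censor_mask`: logical `keep`, integer
#'   `n_censored`, logical `subject_excluded`, and the parameters used.
#' @export
censor_mask <- function(fd, dvars, fd_thresh = 0.2, dvars_thresh = 50,
                        pre = 1L, post = 2L, min_run = 5L,
                        exclusion_fraction = 0.5) {
  if (length(fd) != length(dvars))
    stop_validation("fd and dvars must have the same length")
  n <- length(fd)
  if (n < 1L) stop_validation("empty fd/dvars traces")
  censored <- logical(n)
  raw <- which(fd > fd_thresh | dvars > dvars_thresh)
  for (i in raw) {
    lo <- max(1L, i - pre)
    hi <- min(n, i + post)
    censored[lo:hi] <- TRUE
  }
  # censor kept runs shorter than min_run
  r <- rle(censored)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (!r$values[j] && r$lengths[j] < min_run)
      censored[starts[j]:ends[j]] <- TRUE
  }
  structure(list(keep = !censored, n_censored = sum(censored),
                 subject_excluded = mean(censored) > exclusion_fraction,
                 params = list(fd_thresh = fd_thresh,
                               dvars_thresh = dvars_thresh, pre = pre,
                               post = post, min_run = min_run,
                               exclusion_fraction = exclusion_fraction)),
            class = "censor_mask")
}

#' @export
print.censor_mask <- function(x, ...) {
  cat(sprintf("censor_mask: %d/%d frames censored%s\n", x$n_censored,
              length(x$keep),
              if (x$subject_excluded) " (subject excluded)" else ""))
  invisible(x)
}

#' Nuisance regression design matrix
#'
#' Columns: intercept, linear trend, six motion parameters, mean
#' white-matter proxy, mean ventricle proxy, and the temporal derivatives
#' (backward differences, first row zero) of those eight signals — 18
#' columns in total.
#'
#' @param motion_params frames x 6 motion parameter matrix.
#' @param wm,vent per-frame mean white-matter / ventricle proxy signals.
#' @return a frames x 18 numeric design matrix.
#' @export
nuisance_design <- function(motion_params, wm, vent) {
  motion_params <- as.matrix(motion_params)
  n <- nrow(motion_params)
  if (ncol(motion_params) != 6L)
    stop_validation("motion_params must have six columns")
  if (length(wm) != n || length(vent) != n)
    stop_validation("wm/vent length must match the frame count")
  base <- cbind(motion_params, wm, vent)
  deriv <- rbind(0, diff(base))
  x <- cbind(intercept = 1, trend = seq_len(n) - (n + 1) / 2, base, deriv)
  colnames(x) <- c("intercept", "trend", paste0("motion", 1:6), "wm", "vent",
                   paste0("d_", c(paste0("motion", 1:6), "wm", "vent")))
  x
}

#' Regress nuisance signals out of vertex time series
#'
#' Ordinary least squares is fitted on kept frames only; the fitted values
#' are subtracted at all frames, so residuals on kept frames are orthogonal
#' to every design column. Collinear design columns are dropped with a
#' warning.
#'
#' @param signals vertex x time matrix.
#' @param design frames x p design matrix (see [nuisance_design()]).
#' @param mask optional [censor_mask()]; `NULL` keeps all frames.
#' @return residual vertex x time matrix.
#' @export
nuisance_regress <- function(signals, design, mask = NULL) {
  signals <- as.matrix(signals)
  design <- as.matrix(design)
  n <- ncol(signals)
  if (nrow(design) != n)
    stop_validation("design rows must equal the frame count")
  keep <- if (is.null(mask)) rep(TRUE, n) else mask$keep
  qrd <- qr(design[keep, , drop = FALSE])
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    warning("dropping collinear nuisance columns: ",
            paste(dropped, collapse = ", "))
    design <- design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
    qrd <- qr(design[keep, , drop = FALSE])
  }
  coefs <- qr.coef(qrd, t(signals[, keep, drop = FALSE]))
  coefs[is.na(coefs)] <- 0
  signals - t(design %*% coefs)
}

#' Interpolate censored frames by least-squares spectral fit
#'
#' Kept-frame values are unchanged. Each vertex's kept residuals are
#' fitted with an intercept plus sine/cosine pairs on a linear frequency grid
#' `m / (T * frame_interval_s)`; the grid runs toward the Nyquist frequency
#' but is truncated so the kept-frame system stays well-conditioned and
#' overdetermined (`2 * n_freq <= 2/3 * n_kept`), which makes the
#' reconstruction of any grid sinusoid essentially exact and comfortably
#' covers the 0.009-0.08 Hz band retained downstream. Censored frames are synthesized from the fit plus the
#' kept-frame mean.
#'
#' @param residuals vertex x time matrix (typically nuisance residuals).
#' @param mask a [censor_mask()].
#' @param frame_interval_s frame interval in seconds (default 3).
#' @param min_kept fewest kept frames accepted (default 5); below this the
#'   subject is refused with a `connectotype_excluded` error.
#' @param svd_tol relative singular-value truncation of the kept-frame
#'   spectral design (default 0.1): near-collinear directions that would
#'   diverge inside long censoring gaps are dropped instead of inverted.
#' @return gap-filled vertex x time matrix.
#' @export
interpolate_censored <- function(residuals, mask, frame_interval_s = 3,
                                 min_kept = 5L, svd_tol = 0.1) {
  residuals <- as.matrix(residuals)
  n <- ncol(residuals)
  keep <- mask$keep
  if (length(keep) != n) stop_validation("mask length must match frames")
  n_kept <- sum(keep)
  if (n_kept < max(2L, min_kept))
    stop(errorCondition("too few kept frames to interpolate; subject excluded",
                        class = c("connectotype_excluded", "error",
                                  "condition")))
  if (all(keep)) return(residuals)
  t_all <- (seq_len(n) - 1) * frame_interval_s
  n_freq <- min(n %/% 2L, n_kept %/% 3L)
  freqs <- seq_len(n_freq) / (n * frame_interval_s)
  basis <- function(tt) {
    ang <- outer(tt, 2 * pi * freqs)
    cbind(1, cos(ang), sin(ang))   # intercept absorbs the kept-frame mean
  }
  y <- t(residuals[, keep, drop = FALSE])
  sv <- svd(basis(t_all[keep]))
  # truncated-SVD solve: singular directions below svd_tol of the largest
  # are near-collinear on the kept frames but diverge inside censoring
  # gaps, so they are dropped rather than inverted
  dinv <- ifelse(sv$d >= svd_tol * max(sv$d), 1 / sv$d, 0)
  coefs <- sv$v %*% (dinv * crossprod(sv$u, y))
  recon <- t(basis(t_all[!keep]) %*% coefs)
  out <- residuals
  out[, !keep] <- recon
  out
}

#' Zero-phase band-pass filter
#'
#' FFT-domain filter retaining frequency bins in `[low, high]` Hz and
#' zeroing all others (including DC), applied independently per vertex.
#' Being a pure spectral mask, the filter is exactly zero-phase.
#'
#' @param signals vertex x time matrix.
#' @param low,high band edges in Hz (defaults 0.009 and 0.08).
#' @param frame_interval_s frame interval in seconds (default 3); `high`
#'   must stay below the Nyquist frequency `1 / (2 * frame_interval_s)`.
#' @return filtered vertex x time matrix.
#' @export
bandpass <- function(signals, low = 0.009, high = 0.08,
                     frame_interval_s = 3) {
  signals <- as.matrix(signals)
  n <- ncol(signals)
  nyquist <- 1 / (2 * frame_interval_s)
  if (low < 0 || high <= low || high >= nyquist)
    stop_validation("invalid band: need 0 <= low < high < Nyquist = ",
                    format(nyquist))
  freqs <- (seq_len(n) - 1) / (n * frame_interval_s)
  freqs <- pmin(freqs, 1 / frame_interval_s - freqs)  # two-sided
  keep_bin <- freqs >= low & freqs <= high
  spec <- t(stats::mvfft(t(signals)))
  spec[, !keep_bin] <- 0
  Re(t(stats::mvfft(t(spec), inverse = TRUE))) / n
}

#' Run the full signal quality-control pipeline
#'
#' Fixed stage order: censoring mask, nuisance regression on kept frames,
#' spectral interpolation of censored frames, band-pass filter. The
#' returned mask must be reused downstream so that censored frames stay out
#' of all correlation computations.
#'
#' @param signals vertex x time matrix.
#' @param fd,dvars motion traces (see [censor_mask()]).
#' @param design nuisance design matrix (see [nuisance_design()]); `NULL`
#'   skips regression.
#' @param frame_interval_s frame interval in seconds.
#' @param ... further arguments passed to [censor_mask()].
#' @param low,high band edges in Hz.
#' @return a list with `signals` (cleaned vertex x time), `mask`, and
#'   `excluded` (logical).
#' @export
qc_pipeline <- function(signals, fd, dvars, design = NULL,
                        frame_interval_s = 3, low = 0.009, high = 0.08,
                        ...) {
  mask <- censor_mask(fd, dvars, ...)
  if (mask$subject_excluded)
    return(list(signals = NULL, mask = mask, excluded = TRUE))
  x <- as.matrix(signals)
  if (!is.null(design)) x <- nuisance_regress(x, design, mask)
  x <- tryCatch(
    interpolate_censored(x, mask, frame_interval_s = frame_interval_s),
    connectotype_excluded = function(e) NULL)
  if (is.null(x)) return(list(signals = NULL, mask = mask, excluded = TRUE))
  x <- bandpass(x, low = low, high = high,
                frame_interval_s = frame_interval_s)
  list(signals = x, mask = mask, excluded = FALSE)
}
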
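# Genotype-stratified prediction: RBF-SVM classification of clinical
# subgroups under stratified k-fold cross-validation, and linear
# L2-regularized L2-loss SVR estimation of symptom scores under
# leave-one-out cross-validation with nested (train-only) confound
# residualization and feature selection, permutation-based significance,
# and connection/ROI/network contribution analysis.

#' Residualize features (and scores) on confounds, train-fit only
#'
#' Per feature (and optionally the target), an OLS fit of
#' `value ~ intercept + confounds` on the training rows; residuals are
#' returned for both training and test rows using the training
#' coefficients only, so no information flows from the test subjects.
#' Constant confound columns in the training rows are dropped with a
#' warning.
#'
#' @param features n x p numeric matrix.
#' @param confounds n x c numeric matrix or data frame (e.g. age, sex).
#' @param train_idx,test_idx disjoint row index vectors.
#' @param scores optional length-n target vector to residualize the same
#'   way.
#' @return list with `train`, `test` (residualized feature blocks),
#'   `scores_train`, `scores_test` (if `scores` given), and `refit`, a
#'   function mapping test-row residual predictions back to the raw score
#'   scale.
#' @export
residualize_train_apply <- function(features, confounds, train_idx,
                                    test_idx, scores = NULL) {
  if (length(intersect(train_idx, test_idx)) > 0L)
    stop_validation("train and test rows must be disjoint")
  features <- as.matrix(features)
  z <- cbind(intercept = 1, as.matrix(confounds))
  const <- apply(z[train_idx, -1, drop = FALSE], 2, function(x)
    stats::sd(x) == 0)
  if (any(const)) {
    warning("dropping constant confound columns: ",
            paste(colnames(z[, -1, drop = FALSE])[const], collapse = ", "))
    z <- z[, c(TRUE, !const), drop = FALSE]
  }
  qrz <- qr(z[train_idx, , drop = FALSE])
  bf <- qr.coef(qrz, features[train_idx, , drop = FALSE])
  bf[is.na(bf)] <- 0
  out <- list(train = features[train_idx, , drop = FALSE] -
                z[train_idx, , drop = FALSE] %*% bf,
              test = features[test_idx, , drop = FALSE] -
                z[test_idx, , drop = FALSE] %*% bf)
  if (!is.null(scores)) {
    bs <- qr.coef(qrz, scores[train_idx])
    bs[is.na(bs)] <- 0
    out$scores_train <- scores[train_idx] -
      as.numeric(z[train_idx, , drop = FALSE] %*% bs)
    out$scores_test <- scores[test_idx] -
      as.numeric(z[test_idx, , drop = FALSE] %*% bs)
    out$refit <- function(pred_res)
      pred_res + as.numeric(z[test_idx, , drop = FALSE] %*% bs)
  }
  out
}

#' Two-sample t-test feature selection
#'
#' Pooled-variance two-sample two-sided t-test per feature; features with
#' `p < alpha` are retained. When nothing survives, the `fallback_k`
#' smallest-p features are returned with a message. Features with zero
#' variance in both groups are excluded.
#'
#' @param features n x p matrix.
#' @param group_labels two-level factor/vector of length n (each level
#'   n >= 3).
#' @param alpha significance criterion (default 0.001).
#' @param fallback_k fallback selection size (default 10).
#' @return integer vector of selected feature indices.
#' @export
select_features_ttest <- function(features, group_labels, alpha = 0.001,
                                  fallback_k = 10L) {
  features <- as.matrix(features)
  g <- factor(group_labels)
  if (nlevels(g) != 2L) stop_validation("need exactly two groups")
  n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])
  if (min(n1, n2) < 3L) stop_validation("each group needs n >= 3")
  x1 <- features[g == levels(g)[1], , drop = FALSE]
  x2 <- features[g == levels(g)[2], , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- apply(x1, 2, stats::var); v2 <- apply(x2, 2, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tt), df = n1 + n2 - 2)
  p[sp2 == 0 | !is.finite(p)] <- NA_real_
  sel <- which(!is.na(p) & p < alpha)
  if (length(sel) == 0L) {
    message("no feature passed p < ", alpha, "; falling back to the ",
            fallback_k, " smallest-p features")
    sel <- order(p)[seq_len(min(fallback_k, sum(!is.na(p))))]
  }
  sort(sel)
}

#' Linear L2-regularized L2-loss support vector regression
#'
#' Minimizes `0.5 * ||w||^2 + C * sum_i max(0, |x_i'w + b - y_i| -
#' epsilon)^2` by quasi-Newton optimization with an analytic gradient (the
#' objective is continuously differentiable).
#'
#' @param x n x p training matrix.
#' @param y length-n target.
#' @param C regularization/loss trade-off (default 1).
#' @param epsilon insensitivity width (default 0.1).
#' @return list with `w` (length p), `b`, and `converged`.
#' @export
svr_l2l2_fit <- function(x, y, C = 1, epsilon = 0.1) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (p > n) {
    # the L2-regularized optimum lies in the span of the training rows
    # (any orthogonal component only inflates ||w||), so optimize the
    # span coefficients: p-independent and exact
    k <- tcrossprod(x)
    obj <- function(par) {
      a <- par[seq_len(n)]; b <- par[n + 1]
      ka <- as.numeric(k %*% a)
      r <- ka + b - y
      h <- pmax(abs(r) - epsilon, 0)
      0.5 * sum(a * ka) + C * sum(h^2)
    }
    grad <- function(par) {
      a <- par[seq_len(n)]; b <- par[n + 1]
      ka <- as.numeric(k %*% a)
      r <- ka + b - y
      h <- pmax(abs(r) - epsilon, 0)
      g <- 2 * C * h * sign(r)
      c(as.numeric(k %*% (a + g)), sum(g))
    }
    fit <- stats::optim(rep(0, n + 1), obj, grad, method = "L-BFGS-B",
                        control = list(maxit = 500))
    return(list(w = as.numeric(crossprod(x, fit$par[seq_len(n)])),
                b = fit$par[n + 1], converged = fit$convergence == 0))
  }
  obj <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    r <- as.numeric(x %*% w) + b - y
    h <- pmax(abs(r) - epsilon, 0)
    0.5 * sum(w^2) + C * sum(h^2)
  }
  grad <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    r <- as.numeric(x %*% w) + b - y
    h <- pmax(abs(r) - epsilon, 0)
    g <- 2 * C * h * sign(r)
    c(w + as.numeric(crossprod(x, g)), sum(g))
  }
  fit <- stats::optim(rep(0, p + 1), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = 500))
  list(w = fit$par[seq_len(p)], b = fit$par[p + 1],
       converged = fit$convergence == 0)
}

# Stratified fold assignment: within each class, subjects are shuffled
# (seeded) and dealt into k folds.
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (lev in unique(labels)) {
      idx <- which(labels == lev)
      if (length(idx) < k)
        stop_validation("class ", lev, " has fewer subjects than folds")
      folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  folds
}

#' Cross-validated RBF-SVM classification
#'
#' Stratified k-fold cross-validation; within each training fold the
#' features are residualized on the confounds (train coefficients applied
#' to the test fold), selected by two-sample t-test, standardized, and fed
#' to a radial-basis-function SVM (`C = 1`, kernel width `1/p` after
#' standardization). Metrics are pooled over the test folds; AUC comes
#' from the decision values.
#'
#' @param features n x p matrix.
#' @param labels two-level class vector; the second factor level is
#'   treated as the positive class for sensitivity/AUC.
#' @param confounds optional n x c confound matrix.
#' @param k number of folds (default 5; the cross-genotype separation can
#'   also be run with 10).
#' @param alpha t-test selection criterion (default 0.001, uncorrected).
#' @param cost SVM cost parameter (default 1).
#' @param seed fold-assignment seed.
#' @return a `classification_report` list: `auc`, `acc`, `sen`, `spe`,
#'   `folds`, `n_selected` (per fold), `decision_values`, `predicted`.
#' @export
classify_cv <- function(features, labels, confounds = NULL, k = 5L,
                        alpha = 0.001, cost = 1, seed = 1L) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop_validation("need exactly two classes")
  folds <- stratified_folds(labels, k, seed)
  n <- length(labels)
  dv <- numeric(n)
  pred <- factor(rep(levels(labels)[1], n), levels = levels(labels))
  n_selected <- integer(k)
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    if (is.null(confounds)) {
      xtr <- features[tr, , drop = FALSE]
      xte <- features[te, , drop = FALSE]
    } else {
      res <- residualize_train_apply(features, confounds, tr, te)
      xtr <- res$train; xte <- res$test
    }
    sel <- select_features_ttest(xtr, labels[tr], alpha = alpha)
    n_selected[f] <- length(sel)
    xtr <- xtr[, sel, drop = FALSE]; xte <- xte[, sel, drop = FALSE]
    ctr <- colMeans(xtr)
    sdev <- apply(xtr, 2, stats::sd)
    sdev[sdev == 0] <- 1
    xtr <- sweep(sweep(xtr, 2, ctr), 2, sdev, "/")
    xte <- sweep(sweep(xte, 2, ctr), 2, sdev, "/")
    fit <- e1071::svm(xtr, labels[tr], kernel = "radial", cost = cost,
                      gamma = 1 / ncol(xtr), scale = FALSE)
    pr <- stats::predict(fit, xte, decision.values = TRUE)
    d <- attr(pr, "decision.values")
    # orient decision values so larger means the second factor level
    flip <- if (colnames(d)[1] == paste(levels(labels)[1],
                                        levels(labels)[2], sep = "/"))
      -1 else 1
    dv[te] <- flip * as.numeric(d)
    pred[te] <- pr
  }
  pos <- levels(labels)[2]; neg <- levels(labels)[1]
  roc <- pROC::roc(response = labels, predictor = dv,
                   levels = c(neg, pos), direction = "<", quiet = TRUE)
  structure(list(auc = as.numeric(pROC::auc(roc)),
                 acc = mean(pred == labels),
                 sen = mean(pred[labels == pos] == pos),
                 spe = mean(pred[labels == neg] == neg),
                 folds = folds, n_selected = n_selected,
                 decision_values = dv, predicted = pred),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification_report: AUC %.3f ACC %.3f SEN %.3f SPE %.3f\n",
              x$auc, x$acc, x$sen, x$spe))
  invisible(x)
}

# Core LOOCV engine. score_matrix has one column per score vector (the
# first column is the observed one; further columns are e.g. permutations).
# Feature residualization is score-independent, so it is computed once per
# fold and shared across all score columns. Fold weight vectors are
# collected for the first column only.
svr_loocv_core <- function(features, score_matrix, confounds = NULL,
                           alpha = 0.001, correction = c("bonferroni",
                                                         "none"),
                           fallback_k = 10L, C = 1, epsilon = 0.1) {
  correction <- match.arg(correction)
  features <- as.matrix(features)
  score_matrix <- as.matrix(score_matrix)
  n <- nrow(features); p <- ncol(features); nscore <- ncol(score_matrix)
  if (n < 10L) stop_validation("need n >= 10 subjects")
  if (any(apply(score_matrix, 2, stats::sd) == 0))
    stop_validation("scores must be non-constant")
  z <- cbind(intercept = rep(1, n),
             if (is.null(confounds)) NULL else as.matrix(confounds))
  predicted <- matrix(NA_real_, n, nscore)
  fold_weights <- matrix(0, n, p)
  n_selected <- integer(n)
  m <- n - 1L
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ztr <- z[tr, , drop = FALSE]
    qrz <- qr(ztr)
    bf <- qr.coef(qrz, features[tr, , drop = FALSE])
    bf[is.na(bf)] <- 0
    ftr <- features[tr, , drop = FALSE] - ztr %*% bf
    fte <- features[i, , drop = FALSE] - z[i, , drop = FALSE] %*% bf
    mu <- colMeans(ftr)
    sdev <- sqrt(colSums(sweep(ftr, 2, mu)^2) / (m - 1))
    usable <- sdev > 0
    if (!any(usable)) stop_validation("no feature with variance in a fold")
    fc <- sweep(ftr, 2, mu)
    for (s in seq_len(nscore)) {
      y <- score_matrix[, s]
      bs <- qr.coef(qrz, y[tr]); bs[is.na(bs)] <- 0
      ytr <- y[tr] - as.numeric(ztr %*% bs)
      yc <- ytr - mean(ytr)
      ysd <- sqrt(sum(yc^2) / (m - 1))
      r <- as.numeric(crossprod(fc, yc)) / ((m - 1) * sdev * ysd)
      r[!usable] <- NA_real_
      pv <- cor_pvalue(r, m)
      thr <- if (correction == "bonferroni") alpha / sum(usable) else alpha
      sel <- which(!is.na(pv) & pv < thr)
      if (length(sel) == 0L)
        sel <- order(pv)[seq_len(min(fallback_k, sum(usable)))]
      fit <- svr_l2l2_fit(ftr[, sel, drop = FALSE], ytr, C = C,
                          epsilon = epsilon)
      pred_res <- as.numeric(fte[, sel, drop = FALSE] %*% fit$w) + fit$b
      predicted[i, s] <- pred_res +
        as.numeric(z[i, , drop = FALSE] %*% bs)
      if (s == 1L) {
        fold_weights[i, sel] <- fit$w
        n_selected[i] <- length(sel)
      }
    }
  }
  list(predicted = predicted, fold_weights = fold_weights,
       n_selected = n_selected)
}

#' Leave-one-out SVR symptom prediction
#'
#' For every left-out subject: confounds are regressed from features and
#' scores on the N-1 training subjects (training coefficients applied to
#' the held-out subject), features whose Pearson correlation with the
#' training scores passes `alpha` (Bonferroni-corrected over the tested
#' features by default; the empty-selection fallback to the `fallback_k`
#' smallest-p features is always active) are kept, and a linear
#' L2-regularized L2-loss SVR is fitted and applied to the held-out
#' subject. Each fold's weight vector is stored expanded to the full
#' feature space with zeros at unselected features.
#'
#' @param features n x p connection feature matrix.
#' @param scores length-n symptom scores.
#' @param confounds optional n x c confound matrix (age, sex).
#' @param alpha selection criterion (default 0.001).
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @param fallback_k fallback selection size (default 10).
#' @param C,epsilon SVR hyperparameters (defaults 1 and 0.1).
#' @return a `prediction_report` list: `predicted`, `observed`, `r`
#'   (observed-vs-predicted Pearson correlation), `fold_weights`
#'   (n x p), `mean_weights`, `n_selected`, and `permutation_p` (`NA`
#'   until [permutation_test()] fills it).
#' @export
predict_svr_loocv <- function(features, scores, confounds = NULL,
                              alpha = 0.001, correction = "bonferroni",
                              fallback_k = 10L, C = 1, epsilon = 0.1) {
  core <- svr_loocv_core(features, matrix(scores, ncol = 1), confounds,
                         alpha = alpha, correction = correction,
                         fallback_k = fallback_k, C = C, epsilon = epsilon)
  structure(list(predicted = core$predicted[, 1], observed = scores,
                 r = evaluate_prediction(core$predicted[, 1], scores),
                 fold_weights = core$fold_weights,
                 mean_weights = colMeans(core$fold_weights),
                 n_selected = core$n_selected,
                 permutation_p = NA_real_),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("prediction_report: n = %d, observed-vs-predicted r = %.3f",
              length(x$observed), x$r))
  if (!is.na(x$permutation_p))
    cat(sprintf(", permutation p = %.4g", x$permutation_p))
  cat("\n")
  invisible(x)
}

#' Observed-vs-predicted Pearson correlation
#'
#' @param predicted,observed equal-length numeric vectors (n >= 3).
#' @return Pearson r (`NA` for a constant vector).
#' @export
evaluate_prediction <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 3L)
    stop_validation("need equal length >= 3")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    return(NA_real_)
  stats::cor(predicted, observed)
}

#' Permutation test of the LOOCV prediction correlation
#'
#' Scores are reshuffled across subjects `n_perm` times and the entire
#' LOOCV pipeline (confound residualization and feature selection inside
#' every fold) is re-run on each permutation. The default p-value uses the
#' add-one estimator `(1 + #{r_perm >= r_obs}) / (1 + n_perm)`, which
#' avoids p = 0; `estimator = "raw"` gives the plain exceedance fraction.
#'
#' @inheritParams predict_svr_loocv
#' @param n_perm number of permutations (>= 10; the full-scale analysis
#'   uses 1000).
#' @param seed permutation seed.
#' @param estimator `"add_one"` (default) or `"raw"`.
#' @return a `prediction_report` (as [predict_svr_loocv()]) with
#'   `permutation_p` filled in and `r_perm` (the permuted correlations)
#'   attached.
#' @export
permutation_test <- function(features, scores, confounds = NULL,
                             n_perm = 1000L, seed = 1L, alpha = 0.001,
                             correction = "bonferroni", fallback_k = 10L,
                             C = 1, epsilon = 0.1,
                             estimator = c("add_one", "raw")) {
  estimator <- match.arg(estimator)
  if (n_perm < 10L) stop_config("n_perm must be >= 10")
  n <- length(scores)
  perms <- withr::with_seed(seed, replicate(n_perm, sample(scores)))
  core <- svr_loocv_core(features, cbind(scores, perms), confounds,
                         alpha = alpha, correction = correction,
                         fallback_k = fallback_k, C = C, epsilon = epsilon)
  r_all <- apply(core$predicted, 2, evaluate_prediction,
                 observed = scores)
  # permuted runs are scored against their own permuted targets
  for (s in seq_len(n_perm))
    r_all[s + 1] <- evaluate_prediction(core$predicted[, s + 1],
                                        perms[, s])
  r_obs <- r_all[1]
  exceed <- sum(r_all[-1] >= r_obs)
  p <- if (estimator == "add_one") (1 + exceed) / (1 + n_perm)
  else exceed / n_perm
  structure(list(predicted = core$predicted[, 1], observed = scores,
                 r = r_obs, fold_weights = core$fold_weights,
                 mean_weights = colMeans(core$fold_weights),
                 n_selected = core$n_selected,
                 permutation_p = p, r_perm = r_all[-1]),
            class = "prediction_report")
}

#' Connection, ROI, and network contribution analysis
#'
#' Connection contribution is the fold-averaged SVR weight (zeros included
#' for folds where the connection was unselected). The top set contains
#' the connections whose |mean weight| exceeds the 90th percentile of
#' |mean weight| over connections selected in at least one fold (set
#' `over_all_features = TRUE` to take the percentile over every feature
#' instead). An ROI's contribution sums |mean weight| over its incident
#' connections; the network table sums |mean weight| of the top
#' connections per canonical network, split into within- and
#' between-network parts.
#'
#' @param fold_weights folds x p weight matrix (e.g.
#'   `prediction_report$fold_weights`).
#' @param feature_table p x 2 `(roi_i, roi_j)` table (see
#'   [feature_index()]).
#' @param roi_network ROI -> fine-network map.
#' @param canonical_map fine network -> canonical-network map; `NULL`
#'   treats `roi_network` as already canonical.
#' @param top_quantile percentile defining the top set (default 0.9).
#' @param over_all_features take the percentile over all features rather
#'   than over ever-selected ones (default `FALSE`).
#' @return a `contribution_report` list: `mean_weights`,
#'   `top_connections` (data frame with ROI pair, mean weight, canonical
#'   networks, within/between type), `roi_contribution`,
#'   `network_contribution` (per canonical network, within/between split),
#'   and `frac_top_between`.
#' @export
contribution_analysis <- function(fold_weights, feature_table, roi_network,
                                  canonical_map = NULL, top_quantile = 0.9,
                                  over_all_features = FALSE) {
  w <- as.matrix(fold_weights)
  mean_w <- colMeans(w)
  p <- length(mean_w)
  selected_any <- colSums(abs(w)) > 0
  if (!any(selected_any)) {
    warning("all fold weights are zero; empty contribution report")
    return(structure(list(mean_weights = mean_w,
                          top_connections = NULL, roi_contribution = NULL,
                          network_contribution = NULL,
                          frac_top_between = NA_real_),
                     class = "contribution_report"))
  }
  pool <- if (over_all_features) abs(mean_w) else abs(mean_w[selected_any])
  q <- stats::quantile(pool, top_quantile, type = 7, names = FALSE)
  top <- which(abs(mean_w) > q & selected_any)
  if (length(top) == 0L) {
    # few or tied selected connections: the top set is never empty
    cand <- which(selected_any)
    top <- cand[which(abs(mean_w[cand]) == max(abs(mean_w[cand])))]
  }
  canon_of_roi <- if (is.null(canonical_map)) roi_network
  else canonical_map[roi_network]
  n_rois <- max(feature_table)
  roi_contribution <- vapply(seq_len(n_rois), function(r)
    sum(abs(mean_w)[feature_table[, 1] == r | feature_table[, 2] == r]),
    numeric(1))
  ci <- canon_of_roi[feature_table[top, 1]]
  cj <- canon_of_roi[feature_table[top, 2]]
  within <- ci == cj
  top_df <- data.frame(feature = top,
                       roi_i = feature_table[top, 1],
                       roi_j = feature_table[top, 2],
                       mean_weight = mean_w[top],
                       canonical_i = ci, canonical_j = cj,
                       type = ifelse(within, "within", "between"))
  top_df <- top_df[order(-abs(top_df$mean_weight)), ]
  nets <- sort(unique(canon_of_roi))
  network_contribution <- do.call(rbind, lapply(nets, function(k) {
    data.frame(network = k,
               within = sum(abs(top_df$mean_weight)[
                 top_df$type == "within" & top_df$canonical_i == k]),
               between = sum(abs(top_df$mean_weight)[
                 top_df$type == "between" &
                   (top_df$canonical_i == k | top_df$canonical_j == k)]))
  }))
  structure(list(mean_weights = mean_w, top_connections = top_df,
                 roi_contribution = roi_contribution,
                 network_contribution = network_contribution,
                 frac_top_between = mean(top_df$type == "between")),
            class = "contribution_report")
}

#' @export
print.contribution_report <- function(x, ...) {
  if (is.null(x$top_connections)) {
    cat("contribution_report: empty\n")
  } else {
    cat(sprintf("contribution_report: %d top connections (%.0f%% between-network)\n",
                nrow(x$top_connections), 100 * x$frac_top_between))
  }
  invisible(x)
}
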
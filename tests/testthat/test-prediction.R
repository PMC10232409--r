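test_that("train-fitted residualization removes confounds without leakage", {
  set.seed(61)
  n <- 60
  conf <- cbind(age = rnorm(n, 72, 6), sex = rbinom(n, 1, 0.5))
  feats <- matrix(rnorm(n * 20), n, 20)
  tr <- 1:45; te <- 46:60
  res <- residualize_train_apply(feats, conf, tr, te)
  # train residuals orthogonal to each confound (projection oracle)
  for (j in 1:2) {
    cc <- abs(cor(res$train, conf[tr, j]))
    expect_lt(max(cc), 1e-10)
  }
  # a feature that is exactly 2*age vanishes on the training rows
  f_age <- matrix(2 * conf[, "age"], ncol = 1)
  res2 <- residualize_train_apply(f_age, conf, tr, te)
  expect_lt(max(abs(res2$train)), 1e-10)
  expect_lt(max(abs(res2$test)), 1e-10)
  # a confound-independent feature is approximately just centered
  res3 <- residualize_train_apply(feats[, 1, drop = FALSE], conf, tr, te)
  centered <- feats[tr, 1] - mean(feats[tr, 1])
  expect_gt(cor(as.numeric(res3$train), centered), 0.95)
  expect_lt(abs(mean(res3$train)), 1e-10)
  # constant confound dropped with a warning
  confc <- cbind(conf, site = 1)
  expect_warning(residualize_train_apply(feats, confc, tr, te), "constant")
  expect_error(residualize_train_apply(feats, conf, 1:10, 10:12),
               class = "connectotype_validation_error")
})

test_that("t-test selection keeps strong effects and calibrates under the null", {
  set.seed(62)
  # group means +/-5 with unit SD: t about 31.6, always selected
  n <- 80
  g <- rep(c("a", "b"), each = 40)
  feats <- matrix(rnorm(n * 30), n, 30)
  feats[, 12] <- rnorm(n, ifelse(g == "a", 5, -5), 1)
  sel <- select_features_ttest(feats, g)
  expect_true(12 %in% sel)
  expect_length(select_features_ttest(feats, g, alpha = 1), 30)
  # identical groups: false selections near the alpha rate
  null_feats <- matrix(rnorm(40 * 10000), 40, 10000)
  sel_null <- select_features_ttest(null_feats, rep(c("a", "b"), each = 20),
                                    alpha = 0.001)
  expect_lt(length(sel_null) / 10000, 0.004)
  # empty selection falls back to the smallest-p features
  tiny <- matrix(rnorm(20 * 50), 20, 50)
  expect_message(
    sel_fb <- select_features_ttest(tiny, rep(c("a", "b"), each = 10),
                                    alpha = 1e-12),
    "falling back")
  expect_length(sel_fb, 10)
})

test_that("the span-based SVR solver matches the direct primal objective", {
  set.seed(63)
  x <- matrix(rnorm(25 * 80), 25, 80)   # wide: span path
  y <- x[, 3] * 2 + rnorm(25, 0, 0.1)
  fit <- svr_l2l2_fit(x, y)
  objective <- function(w, b) {
    r <- as.numeric(x %*% w) + b - y
    0.5 * sum(w^2) + sum(pmax(abs(r) - 0.1, 0)^2)
  }
  direct <- stats::optim(rep(0, 81),
                         function(p) objective(p[1:80], p[81]),
                         method = "L-BFGS-B",
                         control = list(maxit = 2000))
  expect_lt(abs(objective(fit$w, fit$b) - direct$value), 1e-4)
})

test_that("classification separates planted groups and not permuted ones", {
  set.seed(64)
  n <- 120
  feats <- matrix(rnorm(n * 100), n, 100)
  g <- rep(c("NA", "AD"), each = 60)
  feats[, 1:5] <- feats[, 1:5] + ifelse(g == "NA", 1.2, -1.2)
  conf <- cbind(age = rnorm(n, 72, 6), sex = rbinom(n, 1, 0.5))
  rep_ <- classify_cv(feats, g, conf, seed = 5)
  expect_gte(rep_$auc, 0.95)
  expect_true(all(c(rep_$auc, rep_$acc, rep_$sen, rep_$spe) >= 0))
  expect_true(all(c(rep_$auc, rep_$acc, rep_$sen, rep_$spe) <= 1))
  # folds partition the subjects and stratify both classes
  expect_setequal(unique(rep_$folds), 1:5)
  expect_true(all(table(rep_$folds, g) > 0))
  # permuted labels give chance-level AUC
  aucs <- vapply(1:10, function(s) {
    gp <- withr::with_seed(900 + s, sample(g))
    suppressMessages(classify_cv(feats, gp, conf, seed = 5))$auc
  }, numeric(1))
  expect_gt(mean(aucs > 0.35 & aucs < 0.65), 0.7)
  expect_lt(mean(aucs), 0.65)
  # determinism under a fixed seed
  expect_equal(classify_cv(feats, g, conf, seed = 5)$auc, rep_$auc)
})

test_that("LOOCV SVR recovers a noise-free planted connection", {
  set.seed(65)
  n <- 60; p <- 120
  feats <- matrix(rnorm(n * p), n, p)
  scores <- 5 * feats[, 42]
  rep_ <- predict_svr_loocv(feats, scores)
  expect_gt(rep_$r, 0.99)
  expect_equal(which.max(abs(rep_$mean_weights)), 42)
  # weights are zero wherever a feature was never selected
  expect_true(all(rep_$mean_weights[colSums(abs(rep_$fold_weights)) == 0]
                  == 0))
  # degenerate input: constant features refuse to fit
  expect_error(predict_svr_loocv(matrix(1, 10, 5), rnorm(10)),
               class = "connectotype_validation_error")
  expect_error(predict_svr_loocv(feats[1:8, ], scores[1:8]),
               class = "connectotype_validation_error")
  expect_error(predict_svr_loocv(feats, rep(1, n)),
               class = "connectotype_validation_error")
})

test_that("a test subject's own score never influences its prediction", {
  set.seed(66)
  n <- 30
  feats <- matrix(rnorm(n * 40), n, 40)
  scores <- feats[, 7] + rnorm(n, 0, 0.3)
  conf <- cbind(age = rnorm(n, 70, 5), sex = rbinom(n, 1, 0.5))
  base <- predict_svr_loocv(feats, scores, conf)
  tampered <- scores; tampered[13] <- 1e3
  mod <- predict_svr_loocv(feats, tampered, conf)
  expect_equal(mod$predicted[13], base$predicted[13], tolerance = 1e-8)
})

test_that("prediction evaluation and the permutation estimator are exact", {
  expect_equal(evaluate_prediction(1:5, 1:5), 1)
  expect_equal(evaluate_prediction(1:5, -(1:5)), -1)
  # explicit arithmetic oracle on fixed 5-point vectors
  pr <- c(2, 4, 1, 7, 6); ob <- c(1, 3, 2, 9, 5)
  hand <- sum((pr - mean(pr)) * (ob - mean(ob))) /
    sqrt(sum((pr - mean(pr))^2) * sum((ob - mean(ob))^2))
  expect_equal(evaluate_prediction(pr, ob), hand, tolerance = 1e-12)
  expect_true(is.na(evaluate_prediction(rep(1, 5), ob)))
  # add-one estimator agrees with its formula on the returned null draws
  set.seed(67)
  feats <- matrix(rnorm(20 * 30), 20, 30)
  scores <- feats[, 2] + rnorm(20, 0, 0.5)
  pt <- permutation_test(feats, scores, n_perm = 19, seed = 3)
  expect_equal(pt$permutation_p,
               (1 + sum(pt$r_perm >= pt$r)) / 20)
  pt_raw <- permutation_test(feats, scores, n_perm = 19, seed = 3,
                             estimator = "raw")
  expect_equal(pt_raw$permutation_p, sum(pt_raw$r_perm >= pt_raw$r) / 19)
})

test_that("contribution analysis ranks connections, ROIs, and networks", {
  idx <- feature_index(10)
  p <- nrow(idx)
  # single nonzero connection: it is the top set and its two ROIs tie
  w1 <- matrix(0, 4, p)
  w1[, 5] <- 0.8
  cr <- contribution_analysis(w1, idx, rep(1:2, 5))
  expect_equal(cr$top_connections$feature, 5)
  i5 <- idx[5, 1]; j5 <- idx[5, 2]
  expect_equal(cr$roi_contribution[i5], cr$roi_contribution[j5])
  expect_equal(sum(cr$roi_contribution > 0), 2)
  # 100 ever-selected connections with distinct weights: top set size 10
  set.seed(68)
  idx2 <- feature_index(20)
  w2 <- matrix(0, 3, nrow(idx2))
  sel <- sample(nrow(idx2), 100)
  w2[, sel] <- rep(runif(100, 0.1, 1), each = 3)
  cr2 <- contribution_analysis(w2, idx2, rep(1:4, 5))
  expect_equal(nrow(cr2$top_connections), 10)
  # within/between split is consistent with the canonical map
  expect_true(all(cr2$top_connections$type %in% c("within", "between")))
  expect_equal(cr2$frac_top_between,
               mean(cr2$top_connections$type == "between"))
  expect_warning(cr0 <- contribution_analysis(matrix(0, 3, p), idx,
                                              rep(1:2, 5)), "zero")
  expect_true(is.na(cr0$frac_top_between))
})
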
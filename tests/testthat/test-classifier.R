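test_that("score model stores hand-computable training moments only", {
  P <- matrix(c(9, 11, 5, 7), ncol = 1)
  m <- fit_score_model(P, c("HC", "HC", "SZ", "SZ"))
  expect_equal(m$moments$mu_hc, 10)
  expect_equal(m$moments$sd_hc, sqrt(2))
  expect_equal(m$moments$mu_sz, 6)
  expect_equal(m$moments$sd_sz, sqrt(2))
  # refit on identical data -> identical model
  expect_identical(fit_score_model(P, c("HC", "HC", "SZ", "SZ")), m)
  # leakage guard: an extreme subject outside the training rows cannot
  # influence the fitted moments
  P_extra <- rbind(P, 1000)
  m3 <- fit_score_model(P_extra[1:4, , drop = FALSE], c("HC", "HC", "SZ", "SZ"))
  expect_identical(m3$moments, m$moments)
  expect_error(fit_score_model(matrix(c(1, 1, 2, 3), ncol = 1),
                               c("HC", "HC", "SZ", "SZ")), "zero variance")
})

test_that("z-score sums classify toward the nearer group distribution", {
  model <- structure(list(moments = data.frame(
    subnetwork = "sn1", mu_hc = 10, sd_hc = 2, mu_sz = 6, sd_sz = 2)),
    class = "score_model")
  sc <- score_subjects(model, matrix(c(7, 10, 8), ncol = 1))
  # x = 7: |7-10|/2 - |7-6|/2 = 1.5 - 0.5 = 1 -> SZ
  expect_equal(sc$total[1], 1)
  expect_equal(as.character(sc$predicted[1]), "SZ")
  # x = mu_hc exactly: s = -|z_SZ| < 0 -> HC
  expect_equal(sc$total[2], -2)
  expect_equal(as.character(sc$predicted[2]), "HC")
  # equidistant in z: s = 0 -> boundary labeled SZ
  expect_equal(sc$total[3], 0)
  expect_equal(as.character(sc$predicted[3]), "SZ")
})

test_that("confusion metrics, predictive values and AUC match hand counts", {
  # SZ scores {1, 2} (both called SZ), HC scores {-1, 3} (one false positive):
  # TP=2 TN=1 FP=1 FN=0
  scores <- c(1, 2, -1, 3)
  labels <- c("SZ", "SZ", "HC", "HC")
  pm <- evaluate_classifier(scores, labels, prevalence = 0.5)
  expect_equal(pm$TP, 2L); expect_equal(pm$TN, 1L)
  expect_equal(pm$FP, 1L); expect_equal(pm$FN, 0L)
  expect_equal(pm$accuracy, 0.75)
  expect_equal(pm$precision, 2 / 3)
  expect_equal(pm$sensitivity, 1)
  expect_equal(pm$specificity, 0.5)
  expect_equal(pm$balanced_accuracy, 0.75)
  # AUC by exhaustive pair count: HC {0.1, 0.2} vs SZ {0.15, 0.3} -> 3/4
  expect_equal(evaluate_classifier(c(0.15, 0.3, 0.1, 0.2),
                                   c("SZ", "SZ", "HC", "HC"))$AUC, 3 / 4)
  # prevalence-adjusted predictive values: sens = spec = q at prevalence .5
  pv <- ppv_npv(0.8, 0.8, 0.5)
  expect_equal(unname(pv), c(0.8, 0.8))
  # at sample prevalence with balanced groups, PPV equals TP/(TP+FP)
  pm2 <- evaluate_classifier(scores, labels, prevalence = 0.5)
  expect_equal(pm2$PPV, pm2$TP / (pm2$TP + pm2$FP))
  expect_error(evaluate_classifier(1:3, c("SZ", "SZ", "SZ")), "both classes")
})

test_that("AUC is invariant under monotone transforms and matches the ROC sweep", {
  withr::with_seed(71, {
    sc <- c(stats::rnorm(15), stats::rnorm(15, mean = 1))
    lab <- rep(c("HC", "SZ"), each = 15)
  })
  a1 <- evaluate_classifier(sc, lab)$AUC
  a2 <- evaluate_classifier(exp(2 * sc) - 5, lab)$AUC
  expect_equal(a1, a2)
  roc <- roc_points(sc, lab)
  expect_equal(attr(roc, "auc"), a1, tolerance = 1e-12)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
})

test_that("cross-validation is stratified, seeded and leakage-free by fold", {
  # perfectly separated projections: every fold classifies its tests exactly
  withr::with_seed(73, {
    P <- matrix(c(stats::rnorm(18, 0, 0.1), stats::rnorm(18, 10, 0.1)), ncol = 1)
  })
  lab <- rep(c("HC", "SZ"), each = 18)
  cv <- cross_validate(P, lab, k = 6, repeats = 2, seed = 11)
  expect_equal(unname(cv$mean["accuracy"]), 1)
  expect_equal(cv$n_folds_used, 12L)
  # determinism
  cv2 <- cross_validate(P, lab, k = 6, repeats = 2, seed = 11)
  expect_identical(cv$folds, cv2$folds)
  # label-shuffled projections give chance-level accuracy
  withr::with_seed(79, {
    Pn <- matrix(stats::rnorm(36), ncol = 1)
  })
  cvn <- cross_validate(Pn, lab, k = 6, repeats = 10, seed = 13)
  expect_lt(abs(cvn$mean[["accuracy"]] - 0.5), 0.12)
  # leave-one-out-like folds still work when a fold has a single subject
  cv1 <- cross_validate(P, lab, k = 18, repeats = 1, seed = 17)
  expect_equal(unname(cv1$mean["accuracy"]), 1)
})
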
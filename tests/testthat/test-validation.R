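test_that("stratified folds partition the data and balance classes", {
  labels <- rep(c(TRUE, FALSE), c(5, 5))
  f <- stratified_kfold(labels, 5, seed = 1)
  expect_setequal(f, 1:5)
  expect_true(all(table(f[labels]) == 1))
  expect_true(all(table(f) == 2))
  # determinism per seed
  expect_identical(stratified_kfold(labels, 5, seed = 9),
                   stratified_kfold(labels, 5, seed = 9))
  big <- rep(c(TRUE, FALSE), c(50, 450))
  expect_false(identical(stratified_kfold(big, 5, seed = 1),
                         stratified_kfold(big, 5, seed = 2)))
  f2 <- stratified_kfold(big, 5, seed = 3)
  expect_true(max(table(f2[big])) - min(table(f2[big])) <= 1)
  expect_error(stratified_kfold(rep(c(TRUE, FALSE), c(3, 20)), 5),
               "fewer than")
})

test_that("ROC endpoints, monotonicity and AUC match the concordance oracle", {
  # perfect separation
  r <- roc_curve(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(auc(r), 1)
  thr <- youden_threshold(r)
  expect_gt(thr, 0.2); expect_lt(thr, 0.8)
  # uninformative
  r0 <- roc_curve(rep(0.3, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(auc(r0), 0.5)
  expect_equal(max(r0$tpr - r0$fpr), 0)
  expect_error(roc_curve(1:3, c(1, 1, 1)), "both classes")

  withr::with_seed(17, {
    for (i in 1:100) {
      n <- sample(10:60, 1)
      scores <- round(runif(n), sample(1:3, 1))  # force ties
      labels <- runif(n) < 0.4
      if (all(labels) || !any(labels)) next
      r <- roc_curve(scores, labels)
      expect_equal(r$threshold, sort(r$threshold))
      expect_true(all(diff(r$tpr) <= 1e-12) && all(diff(r$fpr) <= 1e-12))
      expect_equal(r$tpr[1], 1); expect_equal(r$fpr[1], 1)
      expect_equal(r$tpr[nrow(r)], 0); expect_equal(r$fpr[nrow(r)], 0)
      expect_equal(auc(r), mann_whitney_auc(scores, labels),
                   tolerance = 1e-12)
      # exhaustive-scan Youden oracle over all candidate thresholds
      cand <- r$threshold
      j <- vapply(cand, function(t) {
        mean(scores[labels] > t) - mean(scores[!labels] > t)
      }, numeric(1))
      thr <- youden_threshold(r)
      expect_equal(max(r$tpr - r$fpr), max(j), tolerance = 1e-12)
      got_j <- mean(scores[labels] > thr) - mean(scores[!labels] > thr)
      expect_equal(got_j, max(j), tolerance = 1e-12)
      # smallest curve threshold among the argmax set
      jj <- r$tpr - r$fpr
      expect_equal(thr, min(r$threshold[jj >= max(jj) - 1e-12]))
    }
  })
})

test_that("our ROC/AUC agrees with pROC", {
  withr::with_seed(23, {
    scores <- runif(200)
    labels <- runif(200) < plogis(4 * scores - 2)
    ours <- auc(roc_curve(scores, labels))
    ref <- as.numeric(pROC::auc(pROC::roc(response = labels,
                                          predictor = scores,
                                          quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  })
})

test_that("confusion metrics use the strict > rule", {
  scores <- c(0.9, 0.6, 0.4, 0.35, 0.3, 0.2, 0.1, 0.05)
  labels <- c(1, 1, 0, 1, 0, 0, 1, 0)
  cm <- confusion_metrics(scores, labels, 0.35)
  # hand count: predicted positive = {0.9,0.6,0.4}; TP=2, FP=1, FN=2, TN=3
  expect_equal(cm$sensitivity, 2 / 4)
  expect_equal(cm$specificity, 3 / 4)
  expect_equal(cm$accuracy, 5 / 8)
  expect_equal(confusion_metrics(scores, labels, 0)$sensitivity, 1)
  expect_equal(confusion_metrics(scores, labels, 1)$specificity, 1)
})

test_that("repeated CV is reproducible, calibrated under the null, and perfect under determinism", {
  # outcome independent of everything: mean AUC near 0.5
  withr::with_seed(47, {
    m <- random_binary_matrix(20000, c("out", "a", "b"), "out",
                              p = c(0.3, 0.4, 0.5))
  })
  g <- dag(c("out", "a", "b"), cbind("a", "out"))
  cv <- repeated_cv(m, g, k = 5, repeats = 2, seed = 5)
  expect_equal(nrow(cv$folds), 10L)
  expect_lt(abs(cv$summary$mean[cv$summary$metric == "auc"] - 0.5), 0.05)
  # bitwise reproducibility
  cv2 <- repeated_cv(m, g, k = 5, repeats = 2, seed = 5)
  expect_identical(cv, cv2)
  # repeats = 1 equals one plain pass with the same seed
  cv1 <- repeated_cv(m, g, k = 5, repeats = 1, seed = 5)
  expect_identical(cv1$folds, cv$folds[cv$folds$rep == 1, ])

  # outcome = copy of one AE: perfect discrimination
  data <- m$data
  data[, "out"] <- data[, "a"]
  md <- case_matrix(data, m$levels, "out")
  cvd <- repeated_cv(md, g, k = 5, repeats = 1, seed = 7)
  expect_equal(cvd$summary$mean[cvd$summary$metric == "auc"], 1)

  # per-fold identities
  expect_true(all(cv$folds$accuracy >= 0 & cv$folds$accuracy <= 1))
  for (i in seq_len(nrow(cv$folds))) {
    f <- cv$folds[i, ]
    expect_equal(f$sensitivity + f$specificity - 1,
                 f$sensitivity + f$specificity - 1)
  }
  # summary CI: half-width 1.96 sd / sqrt(#folds), mean inside
  s <- cv$summary[cv$summary$metric == "auc", ]
  expect_equal(s$upper - s$mean, 1.96 * s$sd / sqrt(nrow(cv$folds)))
  expect_true(s$lower <= s$mean && s$mean <= s$upper)
})

test_that("fold thresholds maximize the Youden index on their own fold", {
  b <- gbs_fixture_network()
  m <- sample_cohort(b, 8000, seed = 19)
  cv <- repeated_cv(m, b$dag, k = 5, repeats = 1, seed = 3)
  # re-derive each fold and check sens + spec - 1 equals the curve maximum
  withr::with_seed(3, {
    fold_id <- stratified_kfold(m$data[, "gbs"] == 2L, 5)
  })
  for (f in 1:5) {
    val <- fold_id == f
    fit <- fit_mle(b$dag, cm_subset(m, !val))
    scores <- predict_scores(fit, cm_subset(m, val), "gbs",
                             impossible = "prior")
    labels <- m$data[val, "gbs"] == 2L
    curve <- roc_curve(scores, labels)
    row <- cv$folds[cv$folds$fold == f, ]
    expect_equal(row$sensitivity + row$specificity - 1,
                 max(curve$tpr - curve$fpr), tolerance = 1e-12)
    # accuracy identity from class sizes
    P <- sum(labels); N <- sum(!labels)
    expect_equal(row$accuracy,
                 (row$sensitivity * P + row$specificity * N) / (P + N),
                 tolerance = 1e-12)
  }
})

test_that("external validation transfers the model across cohorts", {
  b <- gbs_fixture_network()
  m_train <- sample_cohort(b, 50000, seed = 31)
  fit <- fit_mle(b$dag, m_train)
  m_ext <- sample_cohort(b, 50000, seed = 32)
  ext <- external_validate(fit, m_ext)
  cv <- repeated_cv(m_train, b$dag, k = 5, repeats = 1, seed = 33)
  expect_lt(abs(ext$auc - cv$summary$mean[cv$summary$metric == "auc"]),
            0.02)
  # destroyed signal
  shuf <- m_ext
  shuf$data[, "gbs"] <- withr::with_seed(9, sample(shuf$data[, "gbs"]))
  ext0 <- external_validate(fit, shuf)
  expect_lt(abs(ext0$auc - 0.5), 0.03)
  # round trip: metrics recomputed from the exported scores
  labels <- m_ext$data[, "gbs"] == 2L
  pred <- ext$scores > ext$threshold
  expect_equal(ext$sensitivity, sum(pred & labels) / sum(labels))
  expect_equal(ext$specificity, sum(!pred & !labels) / sum(!labels))
  expect_equal(ext$accuracy, mean(pred == labels))
  # transferred fixed threshold mode
  extf <- external_validate(fit, m_ext, threshold = ext$threshold)
  expect_equal(extf$sensitivity, ext$sensitivity)
})
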
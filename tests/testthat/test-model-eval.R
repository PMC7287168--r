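test_that("confusion metrics implement the four defining formulas", {
  perfect <- compute_metrics(tp = 50, fp = 0, tn = 50, fn = 0)
  expect_equal(unlist(perfect[c("sn", "sp", "acc", "mcc")]),
               c(sn = 1, sp = 1, acc = 1, mcc = 1))
  chance <- compute_metrics(tp = 25, fp = 25, tn = 25, fn = 25)
  expect_equal(chance$acc, 0.5)
  expect_equal(chance$mcc, 0)
  hand <- compute_metrics(tp = 40, fn = 10, tn = 30, fp = 20)
  expect_equal(hand$sn, 0.8)
  expect_equal(hand$sp, 0.6)
  expect_equal(hand$acc, 0.7)
  expect_equal(hand$mcc, 1000 / sqrt(6e6), tolerance = 1e-12)
})

test_that("metric zero-denominator conventions hold", {
  expect_warning(m <- compute_metrics(tp = 0, fp = 5, tn = 5, fn = 0),
                 "Sn")
  expect_equal(m$sn, 0)
  expect_equal(m$mcc, 0)  # zero TP+FN factor
  # MCC = 0 whenever TP*TN == FP*FN
  m2 <- compute_metrics(tp = 6, tn = 2, fp = 4, fn = 3)
  expect_equal(m2$mcc, 0)
  # inverting the calls flips the MCC sign
  a <- compute_metrics(tp = 40, fn = 10, tn = 30, fp = 20)
  b <- compute_metrics(tp = 10, fn = 40, tn = 20, fp = 30)
  expect_equal(b$mcc, -a$mcc, tolerance = 1e-12)
})

test_that("ROC sweep and trapezoid AUC match the pair-counting oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  hand_scores <- c(0.9, 0.6, 0.4, 0.8, 0.6, 0.1)
  hand_labels <- c(1, 1, 1, 0, 0, 0)
  expect_equal(roc_auc(hand_scores, hand_labels),
               oracle_auc(hand_scores, hand_labels))
  withr::with_seed(7, {
    for (i in 1:25) {
      n <- sample(6:50, 1)
      labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
      scores <- round(runif(n), 2)   # rounding forces ties
      expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels),
                   tolerance = 1e-10)
    }
  })
  expect_error(roc_auc(1:3, c(1, 1, 1)), class = "methsite_validation_error")
  # cross-check against an established ROC implementation
  if (requireNamespace("pROC", quietly = TRUE)) {
    withr::with_seed(11, {
      scores <- round(runif(60), 2)
      labels <- c(1, 0, rbinom(58, 1, 0.5))
    })
    expect_equal(roc_auc(scores, labels),
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-10)
  }
})

test_that("ROC points start at (0,0), end at (1,1) and are monotone", {
  withr::with_seed(8, {
    scores <- runif(40)
    labels <- rbinom(40, 1, 0.5)
    labels[1:2] <- c(0, 1)
  })
  r <- roc_points(scores, labels)
  expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1)
  expect_equal(r$tpr[nrow(r)], 1)
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
})

test_that("SVM training separates a separable toy set and is deterministic", {
  d <- toy_separable(20, seed = 1)
  m1 <- svm_train(d, seed = 3)
  p1 <- predict(m1, d)
  expect_equal(p1$call, d$label)
  expect_true(all(p1$probability >= 0 & p1$probability <= 1))
  m2 <- svm_train(d, seed = 3)
  p2 <- predict(m2, d)
  expect_identical(m1$platt, m2$platt)
  expect_identical(m1$fit$coefs, m2$fit$coefs)
  expect_identical(p1, p2)
})

test_that("the call threshold is strictly more-than-one-half", {
  d <- toy_separable(20, seed = 2)
  m <- svm_train(d, seed = 1)
  # drive probabilities through the platt map directly
  m$platt <- list(A = -1, B = 0)
  dv_for_half <- 0          # p = 0.5 exactly
  expect_equal(methsite:::platt_prob(dv_for_half, m$platt), 0.5)
  expect_equal(as.integer(methsite:::platt_prob(dv_for_half, m$platt) > 0.5),
               0L)
  expect_equal(as.integer(methsite:::platt_prob(0.1, m$platt) > 0.5), 1L)
})

test_that("prediction demands the model's feature columns", {
  d <- toy_separable(10, seed = 3)
  m <- svm_train(d, seed = 1)
  expect_error(predict(m, d[c("id", "label", "f1")]),
               class = "methsite_contract_error")
})

test_that("grid search is exhaustive, tie-broken and reproducible", {
  d <- toy_separable(15, seed = 4)
  # degenerate one-point grid returns that point
  m <- grid_search_train(d, costs = 4, gammas = 0.25, folds = 3, seed = 1)
  expect_equal(m$cost, 4)
  expect_equal(m$gamma, 0.25)
  expect_equal(nrow(m$grid), 1L)
  # separable data: every grid point is perfect, ties resolve to the
  # smallest cost then smallest gamma
  m2 <- grid_search_train(d, costs = c(8, 1), gammas = c(0.5, 0.125),
                          folds = 3, seed = 1)
  expect_equal(max(m2$grid$accuracy), 1)
  expect_equal(m2$cost, 1)
  expect_equal(m2$gamma, 0.125)
  m3 <- grid_search_train(d, costs = c(8, 1), gammas = c(0.5, 0.125),
                          folds = 3, seed = 1)
  expect_identical(m2$grid, m3$grid)
  expect_identical(m2$platt, m3$platt)
})

test_that("a saved and reloaded model reproduces predictions exactly", {
  d <- toy_separable(12, seed = 5)
  m <- svm_train(d, seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict(m, d), predict(m2, d))
})

test_that("stratified cross-validation balances folds and is reproducible", {
  sim <- simulate_sites(n_pos = 40, n_neg = 40, effect_size = 0.9, seed = 1)
  fused <- encode_windows(sim)
  fold_id <- methsite:::make_folds(fused$label, 4L, 1L)
  for (k in 1:4) {
    expect_equal(sum(fold_id == k & fused$label == 1L), 10L)
    expect_equal(sum(fold_id == k & fused$label == 0L), 10L)
  }
  r1 <- cross_validate(fused, folds = 4, seed = 2)
  r2 <- cross_validate(fused, folds = 4, seed = 2)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$summary, r2$summary)
  # per-report identity ACC = (Sn*P + Sp*N) / (P + N) on pooled counts
  with(r1$confusion,
       expect_equal((tp + tn) / (tp + tn + fp + fn),
                    (tp / (tp + fn) * (tp + fn) + tn / (tn + fp) * (tn + fp)) /
                      (tp + tn + fp + fn)))
  expect_error(cross_validate(fused, folds = 80, seed = 1),
               class = "methsite_config_error")
})

test_that("cross-validation tidiers and report writing work", {
  d <- toy_separable(20, seed = 6)
  r <- cross_validate(d, folds = 4, seed = 1)
  expect_equal(nrow(tidy(r)), 4L)
  expect_equal(names(glance(r))[1:5], c("sn", "sp", "acc", "mcc", "auc"))
  expect_s3_class(autoplot(r), "ggplot")
  dir <- withr::local_tempdir()
  write_report(r, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "metrics.tsv")))
  expect_true(file.exists(file.path(dir, "roc.tsv")))
  js <- jsonlite::read_json(file.path(dir, "report.json"),
                            simplifyVector = TRUE)
  expect_equal(js$summary$acc, r$summary$acc)
})

test_that("repeated cross-validation averages over repeats", {
  d <- toy_separable(16, seed = 7)
  r <- cross_validate(d, folds = 4, repeats = 2, seed = 1)
  expect_equal(nrow(r$metrics), 8L)
  expect_equal(r$summary$acc, mean(r$metrics$acc))
})
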
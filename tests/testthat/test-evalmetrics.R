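# Metric implementations against brute-force oracles and their invariants.

test_that("confusion matrices count truth x prediction and conserve n", {
  m <- confusion_matrix(c(1, 1, 0), c(1, 1, 0))
  expect_identical(unname(diag(m)), c(1L, 2L))
  expect_identical(sum(m) - sum(diag(m)), 0L)
  m2 <- confusion_matrix(c(1, 0), c(0, 1))
  expect_identical(unname(diag(m2)), c(0L, 0L))
  set.seed(71)
  for (i in 1:10) {
    n <- sample(1:50, 1)
    t_ <- sample(0:1, n, replace = TRUE)
    p_ <- sample(0:1, n, replace = TRUE)
    expect_identical(sum(confusion_matrix(t_, p_)), as.integer(n))
  }
  expect_error(confusion_matrix(c(0, 1), c(1)), "length")
})

test_that("precision/recall/F1 reproduce the printed triple and handle degeneracy", {
  # printed pair: precision 0.975, recall 0.965 -> F1 0.970 at 3 decimals
  expect_equal(round(f1_score(0.975, 0.965), 3), 0.970)
  perfect <- confusion_matrix(c(0, 1, 1), c(0, 1, 1))
  prf <- precision_recall_f1(perfect)
  expect_equal(unlist(prf[c("precision", "recall", "f1")]),
               c(precision = 1, recall = 1, f1 = 1))
  # no positive predictions: flagged zeros rather than NaN
  none <- confusion_matrix(c(0, 1), c(0, 0))
  prf0 <- precision_recall_f1(none)
  expect_equal(prf0$precision, 0)
  expect_equal(prf0$f1, 0)
  expect_true("no_positive_predictions" %in% prf0$flags)
})

test_that("rank-based AUC equals the pairwise-concordance oracle up to n = 200", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.2)), 0.75)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  set.seed(72)
  for (i in 1:25) {
    n <- sample(2:200, 1)
    truth <- c(0, 1, sample(0:1, n - 2, replace = TRUE)) # both classes present
    scores <- round(runif(n), sample(c(1, 2, 6), 1))     # induce ties sometimes
    expect_equal(roc_auc(truth, scores), auc_pairwise(truth, scores),
                 tolerance = 1e-12)
  }
  expect_warning(a <- roc_auc(c(1, 1), c(0.2, 0.4)), "single-class")
  expect_true(is.na(a))
})

test_that("label swap maps AUC to its complement in the absence of ties", {
  set.seed(73)
  for (i in 1:10) {
    n <- sample(5:100, 1)
    truth <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- runif(n) # continuous, ties almost surely absent
    expect_equal(roc_auc(1 - truth, scores), 1 - roc_auc(truth, scores),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(74)
  truth <- c(0, 1, sample(0:1, 60, replace = TRUE))
  scores <- round(runif(62), 2)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(truth, scores), ref, tolerance = 1e-12)
})

test_that("roc_points trace the empirical ROC from (0,0) to (1,1)", {
  set.seed(75)
  truth <- sample(0:1, 30, replace = TRUE)
  truth[1:2] <- 0:1
  scores <- runif(30)
  pts <- roc_points(truth, scores)
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})

test_that("evaluate produces an internally consistent report", {
  groups <- tiny_groups(20, seed = 76)
  # oracle model: replace prediction by truth via a report on true labels
  truth <- vapply(groups, function(g) g$label, 0L)
  rep_perfect <- metrics_report(truth, truth, as.numeric(truth))
  expect_equal(rep_perfect$accuracy, 1)
  expect_equal(rep_perfect$auc, 1)
  # untrained model: report still satisfies the type invariants
  model <- tiny_fusion(seed = 76)
  rep <- evaluate(model, groups)
  expect_identical(rep$n, 20L)
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / sum(rep$confusion))
  expect_true(all(unlist(rep[c("accuracy", "recall", "precision", "f1")]) >= 0))
  expect_true(all(unlist(rep[c("accuracy", "recall", "precision", "f1")]) <= 1))
  expect_error(evaluate(model, list()), "empty")
})

test_that("coin-flip scores on a balanced set give AUC near one half", {
  set.seed(77)
  n <- 2000
  truth <- rep(0:1, n / 2)
  scores <- runif(n)
  se <- sqrt(1 / 12 * (1 / (n / 2) + 1 / (n / 2))) # conservative MW std. error
  expect_lt(abs(roc_auc(truth, scores) - 0.5), 3 * se)
})

test_that("cross-validation emits k fold reports plus their arithmetic mean", {
  groups <- tiny_groups(30, seed = 78)
  cv <- cross_validate(
    function(s) tiny_fusion(seed = s),
    groups,
    split_config(seed = 78, k = 5L),
    train_config(lr = 1e-3, batch_size = 10L, epochs = 1L, augment = NULL,
                 seed = 78L, selection = "validation", val_fraction = 0.2))
  expect_length(cv$folds, 5L)
  for (f in cv$folds) expect_s3_class(f, "metrics_report")
  expect_equal(cv$average$accuracy,
               mean(vapply(cv$folds, function(r) r$accuracy, 0)))
  expect_equal(cv$average$f1, mean(vapply(cv$folds, function(r) r$f1, 0)))
  expect_identical(sum(cv$average$confusion), 30L)
})
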
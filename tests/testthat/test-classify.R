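test_that("metrics follow the balanced-accuracy identity", {
  m <- classifier_metrics(c(tp = 9, fn = 1, tn = 8, fp = 2))
  expect_equal(unname(m), c(0.9, 0.8, 0.85))
  expect_equal(unname(classifier_metrics(c(tp = 5, fn = 0, tn = 7, fp = 0))),
               c(1, 1, 1))
  set.seed(21)
  for (i in 1:20) {
    cc <- c(tp = sample(0:30, 1), tn = sample(0:30, 1),
            fp = sample(0:30, 1), fn = sample(0:30, 1))
    if (cc["tp"] + cc["fn"] == 0 || cc["tn"] + cc["fp"] == 0) next
    m <- classifier_metrics(cc)
    expect_equal(m[["se"]], cc[["tp"]] / (cc[["tp"]] + cc[["fn"]]))
    expect_equal(m[["sp"]], cc[["tn"]] / (cc[["tn"]] + cc[["fp"]]))
    expect_equal(m[["ac"]], (m[["se"]] + m[["sp"]]) / 2)
  }
  expect_error(classifier_metrics(c(tp = 0, fn = 0, tn = 5, fp = 1)),
               "undefined")
  expect_error(classifier_metrics(c(tp = 3, fn = 1, tn = 0, fp = 0)),
               "undefined")
})

test_that("classification is a strict threshold crossing with ADL ties", {
  m <- threshold_model(0.4, "T1")
  expect_equal(classify(0.5, m), "fall")
  expect_equal(classify(0.4, m), "adl")
  set.seed(22)
  s <- rnorm(200)
  expect_equal(classify(s, m), ifelse(s > 0.4, "fall", "adl"))
  dfm <- threshold_model(0, "T1", feature = "C8")
  sc <- trial_score(c(0.1, 0.9, 0.2), "fall", "t1")
  expect_equal(sc$score, 0.9)
  sc$feature <- "C2"
  expect_error(classify(sc, dfm), "feature mismatch")
})

test_that("trial scores reduce a series to its maximum", {
  expect_equal(trial_score(rep(3.3, 10), "adl", "t")$score, 3.3)
  set.seed(23)
  v <- rnorm(500)
  fs <- extract_feature(random_trace(300), "C8")
  expect_equal(trial_score(fs, "fall", "t")$score, max(fs$values))
  expect_equal(trial_score(v, "fall", "t")$score, max(v))
  expect_error(trial_score(numeric(0), "adl", "t"), "empty")
})

test_that("T1 maximizes training accuracy over all candidate thresholds", {
  m <- fit_t1(c(2, 3, 0, 1), c("fall", "fall", "adl", "adl"))
  expect_equal(m$threshold, 1.5)
  expect_equal(attr(m, "train_ac"), 1)
  # degenerate identical scores: AC is 0.5 everywhere; prefer SE = 1
  m2 <- fit_t1(rep(2, 6), c("fall", "adl", "fall", "adl", "fall", "adl"))
  expect_lt(m2$threshold, 2)
  expect_equal(attr(m2, "train_se"), 1)
  expect_equal(attr(m2, "train_ac"), 0.5)
  expect_error(fit_t1(1:3, c("adl", "adl", "adl")), "both")
  set.seed(24)
  for (i in 1:20) {
    rs <- random_scores(sample(20:200, 1))
    m <- fit_t1(rs$scores, rs$labels)
    expect_equal(attr(m, "train_ac"), best_ac_scan(rs$scores, rs$labels),
                 tolerance = 1e-12)
  }
})

test_that("T2 sits just below the weakest training fall", {
  m <- fit_t2(c(2, 3, 0, 1, 2.5),
              c("fall", "fall", "adl", "adl", "adl"))
  expect_lt(m$threshold, 2)
  expect_gt(m$threshold, 2 - 1e-4)
  expect_equal(attr(m, "train_se"), 1)
  expect_equal(attr(m, "train_sp"), 2 / 3)
  expect_error(fit_t2(1:3, rep("adl", 3)), "at least one fall")
  set.seed(25)
  for (i in 1:20) {
    rs <- random_scores(sample(20:150, 1))
    if (!any(rs$labels == "fall")) next
    m <- fit_t2(rs$scores, rs$labels)
    expect_equal(attr(m, "train_se"), 1)
  }
})

test_that("on the training set T2 never loses sensitivity to T1", {
  set.seed(26)
  for (i in 1:15) {
    rs <- random_scores(80, overlap = runif(1, 0.2, 1.5))
    if (length(unique(rs$labels)) < 2) next
    m1 <- fit_t1(rs$scores, rs$labels)
    m2 <- fit_t2(rs$scores, rs$labels)
    expect_gte(attr(m2, "train_se"), attr(m1, "train_se"))
    expect_lte(attr(m2, "train_sp"), attr(m1, "train_sp"))
  }
})

test_that("separable training scores give identical perfect policies", {
  scores <- c(runif(20, 0, 1), runif(10, 2, 3))
  labels <- c(rep("adl", 20), rep("fall", 10))
  expect_equal(attr(fit_t1(scores, labels), "train_ac"), 1)
  expect_equal(attr(fit_t2(scores, labels), "train_ac"), 1)
})

test_that("stratified folds preserve class proportions and partition", {
  labels <- c(rep("adl", 100), rep("fall", 50))
  f <- stratified_kfold(labels, k = 10, seed = 5)
  expect_equal(sort(unique(f)), 1:10)
  counts <- table(f, labels)
  expect_true(all(counts[, "adl"] == 10))
  expect_true(all(counts[, "fall"] == 5))
  # uneven class: sizes differ by at most one
  labels2 <- c(rep("adl", 101), rep("fall", 50))
  f2 <- stratified_kfold(labels2, k = 10, seed = 5)
  counts2 <- table(f2[labels2 == "adl"])
  expect_true(all(counts2 %in% c(10, 11)))
  expect_equal(length(f2), 151)
  # determinism and seed sensitivity
  expect_identical(f, stratified_kfold(labels, k = 10, seed = 5))
  expect_false(identical(f, stratified_kfold(labels, k = 10, seed = 6)))
  expect_error(stratified_kfold(c(rep("adl", 30), rep("fall", 5)), k = 10),
               "at least k")
})

test_that("cross-validation evaluates held-out folds per policy", {
  scores <- data.frame(score = c(runif(100, 0, 1), runif(50, 2, 3)),
                       label = c(rep("adl", 100), rep("fall", 50)),
                       feature = "C8")
  cv <- cross_validate(scores, policy = "T1", k = 10, seed = 1)
  expect_equal(unname(cv$mean[["ac"]]), 1)
  expect_equal(unname(cv$sd[["ac"]]), 0)
  expect_equal(nrow(cv$folds), 10)
  expect_true(all(abs(cv$folds$ac - (cv$folds$se + cv$folds$sp) / 2)
                  < 1e-12))
  expect_true(all(cv$folds$tp + cv$folds$tn + cv$folds$fp + cv$folds$fn
                  == 15))
  # shuffled labels: chance-level accuracy
  set.seed(31)
  null_scores <- data.frame(score = rnorm(300),
                            label = sample(rep(c("adl", "fall"), 150)))
  cvn <- cross_validate(null_scores, policy = "T1", k = 10, seed = 2)
  expect_lte(abs(cvn$mean[["ac"]] - 0.5),
             3 * max(cvn$sd[["ac"]] / sqrt(10), 0.02))
  # order invariance under the same fold seed
  perm <- sample(nrow(scores))
  cvp <- cross_validate(scores[perm, ], policy = "T1", k = 10, seed = 1)
  expect_equal(cvp$mean, cv$mean)
  expect_error(cross_validate(scores[c(1:15, 101:105), ], k = 10,
                              seed = 1),
               "at least k")
})

test_that("transfer evaluation fits once and scores the test set once", {
  train <- data.frame(score = c(runif(40, 0, 1), runif(20, 2, 3)),
                      label = c(rep("adl", 40), rep("fall", 20)),
                      feature = "C8")
  same <- transfer_evaluate(train, train, policy = "T1")
  expect_equal(unname(same$mean[["ac"]]), attr(same$model, "train_ac"))
  shrunk <- train
  shrunk$score <- shrunk$score * 0.7
  tr <- transfer_evaluate(train, shrunk, policy = "T1")
  expect_lte(tr$mean[["se"]], same$mean[["se"]])
  expect_error(transfer_evaluate(train, train[0, ], policy = "T1"),
               "empty test")
})
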
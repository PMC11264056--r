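test_that("downsampling balances every stage at the minority count", {
  feat <- separable_features(20)
  extra <- feat[feat$stage == "N2", ][rep(1, 30), ]
  unbal <- rbind(feat, extra)
  bal <- downsample_balance(unbal, seed = 1)
  expect_true(all(table(bal$stage) == 20))
  # already balanced input is returned unchanged as a multiset
  rebal <- downsample_balance(feat, seed = 2)
  expect_equal(dim(rebal), dim(feat))
  expect_equal(sort(rebal$mi_delta), sort(feat$mi_delta))
})

test_that("downsampling is seeded and errors on a missing stage", {
  feat <- separable_features(20)
  unbal <- rbind(feat, feat[feat$stage == "W", ])
  b1 <- downsample_balance(unbal, seed = 5)
  b2 <- downsample_balance(unbal, seed = 5)
  b3 <- downsample_balance(unbal, seed = 6)
  expect_identical(rownames(b1), rownames(b2))
  expect_false(identical(rownames(b1), rownames(b3)))
  expect_error(downsample_balance(feat[feat$stage != "N3", ]), "N3")
})

test_that("metrics from an identity confusion matrix are all 100%", {
  cm <- diag(c(10, 10, 10, 10, 10))
  m <- compute_metrics(cm)
  expect_equal(unname(m), rep(100, 4))
})

test_that("binary toy matrix reproduces the hand-computed class metrics", {
  cm <- matrix(c(3, 1, 2, 4), 2, 2, byrow = TRUE)
  m <- compute_metrics(cm)
  # class 1: TP=3, FP=2, FN=1; class 2: TP=4, FP=1, FN=2
  expect_equal(unname(m["accuracy"]), 100 * 7 / 10)
  expect_equal(unname(m["precision"]), 100 * mean(c(3 / 5, 4 / 5)))
  expect_equal(unname(m["recall"]), 100 * mean(c(3 / 4, 4 / 6)))
  expect_equal(unname(m["f1"]), 100 * mean(c(2 * 3 / (2 * 3 + 2 + 1),
                                             2 * 4 / (2 * 4 + 1 + 2))))
})

test_that("a degenerate one-class predictor scores chance accuracy", {
  cm <- matrix(0, 5, 5)
  cm[, 1] <- 10  # everything predicted as class 1, balanced truth
  suppressMessages(m <- compute_metrics(cm))
  expect_equal(unname(m["accuracy"]), 20)
  expect_equal(unname(m["recall"]), 20)
  expect_message(compute_metrics(cm), "zero predicted positives")
})

test_that("accuracy equals trace over total for any confusion matrix", {
  set.seed(9)
  for (i in 1:10) {
    cm <- matrix(rpois(25, 5), 5, 5)
    m <- suppressMessages(compute_metrics(cm))
    expect_equal(unname(m["accuracy"]), 100 * sum(diag(cm)) / sum(cm))
  }
})

test_that("perfectly separable features are classified at 100%", {
  feat <- separable_features(20)
  for (cl in c("rf", "svm", "knn")) {
    res <- run_experiment(feat, classifier_spec(cl), n_rounds = 3, seed = 2)
    expect_equal(unname(res$mean["accuracy"]), 100)
  }
})

test_that("permuted labels drop every classifier to chance level", {
  feat <- separable_features(40)  # 60 test epochs/round keeps the MC noise small
  for (cl in c("rf", "svm", "knn")) {
    res <- run_experiment(feat, classifier_spec(cl), n_rounds = 10, seed = 3,
                          permute_labels = TRUE)
    expect_lt(abs(res$mean["accuracy"] - 20), 5)
  }
})

test_that("confusion-matrix totals conserve the test-set size", {
  feat <- separable_features(20)
  res <- run_experiment(feat, classifier_spec("rf"), n_rounds = 4, seed = 7)
  # 20 per stage balanced, 30% of each stage tested, 4 rounds
  expect_equal(sum(res$confusion), 4 * 5 * round(0.3 * 20))
})

test_that("experiments are bit-reproducible given seed and config", {
  feat <- separable_features(15)
  r1 <- run_experiment(feat, classifier_spec("rf"), n_rounds = 3, seed = 11)
  r2 <- run_experiment(feat, classifier_spec("rf"), n_rounds = 3, seed = 11)
  expect_identical(r1$rounds, r2$rounds)
  expect_identical(r1$confusion, r2$confusion)
})

test_that("experiments refuse subgroups too small to split", {
  feat <- separable_features(5)
  expect_error(run_experiment(feat, classifier_spec("rf")), "too few epochs")
})

test_that("the subgroup suite covers all plus the six age x sex cells", {
  cohort <- generate_cohort(cohort_spec(2, 5, seed = 17))
  feat <- connectivity_features(cohort)
  suite <- run_subgroup_suite(feat, classifiers = "rf", n_rounds = 3, seed = 1)
  expect_equal(nrow(suite$table), 7)
  expect_setequal(suite$table$subgroup,
                  c("all", "young_female", "young_male", "middle_female",
                    "middle_male", "old_female", "old_male"))
  expect_equal(suite$summary$subgroup_gain,
               suite$summary$subgroup_mean_accuracy - suite$summary$all_accuracy)
  expect_true(all(suite$table$accuracy >= 0 & suite$table$accuracy <= 100))
})
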
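test_that("LOSO folds partition epochs with no subject leakage", {
  tab <- make_feature_table(23, 6, n_mci = 16, seed = 5)
  folds <- loso_folds(tab)
  expect_length(folds, 23)
  tested <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(tested, seq_len(nrow(tab)))  # each epoch tested exactly once
  for (f in folds) {
    expect_false(f$subject %in% tab$subject_id[f$train])
    expect_length(intersect(f$train, f$test), 0)
  }
  expect_error(loso_folds(make_feature_table(1, 5, n_mci = 1)), "2 subjects")
})

test_that("chance level is the rounded majority-class percentage", {
  expect_equal(chance_level(rep(c("mci", "healthy"), c(16, 7))), 70L)
  expect_equal(chance_level(rep(c("a", "b"), c(10, 10))), 50L)
  expect_equal(chance_level(rep(c("a", "b"), c(3, 1))), 75L)
  expect_error(chance_level(character(0)), "nonempty")
})

test_that("metric suite reproduces confusion-matrix arithmetic", {
  truth <- c("mci", "mci", "healthy", "healthy")
  pred <- c("mci", "healthy", "healthy", "healthy")
  m <- metric_suite(truth, pred, average = "positive")
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, 1.0)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 2 / 3)

  perfect <- metric_suite(truth, truth, scores = c(1, 1, 0, 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)

  expect_warning(one <- metric_suite(c("mci", "mci"), c("mci", "mci"),
                                     scores = c(0.9, 0.8)),
                 "AUC undefined")
  expect_equal(one$accuracy, 1)
  expect_true(is.na(one$auc))

  expect_error(metric_suite(1:3, 1:4), "same length")
})

test_that("regression metrics match hand arithmetic and Jensen bound", {
  truth <- c(20, 25, 30); pred <- c(22, 24, 33)
  m <- metric_suite(truth, pred)
  expect_equal(m$mae, 2)
  expect_equal(m$mape, (2 / 20 + 1 / 25 + 3 / 30) * 100 / 3)
  o <- regmetrics_oracle(truth, pred)
  expect_equal(m$r2, o$r2); expect_equal(m$mse, o$mse)

  exact <- metric_suite(truth, truth)
  expect_equal(exact$r2, 1); expect_equal(exact$mse, 0)
  expect_equal(exact$mae, 0); expect_equal(exact$mape, 0)

  const <- metric_suite(truth, rep(mean(truth), 3))
  expect_equal(const$r2, 0)

  set.seed(6)
  for (r in 1:20) {
    a <- rnorm(30); b <- rnorm(30)
    mm <- metric_suite(a, b)
    expect_lte(mm$mae, sqrt(mm$mse) + 1e-12)
  }
})

test_that("classifier is perfect when a feature encodes the group", {
  tab <- make_feature_table(8, 10, n_mci = 5, effect = 0, seed = 7)
  tab$total_cycles <- ifelse(tab$group == "mci", 100, 0) + rnorm(nrow(tab))
  panel <- classify_loso(tab, "ALL", n_trees = 100, seed = 1)
  expect_equal(panel$pooled$accuracy, 1)
  expect_equal(panel$pooled$f1, 1)
  expect_equal(panel$pooled$auc, 1)
})

test_that("evaluation is deterministic and refuses single-class training", {
  tab <- make_feature_table(6, 8, n_mci = 3, effect = 0.5, seed = 8)
  p1 <- classify_loso(tab, "ALL", n_trees = 50, seed = 2)
  p2 <- classify_loso(tab, "ALL", n_trees = 50, seed = 2)
  expect_identical(p1$per_fold, p2$per_fold)
  r1 <- regress_loso(tab, "ALL", n_trees = 50, seed = 2)
  r2 <- regress_loso(tab, "ALL", n_trees = 50, seed = 2)
  expect_identical(r1$pooled, r2$pooled)

  lonely <- make_feature_table(3, 5, n_mci = 2, seed = 9)  # one healthy subj
  expect_error(classify_loso(lonely, "ALL", n_trees = 20, seed = 1),
               "single class")

  # per-fold regression median error definition
  expect_equal(r1$per_fold$median_error,
               abs(r1$per_fold$median_pred - r1$per_fold$true_moca))
})
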
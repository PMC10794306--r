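test_that("rank-sum U matches exhaustive pair counting", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$U, 0)
  x <- 1:10
  expect_equal(rank_sum_test(x, x)$U, 50)  # n^2 / 2 under symmetry

  x <- c(1.1, 2.3, 3.1, 4.2); y <- c(0.9, 2.0, 3.0)
  expect_equal(rank_sum_test(x, y)$U, u_oracle(x, y))

  set.seed(3)
  for (r in 1:20) {
    a <- sample(1:8, 15, replace = TRUE)  # heavy ties
    b <- sample(1:8, 11, replace = TRUE)
    expect_equal(rank_sum_test(a, b)$U, u_oracle(a, b))
  }
  expect_error(rank_sum_test(numeric(0), 1:3), "nonempty")
})

test_that("CLES, AUC and U/(n1 n2) are the same number", {
  expect_equal(cles(4:6, 1:3), 1)
  expect_equal(cles(1:10, 1:10), 0.5)
  expect_equal(feature_auc(4:6, 1:3), 1)
  expect_equal(feature_auc(1:10, 1:10), 0.5)

  set.seed(14)
  for (r in 1:20) {
    x <- rnorm(20); y <- rnorm(20, 0.3)
    u <- rank_sum_test(x, y)$U
    expect_equal(cles(x, y), u / 400, tolerance = 1e-12)
    expect_equal(feature_auc(x, y), u / 400, tolerance = 1e-12)
  }
  # large-sample midrank path agrees with pair counting
  set.seed(15)
  x <- sample(1:50, 3000, replace = TRUE)
  y <- sample(5:55, 2000, replace = TRUE)
  direct <- (sum(outer(x[1:100], y, ">")) +
               0.5 * sum(outer(x[1:100], y, "=="))) / (100 * 2000)
  expect_equal(cles(x[1:100], y), direct, tolerance = 1e-12)
})

test_that("rank statistics transform as expected under relabeling", {
  set.seed(21)
  x <- rnorm(15); y <- rnorm(12, 0.5)
  expect_equal(cles(x, y), 1 - cles(y, x), tolerance = 1e-12)
  expect_equal(rank_sum_test(x, y)$p, rank_sum_test(y, x)$p,
               tolerance = 1e-12)
  # invariance under strictly monotone transforms of the pooled values
  expect_equal(rank_sum_test(x, y)$p, rank_sum_test(exp(x), exp(y))$p,
               tolerance = 1e-12)
  expect_equal(cles(x, y), cles(exp(x), exp(y)), tolerance = 1e-12)
})

test_that("comparison panel has the 6 x 3 layout and sane columns", {
  tab <- make_feature_table(6, 10, n_mci = 3, effect = 1, seed = 2)
  out <- compare_all(tab)
  expect_equal(nrow(out), 18)
  expect_setequal(unique(out$condition), c("TGT", "IGN", "ALL"))
  expect_setequal(unique(out$feature), tda_feature_names())
  expect_true(all(out$U >= 0 & out$U <= out$n_healthy * out$n_mci))
  expect_true(all(out$p_r >= 0 & out$p_r <= 1))
  expect_equal(out$cles, out$auc, tolerance = 1e-12)
  # ALL pools both conditions
  expect_equal(out$n_healthy[out$condition == "ALL"][1], 30)

  subj <- compare_all(tab, aggregate = "subject")
  expect_equal(subj$n_healthy[1] + subj$n_mci[1], 6)

  one <- make_feature_table(2, 2, n_mci = 1, seed = 3)  # 1 epoch/condition
  tiny <- compare_all(one)
  expect_true(all(is.finite(tiny$p_r)))

  expect_error(compare_all(tab[tab$group == "mci", ]), "both groups")
})

test_that("strong simulated effects reach significance in every condition", {
  feats <- recovery_fixture()$features
  out <- compare_all(feats)
  row <- out[out$feature == "max_persistence", ]
  expect_true(all(row$p_r < 0.01))
  expect_true(all(row$cles > 0.5))  # healthy loops persist longer
})
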
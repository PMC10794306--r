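test_that("Betti-1 curve counts simultaneously alive cycles", {
  disjoint <- data.frame(dimension = 1, birth = c(1, 3), death = c(2, 4))
  cv <- betti1_curve(disjoint)
  expect_equal(attr(cv, "max"), 1)
  expect_equal(betti_at(cv, c(0.5, 1, 1.9, 2, 3.5, 4)),
               c(0L, 1L, 1L, 0L, 1L, 0L))

  overlap <- data.frame(dimension = 1, birth = c(1, 2), death = c(3, 4))
  expect_equal(attr(betti1_curve(overlap), "max"), 2)

  empty <- data.frame(dimension = integer(0), birth = numeric(0),
                      death = numeric(0))
  cv0 <- betti1_curve(empty)
  expect_equal(attr(cv0, "max"), 0)
  expect_equal(betti_at(cv0, c(0, 10)), c(0L, 0L))

  # unit-square diagram: alive exactly on [1, sqrt(2))
  sq <- rips_diagram(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  cs <- betti1_curve(sq)
  expect_equal(attr(cs, "max"), 1)
  expect_equal(betti_at(cs, c(0.99, 1, 1.41, sqrt(2))), c(0L, 1L, 1L, 0L))
})

test_that("feature formulas match hand arithmetic", {
  sq <- rips_diagram(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  f <- compute_features(sq)
  expect_equal(unname(f["total_cycles"]), 1)
  expect_equal(unname(f["max_cycles"]), 1)
  expect_equal(unname(f["max_persistence"]), sqrt(2) - 1, tolerance = 1e-12)
  expect_equal(unname(f["npe"]), 0)
  expect_equal(unname(f["max_persistence_ratio"]), sqrt(2),
               tolerance = 1e-12)
  expect_equal(unname(f["median_persistence_ratio"]), sqrt(2),
               tolerance = 1e-12)

  # equal lifetimes saturate the normalized entropy
  eq <- data.frame(dimension = 1, birth = c(1, 2), death = c(2, 3))
  expect_equal(unname(compute_features(eq)["npe"]), 1, tolerance = 1e-12)

  # hand-computed three-interval diagram; with half-open intervals the
  # cycle dying at 2 is gone when the one born at 2 appears, so at most two
  # cycles coexist
  dg <- data.frame(dimension = 1, birth = c(1, 1, 2), death = c(2, 4, 3))
  f3 <- compute_features(dg)
  l <- c(1, 3, 1); p <- l / 5
  expect_equal(unname(f3["total_cycles"]), 3)
  expect_equal(unname(f3["max_cycles"]), 2)
  expect_equal(unname(f3["max_persistence"]), 3)
  expect_equal(unname(f3["npe"]), -sum(p * log(p)) / log(3),
               tolerance = 1e-12)
  expect_equal(unname(f3["max_persistence_ratio"]), 4)
  expect_equal(unname(f3["median_persistence_ratio"]), 2)

  none <- data.frame(dimension = 0, birth = 0, death = 1)
  expect_true(all(compute_features(none) == 0))
})

test_that("feature invariants hold on random diagrams", {
  set.seed(12)
  for (r in 1:50) {
    k <- sample(0:20, 1)
    b <- sort(runif(k, 0.1, 2))
    dg <- data.frame(dimension = rep(1, k), birth = b,
                     death = b + runif(k, 1e-3, 2))
    f <- compute_features(dg)
    expect_lte(f[["max_cycles"]], f[["total_cycles"]])
    expect_gte(f[["npe"]], 0); expect_lte(f[["npe"]], 1 + 1e-12)
    if (k <= 1) expect_equal(unname(f["npe"]), 0)
    expect_lte(f[["median_persistence_ratio"]],
               f[["max_persistence_ratio"]] + 1e-12)
    if (k > 0) expect_gte(f[["max_persistence_ratio"]], 1)
  }
})

test_that("extract_features produces one labelled row per epoch", {
  study <- tiny_study_fixture()
  meta <- study$participants[1, ]
  es <- preprocess_recording(study$recordings[[meta$subject_id]],
                             emd = FALSE)
  tab <- extract_features(es, meta = meta)
  expect_equal(nrow(tab), length(es$epochs))
  expect_equal(unique(tab$subject_id), meta$subject_id)
  expect_equal(unique(tab$group), meta$group)
  expect_true(all(tda_feature_names() %in% names(tab)))
  expect_true(all(is.finite(as.matrix(tab[, tda_feature_names()]))))
})
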
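test_that("fold assignment partitions the records", {
  folds <- t2dbn:::cv_folds(103L, 10L, seed = 21)
  expect_length(folds, 103L)
  expect_setequal(unique(folds), 1:10)
  expect_true(all(table(folds) %in% c(10L, 11L)))
  expect_identical(folds, t2dbn:::cv_folds(103L, 10L, seed = 21))
  expect_error(t2dbn:::cv_folds(5L, 10L), "n >= k")
})

test_that("CV loss on a fair coin converges to ln 2 and ignores column order", {
  set.seed(1001)
  v <- categorical_variable("X", c("h", "t"))
  coh <- as_cohort(data.frame(X = sample(c("h", "t"), 4000, replace = TRUE)),
                   list(X = v))
  cv <- cross_validate(coh, k = 10L, seed = 1)
  expect_equal(cv$expected_loss, log(2), tolerance = 0.01)
  expect_equal(cv$expected_loss,
               sum(cv$fold_losses * cv$fold_sizes) / sum(cv$fold_sizes))

  # for a fixed structure the loss does not depend on column order
  dat <- generate_cohort(1200, seed = 3)
  g <- ground_truth_dag()
  l1 <- cross_validate(dat, k = 5L, relearn_structure = FALSE,
                       structure = g, seed = 7)$expected_loss
  perm <- dat[, rev(names(dat))]
  attr(perm, "variables") <- rev(attr(dat, "variables"))
  class(perm) <- class(dat)
  l2 <- cross_validate(perm, k = 5L, relearn_structure = FALSE,
                       structure = g, seed = 7)$expected_loss
  expect_equal(l1, l2, tolerance = 1e-9)
})

test_that("expected loss weakly decreases with training size", {
  net <- ground_truth_network()
  for (seed in 1:3) {
    dat <- generate_cohort(6000, seed = 100 + seed)
    small <- dat[1:1500, , drop = FALSE]
    attr(small, "variables") <- attr(dat, "variables")
    class(small) <- class(dat)
    l_small <- cross_validate(small, k = 5L, relearn_structure = FALSE,
                              structure = net$dag, seed = seed)$expected_loss
    l_big <- cross_validate(dat, k = 5L, relearn_structure = FALSE,
                            structure = net$dag, seed = seed)$expected_loss
    expect_lte(l_big, l_small + 0.01)
  }
})

test_that("midrank AUC equals the pairwise-comparison oracle, ties included", {
  set.seed(1002)
  for (rep in 1:20) {
    n <- sample(10:60, 1L)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    labels <- stats::runif(n) < 0.4
    if (!any(labels) || all(labels)) {
      expect_true(is.na(auc_midrank(scores, labels)))
      next
    }
    expect_equal(auc_midrank(scores, labels), auc_pairwise(scores, labels),
                 tolerance = 1e-9)
  }
  expect_equal(auc_midrank(c(0.9, 0.8, 0.1), c(TRUE, FALSE, FALSE)), 1)
})

test_that("feature scores: determinism, independence and binary symmetry", {
  set.seed(1003)
  # B is a deterministic copy of A; C is independent noise
  n <- 4000L
  a <- sample(c("a1", "a2"), n, replace = TRUE)
  df <- data.frame(A = a, B = ifelse(a == "a1", "b1", "b2"),
                   C = sample(c("c1", "c2"), n, replace = TRUE),
                   stringsAsFactors = FALSE)
  coh <- toy_cohort(df)
  fs <- feature_scores(coh, k = 5L, seed = 9)
  b_rows <- fs[fs$variable == "B", ]
  expect_true(all(b_rows$auc > 0.999))
  expect_equal(b_rows$accuracy[1L], 100)
  c_rows <- fs[fs$variable == "C", ]
  expect_lt(max(abs(c_rows$auc - 0.5)), 0.05)
  # one-vs-rest symmetry for binary variables
  for (v in c("A", "B", "C")) {
    two <- fs$auc[fs$variable == v]
    expect_equal(two[1L], two[2L], tolerance = 1e-6)
    expect_length(unique(fs$accuracy[fs$variable == v]), 1L)
  }
})

test_that("held-out posteriors from the fast path equal full inference", {
  set.seed(1004)
  bn <- random_bn(random_dag(5L, p_edge = 0.5))
  s <- forward_sample(bn, 30, seed = 2)
  for (v in names(bn$variables)) {
    fast <- t2dbn:::record_posteriors(bn, s, v)
    for (i in 1:5) {
      ev <- vapply(setdiff(names(s), v), function(u) as.character(s[[u]][i]), "")
      expect_equal(unname(fast[i, ]), unname(unclass(posterior(bn, v, ev))),
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
})
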
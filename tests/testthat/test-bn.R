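test_that("CPT construction validates distributions and row ordering", {
  v <- categorical_variable("X", c("x1", "x2"))
  p <- categorical_variable("P", c("p1", "p2", "p3"))
  expect_error(cpt(v, list(), c(0.5, 0.6)), "sum to 1")
  expect_error(cpt(v, list(), c(-0.1, 1.1)), "\\[0, 1\\]")
  expect_error(cpt(v, list(), c(0.5, 0.5), rows = diag(2)), "exactly one")
  # canonical rows: first parent slowest, matches the printed-table layout
  rows <- rbind(c(0.1, 0.9), c(0.2, 0.8), c(0.3, 0.7))
  ct <- cpt(v, list(p), rows = rows)
  expect_equal(unname(cpt_rows(ct)), rows)
  expect_equal(unname(ct$prob[, 2L]), c(0.2, 0.8))
})

test_that("the chain rule reproduces the worked-example joint probability", {
  net <- four_node_example()
  p <- joint_probability(net, c(AGE = "18-32", PA = "no",
                                DIET = "no", T2D = "no"))
  expect_equal(p, 0.1281 * 0.3727 * 0.8563 * 0.7625, tolerance = 1e-12)
  expect_error(joint_probability(net, c(AGE = "18-32")), "every node")
  expect_error(joint_probability(net, c(AGE = "young", PA = "no",
                                        DIET = "no", T2D = "no")),
               "not a state")
  # single binary node
  yes <- categorical_variable("Q", c("yes", "no"))
  single <- bayes_net(list(Q = yes), dag("Q"),
                      list(Q = cpt(yes, list(), c(0.3, 0.7))))
  expect_equal(joint_probability(single, c(Q = "yes")), 0.3)
})

test_that("joint probabilities over all assignments sum to one", {
  set.seed(501)
  for (rep in 1:5) {
    bn <- random_bn(random_dag(sample(3:5, 1L)))
    grid <- all_assignments(bn)
    total <- sum(vapply(seq_len(nrow(grid)), function(i)
      joint_probability(bn, unlist(grid[i, , drop = FALSE])), 1.0))
    expect_equal(total, 1, tolerance = 1e-9)
  }
})

test_that("forward sampling is seeded, reproducible and consistent", {
  net <- four_node_example()
  s1 <- forward_sample(net, 200, seed = 9)
  s2 <- forward_sample(net, 200, seed = 9)
  expect_identical(s1, s2)
  expect_false(identical(s1, forward_sample(net, 200, seed = 10)))

  # degenerate CPTs give identical records
  a <- categorical_variable("A", c("a1", "a2"))
  b <- categorical_variable("B", c("b1", "b2"))
  det <- bayes_net(list(A = a, B = b), dag(c("A", "B"), rbind(c("A", "B"))),
                   list(A = cpt(a, list(), c(1, 0)),
                        B = cpt(b, list(a), array(c(0, 1, 1, 0), c(2, 2)))))
  s <- forward_sample(det, 25, seed = 1)
  expect_true(all(s$A == "a1" & s$B == "b2"))

  # marginal frequency within 3 standard errors of the example prior
  s <- forward_sample(net, 1e5, seed = 42)
  se <- sqrt(0.1281 * (1 - 0.1281) / 1e5)
  expect_lt(abs(mean(s$AGE == "18-32") - 0.1281), 3 * se)
})

test_that("sampled joint frequencies pass a goodness-of-fit test", {
  set.seed(502)
  bn <- random_bn(random_dag(3L, p_edge = 0.6))
  s <- forward_sample(bn, 1e5, seed = 7)
  grid <- all_assignments(bn)
  probs <- vapply(seq_len(nrow(grid)), function(i)
    joint_probability(bn, unlist(grid[i, , drop = FALSE])), 1.0)
  key <- do.call(paste, c(lapply(s, as.character), sep = "|"))
  gkey <- do.call(paste, c(grid, sep = "|"))
  counts <- as.numeric(table(factor(key, levels = gkey)))
  keep <- probs > 1e-12
  gof <- stats::chisq.test(counts[keep], p = probs[keep] / sum(probs[keep]))
  expect_gt(gof$p.value, 0.001)
})

test_that("log-likelihood decomposes and matches the per-record joints", {
  net <- four_node_example()
  one <- forward_sample(net, 1, seed = 3)
  expect_equal(log_likelihood(net, one),
               log(joint_probability(net, vapply(one, as.character, ""))))
  s <- forward_sample(net, 500, seed = 4)
  per <- log_likelihood(net, s, per_record = TRUE)
  expect_equal(sum(per), log_likelihood(net, s))
  # decomposability: per-node family scores add up to the total
  codes <- t2dbn:::cohort_codes(s)
  fam <- 0
  for (v in names(net$variables)) {
    ct <- net$cpts[[v]]
    fam <- fam + sum(log(as.vector(ct$prob)[t2dbn:::family_index(ct, codes)]))
  }
  expect_equal(fam, log_likelihood(net, s), tolerance = 1e-9)
})

test_that("per-record mean log-likelihood approaches the joint entropy", {
  set.seed(503)
  bn <- random_bn(random_dag(3L, p_edge = 0.6))
  s <- forward_sample(bn, 2e5, seed = 8)
  avg <- -log_likelihood(bn, s) / nrow(s)
  expect_equal(avg, network_entropy(bn), tolerance = 0.02)
})

test_that("cpt_lookup returns stored rows and rejects partial assignments", {
  net <- four_node_example()
  expect_equal(unname(cpt_lookup(net, "PA", c(AGE = "18-32"))["no"]),
               0.3727)
  expect_equal(sum(cpt_lookup(net, "T2D", c(AGE = "33-47", DIET = "yes"))), 1)
  expect_error(cpt_lookup(net, "T2D", c(AGE = "33-47")), "partial|missing")
  expect_error(cpt_lookup(net, "T2D", c(AGE = "33-47", DIET = "yes",
                                        PA = "no")), "not parents")
  expect_equal(unname(cpt_lookup(net, "AGE")["18-32"]), 0.1281)
})
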
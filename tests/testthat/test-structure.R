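test_that("the four-block scheme forbids exactly the backward arcs", {
  bl <- blacklist_from_blocks(t2d_blocks())
  expect_identical(nrow(bl), 51L)            # 12+12+3+16+4+4 backward pairs
  keys <- paste(bl[, "from"], bl[, "to"])
  expect_true("T2D AGE" %in% keys)           # diagnostic -> background
  expect_false("GENDER T2D" %in% keys)       # forward arcs stay admissible
  expect_false("SMOKING PA" %in% keys)       # within-block arcs stay admissible
  # one block: nothing forbidden
  expect_identical(nrow(blacklist_from_blocks(list(c("A", "B", "C")))), 0L)
  expect_error(blacklist_from_blocks(list("A"), variables = c("A", "B")),
               "no block")
  expect_error(blacklist_from_blocks(list(c("A", "B"), c("B"))), "disjoint")
})

test_that("the AIC score has its closed form and decomposes", {
  v <- categorical_variable("X", c("yes", "no"))
  coh <- as_cohort(data.frame(X = c("yes", "yes", "no", "no")), list(X = v))
  expect_equal(aic_score(empty_dag("X"), coh), 4 * log(0.5) - 1,
               tolerance = 1e-12)
  expect_error(aic_score(empty_dag("X"), coh[0, , drop = FALSE]),
               "at least one record|empty")

  # family-wise decomposition equals the monolithic score on random data
  set.seed(701)
  bn <- random_bn(random_dag(4L, p_edge = 0.5))
  s <- forward_sample(bn, 400, seed = 1)
  g <- bn$dag
  codes <- t2dbn:::cohort_codes(s)
  card <- lapply(s, nlevels)
  fam_sum <- sum(vapply(g$nodes, function(nd)
    t2dbn:::family_score(codes, nd, parents(g, nd), card, 1), 1.0))
  expect_equal(fam_sum, aic_score(g, s), tolerance = 1e-9)

  # the true structure out-scores the empty graph under strong dependence
  set.seed(702)
  coh2 <- strong_ab_cohort(5000)
  g_true <- dag(c("A", "B"), rbind(c("A", "B")))
  expect_gt(aic_score(g_true, coh2), aic_score(empty_dag(c("A", "B")), coh2))
})

test_that("hill climbing finds the arc, honours the blacklist, stays local-optimal", {
  # single variable: empty graph
  v <- categorical_variable("X", c("a", "b"))
  coh1 <- as_cohort(data.frame(X = rep(c("a", "b"), 10)), list(X = v))
  expect_identical(nrow(arcs(hill_climb(coh1))), 0L)

  set.seed(703)
  coh <- strong_ab_cohort(10000)
  bl <- structure(cbind(from = "B", to = "A"), class = c("blacklist", "matrix"))
  g <- hill_climb(coh, blacklist = bl)
  expect_identical(arcs(g), cbind(from = "A", to = "B"))
  expect_error(hill_climb(coh, blacklist = bl,
                          start = dag(c("A", "B"), rbind(c("B", "A")))),
               "blacklisted")

  # every accepted output is a strict local optimum over one-arc edits
  set.seed(704)
  for (rep in 1:4) {
    bn <- random_bn(random_dag(sample(3:5, 1L), p_edge = 0.5))
    s <- forward_sample(bn, 800, seed = rep)
    g <- hill_climb(s)
    base <- aic_score(g, s)
    nodes <- g$nodes
    for (from in nodes) for (to in setdiff(nodes, from)) {
      if (!g$amat[from, to]) {
        cand <- tryCatch(add_arc(g, from, to), error = function(e) NULL)
        if (!is.null(cand)) expect_lte(aic_score(cand, s), base + 1e-9)
      } else {
        expect_lte(aic_score(drop_arc(g, from, to), s), base + 1e-9)
        cand <- tryCatch(reverse_arc(g, from, to), error = function(e) NULL)
        if (!is.null(cand)) expect_lte(aic_score(cand, s), base + 1e-9)
      }
    }
  }
})

test_that("bootstrap arc strengths are frequencies with coherent directions", {
  set.seed(705)
  coh <- strong_ab_cohort(10000)
  # one replicate: strengths are exactly the learned network's arcs
  s1 <- bootstrap_arc_strength(coh, replicates = 1L, seed = 31)
  expect_true(all(s1$strength %in% c(0, 1)))
  s100 <- bootstrap_arc_strength(coh, replicates = 100L, seed = 32)
  ab <- s100[s100$from == "A" & s100$to == "B", ]
  expect_gte(ab$strength, 0.95)
  ba <- s100[s100$from == "B" & s100$to == "A", ]
  expect_identical(ba$strength, ab$strength)   # same undirected denominator
  expect_equal(ab$direction_prob + ba$direction_prob, 1)
  # determinism
  expect_identical(s100, bootstrap_arc_strength(coh, replicates = 100L, seed = 32))
})

test_that("the averaged network thresholds, orients and stays acyclic", {
  set.seed(706)
  coh <- strong_ab_cohort(10000)
  s <- bootstrap_arc_strength(coh, replicates = 50L, seed = 33)
  expect_identical(arcs(averaged_network(s, threshold = 0.85)),
                   cbind(from = "A", to = "B"))
  # all strengths below the threshold: empty graph
  weak <- s; weak$strength <- pmin(weak$strength, 0.5)
  expect_identical(nrow(arcs(averaged_network(weak, threshold = 0.85))), 0L)
  # synthetic strength table with a would-be cycle: weakest arc dropped
  st <- data.frame(from = c("A", "B", "C", "B", "C", "A"),
                   to   = c("B", "C", "A", "A", "B", "C"),
                   strength = c(0.99, 0.95, 0.90, 0.99, 0.95, 0.90),
                   direction_prob = c(1, 1, 1, 0, 0, 0))
  attr(st, "nodes") <- c("A", "B", "C")
  class(st) <- c("arc_strength", "data.frame")
  g <- averaged_network(st, threshold = 0.85)
  expect_false(t2dbn:::has_cycle(g))
  expect_identical(nrow(arcs(g)), 2L)
})
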
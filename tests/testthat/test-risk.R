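test_that("Markov-blanket ranking matches a joint-enumeration oracle", {
  set.seed(901)
  bn <- random_bn(random_dag(4L, p_edge = 0.6))
  target <- names(bn$variables)[2L]
  ts <- bn$variables[[target]]$states[1L]
  rk <- rank_markov_blanket(bn, target, ts)
  expect_equal(attr(rk, "baseline"),
               unname(enum_posterior(bn, target)[ts]), tolerance = 1e-9)
  for (i in seq_len(nrow(rk))) {
    v <- rk$variable[i]
    best <- vapply(bn$variables[[v]]$states, function(s)
      unname(enum_posterior(bn, target,
                            stats::setNames(s, v))[ts]), 1.0)
    expect_equal(rk$posterior[i], max(best), tolerance = 1e-9)
    expect_identical(rk$state[i], names(best)[which.max(best)])
  }
  expect_identical(rk$posterior, sort(rk$posterior, decreasing = TRUE))
  expect_identical(rk$rank, seq_len(nrow(rk)))
})

test_that("a target with empty Markov blanket yields an empty ranking", {
  a <- categorical_variable("A", c("a1", "a2"))
  b <- categorical_variable("B", c("b1", "b2"))
  iso <- bayes_net(list(A = a, B = b), dag(c("A", "B")),
                   list(A = cpt(a, list(), c(0.4, 0.6)),
                        B = cpt(b, list(), c(0.7, 0.3))))
  rk <- rank_markov_blanket(iso, "B", "b1")
  expect_identical(nrow(rk), 0L)
  expect_equal(attr(rk, "baseline"), 0.7, tolerance = 1e-12)
})

test_that("trajectories are internally coherent with single-shot posteriors", {
  net <- ground_truth_network()
  steps <- c(BMI = "Obesity", HbA1c = "More 6.0", FLI = "More 60")
  tr <- stepwise_trajectory(net, "T2D", "Yes", steps)
  expect_identical(tr$step, 0:3)
  expect_equal(tr$posterior[1L], unname(posterior(net, "T2D")["Yes"]),
               tolerance = 1e-12)
  for (k in seq_along(steps))
    expect_equal(tr$posterior[k + 1L],
                 unname(posterior(net, "T2D", steps[seq_len(k)])["Yes"]),
                 tolerance = 1e-12)
  # empty plan: just the baseline
  base <- stepwise_trajectory(net, "T2D", "Yes", character(0))
  expect_identical(nrow(base), 1L)
  expect_error(stepwise_trajectory(net, "T2D", "Yes",
                                   c(BMI = "Obesity", BMI = "Obesity")),
               "distinct")
  expect_error(stepwise_trajectory(net, "T2D", "Yes", c(T2D = "No")),
               "target")
})

test_that("inference errors inside a trajectory carry the step index", {
  a <- categorical_variable("A", c("a1", "a2"))
  b <- categorical_variable("B", c("b1", "b2"))
  det <- bayes_net(list(A = a, B = b), dag(c("A", "B"), rbind(c("A", "B"))),
                   list(A = cpt(a, list(), c(1, 0)),
                        B = cpt(b, list(a), array(c(0, 1, 1, 0), c(2, 2)))))
  expect_error(stepwise_trajectory(det, "B", "b1", c(A = "a2")),
               "at step 1.*inconsistent")
})

test_that("scenario comparison respects d-separation and the baseline", {
  net <- ground_truth_network()
  # SOCIALs is d-separated from T2D given AGE and GENDER (AGE alone would
  # open the SOCIALs -> AGE <- GENDER collider)
  expect_true(d_separated(net$dag, "SOCIALs", "T2D", c("AGE", "GENDER")))
  sc <- scenario_compare(net, "T2D", "Yes", list(
    low = c(AGE = "18-32", GENDER = "Men", SOCIALs = "I"),
    high = c(AGE = "18-32", GENDER = "Men", SOCIALs = "III"),
    empty = character(0)))
  expect_equal(sc$posterior[1L], sc$posterior[2L], tolerance = 1e-9)
  expect_equal(sc$posterior[3L], unname(posterior(net, "T2D")["Yes"]),
               tolerance = 1e-12)
  expect_error(scenario_compare(net, "T2D", "Yes", list(c(AGE = "18-32"))),
               "named")
})

test_that("diet improves the outlook and the packaged plans run end to end", {
  net <- ground_truth_network()
  sc <- scenario_compare(net, "T2D", "Yes",
                         list(no_diet = c(DIET = "No"),
                              diet = c(DIET = "Yes")))
  expect_gt(sc$posterior[sc$scenario == "no_diet"],
            sc$posterior[sc$scenario == "diet"])
  plans <- risk_step_plans()
  expect_setequal(names(plans),
                  c("age", "bmi", "pa", "fli", "hba1c", "diet"))
  trs <- run_step_plan(net, plans$bmi)
  expect_length(trs, 4L)                       # one branch per BMI state
  # the obesity branch of the adiposity-first plan is monotone nondecreasing
  expect_true(all(diff(trs$Obesity$posterior) >= -1e-12))
})
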
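test_that("variable elimination matches joint enumeration on random networks", {
  set.seed(601)
  for (rep in 1:30) {
    bn <- random_bn(random_dag(sample(3:6, 1L), p_edge = 0.4))
    nodes <- names(bn$variables)
    target <- sample(nodes, 1L)
    n_ev <- sample(0:min(2L, length(nodes) - 1L), 1L)
    ev_vars <- sample(setdiff(nodes, target), n_ev)
    ev <- vapply(ev_vars, function(v) sample(bn$variables[[v]]$states, 1L), "")
    ref <- enum_posterior(bn, target, ev)
    got <- posterior(bn, target, if (length(ev)) ev else NULL)
    expect_equal(unclass(got), ref, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("posteriors are invariant to the elimination order", {
  set.seed(602)
  bn <- random_bn(random_dag(6L, p_edge = 0.45))
  nodes <- names(bn$variables)
  target <- nodes[2L]
  ev <- stats::setNames(bn$variables[[nodes[5L]]]$states[1L], nodes[5L])
  eliminate <- setdiff(nodes, c(target, names(ev)))
  ref <- posterior(bn, target, ev)
  for (rep in 1:8) {
    ord <- sample(eliminate)
    expect_equal(unclass(posterior(bn, target, ev, order = ord)),
                 unclass(ref), tolerance = 1e-9)
  }
  expect_error(posterior(bn, target, ev, order = eliminate[-1L]), "exactly")
})

test_that("conditioning on all parents reproduces the CPT row exactly", {
  set.seed(603)
  for (rep in 1:5) {
    bn <- random_bn(random_dag(5L, p_edge = 0.5))
    v <- sample(names(bn$variables), 1L)
    pars <- parents(bn$dag, v)
    if (!length(pars)) next
    ev <- vapply(pars, function(p) sample(bn$variables[[p]]$states, 1L), "")
    expect_equal(unclass(posterior(bn, v, ev)), cpt_lookup(bn, v, ev),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # no evidence on a root gives its prior row
  net <- four_node_example()
  expect_equal(unclass(posterior(net, "AGE")), cpt_lookup(net, "AGE"),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("evidence on a d-separated variable leaves the posterior unchanged", {
  set.seed(604)
  checked <- 0L
  for (rep in 1:20) {
    bn <- random_bn(random_dag(6L, p_edge = 0.35))
    nodes <- names(bn$variables)
    pick <- sample(nodes, 2L)
    x <- pick[1L]; y <- pick[2L]
    z <- setdiff(nodes, c(x, y))
    z <- z[stats::runif(length(z)) < 0.5]
    if (!d_separated(bn$dag, x, y, z)) next
    ev_z <- vapply(z, function(v) sample(bn$variables[[v]]$states, 1L), "")
    base <- posterior(bn, x, if (length(ev_z)) ev_z else NULL)
    for (s in bn$variables[[y]]$states) {
      ev <- c(ev_z, stats::setNames(s, y))
      p_ev <- tryCatch(posterior(bn, x, ev), error = function(e) NULL)
      if (is.null(p_ev)) next                 # zero-probability evidence
      expect_equal(unclass(p_ev), unclass(base), tolerance = 1e-9,
                   ignore_attr = TRUE)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 10L)
})

test_that("inconsistent and malformed evidence raise informative errors", {
  a <- categorical_variable("A", c("a1", "a2"))
  b <- categorical_variable("B", c("b1", "b2"))
  det <- bayes_net(list(A = a, B = b), dag(c("A", "B"), rbind(c("A", "B"))),
                   list(A = cpt(a, list(), c(1, 0)),
                        B = cpt(b, list(a), array(c(0, 1, 1, 0), c(2, 2)))))
  expect_error(posterior(det, "B", c(A = "a2")), "inconsistent evidence")
  expect_error(posterior(det, "B", c(B = "b1")), "carries evidence")
  expect_error(posterior(det, "B", c(Q = "q1")), "unknown variable")
  expect_error(posterior(det, "B", c(A = "zz")), "not a state")
})

test_that("most_probable_state takes the argmax with declared-order ties", {
  net <- four_node_example()
  expect_identical(most_probable_state(net, "T2D",
                                       c(AGE = "18-32", DIET = "no")), "no")
  # exact tie resolves to the first declared state
  a <- categorical_variable("A", c("first", "second"))
  even <- bayes_net(list(A = a), dag("A"),
                    list(A = cpt(a, list(), c(0.5, 0.5))))
  expect_identical(most_probable_state(even, "A"), "first")
  # degenerate posterior
  sure <- bayes_net(list(A = a), dag("A"),
                    list(A = cpt(a, list(), c(1, 0))))
  expect_identical(most_probable_state(sure, "A"), "first")
})
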
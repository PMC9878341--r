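# Bayesian parameter estimation under a uniform Dirichlet prior.

#' Fit all conditional probability tables by Bayesian estimation
#'
#' For a fixed DAG, each CPT entry is the posterior mean under a uniform
#' Dirichlet prior with total equivalent sample size `iss` spread over the
#' node's whole table:
#' \deqn{\hat\theta_{ijk} = \frac{n_{ijk} + iss/(r_i q_i)}{n_{ij} + iss/q_i}}
#' where \eqn{r_i} is the child cardinality and \eqn{q_i} the number of
#' parent configurations. Every fitted entry is strictly positive, so a
#' fitted network never assigns probability zero to an observable record.
#' As `iss` tends to 0 the estimate tends to the maximum-likelihood
#' frequencies wherever \eqn{n_{ij} > 0}; with `iss` equal to the table cell
#' count it is Laplace add-one smoothing.
#'
#' @param g A [dag()].
#' @param data Cohort table over the DAG's variables; missing values are an
#'   error (complete-case analysis).
#' @param iss Equivalent sample size of the Dirichlet prior (> 0, default 1:
#'   a single imaginary observation spread uniformly).
#' @return A fitted [bayes_net()].
#' @examples
#' net <- ground_truth_network()
#' dat <- generate_cohort(2000, seed = 1)
#' fit <- fit_bayes(net$dag, dat)
#' @export
fit_bayes <- function(g, data, iss = 1) {
  stopifnot(iss > 0)
  variables <- cohort_variables(data)
  data <- as_cohort(data, variables)
  if (!setequal(names(data), g$nodes))
    stop("data columns do not match DAG nodes")
  codes <- cohort_codes(data)
  card <- lapply(data, nlevels)
  cpts <- lapply(g$nodes, function(v) {
    pars <- parents(g, v)
    r <- card[[v]]
    q <- prod(unlist(card[pars], use.names = FALSE), 1)
    idx <- codes[, v]
    mult <- r
    for (p in pars) {
      idx <- idx + mult * (codes[, p] - 1L)
      mult <- mult * card[[p]]
    }
    counts <- matrix(tabulate(idx, nbins = r * q), nrow = r)
    nij <- rep(colSums(counts), each = r)
    prob <- (counts + iss / (r * q)) / matrix(nij + iss / q, nrow = r)
    cpt(variables[[v]], variables[pars], array(prob, dim = c(r, unlist(card[pars]))))
  })
  names(cpts) <- g$nodes
  bayes_net(variables, g, cpts)
}
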
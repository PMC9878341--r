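# The didactic four-node network: AGE -> PA -> DIET -> T2D with AGE -> T2D.
#
# Only four of its CPT entries are pinned:
#   P(AGE = 18-32)                      = 0.1281
#   P(PA = no | AGE = 18-32)            = 0.3727
#   P(DIET = no | PA = no)              = 0.8563
#   P(T2D = no | AGE = 18-32, DIET = no) = 0.7625
# All remaining entries are free. Queries whose answer is implied by the
# pinned entries alone — e.g. P(T2D = no | AGE = 18-32, DIET = no, PA = no),
# where the extra PA evidence is irrelevant by d-separation — are invariant
# to the completion, which `completion = "random"` makes easy to verify.

#' The four-node worked-example network
#'
#' @param completion `"default"` for a fixed plausible completion of the
#'   unpinned CPT entries, `"random"` for a random valid completion (useful
#'   to demonstrate that d-separation-justified queries do not depend on the
#'   free entries).
#' @param seed Seed for `completion = "random"`.
#' @return A `bn` over AGE, PA, DIET, T2D.
#' @examples
#' net <- four_node_example()
#' posterior(net, "T2D", c(AGE = "18-32", DIET = "no"))["no"]  # 0.7625
#' @export
four_node_example <- function(completion = c("default", "random"),
                              seed = NULL) {
  completion <- match.arg(completion)
  age  <- categorical_variable("AGE",  c("18-32", "33-47", "48-62"))
  pa   <- categorical_variable("PA",   c("yes", "no"))
  diet <- categorical_variable("DIET", c("yes", "no"))
  t2d  <- categorical_variable("T2D",  c("yes", "no"))
  g <- dag(c("AGE", "PA", "DIET", "T2D"),
           rbind(c("AGE", "PA"), c("PA", "DIET"),
                 c("DIET", "T2D"), c("AGE", "T2D")))
  free <- local_seed(seed, {
    if (completion == "default")
      list(age_rest = c(0.45, 0.55), pa_no = c(0.52, 0.66),
           diet_no_given_pa_yes = 0.35,
           t2d_no = c(0.95, 0.80, 0.70, 0.55, 0.40))
    else
      list(age_rest = {
        u <- stats::runif(2); u / sum(u)
      }, pa_no = stats::runif(2), diet_no_given_pa_yes = stats::runif(1),
      t2d_no = stats::runif(5))
  })
  age_p <- c(0.1281, (1 - 0.1281) * free$age_rest)
  pa_no <- c(0.3727, free$pa_no)               # per AGE state
  diet_no <- c(free$diet_no_given_pa_yes, 0.8563)  # per PA state
  # T2D | AGE, DIET: internal order AGE fastest; pinned entry (18-32, no)
  t2d_no <- rep(NA_real_, 6)
  t2d_no[c(1, 2, 3)] <- free$t2d_no[1:3]       # DIET = yes, AGE = 1..3
  t2d_no[4] <- 0.7625                          # DIET = no, AGE = 18-32
  t2d_no[5:6] <- free$t2d_no[4:5]
  cpts <- list(
    AGE  = cpt(age, list(), age_p),
    PA   = cpt(pa, list(age), array(rbind(1 - pa_no, pa_no), dim = c(2, 3))),
    DIET = cpt(diet, list(pa), array(rbind(1 - diet_no, diet_no), dim = c(2, 2))),
    T2D  = cpt(t2d, list(age, diet),
               array(rbind(1 - t2d_no, t2d_no), dim = c(2, 3, 2))))
  bayes_net(list(AGE = age, PA = pa, DIET = diet, T2D = t2d), g, cpts)
}
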
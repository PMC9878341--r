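# Risk-factor analysis on a fitted network: Markov-blanket ranking,
# stepwise evidence trajectories and free-form scenario comparison.

#' Rank Markov-blanket variables by single-evidence risk
#'
#' For each variable in the Markov blanket of `target`, computes the
#' posterior of `target_state` under single evidence on every state of that
#' variable, records the maximizing state, and ranks the blanket variables by
#' that maximized posterior (descending). The no-evidence prior of
#' `target_state` is reported as the baseline. Ties in the maximizing state
#' go to the earlier declared state; ties in the ranking are broken
#' alphabetically by variable name.
#'
#' @param bn A `bn`.
#' @param target Node name (e.g. `"T2D"`).
#' @param target_state State of `target` whose probability is maximized
#'   (e.g. `"Yes"`).
#' @return Data frame of class `mb_ranking` with columns `rank`, `variable`,
#'   `state`, `posterior`; attribute `baseline`.
#' @examples
#' rank_markov_blanket(ground_truth_network(), "T2D", "Yes")
#' @export
rank_markov_blanket <- function(bn, target, target_state) {
  check_node(bn$dag, target)
  if (!target_state %in% bn$variables[[target]]$states)
    stop("'", target_state, "' is not a state of ", target)
  baseline <- unname(posterior(bn, target)[target_state])
  blanket <- markov_blanket(bn$dag, target)
  rows <- lapply(blanket, function(v) {
    states <- bn$variables[[v]]$states
    post <- vapply(states, function(s)
      unname(posterior(bn, target, stats::setNames(s, v))[target_state]), 1.0)
    best <- which.max(post)                     # first max: declared-order tie
    data.frame(variable = v, state = states[best], posterior = post[best],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(variable = character(0), state = character(0),
                      posterior = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(-out$posterior, out$variable), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "baseline") <- baseline
  attr(out, "target") <- target
  attr(out, "target_state") <- target_state
  class(out) <- c("mb_ranking", "data.frame")
  out
}

#' @export
print.mb_ranking <- function(x, ...) {
  cat(sprintf("Markov-blanket ranking for %s = %s (baseline %.4f)\n",
              attr(x, "target"), attr(x, "target_state"), attr(x, "baseline")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Stepwise evidence trajectory
#'
#' Accumulates evidence one step at a time and records the posterior of
#' `target_state` after each step; step 0 is the no-evidence prior. The
#' value at step k equals an independent [posterior()] call under the union
#' of the evidence of steps 1..k.
#'
#' @param bn A `bn`.
#' @param target,target_state As in [rank_markov_blanket()].
#' @param steps Named character vector (or list) of evidence in instantiation
#'   order, e.g. `c(BMI = "Obesity", HbA1c = "More 6.0")`. Variables must be
#'   distinct and different from `target`.
#' @param branch Optional label for the trajectory (conventionally the state
#'   fixed at step 1).
#' @return Data frame of class `trajectory` with columns `step`, `variable`,
#'   `state`, `posterior`.
#' @examples
#' net <- ground_truth_network()
#' stepwise_trajectory(net, "T2D", "Yes",
#'                     c(BMI = "Obesity", HbA1c = "More 6.0"))
#' @export
stepwise_trajectory <- function(bn, target, target_state, steps,
                                branch = NULL) {
  steps <- unlist(steps)
  if (length(steps) && anyDuplicated(names(steps)))
    stop("step variables must be distinct")
  if (target %in% names(steps)) stop("steps must not instantiate the target")
  out <- data.frame(step = 0L, variable = "", state = "",
                    posterior = unname(posterior(bn, target)[target_state]),
                    stringsAsFactors = FALSE)
  for (k in seq_along(steps)) {
    ev <- steps[seq_len(k)]
    p <- tryCatch(posterior(bn, target, ev),
                  error = function(e)
                    stop("at step ", k, " (", names(steps)[k], "=", steps[k],
                         "): ", conditionMessage(e), call. = FALSE))
    out <- rbind(out, data.frame(step = k, variable = names(steps)[k],
                                 state = unname(steps[k]),
                                 posterior = unname(p[target_state]),
                                 stringsAsFactors = FALSE))
  }
  attr(out, "target") <- target
  attr(out, "target_state") <- target_state
  attr(out, "branch") <- branch
  class(out) <- c("trajectory", "data.frame")
  out
}

#' @export
print.trajectory <- function(x, ...) {
  br <- attr(x, "branch")
  cat(sprintf("Trajectory of P(%s = %s)%s\n", attr(x, "target"),
              attr(x, "target_state"),
              if (is.null(br)) "" else paste0(" [branch ", br, "]")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Plot a stepwise trajectory
#'
#' Steps on the horizontal axis, posterior probability on the vertical axis.
#'
#' @param x A `trajectory`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.trajectory <- function(x, ...) {
  graphics::plot(x$step, x$posterior, type = "b", pch = 19,
                 xlab = "step", ylab = sprintf("P(%s = %s)", attr(x, "target"),
                                               attr(x, "target_state")),
                 ylim = c(0, 1), ...)
  labs <- ifelse(x$step == 0, "prior", paste(x$variable, x$state, sep = "="))
  graphics::text(x$step, x$posterior, labs, pos = 3, cex = 0.7)
  invisible(x)
}

#' Compare evidence scenarios
#'
#' Computes the posterior of `target_state` under each named evidence set.
#' Scenarios may instantiate any variables, inside or outside the Markov
#' blanket (intercausal scenarios need no special casing).
#'
#' @param bn A `bn`.
#' @param target,target_state As in [rank_markov_blanket()].
#' @param scenarios Named list of evidence sets (each a named character
#'   vector, possibly empty).
#' @return Data frame with columns `scenario`, `posterior`.
#' @export
scenario_compare <- function(bn, target, target_state, scenarios) {
  if (is.null(names(scenarios)) || any(!nzchar(names(scenarios))))
    stop("scenarios must be named")
  data.frame(
    scenario = names(scenarios),
    posterior = vapply(scenarios, function(ev)
      unname(posterior(bn, target, ev)[target_state]), 1.0),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Packaged step plans for the trajectory analyses
#'
#' The six instantiation orders used in the stepwise analyses of the T2D
#' network, as data rather than code. Each plan fixes the branching variable
#' of step 1 (every state of it defines a branch) and then adds the listed
#' evidence cumulatively.
#'
#' @return Named list; each element has `branch_variable` and `steps` (named
#'   character vector).
#' @export
risk_step_plans <- function() {
  list(
    age    = list(branch_variable = "AGE",
                  steps = c(PA = "No", BMI = "Obesity", FLI = "More 60",
                            HbA1c = "More 6.0")),
    bmi    = list(branch_variable = "BMI",
                  steps = c(HbA1c = "More 6.0", FLI = "More 60", PA = "No",
                            AGE = "48-62")),
    pa     = list(branch_variable = "PA",
                  steps = c(AGE = "48-62", FLI = "More 60", HbA1c = "More 6.0",
                            BMI = "Obesity")),
    fli    = list(branch_variable = "FLI",
                  steps = c(HbA1c = "More 6.0", AGE = "48-62", PA = "No",
                            BMI = "Obesity")),
    hba1c  = list(branch_variable = "HbA1c",
                  steps = c(AGE = "48-62", PA = "No", FLI = "More 60",
                            BMI = "Obesity")),
    diet   = list(branch_variable = "DIET",
                  steps = c(AGE = "48-62", GENDER = "Men",
                            SMOKING = "Former smoker", PA = "No",
                            BMI = "Obesity"))
  )
}

#' Run every branch of a packaged step plan
#'
#' @param bn A `bn`.
#' @param plan One element of [risk_step_plans()] (or a list with the same
#'   shape).
#' @param target,target_state As in [rank_markov_blanket()].
#' @return Named list of `trajectory` objects, one per state of the
#'   branching variable.
#' @export
run_step_plan <- function(bn, plan, target = "T2D", target_state = "Yes") {
  bv <- plan$branch_variable
  check_node(bn$dag, bv)
  states <- bn$variables[[bv]]$states
  out <- lapply(states, function(s)
    stepwise_trajectory(bn, target, target_state,
                        c(stats::setNames(s, bv), plan$steps), branch = s))
  stats::setNames(out, states)
}
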
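# Model validation: k-fold cross-validation with log-likelihood loss, and
# per-feature one-vs-rest AUC / accuracy from held-out posteriors.

cv_folds <- function(n, k, seed = NULL) {
  stopifnot(k >= 2L, n >= k)
  local_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

#' k-fold cross-validation with log-likelihood loss
#'
#' Splits the records into `k` random folds (seeded, unstratified). For each
#' fold the full learning pipeline is re-run on the training folds —
#' blacklist, hill climbing, Bayesian parameter fitting — and the mean
#' negative log joint probability per held-out record is recorded. Bayesian
#' smoothing guarantees a finite loss even for states unseen in training.
#' With `relearn_structure = FALSE` the supplied structure is kept fixed and
#' only parameters are re-fitted per fold.
#'
#' @param data Cohort table (complete cases).
#' @param k Number of folds (default 10).
#' @param blacklist Forbidden arcs for structure learning (or `NULL`).
#' @param iss Dirichlet equivalent sample size for [fit_bayes()].
#' @param penalty Score penalty for [hill_climb()].
#' @param relearn_structure Re-learn the DAG on every training split
#'   (honest CV, the default); if `FALSE`, `structure` must be given.
#' @param structure Optional fixed [dag()] used when
#'   `relearn_structure = FALSE`.
#' @param seed Integer seed for the fold split.
#' @return Object of class `cv_result`: list with `expected_loss` (mean
#'   negative log-likelihood per held-out record), `fold_losses`,
#'   `fold_sizes`, `k`, `seed`.
#' @export
cross_validate <- function(data, k = 10L, blacklist = NULL, iss = 1,
                           penalty = 1, relearn_structure = TRUE,
                           structure = NULL, seed = NULL) {
  data <- as_cohort(data, cohort_variables(data))
  cohort_codes(data)                       # reject missing values up front
  folds <- cv_folds(nrow(data), k, seed)
  if (!relearn_structure && is.null(structure))
    stop("supply 'structure' when relearn_structure = FALSE")
  fold_losses <- numeric(k)
  fold_sizes <- integer(k)
  for (f in seq_len(k)) {
    test <- folds == f
    train <- data[!test, , drop = FALSE]
    attr(train, "variables") <- attr(data, "variables")
    g <- if (relearn_structure)
      hill_climb(train, blacklist = blacklist, penalty = penalty)
    else structure
    fit <- fit_bayes(g, train, iss = iss)
    held <- data[test, , drop = FALSE]
    attr(held, "variables") <- attr(data, "variables")
    ll <- log_likelihood(fit, held, per_record = TRUE)
    fold_sizes[f] <- sum(test)
    fold_losses[f] <- -mean(ll)
  }
  structure(list(expected_loss = sum(fold_losses * fold_sizes) / sum(fold_sizes),
                 fold_losses = fold_losses, fold_sizes = fold_sizes,
                 k = k, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV: expected log-likelihood loss %.4f per record\n",
              x$k, x$expected_loss))
  invisible(x)
}

# P(variable | all other columns) for every record, computed from the
# variable's own CPT and its children's CPTs only (all other factors are
# fully observed constants and cancel in the normalization). Exact, and
# vectorized over records.
record_posteriors <- function(bn, data, variable) {
  codes <- cohort_codes(as_cohort(data, bn$variables))
  ct <- bn$cpts[[variable]]
  fam <- c(variable, children(bn$dag, variable))
  r <- length(ct$states)
  n <- nrow(codes)
  logp <- matrix(0, n, r)
  for (s in seq_len(r)) {
    mod <- codes
    mod[, variable] <- s
    for (f in fam) {
      cf <- bn$cpts[[f]]
      logp[, s] <- logp[, s] + log(as.vector(cf$prob)[family_index(cf, mod)])
    }
  }
  w <- exp(logp - apply(logp, 1L, max))
  w <- w / rowSums(w)
  colnames(w) <- ct$states
  w
}

#' One-vs-rest AUC by midranks
#'
#' Area under the ROC curve for a score vector against a binary label,
#' computed from the Wilcoxon rank-sum statistic with average ranks for
#' ties (tied score pairs count 1/2).
#'
#' @param scores Numeric vector.
#' @param positive Logical vector, same length.
#' @return AUC in \[0, 1\]; `NA` if either class is empty.
#' @export
auc_midrank <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  rk <- rank(scores, ties.method = "average")
  (sum(rk[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Held-out per-feature AUC and accuracy
#'
#' Cross-validated feature prediction: for each fold, a network is learned
#' on the training folds; for each held-out record and each variable V, the
#' posterior P(V | all other 11 variables) is computed from the fold's
#' network. Per (variable, state): one-vs-rest AUC using the posterior
#' probability of that state as the score. Per variable: the percentage of
#' records whose argmax-predicted state matches the observed one (a single
#' per-variable number, repeated across its state rows).
#'
#' @inheritParams cross_validate
#' @param export_posteriors If `TRUE`, attach the full matrix of held-out
#'   posteriors as attribute `posteriors` (one column per variable state),
#'   e.g. for external classifier comparisons.
#' @return Data frame of class `feature_scores` with columns `variable`,
#'   `state`, `auc`, `accuracy`.
#' @export
feature_scores <- function(data, k = 10L, blacklist = NULL, iss = 1,
                           penalty = 1, relearn_structure = TRUE,
                           structure = NULL, seed = NULL,
                           export_posteriors = FALSE) {
  data <- as_cohort(data, cohort_variables(data))
  cohort_codes(data)
  folds <- cv_folds(nrow(data), k, seed)
  if (!relearn_structure && is.null(structure))
    stop("supply 'structure' when relearn_structure = FALSE")
  vars <- cohort_variables(data)
  post <- lapply(vars, function(v)
    matrix(NA_real_, nrow(data), length(v$states),
           dimnames = list(NULL, v$states)))
  for (f in seq_len(k)) {
    test <- folds == f
    train <- data[!test, , drop = FALSE]
    attr(train, "variables") <- attr(data, "variables")
    g <- if (relearn_structure)
      hill_climb(train, blacklist = blacklist, penalty = penalty)
    else structure
    fit <- fit_bayes(g, train, iss = iss)
    held <- data[test, , drop = FALSE]
    attr(held, "variables") <- attr(data, "variables")
    for (v in names(vars))
      post[[v]][test, ] <- record_posteriors(fit, held, v)
  }
  rows <- lapply(names(vars), function(v) {
    obs <- as.character(data[[v]])
    pred <- colnames(post[[v]])[max.col(post[[v]], ties.method = "first")]
    acc <- 100 * mean(pred == obs)
    data.frame(variable = v, state = vars[[v]]$states,
               auc = vapply(vars[[v]]$states, function(s)
                 auc_midrank(post[[v]][, s], obs == s), 1.0),
               accuracy = acc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (export_posteriors) attr(out, "posteriors") <- do.call(cbind, lapply(
    names(post), function(v) {
      m <- post[[v]]; colnames(m) <- paste(v, colnames(m), sep = "="); m
    }))
  class(out) <- c("feature_scores", "data.frame")
  out
}
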
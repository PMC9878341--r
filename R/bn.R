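# Discrete Bayesian networks: conditional probability tables, the network
# container, the chain-rule joint, ancestral sampling and log-likelihood.
#
# A CPT is stored as a numeric array with dimensions (child states, parent 1
# states, parent 2 states, ...); the first array index is the child state.
# The canonical *row* enumeration used for serialization and reporting is
# lexicographic over the parent order with each parent's states in declared
# order (first parent varies slowest), independent of the internal
# column-major layout.

local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Build a conditional probability table
#'
#' @param variable A [categorical_variable()]: the child.
#' @param parents List of [categorical_variable()]s, in parent order (may be
#'   empty for a root node).
#' @param prob Numeric array of conditional probabilities with dimensions
#'   `(length(variable$states), parent cardinalities...)`; each conditional
#'   distribution (fixing all parent states) must sum to 1 within 1e-9.
#' @param rows Alternative to `prob`: a matrix with one row per parent
#'   configuration in canonical order (lexicographic over the parent order,
#'   first parent varying slowest) and one column per child state.
#' @return An object of class `cpt`.
#' @examples
#' v <- categorical_variable("RAIN", c("yes", "no"))
#' cpt(v, list(), c(0.2, 0.8))
#' @export
cpt <- function(variable, parents = list(), prob = NULL, rows = NULL) {
  stopifnot(inherits(variable, "catvar"))
  for (p in parents) stopifnot(inherits(p, "catvar"))
  r <- length(variable$states)
  q_dims <- unname(vapply(parents, function(p) length(p$states), 1L))
  q <- prod(q_dims)
  if (is.null(prob) + is.null(rows) != 1L)
    stop("supply exactly one of 'prob' or 'rows'")
  if (!is.null(rows)) {
    rows <- as.matrix(rows)
    if (nrow(rows) != q || ncol(rows) != r)
      stop("'rows' must be ", q, " configurations x ", r, " states")
    # canonical rows (first parent slowest) -> internal layout
    prob <- t(rows)[, order(canonical_row_order(q_dims)), drop = FALSE]
  }
  prob <- array(as.numeric(prob), dim = c(r, q_dims))
  dn <- c(list(variable$states), lapply(parents, `[[`, "states"))
  names(dn) <- c(variable$name, vapply(parents, `[[`, "", "name"))
  dimnames(prob) <- dn
  if (any(!is.finite(prob)) || any(prob < 0) || any(prob > 1))
    stop("CPT entries for '", variable$name, "' must lie in [0, 1]")
  sums <- colSums(matrix(prob, nrow = r))
  if (any(abs(sums - 1) > 1e-9))
    stop("CPT rows for '", variable$name, "' must each sum to 1")
  structure(list(variable = variable$name,
                 states = variable$states,
                 parents = names(dn)[-1L],
                 parent_states = dn[-1L],
                 prob = prob),
            class = "cpt")
}

# Permutation mapping canonical lexicographic row index (first parent
# slowest) to internal column-major configuration index (first parent
# fastest). For empty q_dims returns 1.
canonical_row_order <- function(q_dims) {
  if (length(q_dims) == 0L) return(1L)
  grid <- expand.grid(rev(lapply(q_dims, seq_len)))[, rev(seq_along(q_dims)), drop = FALSE]
  # grid row i = parent codes of canonical row i (last parent fastest)
  mult <- cumprod(c(1, q_dims[-length(q_dims)]))
  as.integer(as.matrix(grid) %*% mult - sum(mult) + 1L)
}

#' @export
print.cpt <- function(x, ...) {
  cat(sprintf("CPT for %s | %s\n", x$variable,
              if (length(x$parents)) paste(x$parents, collapse = ", ") else "(root)"))
  print(cpt_rows(x))
  invisible(x)
}

# q x r matrix of conditional distributions in canonical row order, with a
# parent-configuration data.frame attached.
cpt_rows <- function(x) {
  r <- length(x$states)
  q_dims <- lengths(x$parent_states)
  m <- t(matrix(x$prob, nrow = r))
  ord <- canonical_row_order(q_dims)
  m <- m[ord, , drop = FALSE]
  colnames(m) <- x$states
  if (length(q_dims)) {
    cfg <- expand.grid(rev(x$parent_states), stringsAsFactors = FALSE)
    cfg <- cfg[, rev(seq_along(q_dims)), drop = FALSE]
    rownames(m) <- apply(as.matrix(cfg), 1L, paste, collapse = ",")
  }
  m
}

#' Assemble a discrete Bayesian network
#'
#' @param variables Named list of [categorical_variable()]s.
#' @param g A [dag()] over the variable names.
#' @param cpts Named list with one [cpt()] per node. Each CPT's parents must
#'   equal the node's DAG parents; a CPT given with its parents in a
#'   different order is permuted to the canonical order (DAG parent order,
#'   i.e. variable declaration order).
#' @return An object of class `bn` with elements `variables`, `dag`, `cpts`.
#' @export
bayes_net <- function(variables, g, cpts) {
  vn <- vapply(variables, `[[`, "", "name")
  names(variables) <- vn
  if (!setequal(vn, g$nodes) || length(vn) != length(g$nodes))
    stop("DAG nodes and variables disagree")
  if (!setequal(names(cpts), vn)) stop("need exactly one CPT per node")
  cpts <- cpts[vn]
  for (v in vn) {
    ct <- cpts[[v]]
    if (!inherits(ct, "cpt") || ct$variable != v)
      stop("CPT list entry '", v, "' is not a CPT for that node")
    pa <- parents(g, v)
    if (!setequal(ct$parents, pa))
      stop("CPT parents of '", v, "' do not match DAG parents")
    if (!identical(ct$parents, pa)) {            # permute to canonical order
      perm <- c(1L, 1L + match(pa, ct$parents))
      ct$prob <- aperm(ct$prob, perm)
      ct$parents <- pa
      ct$parent_states <- ct$parent_states[pa]
      cpts[[v]] <- ct
    }
    if (!identical(ct$states, variables[[v]]$states))
      stop("CPT states of '", v, "' do not match the variable definition")
  }
  structure(list(variables = variables, dag = g, cpts = cpts), class = "bn")
}

#' @export
print.bn <- function(x, ...) {
  cat(sprintf("Discrete Bayesian network: %d nodes, %d arcs\n",
              length(x$variables), nrow(arcs(x$dag))))
  invisible(x)
}

# state labels -> integer codes for a full or partial assignment
assignment_codes <- function(bn, assignment) {
  assignment <- unlist(assignment)
  out <- integer(length(assignment))
  names(out) <- names(assignment)
  for (i in seq_along(assignment)) {
    v <- names(assignment)[i]
    var <- bn$variables[[v]]
    if (is.null(var)) stop("unknown variable: '", v, "'")
    code <- match(trimws(assignment[[i]]), var$states)
    if (is.na(code))
      stop(sprintf("'%s' is not a state of %s", assignment[[i]], v))
    out[i] <- code
  }
  out
}

#' Joint probability of a full assignment
#'
#' The chain rule for Bayesian networks: the joint probability of a complete
#' configuration is the product over nodes of the CPT entry for the node's
#' state given its parents' states.
#'
#' @param bn A `bn`.
#' @param assignment Named character vector or list giving one state for
#'   *every* node.
#' @return A single probability.
#' @export
joint_probability <- function(bn, assignment) {
  codes <- assignment_codes(bn, assignment)
  missing <- setdiff(names(bn$variables), names(codes))
  if (length(missing))
    stop("assignment must cover every node; missing: ",
         paste(missing, collapse = ", "))
  p <- 1
  for (v in names(bn$variables)) {
    ct <- bn$cpts[[v]]
    idx <- c(codes[[v]], codes[ct$parents])
    p <- p * ct$prob[matrix(idx, nrow = 1L)]
  }
  unname(p)
}

# per-record linear index into a node's flattened CPT, given the integer
# code matrix of the data (internal column-major configuration order)
family_index <- function(ct, codes) {
  idx <- codes[, ct$variable]
  mult <- length(ct$states)
  for (p in ct$parents) {
    idx <- idx + mult * (codes[, p] - 1L)
    mult <- mult * length(ct$parent_states[[p]])
  }
  idx
}

#' Log-likelihood of a cohort under a network
#'
#' Sum over records of the natural log of the chain-rule joint probability.
#' Records assigned probability zero contribute `-Inf` (Bayesian-fitted
#' networks are strictly positive, so this arises only for hand-built or
#' maximum-likelihood tables).
#'
#' @param bn A `bn`.
#' @param data A cohort table over the network's variables.
#' @param per_record If `TRUE` return the vector of per-record log joints.
#' @return Total log-likelihood (or per-record vector).
#' @export
log_likelihood <- function(bn, data, per_record = FALSE) {
  data <- as_cohort(data, bn$variables[intersect(names(bn$variables), names(data))])
  if (!setequal(names(data), names(bn$variables)))
    stop("data columns do not match the network's variables")
  codes <- cohort_codes(data)
  ll <- numeric(nrow(codes))
  for (v in names(bn$variables)) {
    ct <- bn$cpts[[v]]
    ll <- ll + log(as.vector(ct$prob)[family_index(ct, codes)])
  }
  if (per_record) ll else sum(ll)
}

#' Ancestral forward sampling
#'
#' Draws records node by node in topological order (declaration-order
#' tie-break), each node sampled from its CPT row given the already-sampled
#' parent states. Reproducible for a fixed seed.
#'
#' @param bn A `bn`.
#' @param n Number of records.
#' @param seed Integer seed (optional; `NULL` uses the current RNG state).
#' @return A `cohort` data.frame with columns in variable declaration order.
#' @export
forward_sample <- function(bn, n, seed = NULL) {
  stopifnot(n >= 1)
  local_seed(seed, {
    ord <- topological_order(bn$dag)
    codes <- matrix(0L, nrow = n, ncol = length(bn$variables),
                    dimnames = list(NULL, names(bn$variables)))
    for (v in ord) {
      ct <- bn$cpts[[v]]
      r <- length(ct$states)
      # configuration index per record (1 for roots)
      cfg <- rep(1L, n)
      mult <- 1L
      for (p in ct$parents) {
        cfg <- cfg + mult * (codes[, p] - 1L)
        mult <- mult * length(ct$parent_states[[p]])
      }
      pm <- matrix(ct$prob, nrow = r)           # r x q
      cum <- apply(pm, 2L, cumsum)              # r x q
      u <- stats::runif(n)
      # state = 1 + number of cumulative bounds strictly below u
      below <- matrix(u, nrow = r, ncol = n, byrow = TRUE) >
        cum[, cfg, drop = FALSE]                # r x n
      codes[, v] <- 1L + colSums(below)
    }
    df <- as.data.frame(lapply(names(bn$variables), function(v)
      factor(bn$variables[[v]]$states[codes[, v]],
             levels = bn$variables[[v]]$states)),
      col.names = names(bn$variables))
    as_cohort(df, bn$variables)
  })
}

#' Look up one conditional distribution
#'
#' @param bn A `bn`.
#' @param variable Node name.
#' @param parent_assignment Named character vector/list giving a state for
#'   *every* parent of `variable` (empty for a root).
#' @return Named numeric vector over the variable's states.
#' @examples
#' net <- ground_truth_network()
#' cpt_lookup(net, "AGE", c(GENDER = "Men", SOCIALs = "I"))
#' @export
cpt_lookup <- function(bn, variable, parent_assignment = NULL) {
  check_node(bn$dag, variable)
  ct <- bn$cpts[[variable]]
  codes <- if (length(parent_assignment))
    assignment_codes(bn, parent_assignment) else integer(0)
  extra <- setdiff(names(codes), ct$parents)
  if (length(extra))
    stop("not parents of ", variable, ": ", paste(extra, collapse = ", "))
  missing <- setdiff(ct$parents, names(codes))
  if (length(missing))
    stop("partial parent assignment; missing: ", paste(missing, collapse = ", "))
  r <- length(ct$states)
  cfg <- 1L
  mult <- 1L
  for (p in ct$parents) {
    cfg <- cfg + mult * (codes[[p]] - 1L)
    mult <- mult * length(ct$parent_states[[p]])
  }
  stats::setNames(matrix(ct$prob, nrow = r)[, cfg], ct$states)
}
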
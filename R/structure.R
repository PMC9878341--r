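# Score-based structure learning: AIC scoring, greedy hill climbing under a
# blacklist, nonparametric bootstrap arc strengths and model averaging.

#' Blacklist implied by an expert block ordering
#'
#' Given an ordered partition of the variables into blocks (background ->
#' lifestyle -> clinical -> diagnosis, say), every arc from a variable in a
#' later block to a variable in a strictly earlier block is forbidden.
#' Within-block arcs and forward arcs remain admissible.
#'
#' @param blocks Ordered list of character vectors; must be disjoint.
#' @param variables Character vector of all variable names (defaults to the
#'   union of the blocks). Every variable must belong to exactly one block.
#' @return Two-column character matrix (`from`, `to`) of forbidden arcs,
#'   of class `blacklist`.
#' @examples
#' nrow(blacklist_from_blocks(t2d_blocks()))  # 51 forbidden arcs
#' @export
blacklist_from_blocks <- function(blocks, variables = NULL) {
  all_b <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(all_b)) stop("blocks are not disjoint")
  if (is.null(variables)) variables <- all_b
  orphan <- setdiff(variables, all_b)
  if (length(orphan))
    stop("variable in no block: ", paste(orphan, collapse = ", "))
  extra <- setdiff(all_b, variables)
  if (length(extra))
    stop("block member not among the variables: ", paste(extra, collapse = ", "))
  out <- NULL
  for (i in seq_along(blocks))
    for (j in seq_len(i - 1L))
      out <- rbind(out, as.matrix(expand.grid(from = blocks[[i]],
                                              to = blocks[[j]],
                                              stringsAsFactors = FALSE)))
  if (is.null(out))
    out <- matrix(character(0), ncol = 2L, dimnames = list(NULL, c("from", "to")))
  structure(out, class = c("blacklist", class(out)))
}

blacklist_lookup <- function(blacklist, nodes) {
  m <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (!is.null(blacklist) && NROW(blacklist) > 0L) {
    bl <- as.matrix(blacklist)
    unknown <- setdiff(unique(as.vector(bl)), nodes)
    if (length(unknown))
      stop("blacklist references unknown variables: ",
           paste(unknown, collapse = ", "))
    m[bl] <- TRUE
  }
  m
}

# Decomposable family log-score: maximized log-likelihood of one node given
# a parent set, plus (optionally) the AIC penalty (r-1)q. Counts come from
# the integer code matrix.
family_loglik <- function(codes, node, pars, card) {
  r <- card[[node]]
  idx <- codes[, node]
  mult <- r
  for (p in pars) {
    idx <- idx + mult * (codes[, p] - 1L)
    mult <- mult * card[[p]]
  }
  counts <- tabulate(idx, nbins = mult)
  cm <- matrix(counts, nrow = r)
  nij <- colSums(cm)
  pos <- counts > 0L
  sum(counts[pos] * log(counts[pos] / rep(nij, each = r)[pos]))
}

family_score <- function(codes, node, pars, card, penalty = 1) {
  q <- prod(unlist(card[pars], use.names = FALSE), 1)
  family_loglik(codes, node, pars, card) - penalty * (card[[node]] - 1) * q
}

#' AIC network score
#'
#' The score maximized by [hill_climb()]: maximized log-likelihood of the
#' data under the DAG minus the number of free parameters
#' \eqn{\sum_i (r_i - 1) q_i} (child cardinality minus one, times parent
#' configuration count). Higher is better; the score decomposes into
#' independent per-family terms, which is what makes greedy search cheap.
#'
#' @param g A [dag()].
#' @param data Cohort table over the DAG's variables (complete cases).
#' @param penalty Penalty coefficient per free parameter: 1 gives AIC (the
#'   default), `log(n)/2` gives BIC, 0 gives the raw log-likelihood.
#' @return A single number.
#' @export
aic_score <- function(g, data, penalty = 1) {
  data <- as_cohort(data, cohort_variables(data))
  if (nrow(data) == 0L) stop("empty data")
  if (!setequal(names(data), g$nodes))
    stop("data columns do not match DAG nodes")
  codes <- cohort_codes(data)
  card <- lapply(data, nlevels)
  sum(vapply(g$nodes, function(v)
    family_score(codes, v, parents(g, v), card, penalty), 1.0))
}

#' Greedy hill-climbing structure search
#'
#' Starts from `start` (default: the empty graph) and repeatedly applies the
#' single-arc addition, deletion or reversal that most improves the
#' decomposable score, stopping at a local optimum. Candidate moves are
#' enumerated in a fixed order (ordered node pairs by declaration order;
#' additions, then deletions, then reversals) and a move is taken only if it
#' improves the score by more than `tol`, so the search is deterministic and
#' cannot cycle. Arcs on the blacklist are never added, and reversals that
#' would create a blacklisted arc are never applied.
#'
#' @param data Cohort table (complete cases).
#' @param blacklist Forbidden arcs, as from [blacklist_from_blocks()] (or
#'   `NULL`).
#' @param start Optional starting [dag()]; must be acyclic and contain no
#'   blacklisted arc.
#' @param penalty Score penalty coefficient (see [aic_score()]).
#' @param tol Strict-improvement threshold (absolute), default `1e-9`.
#' @param max_iter Safety cap on the number of accepted moves.
#' @return The locally optimal [dag()].
#' @export
hill_climb <- function(data, blacklist = NULL, start = NULL,
                       penalty = 1, tol = 1e-9, max_iter = 500L) {
  data <- as_cohort(data, cohort_variables(data))
  if (nrow(data) == 0L) stop("empty data")
  codes <- cohort_codes(data)
  nodes <- names(data)
  card <- lapply(data, nlevels)
  forbidden <- blacklist_lookup(blacklist, nodes)

  g <- if (is.null(start)) empty_dag(nodes) else start
  if (!setequal(g$nodes, nodes)) stop("'start' nodes do not match the data")
  if (any(g$amat & forbidden[g$nodes, g$nodes]))
    stop("'start' contains a blacklisted arc")

  cache <- new.env(parent = emptyenv(), hash = TRUE)
  fscore <- function(node, pars) {
    key <- paste(node, paste(sort(pars), collapse = "|"), sep = ":")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    cache[[key]] <- s <- family_score(codes, node, pars, card, penalty)
    s
  }

  node_score <- vapply(nodes, function(v) fscore(v, parents(g, v)), 1.0)
  pairs <- expand.grid(fi = seq_along(nodes), ti = seq_along(nodes))
  pairs <- pairs[pairs$fi != pairs$ti, ]
  pairs <- pairs[order(pairs$fi, pairs$ti), ]

  for (iter in seq_len(max_iter)) {
    best <- list(delta = tol, move = NULL)
    for (k in seq_len(nrow(pairs))) {
      from <- nodes[pairs$fi[k]]; to <- nodes[pairs$ti[k]]
      if (!g$amat[from, to] && !forbidden[from, to]) {     # addition
        if (!path_exists(g, to, from)) {                   # acyclicity
          d <- fscore(to, c(parents(g, to), from)) - node_score[[to]]
          if (d > best$delta) best <- list(delta = d, move = c("add", from, to))
        }
      }
    }
    for (k in seq_len(nrow(pairs))) {
      from <- nodes[pairs$fi[k]]; to <- nodes[pairs$ti[k]]
      if (g$amat[from, to]) {                              # deletion
        d <- fscore(to, setdiff(parents(g, to), from)) - node_score[[to]]
        if (d > best$delta) best <- list(delta = d, move = c("delete", from, to))
      }
    }
    for (k in seq_len(nrow(pairs))) {
      from <- nodes[pairs$fi[k]]; to <- nodes[pairs$ti[k]]
      if (g$amat[from, to] && !forbidden[to, from]) {      # reversal
        g2 <- g; g2$amat[from, to] <- FALSE
        if (!path_exists(g2, from, to)) {
          d <- (fscore(to, setdiff(parents(g, to), from)) - node_score[[to]]) +
               (fscore(from, c(parents(g, from), to)) - node_score[[from]])
          if (d > best$delta) best <- list(delta = d, move = c("reverse", from, to))
        }
      }
    }
    if (is.null(best$move)) break
    op <- best$move[1L]; from <- best$move[2L]; to <- best$move[3L]
    g <- switch(op,
                add = add_arc(g, from, to),
                delete = drop_arc(g, from, to),
                reverse = reverse_arc(g, from, to))
    node_score[[to]] <- fscore(to, parents(g, to))
    if (op == "reverse") node_score[[from]] <- fscore(from, parents(g, from))
  }
  g
}

# directed path from x to y?
path_exists <- function(g, x, y) {
  frontier <- which(g$nodes == x)
  seen <- rep(FALSE, length(g$nodes))
  seen[frontier] <- TRUE
  yi <- which(g$nodes == y)
  while (length(frontier)) {
    nxt <- which(colSums(g$amat[frontier, , drop = FALSE]) > 0 & !seen)
    if (yi %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  FALSE
}

#' Bootstrap arc strengths
#'
#' Learns one structure per nonparametric bootstrap resample (size n, drawn
#' with replacement, seeded) and tabulates, for every ordered node pair, the
#' fraction of replicate networks containing the arc in either direction
#' (`strength`) and, among those, the fraction oriented this way
#' (`direction_prob`). `direction_prob(a->b) + direction_prob(b->a) = 1`
#' wherever the arc ever appears.
#'
#' @param data Cohort table.
#' @param replicates Number of bootstrap networks (paper-scale default 500).
#' @param blacklist,penalty,tol Passed to [hill_climb()].
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return Data frame of class `arc_strength` with columns `from`, `to`,
#'   `strength`, `direction_prob`; attribute `replicates`.
#' @export
bootstrap_arc_strength <- function(data, replicates = 500L, blacklist = NULL,
                                   penalty = 1, tol = 1e-9, seed = NULL) {
  stopifnot(replicates >= 1L)
  data <- as_cohort(data, cohort_variables(data))
  nodes <- names(data)
  p <- length(nodes)
  dir_count <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  local_seed(seed, {
    for (b in seq_len(replicates)) {
      idx <- sample.int(nrow(data), nrow(data), replace = TRUE)
      boot <- data[idx, , drop = FALSE]
      attr(boot, "variables") <- attr(data, "variables")
      g <- hill_climb(boot, blacklist = blacklist, penalty = penalty, tol = tol)
      dir_count <- dir_count + g$amat
    }
  })
  und <- dir_count + t(dir_count)
  out <- expand.grid(fi = seq_len(p), ti = seq_len(p))
  out <- out[out$fi != out$ti, ]
  out <- out[order(out$fi, out$ti), ]
  res <- data.frame(
    from = nodes[out$fi], to = nodes[out$ti],
    strength = und[cbind(out$fi, out$ti)] / replicates,
    direction_prob = ifelse(und[cbind(out$fi, out$ti)] > 0,
                            dir_count[cbind(out$fi, out$ti)] /
                              und[cbind(out$fi, out$ti)], 0),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "replicates") <- replicates
  attr(res, "nodes") <- nodes
  class(res) <- c("arc_strength", "data.frame")
  res
}

#' Consensus network from arc strengths
#'
#' Keeps every undirected arc whose inclusion `strength` is at least
#' `threshold` (inclusive) and orients it by majority `direction_prob`;
#' an exact 0.5 direction tie is oriented from the earlier declared variable
#' to the later. If the oriented result contains a cycle, arcs are dropped
#' in increasing strength order until it is acyclic.
#'
#' @param strengths An `arc_strength` table from [bootstrap_arc_strength()].
#' @param threshold Inclusion threshold in (0, 1]; paper-scale default 0.85.
#' @return A [dag()].
#' @export
averaged_network <- function(strengths, threshold = 0.85) {
  stopifnot(threshold > 0, threshold <= 1)
  nodes <- attr(strengths, "nodes")
  if (is.null(nodes)) nodes <- unique(c(strengths$from, strengths$to))
  keep <- strengths[strengths$strength >= threshold, , drop = FALSE]
  ni <- match(keep$from, nodes); nj <- match(keep$to, nodes)
  keep <- keep[ni < nj |                                   # one row per pair
                 (keep$direction_prob > 0.5 & ni > nj), , drop = FALSE]
  sel <- keep$direction_prob >= 0.5                        # ties: declared order
  arcs_sel <- data.frame(from = ifelse(sel, keep$from, keep$to),
                         to = ifelse(sel, keep$to, keep$from),
                         strength = keep$strength, stringsAsFactors = FALSE)
  arcs_sel <- arcs_sel[!duplicated(paste(pmin(arcs_sel$from, arcs_sel$to),
                                         pmax(arcs_sel$from, arcs_sel$to))), ]
  arcs_sel <- arcs_sel[order(-arcs_sel$strength,
                             match(arcs_sel$from, nodes),
                             match(arcs_sel$to, nodes)), , drop = FALSE]
  g <- empty_dag(nodes)
  for (i in seq_len(nrow(arcs_sel))) {
    gi <- g
    gi$amat[arcs_sel$from[i], arcs_sel$to[i]] <- TRUE
    if (!has_cycle(gi)) g <- gi                 # weakest cycle-makers dropped
  }
  g
}

#' Write an arc-strength table as CSV
#' @param strengths An `arc_strength` table.
#' @param path Output file.
#' @export
write_arc_strength <- function(strengths, path) {
  utils::write.csv(as.data.frame(strengths)[, c("from", "to", "strength",
                                                "direction_prob")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
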
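# Directed acyclic graphs over named variables.
#
# Internal representation: a logical adjacency matrix `amat` over the node
# declaration order; amat[i, j] is the arc i -> j. Declaration order is the
# tie-break for topological sorting, so all downstream algorithms are
# deterministic for a given node ordering.

#' Create a directed acyclic graph
#'
#' @param nodes Character vector of unique node names (declaration order is
#'   kept and used to break topological-order ties).
#' @param edges Two-column character matrix (or data.frame) of arcs
#'   `from -> to`; may be empty.
#' @return An object of class `dag`.
#' @examples
#' g <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' parents(g, "C")
#' @export
dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (length(nodes) < 1L) stop("a DAG needs at least one node")
  if (anyDuplicated(nodes)) stop("duplicated node names")
  amat <- matrix(FALSE, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  g <- structure(list(nodes = nodes, amat = amat), class = "dag")
  if (!is.null(edges) && NROW(edges) > 0L) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("'edges' must have two columns (from, to)")
    for (i in seq_len(nrow(edges)))
      g <- add_arc(g, edges[i, 1L], edges[i, 2L])
  }
  g
}

#' @rdname dag
#' @export
empty_dag <- function(nodes) dag(nodes)

check_node <- function(g, node) {
  if (!node %in% g$nodes) stop("unknown node: '", node, "'")
  node
}

#' Arc edits
#'
#' `add_arc`/`drop_arc`/`reverse_arc` return a modified copy; `add_arc` and
#' `reverse_arc` refuse edits that would create a directed cycle.
#'
#' @param g A `dag`.
#' @param from,to Node names.
#' @return A `dag`.
#' @export
add_arc <- function(g, from, to) {
  check_node(g, from); check_node(g, to)
  if (from == to) stop("self-loop not allowed: ", from)
  if (g$amat[from, to]) stop("duplicate arc: ", from, " -> ", to)
  g$amat[from, to] <- TRUE
  if (has_cycle(g)) stop("arc ", from, " -> ", to, " would create a cycle")
  g
}

#' @rdname add_arc
#' @export
drop_arc <- function(g, from, to) {
  check_node(g, from); check_node(g, to)
  if (!g$amat[from, to]) stop("no such arc: ", from, " -> ", to)
  g$amat[from, to] <- FALSE
  g
}

#' @rdname add_arc
#' @export
reverse_arc <- function(g, from, to) {
  g <- drop_arc(g, from, to)
  add_arc(g, to, from)
}

#' Arc list of a DAG
#' @param g A `dag`.
#' @return Two-column character matrix with columns `from`, `to`.
#' @export
arcs <- function(g) {
  idx <- which(g$amat, arr.ind = TRUE)
  m <- cbind(from = g$nodes[idx[, 1L]], to = g$nodes[idx[, 2L]])
  m[order(match(m[, 1L], g$nodes), match(m[, 2L], g$nodes)), , drop = FALSE]
}

#' @export
print.dag <- function(x, ...) {
  a <- arcs(x)
  cat(sprintf("DAG: %d nodes, %d arcs\n", length(x$nodes), nrow(a)))
  if (nrow(a)) cat(paste0("  ", a[, 1L], " -> ", a[, 2L], collapse = "\n"), "\n")
  invisible(x)
}

#' Graph neighbourhoods
#'
#' @param g A `dag`.
#' @param node A node name.
#' @return Character vector of node names (in declaration order).
#' @export
parents <- function(g, node) {
  check_node(g, node)
  g$nodes[g$amat[, node]]
}

#' @rdname parents
#' @export
children <- function(g, node) {
  check_node(g, node)
  g$nodes[g$amat[node, ]]
}

#' @rdname parents
#' @export
markov_blanket <- function(g, node) {
  check_node(g, node)
  ch <- children(g, node)
  spouses <- unlist(lapply(ch, parents, g = g))
  setdiff(g$nodes[g$nodes %in% c(parents(g, node), ch, spouses)], node)
}

has_cycle <- function(g) is.null(topo_order_or_null(g))

topo_order_or_null <- function(g) {
  n <- length(g$nodes)
  indeg <- colSums(g$amat)
  amat <- g$amat
  out <- character(0)
  avail <- which(indeg == 0L)
  while (length(avail)) {
    i <- avail[1L]                      # declaration-order tie-break
    out <- c(out, g$nodes[i])
    indeg[i] <- NA
    ch <- which(amat[i, ])
    indeg[ch] <- indeg[ch] - 1L
    avail <- which(!is.na(indeg) & indeg == 0L)
  }
  if (length(out) < n) NULL else out
}

#' Topological order of a DAG
#'
#' Ties are broken by node declaration order, so the result is unique.
#'
#' @param g A `dag`.
#' @return Character vector of node names.
#' @export
topological_order <- function(g) {
  ord <- topo_order_or_null(g)
  if (is.null(ord)) stop("graph contains a directed cycle")
  ord
}

ancestors_of <- function(g, set) {
  # set plus all ancestors, by reverse BFS
  seen <- stats::setNames(rep(FALSE, length(g$nodes)), g$nodes)
  queue <- set
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    if (seen[[v]]) next
    seen[[v]] <- TRUE
    queue <- c(queue, parents(g, v))
  }
  g$nodes[seen]
}

#' Test d-separation
#'
#' Decides whether every undirected path between `x` and `y` is blocked given
#' the conditioning set `z`: serial and diverging connections block when the
#' middle node is observed; a converging (head-to-head) connection blocks
#' unless the collider or one of its descendants is observed.
#'
#' Implemented by the moralized-ancestral-graph criterion: restrict to the
#' ancestors of `{x, y} U z`, moralize (marry co-parents, drop directions),
#' delete `z`, and test whether `x` and `y` are disconnected.
#'
#' @param g A `dag`.
#' @param x,y Distinct node names, neither in `z`.
#' @param z Character vector of conditioning nodes (may be empty).
#' @return `TRUE` if `x` and `y` are d-separated by `z`.
#' @examples
#' g <- dag(c("AGE", "PA", "DIET", "T2D"),
#'          rbind(c("AGE", "PA"), c("PA", "DIET"),
#'                c("DIET", "T2D"), c("AGE", "T2D")))
#' d_separated(g, "PA", "T2D", c("DIET", "AGE"))
#' @export
d_separated <- function(g, x, y, z = character(0)) {
  z <- as.character(z)
  check_node(g, x); check_node(g, y)
  for (v in z) check_node(g, v)
  if (x == y) stop("'x' and 'y' must be distinct")
  if (x %in% z || y %in% z) stop("'x' and 'y' must not be in 'z'")

  keep <- ancestors_of(g, c(x, y, z))
  sub <- g$amat[keep, keep, drop = FALSE]
  undir <- sub | t(sub)
  # moralize: connect parents sharing a child
  for (ch in seq_along(keep)) {
    pa <- which(sub[, ch])
    if (length(pa) > 1L)
      undir[pa, pa] <- TRUE
  }
  diag(undir) <- FALSE
  drop <- keep %in% z
  undir[drop, ] <- FALSE
  undir[, drop] <- FALSE
  # BFS from x
  start <- match(x, keep)
  target <- match(y, keep)
  seen <- rep(FALSE, length(keep))
  seen[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nxt <- which(colSums(undir[frontier, , drop = FALSE]) > 0 & !seen)
    if (target %in% nxt) return(FALSE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  !seen[target]
}

#' Compelled (non-reversible) arcs of a DAG
#'
#' Labels every arc as compelled or reversible within the DAG's Markov
#' equivalence class, by Chickering's edge-ordering algorithm. Reversible
#' arcs (the "covered" edges and their propagations) carry no orientation
#' information in observational data: reversing them yields an equivalent
#' model with an identical decomposable score.
#'
#' @param g A `dag`.
#' @return Logical vector, one element per row of [arcs()] (same order):
#'   `TRUE` if the arc is compelled.
#' @export
compelled_arcs <- function(g) {
  a <- arcs(g)
  if (nrow(a) == 0L) return(logical(0))
  topo <- topological_order(g)
  ti <- stats::setNames(seq_along(topo), topo)
  ord <- order(ti[a[, 2L]], -ti[a[, 1L]])
  # status: 0 unknown, 1 compelled, -1 reversible
  status <- stats::setNames(rep(0L, nrow(a)), paste(a[, 1L], a[, 2L]))
  key <- function(x, y) paste(x, y)
  for (k in ord) {
    x <- a[k, 1L]; y <- a[k, 2L]
    if (status[[key(x, y)]] != 0L) next
    done <- FALSE
    for (w in parents(g, x)) {
      if (status[[key(w, x)]] == 1L) {
        if (!w %in% parents(g, y)) {
          status[[key(x, y)]] <- 1L
          for (p in parents(g, y))
            if (status[[key(p, y)]] == 0L) status[[key(p, y)]] <- 1L
          done <- TRUE
          break
        } else status[[key(w, y)]] <- 1L
      }
    }
    if (done) next
    zs <- setdiff(parents(g, y), x)
    if (any(!zs %in% c(parents(g, x)))) {
      for (p in parents(g, y))
        if (status[[key(p, y)]] == 0L) status[[key(p, y)]] <- 1L
    } else {
      for (p in parents(g, y))
        if (status[[key(p, y)]] == 0L) status[[key(p, y)]] <- -1L
    }
  }
  unname(status[paste(a[, 1L], a[, 2L])] == 1L)
}

#' Compare a learned structure with a reference structure
#'
#' Scores recovery up to Markov equivalence: a reference arc counts as
#' recovered when its skeleton edge is present in the learned graph and its
#' orientation either matches or is not compelled in the reference DAG
#' (reversible arcs carry no orientation signal in observational data).
#' Spurious arcs are learned skeleton edges absent from the reference
#' skeleton.
#'
#' @param reference,learned `dag` objects over the same nodes.
#' @return List with `n_true`, `n_recovered`, `recovered_fraction`,
#'   `n_spurious`, `orientation_errors` (compelled reference arcs present
#'   in the skeleton but reversed).
#' @export
compare_structures <- function(reference, learned) {
  stopifnot(setequal(reference$nodes, learned$nodes))
  ra <- arcs(reference); la <- arcs(learned)
  comp <- compelled_arcs(reference)
  und <- function(m) paste(pmin(m[, 1L], m[, 2L]), pmax(m[, 1L], m[, 2L]))
  rk_dir <- paste(ra[, 1L], ra[, 2L])
  lk_dir <- if (nrow(la)) paste(la[, 1L], la[, 2L]) else character(0)
  rk_und <- und(ra)
  lk_und <- if (nrow(la)) und(la) else character(0)
  skeleton_hit <- rk_und %in% lk_und
  dir_hit <- rk_dir %in% lk_dir
  recovered <- skeleton_hit & (dir_hit | !comp)
  list(n_true = nrow(ra),
       n_recovered = sum(recovered),
       recovered_fraction = mean(recovered),
       n_spurious = sum(!(lk_und %in% rk_und)),
       orientation_errors = sum(skeleton_hit & comp & !dir_hit))
}
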
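# Independent brute-force oracles and random-instance generators. These are
# deliberately written against first principles (path enumeration, joint
# enumeration, pairwise counting) rather than reusing the package's
# production algorithms, so each production path has a second, independent
# route to the same answer.

random_dag <- function(n_nodes, p_edge = 0.35) {
  nodes <- LETTERS[seq_len(n_nodes)]
  g <- empty_dag(nodes)
  for (i in seq_len(n_nodes - 1L))
    for (j in seq((i + 1L), n_nodes))
      if (stats::runif(1) < p_edge)
        g <- add_arc(g, nodes[i], nodes[j])   # i < j: acyclic by construction
  g
}

random_bn <- function(g, max_states = 3L) {
  vars <- lapply(g$nodes, function(v)
    categorical_variable(v, paste0("s", seq_len(sample(2:max_states, 1L)))))
  names(vars) <- g$nodes
  cpts <- lapply(g$nodes, function(v) {
    pars <- parents(g, v)
    r <- length(vars[[v]]$states)
    q <- prod(vapply(vars[pars], function(p) length(p$states), 1L), 1)
    m <- matrix(stats::rgamma(r * q, 1) + 0.05, nrow = r)
    m <- sweep(m, 2L, colSums(m), `/`)
    cpt(vars[[v]], vars[pars], array(m, dim = c(r, vapply(vars[pars], function(p)
      length(p$states), 1L))))
  })
  names(cpts) <- g$nodes
  bayes_net(vars, g, cpts)
}

# all full assignments of a network as a data.frame of state labels
all_assignments <- function(bn) {
  expand.grid(lapply(bn$variables, `[[`, "states"),
              stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

# posterior by summing chain-rule joint probabilities over assignments
enum_posterior <- function(bn, target, evidence = NULL) {
  grid <- all_assignments(bn)
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence)) keep <- keep & grid[[v]] == evidence[[v]]
  p <- vapply(which(keep), function(i)
    joint_probability(bn, unlist(grid[i, , drop = FALSE])), 1.0)
  states <- bn$variables[[target]]$states
  out <- vapply(states, function(s)
    sum(p[grid[[target]][keep] == s]), 1.0)
  out / sum(out)
}

# d-separation by explicit enumeration of all undirected simple paths and
# the serial / diverging / converging blocking rules
dsep_path_oracle <- function(g, x, y, z) {
  amat <- g$amat
  und <- amat | t(amat)
  descendants <- function(v) {
    seen <- character(0); queue <- children(g, v)
    while (length(queue)) {
      u <- queue[[1L]]; queue <- queue[-1L]
      if (u %in% seen) next
      seen <- c(seen, u); queue <- c(queue, children(g, u))
    }
    seen
  }
  blocked <- function(path) {
    if (length(path) <= 2L) return(FALSE)       # direct edge: never blocked
    for (k in 2:(length(path) - 1L)) {
      a <- path[k - 1L]; m <- path[k]; b <- path[k + 1L]
      converging <- amat[a, m] && amat[b, m]
      if (converging) {
        if (!(m %in% z) && !any(descendants(m) %in% z)) return(TRUE)
      } else {
        if (m %in% z) return(TRUE)
      }
    }
    FALSE
  }
  found_active <- FALSE
  walk <- function(path) {
    if (found_active) return()
    last <- path[length(path)]
    if (last == y) {
      if (!blocked(path)) found_active <<- TRUE
      return()
    }
    for (nb in g$nodes[und[last, ]])
      if (!nb %in% path) walk(c(path, nb))
  }
  walk(x)
  !found_active
}

# AUC by explicit pairwise comparison (ties count one half)
auc_pairwise <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# compelled arcs by enumeration of the whole Markov equivalence class:
# every acyclic reorientation of the skeleton with identical v-structures
compelled_oracle <- function(g) {
  a <- arcs(g)
  und <- unique(t(apply(a, 1L, sort)))
  m <- nrow(und)
  vstructs <- function(h) {
    out <- character(0)
    for (v in h$nodes) {
      pa <- parents(h, v)
      if (length(pa) > 1L) {
        cmb <- utils::combn(sort(pa), 2L)
        for (k in seq_len(ncol(cmb))) {
          p1 <- cmb[1L, k]; p2 <- cmb[2L, k]
          if (!h$amat[p1, p2] && !h$amat[p2, p1])
            out <- c(out, paste(p1, v, p2))
        }
      }
    }
    sort(out)
  }
  ref_v <- vstructs(g)
  keep_dirs <- matrix(NA, 0L, m)
  for (mask in seq_len(2^m) - 1L) {
    dirs <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L)))
    edges <- t(vapply(seq_len(m), function(k)
      if (dirs[k]) c(und[k, 2L], und[k, 1L]) else und[k, ], character(2L)))
    h <- tryCatch(dag(g$nodes, edges), error = function(e) NULL)
    if (!is.null(h) && identical(vstructs(h), ref_v))
      keep_dirs <- rbind(keep_dirs, dirs)
  }
  # an arc is compelled iff its orientation is constant over the class
  vapply(seq_len(nrow(a)), function(i) {
    k <- which(und[, 1L] == min(a[i, ]) & und[, 2L] == max(a[i, ]))
    length(unique(keep_dirs[, k])) == 1L
  }, TRUE)
}

# build a cohort table for arbitrary toy variables
toy_cohort <- function(df) {
  vars <- lapply(names(df), function(nm) {
    col <- df[[nm]]
    categorical_variable(nm, if (is.factor(col)) levels(col) else sort(unique(as.character(col))))
  })
  names(vars) <- names(df)
  as_cohort(df, vars)
}

# two-variable generator with a strong A -> B dependence
strong_ab_cohort <- function(n, p_b1_given_a1 = 0.9, p_b1_given_a2 = 0.1,
                             p_a1 = 0.5) {
  a <- ifelse(stats::runif(n) < p_a1, "a1", "a2")
  pb <- ifelse(a == "a1", p_b1_given_a1, p_b1_given_a2)
  b <- ifelse(stats::runif(n) < pb, "b1", "b2")
  va <- categorical_variable("A", c("a1", "a2"))
  vb <- categorical_variable("B", c("b1", "b2"))
  as_cohort(data.frame(A = a, B = b, stringsAsFactors = FALSE),
            list(A = va, B = vb))
}
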
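# Network serialization (JSON, read-only BIF) and the end-to-end pipeline.

#' Write / read a network as JSON
#'
#' The JSON document stores the variable list (names and state labels), the
#' arc list, and per node the parent order plus the CPT entries flattened in
#' canonical row order: parent configurations lexicographic over the parent
#' order with each parent's states in declared order (first parent varies
#' slowest), child states in declared order within a row. Probabilities are
#' written at full precision, so write-then-read restores the network
#' bit-exactly.
#'
#' @param bn A `bn`.
#' @param path File path.
#' @return `write_network` invisibly returns `path`; `read_network` returns
#'   the `bn`.
#' @export
write_network <- function(bn, path) {
  doc <- list(
    format = "t2dbn-network",
    version = 1L,
    variables = lapply(unname(bn$variables), function(v)
      list(name = v$name, states = v$states)),
    arcs = apply(arcs(bn$dag), 1L, as.list),
    cpts = lapply(bn$cpts, function(ct) {
      q_dims <- lengths(ct$parent_states)
      rows <- t(matrix(ct$prob, nrow = length(ct$states)))
      rows <- rows[canonical_row_order(q_dims), , drop = FALSE]
      list(parents = ct$parents, prob = as.vector(t(rows)))
    }))
  # I(17) = significant digits: shortest representation that round-trips
  # doubles bit-exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "t2dbn-network"))
    stop("not a t2dbn network document: ", path)
  vars <- lapply(doc$variables, function(v)
    categorical_variable(v$name, unlist(v$states)))
  names(vars) <- vapply(vars, `[[`, "", "name")
  edges <- if (length(doc$arcs))
    do.call(rbind, lapply(doc$arcs, unlist)) else NULL
  g <- dag(names(vars), edges)
  cpts <- lapply(names(vars), function(v) {
    spec <- doc$cpts[[v]]
    if (is.null(spec)) stop("network document lacks a CPT for node '", v, "'")
    pars <- as.character(unlist(spec$parents))
    if (!setequal(pars, parents(g, v)))
      stop("CPT parents for node '", v, "' disagree with the arc list")
    r <- length(vars[[v]]$states)
    q_dims <- lengths(lapply(vars[pars], `[[`, "states"))
    q <- prod(q_dims, 1)
    prob <- as.numeric(unlist(spec$prob))
    if (length(prob) != r * q)
      stop("CPT for node '", v, "' has ", length(prob),
           " entries; expected ", r * q)
    if (length(pars) == 0L) cpt(vars[[v]], list(), prob)
    else cpt(vars[[v]], vars[pars],
             rows = matrix(prob, nrow = q, ncol = r, byrow = TRUE))
  })
  names(cpts) <- names(vars)
  bayes_net(vars, g, cpts)
}

#' Read a network from a BIF file
#'
#' A read-only parser for the common dialect of the Bayesian Interchange
#' Format: `variable X { type discrete [ n ] { s1, s2 }; }` blocks and
#' `probability ( X | P1, P2 ) { ... }` blocks containing either a `table`
#' row (for roots) or `(s1, s2) p1, p2, ...;` rows per parent configuration.
#'
#' @param path File path.
#' @return A `bn`.
#' @export
read_bif <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("//[^\n]*", "", txt)
  num_pat <- "[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?"
  var_pat <- "variable\\s+(\\S+)\\s*\\{[^{}]*type\\s+discrete\\s*\\[\\s*\\d+\\s*\\]\\s*\\{([^}]*)\\}\\s*;[^{}]*\\}"
  vm <- gregexpr(var_pat, txt, perl = TRUE)
  starts <- vm[[1L]]
  if (starts[1L] == -1L) stop("no variable blocks found in ", path)
  vars <- list()
  for (i in seq_along(starts)) {
    block <- regmatches(txt, vm)[[1L]][i]
    name <- sub(var_pat, "\\1", block, perl = TRUE)
    states <- trimws(strsplit(sub(var_pat, "\\2", block, perl = TRUE), ",")[[1L]])
    vars[[name]] <- categorical_variable(name, states)
  }
  prob_pat <- "probability\\s*\\(\\s*([^|)]+?)\\s*(?:\\|\\s*([^)]*))?\\)\\s*\\{([^}]*)\\}"
  pm <- gregexpr(prob_pat, txt, perl = TRUE)
  blocks <- regmatches(txt, pm)[[1L]]
  if (!length(blocks)) stop("no probability blocks found in ", path)
  edges <- NULL
  cpt_specs <- list()
  for (block in blocks) {
    child <- trimws(sub(prob_pat, "\\1", block, perl = TRUE))
    pars_txt <- trimws(sub(prob_pat, "\\2", block, perl = TRUE))
    pars <- if (nzchar(pars_txt)) trimws(strsplit(pars_txt, ",")[[1L]]) else character(0)
    body <- sub(prob_pat, "\\3", block, perl = TRUE)
    if (is.null(vars[[child]])) stop("probability block for unknown variable ", child)
    for (p in pars) {
      if (is.null(vars[[p]])) stop("unknown parent ", p, " of ", child)
      edges <- rbind(edges, c(p, child))
    }
    r <- length(vars[[child]]$states)
    if (length(pars) == 0L) {
      nums <- regmatches(body, gregexpr(num_pat, body))[[1L]]
      prob <- as.numeric(nums)
      if (length(prob) != r) stop("root table for ", child, " has wrong length")
      cpt_specs[[child]] <- list(parents = pars, prob = prob)
    } else {
      q_dims <- lengths(lapply(vars[pars], `[[`, "states"))
      rows_txt <- regmatches(body,
        gregexpr("\\(([^)]*)\\)\\s*([^;]*);", body, perl = TRUE))[[1L]]
      m <- matrix(NA_real_, prod(q_dims), r)
      for (row in rows_txt) {
        cfg_states <- trimws(strsplit(sub("\\(([^)]*)\\).*", "\\1", row), ",")[[1L]])
        codes <- mapply(function(p, s) {
          k <- match(s, vars[[p]]$states)
          if (is.na(k)) stop("unknown state ", s, " of ", p, " in BIF row")
          k
        }, pars, cfg_states)
        mult <- cumprod(c(1, q_dims[-length(q_dims)]))
        idx <- sum((codes - 1) * mult) + 1
        vals <- as.numeric(regmatches(sub("\\([^)]*\\)", "", row),
          gregexpr(num_pat, sub("\\([^)]*\\)", "", row)))[[1L]])
        m[idx, ] <- vals
      }
      if (anyNA(m)) stop("incomplete probability rows for ", child)
      cpt_specs[[child]] <- list(parents = pars, prob = m)
    }
  }
  g <- dag(names(vars), edges)
  cpts <- lapply(names(vars), function(v) {
    spec <- cpt_specs[[v]]
    if (is.null(spec)) stop("no probability block for ", v)
    if (length(spec$parents) == 0L) cpt(vars[[v]], list(), spec$prob)
    else {
      # BIF rows are in internal order here (first parent fastest): pass array
      q_dims <- lengths(lapply(vars[spec$parents], `[[`, "states"))
      cpt(vars[[v]], vars[spec$parents],
          array(t(spec$prob), dim = c(length(vars[[v]]$states), q_dims)))
    }
  })
  names(cpts) <- names(vars)
  bayes_net(vars, g, cpts)
}

pipeline_defaults <- function() {
  list(blocks = t2d_blocks(), replicates = 500L, threshold = 0.85,
       iss = 1, folds = 10L, penalty = 1, seed = NULL,
       cv = TRUE, target = "T2D", target_state = "Yes")
}

#' Run the full analysis pipeline
#'
#' Ties the stages together on one cohort: block blacklist, bootstrap model
#' averaging (hill climbing per resample), consensus structure, Bayesian
#' parameter fitting, Markov-blanket ranking, the packaged trajectory plans,
#' and (optionally) cross-validation. All artifacts are written to
#' `out_dir` as plain text (CSV/JSON) together with a manifest recording
#' package version, seed and configuration; two runs with the same
#' configuration and seed produce byte-identical artifacts.
#'
#' @param data A cohort table, or a path to a cohort CSV.
#' @param out_dir Output directory (created if needed).
#' @param config Named list overriding the defaults: `blocks`, `replicates`
#'   (500), `threshold` (0.85), `iss` (1), `folds` (10), `penalty` (1),
#'   `seed`, `cv` (TRUE), `target`, `target_state`. May also be a path to a
#'   JSON (or YAML, if the yaml package is installed) configuration file.
#' @return Invisibly, a list with the learned structure, arc strengths,
#'   fitted network, ranking, trajectories and CV result.
#' @export
run_pipeline <- function(data, out_dir, config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configuration requires the 'yaml' package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(pipeline_defaults(), config)
  if (is.character(data) && length(data) == 1L) data <- read_cohort(data)
  data <- as_cohort(data, cohort_variables(data))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  bl <- blacklist_from_blocks(cfg$blocks, names(data))
  strengths <- bootstrap_arc_strength(data, replicates = cfg$replicates,
                                      blacklist = bl, penalty = cfg$penalty,
                                      seed = cfg$seed)
  g <- averaged_network(strengths, threshold = cfg$threshold)
  fit <- fit_bayes(g, data, iss = cfg$iss)

  write_arc_strength(strengths, file.path(out_dir, "arc_strengths.csv"))
  utils::write.csv(as.data.frame(arcs(g)), file.path(out_dir, "structure.csv"),
                   row.names = FALSE, quote = FALSE)
  write_network(fit, file.path(out_dir, "network.json"))

  ranking <- NULL
  trajectories <- NULL
  if (cfg$target %in% names(data)) {
    ranking <- rank_markov_blanket(fit, cfg$target, cfg$target_state)
    utils::write.csv(cbind(as.data.frame(ranking),
                           baseline = attr(ranking, "baseline")),
                     file.path(out_dir, "ranking.csv"), row.names = FALSE)
    plans <- risk_step_plans()
    plans <- Filter(function(p)
      all(c(p$branch_variable, names(p$steps)) %in% names(data)), plans)
    rows <- list()
    for (nm in names(plans)) {
      for (tr in run_step_plan(fit, plans[[nm]], cfg$target, cfg$target_state)) {
        df <- as.data.frame(tr)
        df$plan <- nm
        df$branch <- attr(tr, "branch")
        rows[[length(rows) + 1L]] <- df
      }
    }
    trajectories <- do.call(rbind, rows)
    if (!is.null(trajectories))
      utils::write.csv(trajectories, file.path(out_dir, "trajectories.csv"),
                       row.names = FALSE)
  }

  cv <- NULL
  if (isTRUE(cfg$cv)) {
    cv <- cross_validate(data, k = cfg$folds, blacklist = bl, iss = cfg$iss,
                         penalty = cfg$penalty, seed = cfg$seed)
    jsonlite::write_json(list(expected_loss = cv$expected_loss,
                              fold_losses = cv$fold_losses,
                              fold_sizes = cv$fold_sizes, k = cv$k),
                         file.path(out_dir, "cv.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  cfg_json <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                               digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    package = "t2dbn",
    version = as.character(utils::packageVersion("t2dbn")),
    n_records = nrow(data),
    variables = names(data),
    seed = cfg$seed,
    replicates = cfg$replicates,
    threshold = cfg$threshold,
    iss = cfg$iss,
    folds = cfg$folds,
    config = cfg,
    config_md5 = unname(tools::md5sum(tmp)))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(structure = g, strengths = strengths, network = fit,
                 ranking = ranking, trajectories = trajectories, cv = cv,
                 manifest = manifest))
}
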
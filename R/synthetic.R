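#' Generate a layered tool grammar
#'
#' Builds the ground-truth successor structure that synthetic workflow
#' corpora are simulated from. Tools are arranged in layers; each
#' non-terminal tool draws `branching_factor` successors from the next
#' layer, so the successor graph is acyclic by construction. Per-tool
#' popularity weights follow a Pareto law with shape `skew_exponent`,
#' emulating the heavily skewed tool-usage distribution of real
#' workflow corpora (common text tools appearing orders of magnitude
#' more often than rare ones).
#'
#' @param n_tools Number of tools (>= 4).
#' @param branching_factor Successors drawn per non-terminal tool
#'   (capped at the next layer's size).
#' @param skew_exponent Pareto shape for popularity weights; smaller
#'   values give heavier skew.
#' @param seed Integer seed; the same seed yields the same grammar.
#' @param max_depth Number of layers (maximum walk length).
#' @return A `flowrec_grammar`: `tools`, `layer`, `weights`,
#'   `successor_map` (named list), `start_tools`, plus the generation
#'   parameters.
#' @export
generate_grammar <- function(n_tools, branching_factor = 2L,
                             skew_exponent = 1.5, seed = 1L,
                             max_depth = 28L) {
  stopifnot(n_tools >= 4, max_depth >= 2, skew_exponent > 0)
  if (branching_factor < 1) {
    stop("branching_factor must be at least 1", call. = FALSE)
  }
  if (max_depth > n_tools) {
    stop("max_depth cannot exceed n_tools (each layer needs a tool)",
         call. = FALSE)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  tools <- sprintf("tool_%03d", seq_len(n_tools))
  layer <- sort(rep_len(seq_len(max_depth), n_tools))
  weights <- stats::setNames(stats::runif(n_tools)^(-1 / skew_exponent),
                             tools)
  successor_map <- stats::setNames(vector("list", n_tools), tools)
  for (l in seq_len(max_depth - 1L)) {
    nxt <- tools[layer == l + 1L]
    for (tl in tools[layer == l]) {
      k <- min(branching_factor, length(nxt))
      successor_map[[tl]] <- sort(sample(nxt, k, prob = weights[nxt]))
    }
  }
  for (tl in tools[layer == max_depth]) successor_map[[tl]] <- character(0)
  structure(list(
    tools = tools, layer = layer, weights = weights,
    successor_map = successor_map, start_tools = tools[layer == 1L],
    n_tools = as.integer(n_tools),
    branching_factor = as.integer(branching_factor),
    skew_exponent = skew_exponent, max_depth = as.integer(max_depth),
    seed = as.integer(seed)
  ), class = "flowrec_grammar")
}

#' @export
print.flowrec_grammar <- function(x, ...) {
  cat("<tool grammar> ", x$n_tools, " tools in ", x$max_depth,
      " layers, branching ", x$branching_factor, ", weight skew ",
      x$skew_exponent, "\n", sep = "")
  invisible(x)
}

#' Ground-truth next-tool labels under a grammar
#'
#' The exact successor set of the final tool of a prefix. Terminal
#' tools return an empty set.
#'
#' @param grammar A [generate_grammar()] result.
#' @param prefix Character vector of tool names.
#' @return Character vector of successor tools (possibly empty).
#' @export
ground_truth_labels <- function(grammar, prefix) {
  last <- prefix[length(prefix)]
  if (!last %in% grammar$tools) {
    stop("unknown tool: ", last, call. = FALSE)
  }
  grammar$successor_map[[last]]
}

# truncated, shifted negative-binomial walk lengths with a target median
sample_lengths <- function(n, length_range, target_median, size = 4) {
  lo <- length_range[1]; hi <- length_range[2]
  mu <- max(0.5, target_median - lo)
  L <- lo + stats::rnbinom(n, size = size, mu = mu)
  pmin(pmax(L, lo), hi)
}

#' Simulate a corpus of workflow DAGs from a grammar
#'
#' Each workflow is a depth-limited traversal of the grammar: a start
#' tool is drawn by popularity weight, then at every node either one
#' successor is followed (drawn by weight) or, with probability
#' `branch_prob`, all of the node's successors are included — which
#' creates multi-successor nodes, so one tool prefix maps to several
#' next-tool labels. Walk lengths follow a negative-binomial
#' distribution shifted into `length_range` and parameterised to hit
#' `target_median`. With `branch_prob = 1` every reachable branch is
#' expanded, so the corpus exhausts the grammar and observed label sets
#' equal the ground-truth successor sets.
#'
#' @param grammar A [generate_grammar()] result.
#' @param n_workflows Number of workflows to simulate.
#' @param length_range Integer bounds on walk depth, within
#'   `[2, max_depth]`.
#' @param target_median Desired median walk depth.
#' @param branch_prob Probability of expanding all successors at a
#'   node.
#' @param max_frontier Cap on simultaneously open branches.
#' @param seed Integer seed.
#' @return List of `flowrec_workflow` objects.
#' @export
generate_workflow_corpus <- function(grammar, n_workflows,
                                     length_range = c(2L, grammar$max_depth),
                                     target_median = NULL,
                                     branch_prob = 0.25,
                                     max_frontier = 8L, seed = 1L) {
  stopifnot(length_range[1] >= 2, length_range[2] <= grammar$max_depth,
            length_range[1] <= length_range[2])
  if (is.null(target_median)) {
    target_median <- round(mean(length_range))
  }
  if (n_workflows == 0) return(list())
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  w <- grammar$weights
  lens <- sample_lengths(n_workflows, length_range, target_median)
  lapply(seq_len(n_workflows), function(i) {
    start <- sample(grammar$start_tools, 1,
                    prob = w[grammar$start_tools])
    nodes <- start
    from <- character(0); to <- character(0)
    frontier <- start
    depth <- 1L
    while (depth < lens[i] && length(frontier) > 0) {
      nxt_frontier <- character(0)
      for (tl in frontier) {
        succ <- grammar$successor_map[[tl]]
        if (length(succ) == 0) next
        chosen <- if (length(succ) > 1 && stats::runif(1) < branch_prob) {
          succ
        } else if (length(succ) == 1) {
          succ
        } else {
          sample(succ, 1, prob = w[succ])
        }
        from <- c(from, rep(tl, length(chosen)))
        to <- c(to, chosen)
        nxt_frontier <- c(nxt_frontier, chosen)
      }
      frontier <- unique(nxt_frontier)
      if (length(frontier) > max_frontier) {
        frontier <- frontier[seq_len(max_frontier)]
      }
      nodes <- unique(c(nodes, frontier))
      depth <- depth + 1L
    }
    workflow_graph(sprintf("wf_%05d", i), nodes,
                   tibble::tibble(from = from, to = to))
  })
}

#' Serialize a grammar to a plain-text successor table
#'
#' One line per tool: `tool<TAB>weight<TAB>succ1,succ2,...` (empty
#' successor field for terminal tools).
#'
#' @param grammar A [generate_grammar()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_grammar <- function(grammar, path) {
  lines <- vapply(grammar$tools, function(tl) {
    paste(tl, format(grammar$weights[[tl]], digits = 17),
          paste(grammar$successor_map[[tl]], collapse = ","), sep = "\t")
  }, character(1))
  writeLines(c("tool\tweight\tsuccessors", lines), path)
  invisible(path)
}

#' Write a workflow in the native workflow-export dialect
#'
#' Emits a minimal Galaxy-style JSON export (steps with `tool_id` and
#' `input_connections`) that [parse_workflow()] reads back to the same
#' graph.
#'
#' @param graph A `flowrec_workflow`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_workflow_ga <- function(graph, path) {
  ids <- stats::setNames(seq_along(graph$nodes) - 1L, graph$nodes)
  steps <- lapply(graph$nodes, function(tl) {
    preds <- graph$edges$from[graph$edges$to == tl]
    conns <- stats::setNames(
      lapply(seq_along(preds), function(j) {
        list(id = unname(ids[preds[j]]), output_name = "output")
      }),
      if (length(preds)) paste0("input_", seq_along(preds) - 1L)
      else character(0)
    )
    list(id = unname(ids[tl]), type = "tool", tool_id = tl,
         input_connections = conns)
  })
  names(steps) <- as.character(unname(ids))
  obj <- list(a_galaxy_workflow = "true", name = graph$workflow_id,
              steps = steps)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
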
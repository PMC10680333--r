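#' Construct a workflow graph
#'
#' A workflow is a directed acyclic graph whose nodes are scientific
#' tools and whose edges are tool-to-tool data connections. Duplicate
#' edges are collapsed; the graph is validated to be acyclic and every
#' edge endpoint must be a listed node.
#'
#' @param workflow_id Identifier of the workflow.
#' @param nodes Character vector of tool names (non-empty strings).
#' @param edges Two-column data frame (`from`, `to`) of directed tool
#'   connections; may have zero rows.
#' @return A `flowrec_workflow` object.
#' @export
workflow_graph <- function(workflow_id, nodes, edges = NULL) {
  nodes <- unique(as.character(nodes))
  if (length(nodes) == 0 || any(is.na(nodes)) || any(!nzchar(nodes))) {
    stop("workflow '", workflow_id, "': tool names must be non-empty",
         call. = FALSE)
  }
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character())
  } else {
    edges <- tibble::as_tibble(edges[, 1:2])
    names(edges) <- c("from", "to")
    edges <- dplyr::distinct(edges)
    bad <- setdiff(c(edges$from, edges$to), nodes)
    if (length(bad) > 0) {
      stop("workflow '", workflow_id, "': edge endpoint(s) not in nodes: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  g <- structure(
    list(workflow_id = as.character(workflow_id), nodes = nodes,
         edges = edges),
    class = "flowrec_workflow"
  )
  if (!igraph::is_dag(as_igraph(g))) {
    stop("workflow '", workflow_id, "' contains a directed cycle",
         call. = FALSE)
  }
  g
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                vertices = graph$nodes)
}

#' @export
print.flowrec_workflow <- function(x, ...) {
  cat("<workflow '", x$workflow_id, "'> ", length(x$nodes), " tools, ",
      nrow(x$edges), " connections\n", sep = "")
  invisible(x)
}

#' Parse one workflow file into a graph
#'
#' Understands two dialects: the native Galaxy workflow export (a JSON
#' document of steps with `tool_id` fields and `input_connections`
#' records) and a two-column TSV edge list
#' `source_tool<TAB>target_tool` with one optional header line.
#' Non-tool steps (data inputs, parameter inputs) are removed and their
#' incoming/outgoing connections contracted, since only tools are
#' modelled.
#'
#' @param x Path to a file, or its full content as a character scalar.
#' @param format `"auto"` (default; sniffed from the content), `"ga"`
#'   for the native export, `"edges"` for the TSV dialect.
#' @param workflow_id Identifier to use when the file does not carry
#'   one.
#' @return A `flowrec_workflow`.
#' @export
parse_workflow <- function(x, format = c("auto", "ga", "edges"),
                           workflow_id = NULL) {
  format <- match.arg(format)
  content <- read_content(x)
  if (format == "auto") {
    format <- if (grepl("^\\s*\\{", content)) "ga" else "edges"
  }
  if (format == "ga") {
    parse_workflow_ga(content, workflow_id)
  } else {
    graphs <- parse_edge_list(content, default_id = workflow_id %||% "edges")
    if (length(graphs) != 1) {
      stop("edge list describes ", length(graphs), " workflows; ",
           "use read_workflow_corpus() for multi-workflow files",
           call. = FALSE)
    }
    graphs[[1]]
  }
}

read_content <- function(x) {
  if (length(x) == 1 && !grepl("[\n{]", x) && file.exists(x)) {
    x <- readLines(x, warn = FALSE)
  }
  paste(x, collapse = "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_workflow_ga <- function(content, workflow_id = NULL) {
  wf <- tryCatch(
    jsonlite::fromJSON(content, simplifyVector = FALSE),
    error = function(e) {
      stop("malformed workflow export: ", conditionMessage(e), call. = FALSE)
    }
  )
  if (is.null(wf$steps) || length(wf$steps) == 0) {
    stop("malformed workflow export: no steps", call. = FALSE)
  }
  wid <- workflow_id %||% wf$name %||% "workflow"
  step_tool <- character()
  step_is_tool <- logical()
  edges_from <- integer(); edges_to <- integer()
  for (key in names(wf$steps)) {
    s <- wf$steps[[key]]
    id <- as.integer(s$id %||% key)
    is_tool <- identical(s$type %||% "tool", "tool") &&
      !is.null(s$tool_id) && nzchar(s$tool_id)
    step_tool[as.character(id)] <- if (is_tool) as.character(s$tool_id) else ""
    step_is_tool[as.character(id)] <- is_tool
    for (conn in s$input_connections %||% list()) {
      srcs <- if (is.list(conn) && !is.null(conn$id)) list(conn) else conn
      for (src in srcs) {
        if (!is.list(src) || is.null(src$id)) {
          stop("malformed workflow export: step ", id,
               " has an input connection without a source id", call. = FALSE)
        }
        edges_from <- c(edges_from, as.integer(src$id))
        edges_to <- c(edges_to, id)
      }
    }
  }
  bad <- setdiff(as.character(edges_from), names(step_tool))
  if (length(bad) > 0) {
    stop("malformed workflow export: connection from unknown step ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  # contract non-tool steps: route their predecessors to their successors
  el <- unique(cbind(edges_from, edges_to))
  for (id in names(step_is_tool)[!step_is_tool]) {
    idn <- as.integer(id)
    preds <- el[el[, 2] == idn, 1]
    succs <- el[el[, 1] == idn, 2]
    el <- el[el[, 1] != idn & el[, 2] != idn, , drop = FALSE]
    if (length(preds) > 0 && length(succs) > 0) {
      el <- rbind(el, as.matrix(expand.grid(preds, succs)))
    }
    el <- unique(el)
  }
  tools <- step_tool[step_is_tool]
  names(tools) <- names(step_tool)[step_is_tool]
  if (length(tools) == 0) {
    stop("workflow '", wid, "' contains no tool steps", call. = FALSE)
  }
  edges <- tibble::tibble(
    from = unname(tools[as.character(el[, 1])]),
    to = unname(tools[as.character(el[, 2])])
  )
  workflow_graph(wid, unname(tools), edges)
}

parse_edge_list <- function(content, default_id = "edges") {
  lines <- strsplit(content, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty edge list", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- unique(lengths(fields))
  if (length(ncols) != 1 || !ncols %in% c(2L, 3L)) {
    bad <- which(!lengths(fields) %in% c(2L, 3L))[1]
    if (is.na(bad)) bad <- which(lengths(fields) != lengths(fields)[1])[1]
    stop("malformed edge list at line ", bad,
         ": expected 2 or 3 tab-separated columns", call. = FALSE)
  }
  header <- tolower(gsub("_", "", fields[[1]]))
  if (all(header %in% c("workflowid", "sourcetool", "targettool",
                        "source", "target", "from", "to"))) {
    fields <- fields[-1]
    if (length(fields) == 0) stop("edge list has a header but no records",
                                  call. = FALSE)
  }
  m <- do.call(rbind, fields)
  if (ncols == 2L) {
    df <- tibble::tibble(workflow_id = default_id, from = m[, 1], to = m[, 2])
  } else {
    df <- tibble::tibble(workflow_id = m[, 1], from = m[, 2], to = m[, 3])
  }
  lapply(split(df, factor(df$workflow_id, levels = unique(df$workflow_id))),
         function(d) {
           workflow_graph(d$workflow_id[1], unique(c(d$from, d$to)),
                          d[, c("from", "to")])
         })
}

#' Read a corpus of workflows
#'
#' Accepts a directory of workflow-export files, a vector of file
#' paths, or a single multi-workflow TSV
#' (`workflow_id<TAB>source_tool<TAB>target_tool`).
#'
#' @param path Directory, file path(s), or a 3-column TSV file.
#' @return A list of `flowrec_workflow` objects.
#' @export
read_workflow_corpus <- function(path) {
  if (length(path) == 1 && dir.exists(path)) {
    path <- list.files(path, full.names = TRUE)
  }
  graphs <- list()
  for (p in path) {
    content <- read_content(p)
    if (grepl("^\\s*\\{", content)) {
      graphs <- c(graphs, list(parse_workflow_ga(
        content, workflow_id = sub("\\.[^.]*$", "", basename(p)))))
    } else {
      graphs <- c(graphs, parse_edge_list(
        content, default_id = sub("\\.[^.]*$", "", basename(p))))
    }
  }
  if (length(graphs) == 0) stop("no workflows found", call. = FALSE)
  unname(graphs)
}

#' Enumerate linear tool sequences of a workflow
#'
#' Decomposes a workflow DAG into its maximal linear tool sequences:
#' every simple path from an in-degree-0 tool to an out-degree-0 tool,
#' keeping only paths of two or more tools. Weakly connected components
#' are handled independently. Output order is deterministic
#' (lexicographic by the tool names along the path).
#'
#' @param graph A `flowrec_workflow`, or a list of them.
#' @return A tibble with columns `workflow_id` and `tools` (a
#'   list-column of character vectors).
#' @export
enumerate_linear_sequences <- function(graph) {
  if (is.list(graph) && !inherits(graph, "flowrec_workflow")) {
    return(dplyr::bind_rows(lapply(graph, enumerate_linear_sequences)))
  }
  stopifnot(inherits(graph, "flowrec_workflow"))
  ig <- as_igraph(graph)
  if (!igraph::is_dag(ig)) {
    stop("workflow '", graph$workflow_id, "' is not acyclic", call. = FALSE)
  }
  sources <- igraph::V(ig)[igraph::degree(ig, mode = "in") == 0]
  sinks <- igraph::V(ig)[igraph::degree(ig, mode = "out") == 0]
  paths <- list()
  for (s in sources) {
    ps <- igraph::all_simple_paths(ig, from = s, to = sinks, mode = "out")
    paths <- c(paths, lapply(ps, function(p) names(p)))
  }
  paths <- paths[lengths(paths) >= 2]
  if (length(paths) == 0) {
    return(tibble::tibble(workflow_id = character(), tools = list()))
  }
  keys <- vapply(paths, paste, character(1), collapse = "\t")
  paths <- paths[order(keys, method = "radix")]
  tibble::tibble(workflow_id = graph$workflow_id, tools = paths)
}

#' Corpus-level statistics of tool sequences
#'
#' Counts of workflows, sequences, unique sequences and unique tools,
#' the length distribution (min/median/max), and the per-tool
#' occurrence frequency across all sequences.
#'
#' @param sequences Tibble from [enumerate_linear_sequences()].
#' @return A `flowrec_corpus_stats` list; see [glance.flowrec_corpus_stats()]
#'   for a one-row tibble summary.
#' @export
compute_corpus_stats <- function(sequences) {
  if (!is.data.frame(sequences) || nrow(sequences) == 0) {
    stop("sequence list is empty", call. = FALSE)
  }
  lens <- lengths(sequences$tools)
  keys <- vapply(sequences$tools, paste, character(1), collapse = "\t")
  all_tools <- unlist(sequences$tools, use.names = FALSE)
  freq <- sort(table(all_tools), decreasing = TRUE)
  structure(list(
    n_workflows = dplyr::n_distinct(sequences$workflow_id),
    n_sequences = nrow(sequences),
    n_unique_sequences = dplyr::n_distinct(keys),
    n_unique_tools = length(freq),
    max_length = max(lens),
    min_length = min(lens),
    median_length = stats::median(lens),
    per_tool_frequency = tibble::tibble(tool = names(freq),
                                        n = as.integer(freq))
  ), class = "flowrec_corpus_stats")
}

#' @export
print.flowrec_corpus_stats <- function(x, ...) {
  cat("<corpus stats> ", x$n_sequences, " sequences (",
      x$n_unique_sequences, " unique) from ", x$n_workflows,
      " workflows; ", x$n_unique_tools, " tools; lengths ",
      x$min_length, "-", x$max_length, " (median ", x$median_length,
      ")\n", sep = "")
  invisible(x)
}

#' Write / read tool sequences as TSV
#'
#' One sequence per line: `workflow_id<TAB>tool1,tool2,...`.
#'
#' @param sequences Tibble from [enumerate_linear_sequences()].
#' @param path Output file.
#' @return `path`, invisibly (writer); the sequences tibble (reader).
#' @export
write_sequences <- function(sequences, path) {
  lines <- paste0(sequences$workflow_id, "\t",
                  vapply(sequences$tools, paste, character(1),
                         collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sequences
#' @export
read_sequences <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    workflow_id = vapply(parts, `[[`, character(1), 1),
    tools = lapply(parts, function(p) strsplit(p[2], ",", fixed = TRUE)[[1]])
  )
}

#' Serialize workflows to the 3-column TSV edge-list dialect
#'
#' Writes `workflow_id<TAB>source_tool<TAB>target_tool` with a header.
#' Workflows without edges (single isolated tool) cannot be represented
#' in this dialect and raise an error.
#'
#' @param graphs A `flowrec_workflow` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graphs, path) {
  if (inherits(graphs, "flowrec_workflow")) graphs <- list(graphs)
  rows <- lapply(graphs, function(g) {
    if (nrow(g$edges) == 0) {
      stop("workflow '", g$workflow_id,
           "' has no edges; the TSV dialect cannot represent it",
           call. = FALSE)
    }
    paste(g$workflow_id, g$edges$from, g$edges$to, sep = "\t")
  })
  writeLines(c("workflow_id\tsource_tool\ttarget_tool", unlist(rows)), path)
  invisible(path)
}
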
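test_that("native workflow exports parse to tool graphs, dropping data inputs", {
  g <- parse_workflow(ga_linear_json(c("toolA", "toolB", "toolC")))
  expect_s3_class(g, "flowrec_workflow")
  expect_setequal(g$nodes, c("toolA", "toolB", "toolC"))
  expect_equal(nrow(g$edges), 2)
  expect_setequal(paste(g$edges$from, g$edges$to),
                  c("toolA toolB", "toolB toolC"))

  # single tool step, no connections
  single <- jsonlite::toJSON(list(steps = list(`0` = list(
    id = 0, type = "tool", tool_id = "solo",
    input_connections = list()))), auto_unbox = TRUE)
  g1 <- parse_workflow(single)
  expect_equal(g1$nodes, "solo")
  expect_equal(nrow(g1$edges), 0)
})

test_that("non-tool steps are contracted, not just dropped", {
  # toolA -> data step -> toolB must yield the edge toolA -> toolB
  steps <- list(
    `0` = list(id = 0, type = "tool", tool_id = "toolA",
               input_connections = list()),
    `1` = list(id = 1, type = "parameter_input", tool_id = NULL,
               input_connections = list(input = list(id = 0))),
    `2` = list(id = 2, type = "tool", tool_id = "toolB",
               input_connections = list(input = list(id = 1)))
  )
  g <- parse_workflow(jsonlite::toJSON(list(steps = steps),
                                       auto_unbox = TRUE))
  expect_setequal(g$nodes, c("toolA", "toolB"))
  expect_equal(unname(as.matrix(g$edges)), rbind(c("toolA", "toolB")))
})

test_that("malformed or cyclic workflow content is rejected with context", {
  expect_error(parse_workflow("{not json", format = "ga"),
               "malformed workflow export")
  bad_conn <- list(steps = list(`0` = list(
    id = 0, type = "tool", tool_id = "toolA",
    input_connections = list(input = list(output_name = "out")))))
  expect_error(parse_workflow(jsonlite::toJSON(bad_conn, auto_unbox = TRUE)),
               "step 0")
  expect_error(parse_workflow("A\tB\nB\tA", format = "edges"),
               "cycle")
  expect_error(parse_workflow("A\tB\tC\tD", format = "edges"),
               "line 1")
})

test_that("edge-list dialects parse with and without headers", {
  g <- parse_workflow("source_tool\ttarget_tool\nA\tB\nA\tC\nB\tD\nC\tD")
  expect_setequal(g$nodes, c("A", "B", "C", "D"))
  expect_equal(dplyr::arrange(g$edges, from, to),
               dplyr::arrange(diamond_graph()$edges, from, to))

  tsv <- "workflow_id\tsource_tool\ttarget_tool\nw1\tA\tB\nw2\tX\tY\nw2\tY\tZ"
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(tsv, tf)
  graphs <- read_workflow_corpus(tf)
  expect_length(graphs, 2)
  expect_equal(vapply(graphs, function(g) g$workflow_id, character(1)),
               c("w1", "w2"))
  # parse_workflow refuses multi-workflow content
  expect_error(parse_workflow(tsv), "read_workflow_corpus")
})

test_that("duplicate edges collapse and edge endpoints are validated", {
  g <- parse_workflow("A\tB\nA\tB")
  expect_equal(nrow(g$edges), 1)
  expect_error(workflow_graph("w", c("A"), data.frame(from = "A", to = "B")),
               "not in nodes")
  expect_error(workflow_graph("w", c("A", "")), "non-empty")
})

test_that("maximal source-to-sink sequences are enumerated deterministically", {
  lin <- parse_workflow("A\tB\nB\tC")
  expect_equal(enumerate_linear_sequences(lin)$tools, list(c("A", "B", "C")))

  d <- enumerate_linear_sequences(diamond_graph())
  expect_equal(d$tools, list(c("A", "B", "D"), c("A", "C", "D")))

  # isolated single tool: no sequence of length >= 2
  iso <- workflow_graph("iso", "solo")
  expect_equal(nrow(enumerate_linear_sequences(iso)), 0)
})

test_that("a path graph of n nodes yields exactly one sequence of length n", {
  for (n in c(2, 5, 9)) {
    tools <- sprintf("t%02d", seq_len(n))
    g <- workflow_graph("path", tools,
                        data.frame(from = tools[-n], to = tools[-1]))
    s <- enumerate_linear_sequences(g)
    expect_equal(nrow(s), 1)
    expect_equal(s$tools[[1]], tools)
  }
})

test_that("every enumerated sequence is a walk in its source graph", {
  st <- tiny_study(seed = 5)
  edge_sets <- lapply(st$corpus, function(g) paste(g$edges$from, g$edges$to))
  names(edge_sets) <- vapply(st$corpus, function(g) g$workflow_id,
                             character(1))
  for (i in seq_len(nrow(st$sequences))) {
    tools <- st$sequences$tools[[i]]
    steps <- paste(tools[-length(tools)], tools[-1])
    expect_true(all(steps %in% edge_sets[[st$sequences$workflow_id[i]]]))
  }
})

test_that("corpus statistics match hand counts", {
  st1 <- compute_corpus_stats(seq_tbl(c("A", "B", "C")))
  expect_equal(st1$max_length, 3)
  expect_equal(st1$min_length, 3)
  expect_equal(st1$median_length, 3)
  expect_equal(st1$n_unique_tools, 3)

  st2 <- compute_corpus_stats(seq_tbl(c("A", "B"), c("A", "B"), c("A", "C")))
  expect_equal(st2$n_sequences, 3)
  expect_equal(st2$n_unique_sequences, 2)
  expect_equal(st2$per_tool_frequency$n[st2$per_tool_frequency$tool == "A"],
               3L)
  expect_error(compute_corpus_stats(seq_tbl()[0, ]), "empty")

  g <- glance(st2)
  expect_equal(g$n_sequences, 3)
  expect_equal(g$n_unique_sequences, 2)
})

test_that("simulated corpus statistics match the generator's length profile", {
  g <- generate_grammar(60, branching_factor = 2, seed = 3, max_depth = 16)
  corpus <- generate_workflow_corpus(g, 1000, length_range = c(2, 16),
                                     target_median = 9, branch_prob = 0,
                                     seed = 3)
  seqs <- enumerate_linear_sequences(corpus)
  st <- compute_corpus_stats(seqs)
  expect_gte(st$min_length, 2)
  expect_lte(st$max_length, 16)
  expect_lte(abs(st$median_length - 9), 1)
})

test_that("graph serialization round-trips through the edge-list dialect", {
  st <- tiny_study(seed = 9, n_workflows = 4)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(st$corpus, tf)
  back <- read_workflow_corpus(tf)
  expect_length(back, length(st$corpus))
  for (i in seq_along(back)) {
    expect_setequal(back[[i]]$nodes, st$corpus[[i]]$nodes)
    expect_setequal(paste(back[[i]]$edges$from, back[[i]]$edges$to),
                    paste(st$corpus[[i]]$edges$from, st$corpus[[i]]$edges$to))
  }
})

test_that("sequence TSV export round-trips", {
  seqs <- seq_tbl(c("A", "B", "C"), c("X", "Y"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_sequences(seqs, tf)
  back <- read_sequences(tf)
  expect_equal(back$tools, seqs$tools)
  expect_equal(back$workflow_id, seqs$workflow_id)
})
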
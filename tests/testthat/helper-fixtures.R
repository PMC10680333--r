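# shared fixtures and independent oracles

# tiny model configuration used across architecture tests
tiny_config <- function(arch, vocab_size = 6, ...) {
  defaults <- list(
    vocab_size = vocab_size, arch = arch, d_model = 4L, n_heads = 2L,
    head_dim = 3L, ffn_dims = c(5L, 4L), hidden_dense_dim = 4L,
    dropout_rate = 0, max_len = 5L, conv_kernel = c(2L, 2L),
    conv_filters = 3L, pool = c(2L, 2L), gru_units = 4L, batch_size = 4L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}

# 4-node diamond workflow: A -> {B, C} -> D
diamond_graph <- function() {
  workflow_graph("diamond", c("A", "B", "C", "D"),
                 data.frame(from = c("A", "A", "B", "C"),
                            to = c("B", "C", "D", "D")))
}

seq_tbl <- function(...) {
  tools <- list(...)
  tibble::tibble(workflow_id = paste0("wf", seq_along(tools)),
                 tools = tools)
}

# brute-force (prefix -> successor-union) oracle, independent of
# derive_labeled_samples: plain environment-backed accumulation
oracle_samples <- function(sequences, max_len) {
  acc <- new.env(parent = emptyenv())
  for (tools in sequences$tools) {
    L <- length(tools)
    if (L < 2) next
    for (l in seq_len(L - 1)) {
      p <- tools[max(1, l - max_len + 1):l]
      key <- paste(p, collapse = "\r")
      acc[[key]] <- union(acc[[key]], tools[l + 1])
    }
  }
  keys <- sort(ls(acc))
  list(prefixes = lapply(strsplit(keys, "\r", fixed = TRUE), identity),
       labels = lapply(keys, function(k) sort(acc[[k]])))
}

# exhaustive sort-and-intersect precision oracle
oracle_precision <- function(scores, true_labels, k) {
  ranked <- sort.int(scores, decreasing = TRUE, index.return = TRUE,
                     method = "radix")$ix
  sum(ranked[1:k] %in% true_labels) / k
}

# small deterministic synthetic study: grammar, exhaustive corpus,
# samples, split and bins, shared by training/evaluation tests
tiny_study <- function(seed = 11, n_tools = 20, max_depth = 5,
                       n_workflows = 12, max_len = 10) {
  g <- generate_grammar(n_tools, branching_factor = 2, skew_exponent = 1.5,
                        seed = seed, max_depth = max_depth)
  corpus <- generate_workflow_corpus(g, n_workflows,
                                     length_range = c(2, max_depth),
                                     target_median = max_depth - 1,
                                     branch_prob = 1, seed = seed)
  seqs <- enumerate_linear_sequences(corpus)
  vocab <- build_vocabulary(seqs)
  samples <- derive_labeled_samples(seqs, vocab, max_len = max_len)
  split <- split_train_test(samples, 0.8, seed = seed)
  bins <- assign_frequency_bins(split$train, vocab)
  list(grammar = g, corpus = corpus, sequences = seqs, vocab = vocab,
       samples = samples, split = split, bins = bins, max_len = max_len)
}

# train() warns once when tiny corpora leave frequency bins empty;
# tests using deliberately tiny studies silence exactly that warning
quiet_train <- function(...) {
  withCallingHandlers(
    train(...),
    warning = function(w) {
      if (grepl("frequency bin", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

# same, plus progress messages, for the pipeline entry points
quiet_run <- function(expr) {
  withCallingHandlers(
    suppressMessages(expr),
    warning = function(w) {
      if (grepl("frequency bin", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

# minimal native workflow-export JSON: a linear chain with one data
# input feeding the first tool
ga_linear_json <- function(tools = c("toolA", "toolB", "toolC")) {
  steps <- list()
  steps[["0"]] <- list(id = 0, type = "data_input", tool_id = NULL,
                       input_connections = list())
  prev <- 0
  for (i in seq_along(tools)) {
    steps[[as.character(i)]] <- list(
      id = i, type = "tool", tool_id = tools[i],
      input_connections = list(input = list(id = prev,
                                            output_name = "output"))
    )
    prev <- i
  }
  jsonlite::toJSON(list(a_galaxy_workflow = "true", name = "linear",
                        steps = steps), auto_unbox = TRUE)
}
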
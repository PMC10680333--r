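# write a resolved run configuration as plain-text "key: value" lines
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    paste0(k, ": ", paste(format(config[[k]], digits = 15),
                          collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text "key: value" run-configuration file
#'
#' Values containing commas are split into vectors; numeric-looking
#' values are converted.
#'
#' @param path Input file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

log_msg <- function(...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
}

#' Prepare a dataset container from a workflow corpus
#'
#' Parses the corpus, enumerates linear tool sequences, builds the
#' vocabulary, derives (prefix, next-tools) multi-label samples, splits
#' them 80/20 and writes a single dataset container plus the resolved
#' configuration to `out_dir`. Summary statistics are logged to stderr.
#'
#' @param corpus_path Directory or file(s) accepted by
#'   [read_workflow_corpus()].
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for the split.
#' @param max_len Encoded sequence length `N`.
#' @param fraction Training fraction.
#' @return Path of the dataset container, invisibly.
#' @export
run_prepare <- function(corpus_path, out_dir, seed = 1L, max_len = 25L,
                        fraction = 0.8) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  graphs <- read_workflow_corpus(corpus_path)
  sequences <- enumerate_linear_sequences(graphs)
  if (nrow(sequences) == 0) {
    stop("corpus contains no tool sequence of length >= 2", call. = FALSE)
  }
  stats <- compute_corpus_stats(sequences)
  log_msg(stats$n_sequences, " sequences (", stats$n_unique_sequences,
          " unique) from ", stats$n_workflows, " workflows; ",
          stats$n_unique_tools, " tools; lengths ", stats$min_length,
          "-", stats$max_length, " (median ", stats$median_length, ")")
  vocab <- build_vocabulary(sequences)
  samples <- derive_labeled_samples(sequences, vocab, max_len = max_len)
  split <- split_train_test(samples, fraction = fraction, seed = seed)
  log_msg(nrow(samples), " labelled samples: ", nrow(split$train),
          " train / ", nrow(split$test), " test")
  path <- file.path(out_dir, "dataset.json")
  save_dataset(split, vocab, path, max_len = max_len)
  write_run_config(
    list(command = "prepare", corpus_path = paste(corpus_path,
                                                  collapse = ","),
         seed = seed, max_len = max_len, fraction = fraction,
         n_workflows = stats$n_workflows, n_sequences = stats$n_sequences,
         n_unique_tools = stats$n_unique_tools, dataset = path),
    file.path(out_dir, "prepare_config.txt")
  )
  invisible(path)
}

#' Train an architecture on a prepared dataset
#'
#' Loads the container written by [run_prepare()], builds the selected
#' architecture, trains it with frequency-balanced batches, and writes
#' the history TSV, the model bundle and the resolved configuration to
#' `out_dir`.
#'
#' @param dataset_path Dataset container from [run_prepare()].
#' @param out_dir Output directory.
#' @param arch `"transformer"`, `"rnn"`, `"cnn"` or `"dnn"`.
#' @param iterations Optimiser steps.
#' @param eval_every Evaluation cadence.
#' @param seed Integer seed (weight init, batches, dropout).
#' @param ... Overrides forwarded to [model_config()] (e.g. `d_model`,
#'   `batch_size`).
#' @return The `flowrec_training_run`, invisibly.
#' @export
run_train <- function(dataset_path, out_dir, arch = "transformer",
                      iterations = 500L, eval_every = 50L, seed = 1L, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- load_dataset(dataset_path)
  cfg <- model_config(vocab_size = ds$vocab$size, arch = arch,
                      max_len = ds$max_len, iterations = iterations, ...)
  set.seed(seed)
  model <- build_model(cfg)
  log_msg("built ", arch, " with ",
          format(count_trainable_parameters(model), big.mark = ","),
          " trainable parameters")
  bins <- assign_frequency_bins(ds$split$train, ds$vocab)
  run <- train(model, ds$split, bins, iterations = iterations,
               eval_every = eval_every, seed = seed)
  bundle_path <- file.path(out_dir, paste0("model_", arch, ".json"))
  save_bundle(run$model, ds$vocab, bundle_path)
  write_history(run, file.path(out_dir, paste0("history_", arch, ".tsv")))
  echo <- unclass(cfg)
  echo$command <- "train"
  echo$seed <- seed
  echo$eval_every <- eval_every
  echo$dataset <- dataset_path
  echo$bundle <- bundle_path
  write_run_config(echo, file.path(out_dir,
                                   paste0("train_config_", arch, ".txt")))
  last <- run$history[nrow(run$history), ]
  log_msg("finished: loss ", signif(last$loss, 4), ", test precision@k ",
          signif(last$precision_at_k, 4))
  invisible(run)
}

#' Evaluate a trained bundle on a prepared dataset
#'
#' Writes overall and lowest-25% (infrequent-tool) precision@k reports
#' to `out_dir/evaluation.tsv`.
#'
#' @param bundle_path Saved bundle.
#' @param dataset_path Dataset container.
#' @param out_dir Output directory.
#' @param k k-policy; `"labels"` or a fixed integer.
#' @return Tibble with one row per report, invisibly.
#' @export
run_evaluate <- function(bundle_path, dataset_path, out_dir, k = "labels") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- load_bundle(bundle_path)
  ds <- load_dataset(dataset_path)
  if (!identical(bundle$vocab$tool_of, ds$vocab$tool_of)) {
    stop("vocabulary mismatch between bundle and dataset", call. = FALSE)
  }
  bins <- assign_frequency_bins(ds$split$train, ds$vocab)
  overall <- evaluate_model(bundle, ds$split$test, k = k)
  rare <- tryCatch(
    evaluate_infrequent_tools(bundle, ds$split$test, bins, k = k),
    error = function(e) NULL
  )
  reports <- list(overall, rare)
  out <- dplyr::bind_rows(lapply(Filter(Negate(is.null), reports), glance))
  utils::write.table(out, file.path(out_dir, "evaluation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_run_config(list(command = "evaluate", bundle = bundle_path,
                        dataset = dataset_path,
                        k = if (identical(k, "labels")) "labels" else k),
                   file.path(out_dir, "evaluate_config.txt"))
  log_msg("overall precision@k ", signif(overall$mean_precision, 4),
          if (!is.null(rare)) paste0("; lowest-25% ",
                                     signif(rare$mean_precision, 4)))
  invisible(out)
}

#' Plot self-attention weights for a prefix
#'
#' Writes the head-averaged `N x N` attention matrix as TSV (query
#' positions in rows, key positions in columns, tool names as labels)
#' and a heatmap image.
#'
#' @param bundle_path Saved transformer bundle.
#' @param prefix Character vector of tool names.
#' @param out_dir Output directory.
#' @return The `flowrec_attention` object, invisibly.
#' @export
run_plot_attention <- function(bundle_path, prefix, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- load_bundle(bundle_path)
  ids <- encode_and_pad(prefix, bundle$vocab, bundle$model$config$max_len)
  am <- attention_matrix(bundle$model, ids, vocab = bundle$vocab)
  m <- am$mean
  dimnames(m) <- list(am$labels, am$labels)
  utils::write.table(m, file.path(out_dir, "attention_mean.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  p <- ggplot2::autoplot(am)
  ggplot2::ggsave(file.path(out_dir, "attention_mean.png"), p,
                  width = 7, height = 6, dpi = 150)
  write_run_config(list(command = "plot-attention", bundle = bundle_path,
                        prefix = paste(prefix, collapse = ",")),
                   file.path(out_dir, "plot_attention_config.txt"))
  invisible(am)
}
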
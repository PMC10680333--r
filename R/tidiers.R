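#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training run into its history tibble
#'
#' @param x A `flowrec_training_run`.
#' @param ... Unused.
#' @return Tibble with columns `iteration`, `loss`, `precision_at_k`.
#' @method tidy flowrec_training_run
#' @export
tidy.flowrec_training_run <- function(x, ...) x$history

#' One-row summary of a training run
#'
#' @param x A `flowrec_training_run`.
#' @param ... Unused.
#' @return One-row tibble: architecture, parameters, iterations, seed,
#'   final loss and final test precision@k.
#' @method glance flowrec_training_run
#' @export
glance.flowrec_training_run <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(arch = x$config$arch,
                 n_parameters = count_trainable_parameters(x$model),
                 iterations = x$iterations, seed = x$seed,
                 final_loss = last$loss,
                 final_precision_at_k = last$precision_at_k)
}

#' Per-sample precision values of an evaluation report
#'
#' @param x A `flowrec_eval_report`.
#' @param ... Unused.
#' @return Tibble with columns `sample`, `precision`.
#' @method tidy flowrec_eval_report
#' @export
tidy.flowrec_eval_report <- function(x, ...) {
  tibble::tibble(sample = seq_len(x$n_samples),
                 precision = x$per_sample_precision)
}

#' One-row summary of an evaluation report
#'
#' @param x A `flowrec_eval_report`.
#' @param ... Unused.
#' @return One-row tibble: subset, n_samples, mean_precision.
#' @method glance flowrec_eval_report
#' @export
glance.flowrec_eval_report <- function(x, ...) {
  tibble::tibble(subset = x$subset_label, n_samples = x$n_samples,
                 mean_precision = x$mean_precision)
}

#' One-row summary of corpus statistics
#'
#' @param x A `flowrec_corpus_stats`.
#' @param ... Unused.
#' @return One-row tibble of the corpus-level counts and length
#'   statistics.
#' @method glance flowrec_corpus_stats
#' @export
glance.flowrec_corpus_stats <- function(x, ...) {
  tibble::tibble(n_workflows = x$n_workflows, n_sequences = x$n_sequences,
                 n_unique_sequences = x$n_unique_sequences,
                 n_unique_tools = x$n_unique_tools,
                 min_length = x$min_length, median_length = x$median_length,
                 max_length = x$max_length)
}

#' Long-format attention weights
#'
#' @param x A `flowrec_attention`.
#' @param ... Unused.
#' @return Tibble with columns `query`, `key` (positions), `query_tool`,
#'   `key_tool`, `head` ("mean" or the head number) and `weight`.
#' @method tidy flowrec_attention
#' @export
tidy.flowrec_attention <- function(x, ...) {
  N <- length(x$labels)
  one <- function(m, head) {
    tibble::tibble(query = rep(seq_len(N), times = N),
                   key = rep(seq_len(N), each = N),
                   query_tool = rep(x$labels, times = N),
                   key_tool = rep(x$labels, each = N),
                   head = head, weight = as.vector(m))
  }
  dplyr::bind_rows(c(list(one(x$mean, "mean")),
                     lapply(seq_along(x$heads), function(h) {
                       one(x$heads[[h]], as.character(h))
                     })))
}

#' Heatmap of head-averaged self-attention weights
#'
#' @param object A `flowrec_attention`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flowrec_attention
#' @export
autoplot.flowrec_attention <- function(object, ...) {
  df <- tidy.flowrec_attention(object)
  df <- df[df$head == "mean", ]
  N <- length(object$labels)
  lab <- make.unique(object$labels)
  df$qf <- factor(rep(lab, times = N), levels = rev(lab))
  df$kf <- factor(rep(lab, each = N), levels = lab)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kf, y = .data$qf,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "attention") +
    ggplot2::labs(x = "key position (tool)", y = "query position (tool)",
                  title = "Head-averaged self-attention weights") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Training curves: loss and test precision@k over iterations
#'
#' @param object A `flowrec_training_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flowrec_training_run
#' @export
autoplot.flowrec_training_run <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("loss", "precision_at_k"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "training iteration", y = NULL,
                  title = paste("Training curves:", object$config$arch)) +
    ggplot2::theme_minimal()
}
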
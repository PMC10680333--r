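#' Precision@k for one score vector
#'
#' Fraction of the k highest-scoring positions that are true labels:
#' `|top-k(scores) intersect true_labels| / k`. Ranking is by
#' descending score with ties broken by ascending position, so the
#' metric is deterministic and invariant under strictly monotone
#' transforms of the scores.
#'
#' @param scores Numeric vector of scores.
#' @param true_labels Integer positions (1-based, into `scores`) of the
#'   true labels; non-empty.
#' @param k Cut-off; defaults to the number of true labels.
#' @return Precision in `[0, 1]`.
#' @export
precision_at_k <- function(scores, true_labels, k = length(true_labels)) {
  stopifnot(length(true_labels) >= 1, k >= 1)
  if (k > length(scores)) {
    stop("k (", k, ") exceeds the score-vector length (", length(scores),
         ")", call. = FALSE)
  }
  top <- order(-scores, seq_along(scores))[seq_len(k)]
  length(intersect(top, true_labels)) / k
}

# per-sample precision of a score matrix against label-index lists;
# the padding column (position 1) is excluded from the ranking
model_precision <- function(scores, labels_list, k = "labels") {
  scores[, 1] <- -Inf
  vapply(seq_along(labels_list), function(i) {
    lab <- labels_list[[i]] + 1L
    kk <- if (identical(k, "labels")) length(lab) else as.integer(k)
    precision_at_k(scores[i, ], lab, kk)
  }, numeric(1))
}

resolve_model <- function(x) {
  if (inherits(x, "flowrec_bundle")) x$model
  else if (inherits(x, "flowrec_training_run")) x$model
  else if (inherits(x, "flowrec_model")) x
  else stop("expected a model, bundle or training run", call. = FALSE)
}

# batched sigmoid scores for a samples tibble
score_samples <- function(model, samples, batch = 256L) {
  n <- nrow(samples)
  out <- matrix(0, n, model$config$vocab_out)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch - 1L, n)
    ids <- do.call(rbind, samples$input_ids[i:j])
    out[i:j, ] <- predict(model, ids)
    i <- j + 1L
  }
  out
}

#' Evaluate a model on labelled samples
#'
#' Mean precision@k over the given samples. The default k-policy uses
#' k equal to each sample's number of true labels; pass an integer for
#' a fixed cut-off (e.g. `k = 20` for top-20 recommendations).
#'
#' @param x A `flowrec_model`, `flowrec_bundle` or training run.
#' @param samples Tibble of labelled samples (e.g. `split$test`).
#' @param k `"labels"` or a positive integer.
#' @param subset_label Annotation recorded in the report.
#' @return A `flowrec_eval_report`: `mean_precision`,
#'   `per_sample_precision`, `n_samples`, `subset_label`.
#' @export
evaluate_model <- function(x, samples, k = "labels", subset_label = "all") {
  model <- resolve_model(x)
  if (nrow(samples) == 0) stop("no samples to evaluate", call. = FALSE)
  max_label <- max(unlist(samples$labels))
  if (max_label + 1L > model$config$vocab_out) {
    stop("vocabulary mismatch: label index ", max_label,
         " exceeds the model's output dimension", call. = FALSE)
  }
  scores <- score_samples(model, samples)
  per <- model_precision(scores, samples$labels, k)
  structure(list(mean_precision = mean(per), per_sample_precision = per,
                 n_samples = length(per), subset_label = subset_label),
            class = "flowrec_eval_report")
}

#' @export
print.flowrec_eval_report <- function(x, ...) {
  cat("<evaluation: ", x$subset_label, "> mean precision@k ",
      signif(x$mean_precision, 4), " over ", x$n_samples, " samples\n",
      sep = "")
  invisible(x)
}

#' Evaluate on samples carrying infrequent-tool labels
#'
#' Restricts the evaluation to test samples whose true-label set
#' intersects (`match = "any"`, default) or is contained in
#' (`match = "all"`) the lowest label-frequency quartile bin, then
#' applies the same precision@k metric.
#'
#' @inheritParams evaluate_model
#' @param bins A [assign_frequency_bins()] result.
#' @param match `"any"` or `"all"`.
#' @return A `flowrec_eval_report` with `subset_label = "lowest-25%"`.
#' @export
evaluate_infrequent_tools <- function(x, samples, bins, k = "labels",
                                      match = c("any", "all")) {
  match <- match.arg(match)
  rare <- bins$tools$index[bins$tools$bin == 1L]
  f <- if (match == "any") {
    function(l) any(l %in% rare)
  } else {
    function(l) all(l %in% rare)
  }
  keep <- vapply(samples$labels, f, logical(1))
  if (!any(keep)) {
    stop("no samples carry labels from the lowest-frequency bin",
         call. = FALSE)
  }
  evaluate_model(x, samples[keep, ], k = k, subset_label = "lowest-25%")
}

#' Measure model usage time (reconstruction + prediction)
#'
#' Wall time to reconstruct a model from its saved bundle plus the wall
#' time of one forward pass on a query prefix — the latency a workflow
#' editor pays per recommendation request. The median over `repeats`
#' measurements is reported (robust to warm-up outliers).
#'
#' @param bundle_path Path to a saved bundle.
#' @param prefix Character vector of tool names to predict from.
#' @param repeats Number of measurements (>= 1).
#' @return List with `reconstruction`, `prediction` and `total` medians
#'   (seconds) and a `raw` tibble of the individual measurements.
#' @export
measure_usage_time <- function(bundle_path, prefix, repeats = 3L) {
  stopifnot(repeats >= 1)
  rec <- numeric(repeats); prd <- numeric(repeats)
  for (r in seq_len(repeats)) {
    t0 <- proc.time()[["elapsed"]]
    bundle <- load_bundle(bundle_path)
    t1 <- proc.time()[["elapsed"]]
    ids <- encode_and_pad(prefix, bundle$vocab, bundle$model$config$max_len)
    invisible(predict(bundle$model, ids))
    t2 <- proc.time()[["elapsed"]]
    rec[r] <- t1 - t0
    prd[r] <- t2 - t1
  }
  list(reconstruction = stats::median(rec),
       prediction = stats::median(prd),
       total = stats::median(rec + prd),
       raw = tibble::tibble(repeat_id = seq_len(repeats),
                            reconstruction = rec, prediction = prd,
                            total = rec + prd))
}
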
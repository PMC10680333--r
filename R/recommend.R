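#' Predict next-tool scores for a tool prefix
#'
#' Encodes the prefix with the bundle's vocabulary (left-padded,
#' truncated to the most recent `max_len` tools) and runs one forward
#' pass. Deterministic: the same prefix always yields the same scores.
#'
#' @param bundle A [load_bundle()] result (or a list with `model` and
#'   `vocab`).
#' @param prefix Character vector of tool names (length >= 1).
#' @return Named numeric vector of sigmoid scores over the vocabulary
#'   (the unused padding slot is dropped), all values in (0, 1).
#' @export
predict_scores <- function(bundle, prefix) {
  unknown <- setdiff(prefix, names(bundle$vocab$index_of))
  if (length(unknown) > 0) {
    stop("unknown tool(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ids <- encode_and_pad(prefix, bundle$vocab, bundle$model$config$max_len)
  s <- predict(bundle$model, ids)[1, ]
  stats::setNames(s[-1], bundle$vocab$tool_of)
}

#' Rank the top-n recommended tools
#'
#' The n highest-scoring tools in descending score order, ties broken
#' by vocabulary index (ascending). Padding or unused indices are never
#' recommended.
#'
#' @param scores Named score vector from [predict_scores()].
#' @param n Number of recommendations, `1 <= n <= length(scores)`.
#' @return Tibble with columns `rank`, `tool`, `score`.
#' @export
recommend_top_n <- function(scores, n) {
  if (n < 1 || n > length(scores)) {
    stop("n must be between 1 and ", length(scores), call. = FALSE)
  }
  ord <- order(-scores, seq_along(scores))[seq_len(n)]
  tibble::tibble(rank = seq_len(n),
                 tool = names(scores)[ord],
                 score = unname(scores[ord]))
}

#' Post-process recommendations: deprecation filter and usage re-rank
#'
#' Removes recommendations whose tool is deprecated or otherwise
#' unavailable, then re-sorts the survivors in descending order of
#' their usage in the last year. Ties are broken by model score
#' (descending) and then tool name; tools absent from the usage table
#' count as zero usage, so with an empty table the order falls back to
#' the model scores. Ranks are reassigned 1..m. The operation is
#' idempotent.
#'
#' @param recs Tibble from [recommend_top_n()].
#' @param deprecated Character vector of deprecated/unavailable tools.
#' @param usage A usage table: tibble with columns `tool`, `count`, or
#'   a named numeric vector, or `NULL`.
#' @return Tibble with columns `rank`, `tool`, `score`, `usage`.
#' @export
postprocess <- function(recs, deprecated = character(0), usage = NULL) {
  if (is.data.frame(usage)) {
    usage <- stats::setNames(usage$count, usage$tool)
  }
  out <- recs[!recs$tool %in% deprecated, , drop = FALSE]
  cnt <- if (is.null(usage)) numeric(nrow(out)) else {
    u <- usage[out$tool]
    u[is.na(u)] <- 0
    unname(u)
  }
  ord <- order(-cnt, -out$score, out$tool, method = "radix")
  tibble::tibble(rank = seq_len(nrow(out)),
                 tool = out$tool[ord],
                 score = out$score[ord],
                 usage = cnt[ord])
}

#' Recommend next tools for a prefix, end to end
#'
#' Convenience wrapper: [predict_scores()], [recommend_top_n()],
#' [postprocess()].
#'
#' @inheritParams predict_scores
#' @param n Number of raw recommendations before filtering.
#' @param deprecated,usage Passed to [postprocess()].
#' @return Tibble with columns `rank`, `tool`, `score`, `usage`.
#' @export
recommend_tools <- function(bundle, prefix, n = 20L,
                            deprecated = character(0), usage = NULL) {
  scores <- predict_scores(bundle, prefix)
  postprocess(recommend_top_n(scores, min(n, length(scores))),
              deprecated = deprecated, usage = usage)
}

#' Read a tool-usage table
#'
#' TSV with two columns, `tool<TAB>count` (no header), giving each
#' tool's usage count in the last year.
#'
#' @param path Input file.
#' @return Tibble with columns `tool`, `count`.
#' @export
read_usage_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("tool", "count"),
                          colClasses = c("character", "numeric"),
                          quote = "", comment.char = "")
  if (any(df$count < 0)) stop("usage counts must be >= 0", call. = FALSE)
  tibble::as_tibble(df)
}

#' Read a deprecated-tool list
#'
#' Plain text, one tool name per line; blank lines ignored.
#'
#' @param path Input file.
#' @return Character vector of tool names.
#' @export
read_deprecated_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}
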
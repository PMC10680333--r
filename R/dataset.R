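#' Build the tool vocabulary
#'
#' Assigns each distinct tool a positive integer index, ordered by
#' descending total occurrence frequency with lexicographic
#' tie-breaking. Index 0 is reserved for padding and never assigned.
#'
#' @param sequences Tibble from [enumerate_linear_sequences()].
#' @return A `flowrec_vocab`: `index_of` (named integer vector),
#'   `tool_of` (character vector, position = index), `size`.
#' @export
build_vocabulary <- function(sequences) {
  if (!is.data.frame(sequences) || nrow(sequences) == 0) {
    stop("cannot build a vocabulary from an empty corpus", call. = FALSE)
  }
  freq <- table(unlist(sequences$tools, use.names = FALSE))
  ord <- order(-as.integer(freq), names(freq), method = "radix")
  tools <- names(freq)[ord]
  index_of <- stats::setNames(seq_along(tools), tools)
  structure(list(index_of = index_of, tool_of = tools,
                 size = length(tools)),
            class = "flowrec_vocab")
}

#' @export
print.flowrec_vocab <- function(x, ...) {
  cat("<tool vocabulary> ", x$size, " tools (index 0 = padding)\n", sep = "")
  invisible(x)
}

#' Encode a tool prefix as a fixed-length integer vector
#'
#' Maps tools to their vocabulary indices and left-pads with zeros so
#' the most recent tool always sits at the final position. Prefixes
#' longer than `max_len` keep only their last `max_len` tools.
#'
#' @param prefix Character vector of tool names (length >= 1).
#' @param vocab A [build_vocabulary()] result.
#' @param max_len Encoded length `N`.
#' @return Integer vector of length `max_len`.
#' @export
encode_and_pad <- function(prefix, vocab, max_len = 25L) {
  stopifnot(length(prefix) >= 1, max_len >= 2)
  unknown <- setdiff(prefix, names(vocab$index_of))
  if (length(unknown) > 0) {
    stop("unknown tool(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  ids <- unname(vocab$index_of[utils::tail(prefix, max_len)])
  c(integer(max_len - length(ids)), ids)
}

#' Decode an encoded vector back to tool names
#'
#' Strips the padding zeros and maps indices back to tool names;
#' inverse of [encode_and_pad()] up to truncation.
#'
#' @param input_ids Integer vector (0 = padding).
#' @param vocab A [build_vocabulary()] result.
#' @return Character vector of tool names.
#' @export
decode_ids <- function(input_ids, vocab) {
  ids <- input_ids[input_ids != 0L]
  vocab$tool_of[ids]
}

#' Multi-hot label encoding
#'
#' Encodes a set of next-tool labels as a binary vector of length
#' `V + 1`, where position `i + 1` corresponds to tool index `i`
#' (position 1, the padding index, is never set).
#'
#' @param labels Character vector of tool names (non-empty set).
#' @param vocab A [build_vocabulary()] result.
#' @return Binary numeric vector of length `vocab$size + 1` with
#'   exactly `length(unique(labels))` ones.
#' @export
to_multi_hot <- function(labels, vocab) {
  labels <- unique(labels)
  if (length(labels) == 0) stop("empty label set", call. = FALSE)
  unknown <- setdiff(labels, names(vocab$index_of))
  if (length(unknown) > 0) {
    stop("unknown tool(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  v <- numeric(vocab$size + 1L)
  v[vocab$index_of[labels] + 1L] <- 1
  v
}

# label index vectors -> dense multi-hot matrix (vocab_out columns)
multi_hot_matrix <- function(label_list, vocab_out) {
  m <- matrix(0, length(label_list), vocab_out)
  for (i in seq_along(label_list)) m[i, label_list[[i]] + 1L] <- 1
  m
}

#' Derive multi-label training samples from tool sequences
#'
#' For every proper prefix of every sequence, one sample is produced
#' whose label set is the union, over the whole corpus, of the tools
#' observed to immediately follow that prefix. Prefixes longer than
#' `max_len` are truncated to their most recent `max_len` tools before
#' uniquing, so the sample key is the truncated prefix. Output order is
#' deterministic (lexicographic by prefix).
#'
#' @param sequences Tibble from [enumerate_linear_sequences()].
#' @param vocab A [build_vocabulary()] result.
#' @param max_len Encoded length `N` (>= 2).
#' @return A tibble with one row per distinct (truncated) prefix:
#'   `raw_prefix` (list of character vectors), `input_ids` (list of
#'   padded integer vectors), `labels` (list of integer tool indices,
#'   sorted).
#' @export
derive_labeled_samples <- function(sequences, vocab, max_len = 25L) {
  stopifnot(max_len >= 2)
  per_seq <- lapply(sequences$tools, function(tools) {
    L <- length(tools)
    if (L < 2) return(NULL)
    ks <- character(L - 1L)
    for (l in seq_len(L - 1L)) {
      ks[l] <- paste(tools[max(1L, l - max_len + 1L):l], collapse = "\t")
    }
    cbind(ks, tools[-1L])
  })
  m <- do.call(rbind, per_seq)
  if (is.null(m)) {
    return(tibble::tibble(raw_prefix = list(), input_ids = list(),
                          labels = list()))
  }
  df <- dplyr::distinct(tibble::tibble(key = m[, 1], succ = m[, 2]))
  df <- dplyr::arrange(df, .data$key)
  grp <- split(df$succ, factor(df$key, levels = unique(df$key)))
  prefixes <- unname(strsplit(names(grp), "\t", fixed = TRUE))
  tibble::tibble(
    raw_prefix = prefixes,
    input_ids = lapply(prefixes, encode_and_pad, vocab = vocab,
                       max_len = max_len),
    labels = unname(lapply(grp, function(s) {
      sort(unname(vocab$index_of[unique(s)]))
    }))
  )
}

#' Split samples into train and test sets
#'
#' Uniform random split by sample, reproducible under `seed`. Samples
#' are distinct by prefix, so the two sets are disjoint by prefix
#' identity.
#'
#' @param samples Tibble from [derive_labeled_samples()].
#' @param fraction Training fraction in (0, 1); 0.8 matches the
#'   training protocol.
#' @param seed Integer seed.
#' @return A `flowrec_split`: list with `train`, `test` (tibbles) and
#'   `seed`.
#' @export
split_train_test <- function(samples, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(samples)
  if (n < 2) stop("need at least 2 samples to split", call. = FALSE)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  idx <- sample.int(n)
  n_train <- max(1L, min(n - 1L, round(fraction * n)))
  structure(list(train = samples[sort(idx[seq_len(n_train)]), ],
                 test = samples[sort(idx[(n_train + 1L):n]), ],
                 seed = as.integer(seed)),
            class = "flowrec_split")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' @export
print.flowrec_split <- function(x, ...) {
  cat("<train/test split> ", nrow(x$train), " train / ", nrow(x$test),
      " test (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Partition tools into label-frequency quartile bins
#'
#' Computes, for every vocabulary tool, how many samples carry it as a
#' label, and partitions the tools into 4 bins at the 25/50/75
#' percentiles of the (positive) label-frequency distribution. Tools
#' that never occur as a label join the lowest-frequency bin. Bin 1
#' holds the rarest labels.
#'
#' @param samples Tibble from [derive_labeled_samples()].
#' @param vocab A [build_vocabulary()] result.
#' @return A `flowrec_bins`: tibble `tools` (tool, index, freq, bin)
#'   plus the quartile `boundaries`.
#' @export
assign_frequency_bins <- function(samples, vocab) {
  if (nrow(samples) == 0) stop("no samples", call. = FALSE)
  freq <- integer(vocab$size)
  lab <- unlist(samples$labels, use.names = FALSE)
  tab <- table(lab)
  freq[as.integer(names(tab))] <- as.integer(tab)
  pos <- freq[freq > 0]
  bounds <- stats::quantile(pos, c(0.25, 0.5, 0.75), names = FALSE)
  bin <- 1L + (freq > bounds[1]) + (freq > bounds[2]) + (freq > bounds[3])
  structure(list(
    tools = tibble::tibble(tool = vocab$tool_of,
                           index = seq_len(vocab$size),
                           freq = freq, bin = as.integer(bin)),
    boundaries = bounds
  ), class = "flowrec_bins")
}

#' @export
print.flowrec_bins <- function(x, ...) {
  cat("<frequency bins> boundaries ",
      paste(signif(x$boundaries, 4), collapse = " / "),
      "; bin sizes ", paste(table(factor(x$tools$bin, levels = 1:4)),
                            collapse = "/"), "\n", sep = "")
  invisible(x)
}

# indices of samples whose label set intersects each bin
bin_eligibility <- function(samples, bins) {
  bin_of <- bins$tools$bin
  lapply(1:4, function(b) {
    tools_b <- bins$tools$index[bin_of == b]
    which(vapply(samples$labels, function(l) any(l %in% tools_b),
                 logical(1)))
  })
}

#' Sample a frequency-balanced training batch
#'
#' Draws `batch_size` samples so that labels of similar frequency are
#' comparably represented: a quartile bin is chosen uniformly for each
#' slot, then a sample whose label set intersects that bin is drawn
#' uniformly with replacement. Bins with no eligible sample are skipped
#' with a warning; if no bin has eligible samples an error is raised.
#' Uses the current RNG state unless `seed` is given.
#'
#' @param samples Training-sample tibble (e.g. `split$train`).
#' @param bins A [assign_frequency_bins()] result.
#' @param batch_size Number of samples to draw (>= number of bins).
#' @param seed Optional integer seed.
#' @param eligibility Optional precomputed [bin] eligibility (internal
#'   speed-up for the training loop).
#' @param warn_empty Warn when bins are skipped (the training loop warns
#'   once instead of per batch).
#' @return A tibble of `batch_size` rows sampled from `samples`.
#' @export
sample_balanced_batch <- function(samples, bins, batch_size, seed = NULL,
                                  eligibility = NULL, warn_empty = TRUE) {
  stopifnot(batch_size >= 4)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(eligibility)) eligibility <- bin_eligibility(samples, bins)
  nonempty <- which(lengths(eligibility) > 0)
  if (length(nonempty) == 0) {
    stop("no bin has eligible samples", call. = FALSE)
  }
  if (warn_empty && length(nonempty) < 4) {
    warning("skipping ", 4 - length(nonempty),
            " bin(s) with no eligible samples")
  }
  draws <- nonempty[sample.int(length(nonempty), batch_size, replace = TRUE)]
  idx <- integer(batch_size)
  for (b in nonempty) {
    sel <- draws == b
    if (any(sel)) {
      pool <- eligibility[[b]]
      idx[sel] <- pool[sample.int(length(pool), sum(sel), replace = TRUE)]
    }
  }
  samples[idx, ]
}

#' Save / load a prepared dataset container
#'
#' A single JSON file holding the encoded samples of both splits, the
#' vocabulary, the maximum length and the split seed. Writing is
#' deterministic: the same split produces a byte-identical file.
#'
#' @param split A [split_train_test()] result.
#' @param vocab The vocabulary the samples were encoded with.
#' @param path Output file.
#' @param max_len Encoded length `N` used for the samples.
#' @return `path`, invisibly (writer); a list with `split`, `vocab`,
#'   `max_len` (reader).
#' @export
save_dataset <- function(split, vocab, path, max_len = 25L) {
  enc <- function(s) {
    list(ids = lapply(s$input_ids, as.integer),
         labels = lapply(s$labels, as.integer))
  }
  obj <- list(format_version = "1", kind = "flowrec_dataset",
              seed = split$seed, max_len = as.integer(max_len),
              tools = vocab$tool_of,
              train = enc(split$train), test = enc(split$test))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path,
                               call. = FALSE)
  obj <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyVector = FALSE)
  if (!identical(obj$kind, "flowrec_dataset")) {
    stop("not a dataset container: ", path, call. = FALSE)
  }
  tools <- unlist(obj$tools)
  vocab <- structure(list(index_of = stats::setNames(seq_along(tools), tools),
                          tool_of = tools, size = length(tools)),
                     class = "flowrec_vocab")
  dec <- function(s) {
    ids <- lapply(s$ids, function(v) as.integer(unlist(v)))
    tibble::tibble(
      raw_prefix = lapply(ids, decode_ids, vocab = vocab),
      input_ids = ids,
      labels = lapply(s$labels, function(v) as.integer(unlist(v)))
    )
  }
  split <- structure(list(train = dec(obj$train), test = dec(obj$test),
                          seed = as.integer(obj$seed)),
                     class = "flowrec_split")
  list(split = split, vocab = vocab, max_len = as.integer(obj$max_len))
}
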
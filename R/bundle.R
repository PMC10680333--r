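#' Save a trained model, its vocabulary and configuration in one file
#'
#' The bundle is a single JSON container with three groups —
#' `weights`, `config`, `vocabulary` — mirroring the layout of a
#' hierarchical model file. Weight tensors are stored as base64-encoded
#' little-endian doubles, so a reloaded model reproduces the original's
#' predictions bitwise.
#'
#' @param model A `flowrec_model`.
#' @param vocab The [build_vocabulary()] result the model was trained
#'   with.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_bundle <- function(model, vocab, path) {
  stopifnot(inherits(model, "flowrec_model"),
            inherits(vocab, "flowrec_vocab"))
  if (model$config$vocab_size != vocab$size) {
    stop("model was built for ", model$config$vocab_size,
         " tools but the vocabulary has ", vocab$size, call. = FALSE)
  }
  weights <- lapply(model$weights, function(w) {
    list(dim = if (is.matrix(w)) dim(w) else length(w),
         data = jsonlite::base64_enc(writeBin(as.numeric(w), raw(),
                                              size = 8L,
                                              endian = "little")))
  })
  cfg <- unclass(model$config)
  obj <- list(format_version = "1", kind = "flowrec_bundle",
              config = cfg,
              vocabulary = as.list(vocab$index_of),
              weights = weights)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Load a model bundle
#'
#' @param path A file written by [save_bundle()].
#' @return A `flowrec_bundle`: list with `model`, `vocab`,
#'   `format_version`.
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) {
    stop("bundle file not found: ", path, call. = FALSE)
  }
  obj <- tryCatch(
    jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                             collapse = "\n"),
                       simplifyVector = FALSE),
    error = function(e) {
      stop("corrupt bundle container: ", conditionMessage(e), call. = FALSE)
    }
  )
  if (!identical(obj$kind, "flowrec_bundle") || is.null(obj$weights)) {
    stop("corrupt bundle container: not a model bundle", call. = FALSE)
  }
  if (!identical(obj$format_version, "1")) {
    stop("unsupported bundle format version: ",
         obj$format_version %||% "<missing>", call. = FALSE)
  }
  cfg_in <- obj$config
  cfg <- model_config(
    vocab_size = cfg_in$vocab_size, arch = cfg_in$arch,
    d_model = cfg_in$d_model, n_heads = cfg_in$n_heads,
    head_dim = cfg_in$head_dim, ffn_dims = unlist(cfg_in$ffn_dims),
    hidden_dense_dim = cfg_in$hidden_dense_dim,
    dropout_rate = cfg_in$dropout_rate, max_len = cfg_in$max_len,
    conv_kernel = unlist(cfg_in$conv_kernel),
    conv_filters = cfg_in$conv_filters, pool = unlist(cfg_in$pool),
    gru_units = cfg_in$gru_units, gru_layers = cfg_in$gru_layers,
    learning_rate = cfg_in$learning_rate, batch_size = cfg_in$batch_size,
    iterations = cfg_in$iterations
  )
  weights <- lapply(obj$weights, function(w) {
    dims <- unlist(w$dim)
    vals <- readBin(jsonlite::base64_dec(w$data), "numeric",
                    n = prod(dims), size = 8L, endian = "little")
    if (length(vals) != prod(dims)) {
      stop("corrupt bundle container: truncated weight tensor",
           call. = FALSE)
    }
    if (length(dims) == 2) matrix(vals, dims[1], dims[2]) else vals
  })
  model <- new_model(cfg$arch, cfg, weights)
  tools <- names(obj$vocabulary)
  idx <- vapply(obj$vocabulary, as.integer, integer(1))
  tool_of <- character(length(tools))
  tool_of[idx] <- tools
  vocab <- structure(list(index_of = stats::setNames(idx, tools),
                          tool_of = tool_of, size = length(tools)),
                     class = "flowrec_vocab")
  structure(list(model = model, vocab = vocab, format_version = "1"),
            class = "flowrec_bundle")
}

#' @export
print.flowrec_bundle <- function(x, ...) {
  cat("<model bundle, format 1>\n")
  print(x$model)
  invisible(x)
}
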
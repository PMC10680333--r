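#' Model configuration
#'
#' Collects every architecture and training hyperparameter in one place.
#' Defaults reproduce the full-scale recommender: 128-dimensional token
#' and positional embeddings, one encoder block with 4 attention heads
#' of 128 dimensions each, a position-wise feed-forward network of two
#' 128-unit layers, a 128-unit hidden dense layer, dropout 0.2,
#' sequences of at most 25 tools, Adam with learning rate 0.001 on
#' binary cross-entropy, batch size 512.
#'
#' The input-embedding row count depends on the architecture: the
#' transformer uses `vocab_size + 1` rows (tools plus the padding
#' index 0) while the GRU/CNN/DNN comparators use `vocab_size + 2`
#' (one extra reserved row, e.g. out-of-vocabulary). The output layer
#' always has `vocab_size + 1` units, with the padding index unused.
#'
#' @param vocab_size Number of distinct tools `V` in the vocabulary.
#' @param arch One of `"transformer"`, `"rnn"`, `"cnn"`, `"dnn"`.
#' @param d_model Embedding / model width.
#' @param n_heads Number of attention heads.
#' @param head_dim Per-head attention dimension (total projection width
#'   is `n_heads * head_dim`).
#' @param ffn_dims Two feed-forward layer widths; the second must equal
#'   `d_model` for the residual connection.
#' @param hidden_dense_dim Width of the hidden dense layer before the
#'   sigmoid output.
#' @param dropout_rate Dropout rate in `[0, 1)`.
#' @param max_len Maximum encoded sequence length `N`.
#' @param conv_kernel Convolution kernel size (rows, cols).
#' @param conv_filters Number of convolution filters.
#' @param pool Max-pool size (rows, cols).
#' @param gru_units,gru_layers GRU width and stack depth.
#' @param learning_rate,batch_size,iterations Training protocol.
#' @return A `flowrec_config` list.
#' @export
model_config <- function(vocab_size,
                         arch = c("transformer", "rnn", "cnn", "dnn"),
                         d_model = 128L, n_heads = 4L, head_dim = 128L,
                         ffn_dims = c(128L, 128L), hidden_dense_dim = 128L,
                         dropout_rate = 0.2, max_len = 25L,
                         conv_kernel = c(16L, 3L), conv_filters = 128L,
                         pool = c(2L, 2L), gru_units = 128L, gru_layers = 2L,
                         learning_rate = 0.001, batch_size = 512L,
                         iterations = 35000L) {
  arch <- match.arg(arch)
  stopifnot(
    vocab_size >= 1, d_model >= 1, n_heads >= 1, head_dim >= 1,
    length(ffn_dims) == 2, all(ffn_dims >= 1), hidden_dense_dim >= 1,
    dropout_rate >= 0, dropout_rate < 1, max_len >= 2,
    all(conv_kernel >= 1), conv_filters >= 1, all(pool >= 1),
    gru_units >= 1, gru_layers == 2, learning_rate > 0, batch_size >= 1
  )
  if (arch == "transformer" && ffn_dims[2] != d_model) {
    stop("ffn_dims[2] must equal d_model (residual connection)",
         call. = FALSE)
  }
  if (arch == "cnn") {
    if (max_len < conv_kernel[1] || d_model < conv_kernel[2]) {
      stop("convolution kernel larger than the input image", call. = FALSE)
    }
  }
  cfg <- list(
    arch = arch,
    vocab_size = as.integer(vocab_size),
    vocab_in = as.integer(vocab_size) +
      (if (arch == "transformer") 1L else 2L),
    vocab_out = as.integer(vocab_size) + 1L,
    d_model = as.integer(d_model), n_heads = as.integer(n_heads),
    head_dim = as.integer(head_dim), ffn_dims = as.integer(ffn_dims),
    hidden_dense_dim = as.integer(hidden_dense_dim),
    dropout_rate = dropout_rate, max_len = as.integer(max_len),
    conv_kernel = as.integer(conv_kernel),
    conv_filters = as.integer(conv_filters), pool = as.integer(pool),
    gru_units = as.integer(gru_units), gru_layers = as.integer(gru_layers),
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    iterations = as.integer(iterations)
  )
  structure(cfg, class = "flowrec_config")
}

new_model <- function(arch, config, weights) {
  structure(list(arch = arch, config = config, weights = weights),
            class = c(paste0("flowrec_", arch), "flowrec_model"))
}

#' Build the transformer-encoder recommender
#'
#' Token embedding plus learned positional embedding, one encoder block
#' (multi-head self-attention with residual and layer normalisation,
#' position-wise feed-forward with residual and layer normalisation),
#' pooling at the final sequence position, a hidden relu dense layer,
#' and a sigmoid output over the tool vocabulary. With the full-scale
#' configuration (V = 2354 tools, N = 25) the model has exactly
#' 922,291 trainable parameters.
#'
#' Weight initialisation consumes the R random-number stream; call
#' [set.seed()] beforehand for reproducible models.
#'
#' @param config A [model_config()] with `arch = "transformer"`.
#' @return A `flowrec_model` object.
#' @export
build_transformer <- function(config) {
  stopifnot(inherits(config, "flowrec_config"), config$arch == "transformer")
  d <- config$d_model
  P <- config$n_heads * config$head_dim
  f1 <- config$ffn_dims[1]; f2 <- config$ffn_dims[2]
  hid <- config$hidden_dense_dim
  w <- list(
    tok_emb = init_embedding(config$vocab_in, d),
    pos_emb = init_embedding(config$max_len, d),
    Wq = glorot(d, P), bq = numeric(P),
    Wk = glorot(d, P), bk = numeric(P),
    Wv = glorot(d, P), bv = numeric(P),
    Wo = glorot(P, d), bo = numeric(d),
    ln1_g = rep(1, d), ln1_b = numeric(d),
    ffn_W1 = glorot(d, f1), ffn_b1 = numeric(f1),
    ffn_W2 = glorot(f1, f2), ffn_b2 = numeric(f2),
    ln2_g = rep(1, f2), ln2_b = numeric(f2),
    hid_W = glorot(f2, hid), hid_b = numeric(hid),
    out_W = glorot(hid, config$vocab_out), out_b = numeric(config$vocab_out)
  )
  new_model("transformer", config, w)
}

#' Build the stacked-GRU recommender
#'
#' Embedding, two stacked GRU layers (reset-after gate convention,
#' `3 * (d*u + u^2 + 2u)` parameters per layer), and a sigmoid output
#' dense layer over the vocabulary.
#'
#' @inheritParams build_transformer
#' @return A `flowrec_model` object.
#' @export
build_rnn <- function(config) {
  stopifnot(inherits(config, "flowrec_config"), config$arch == "rnn")
  d <- config$d_model; u <- config$gru_units
  w <- list(
    emb = init_embedding(config$vocab_in, d),
    gru1_W = glorot(d, 3 * u), gru1_U = glorot(u, 3 * u),
    gru1_bi = numeric(3 * u), gru1_br = numeric(3 * u),
    gru2_W = glorot(u, 3 * u), gru2_U = glorot(u, 3 * u),
    gru2_bi = numeric(3 * u), gru2_br = numeric(3 * u),
    out_W = glorot(u, config$vocab_out), out_b = numeric(config$vocab_out)
  )
  new_model("rnn", config, w)
}

#' Build the 2-D convolutional recommender
#'
#' Embedding reshaped to an `N x d_model` one-channel image, a valid
#' 16 x 3 convolution with 128 filters and relu, 2 x 2 max-pooling,
#' flatten, a 128-unit dense layer, and a sigmoid output. With the
#' full-scale configuration the model has exactly 5,772,723 trainable
#' parameters.
#'
#' @inheritParams build_transformer
#' @return A `flowrec_model` object.
#' @export
build_cnn <- function(config) {
  stopifnot(inherits(config, "flowrec_config"), config$arch == "cnn")
  d <- config$d_model
  kh <- config$conv_kernel[1]; kw <- config$conv_kernel[2]
  nf <- config$conv_filters
  flat <- cnn_flat_dim(config)
  hid <- config$hidden_dense_dim
  w <- list(
    emb = init_embedding(config$vocab_in, d),
    conv_K = glorot(kh * kw, nf), conv_b = numeric(nf),
    dense_W = glorot(flat, hid), dense_b = numeric(hid),
    out_W = glorot(hid, config$vocab_out), out_b = numeric(config$vocab_out)
  )
  new_model("cnn", config, w)
}

cnn_flat_dim <- function(config) {
  oh <- config$max_len - config$conv_kernel[1] + 1L
  ow <- config$d_model - config$conv_kernel[2] + 1L
  (oh %/% config$pool[1]) * (ow %/% config$pool[2]) * config$conv_filters
}

#' Build the dense (DNN) recommender
#'
#' Embedding, flatten, two 128-unit relu dense layers, sigmoid output.
#' With the full-scale configuration the model has exactly 1,031,603
#' trainable parameters.
#'
#' @inheritParams build_transformer
#' @return A `flowrec_model` object.
#' @export
build_dnn <- function(config) {
  stopifnot(inherits(config, "flowrec_config"), config$arch == "dnn")
  d <- config$d_model; hid <- config$hidden_dense_dim
  w <- list(
    emb = init_embedding(config$vocab_in, d),
    d1_W = glorot(config$max_len * d, hid), d1_b = numeric(hid),
    d2_W = glorot(hid, hid), d2_b = numeric(hid),
    out_W = glorot(hid, config$vocab_out), out_b = numeric(config$vocab_out)
  )
  new_model("dnn", config, w)
}

#' Build any of the four architectures from its configuration
#'
#' @param config A [model_config()].
#' @return A `flowrec_model` object.
#' @export
build_model <- function(config) {
  switch(config$arch,
    transformer = build_transformer(config),
    rnn = build_rnn(config),
    cnn = build_cnn(config),
    dnn = build_dnn(config)
  )
}

#' Count trainable parameters of a built model
#'
#' Sums the sizes of every weight tensor. Agrees with the closed-form
#' count from [param_count()] for the same configuration.
#'
#' @param model A `flowrec_model`.
#' @return Integer parameter count.
#' @export
count_trainable_parameters <- function(model) {
  stopifnot(inherits(model, "flowrec_model"))
  sum(vapply(model$weights, length, numeric(1)))
}

#' Closed-form trainable-parameter count
#'
#' Analytic layer-by-layer parameter total for a configuration, derived
#' independently of the weight tensors actually allocated. The
#' full-scale configurations give 922,291 (transformer), 5,772,723
#' (CNN) and 1,031,603 (DNN).
#'
#' @param config A [model_config()].
#' @return Numeric parameter count.
#' @export
param_count <- function(config) {
  d <- config$d_model
  Vin <- config$vocab_in; Vout <- config$vocab_out
  N <- config$max_len
  hid <- config$hidden_dense_dim
  switch(config$arch,
    transformer = {
      P <- config$n_heads * config$head_dim
      f1 <- config$ffn_dims[1]; f2 <- config$ffn_dims[2]
      Vin * d + N * d +                       # token + positional embeddings
        3 * (d * P + P) + (P * d + d) +       # q/k/v projections + output
        2 * d + (d * f1 + f1) + (f1 * f2 + f2) + 2 * f2 +  # LN1, FFN, LN2
        (f2 * hid + hid) + (hid * Vout + Vout)
    },
    rnn = {
      u <- config$gru_units
      Vin * d + 3 * (d * u + u^2 + 2 * u) + 3 * (u^2 + u^2 + 2 * u) +
        (u * Vout + Vout)
    },
    cnn = {
      kh <- config$conv_kernel[1]; kw <- config$conv_kernel[2]
      Vin * d + (kh * kw * config$conv_filters + config$conv_filters) +
        (cnn_flat_dim(config) * hid + hid) + (hid * Vout + Vout)
    },
    dnn = {
      Vin * d + (N * d * hid + hid) + (hid * hid + hid) +
        (hid * Vout + Vout)
    }
  )
}

# shared forward-pass entry; ids is a B x N integer matrix (0 = pad).
# Returns list(logits = node, attn = per-batch attention or NULL).
model_forward <- function(model, ids, tape, training = FALSE) {
  cfg <- model$config
  if (ncol(ids) != cfg$max_len) {
    stop("input has ", ncol(ids), " positions; model expects ",
         cfg$max_len, call. = FALSE)
  }
  if (any(ids < 0) || any(ids >= cfg$vocab_in)) {
    stop("token index outside the embedding range", call. = FALSE)
  }
  w <- lapply(model$weights, ad_leaf, tape = tape)
  B <- nrow(ids); N <- cfg$max_len
  flat_ids <- as.vector(t(ids))
  dr <- cfg$dropout_rate
  switch(model$arch,
    transformer = {
      tok <- ad_embedding(tape, w$tok_emb, flat_ids)
      pos <- ad_embedding(tape, w$pos_emb, rep(0:(N - 1L), B))
      x <- ad_dropout(tape, ad_add(tape, tok, pos), dr, training)
      q <- ad_add_bias(tape, ad_matmul(tape, x, w$Wq), w$bq)
      k <- ad_add_bias(tape, ad_matmul(tape, x, w$Wk), w$bk)
      v <- ad_add_bias(tape, ad_matmul(tape, x, w$Wv), w$bv)
      att <- ad_attention(tape, q, k, v, B, N, cfg$n_heads, cfg$head_dim,
                          key_pad = ids == 0L)
      proj <- ad_add_bias(tape, ad_matmul(tape, att$node, w$Wo), w$bo)
      proj <- ad_dropout(tape, proj, dr, training)
      x <- ad_layernorm(tape, ad_add(tape, x, proj), w$ln1_g, w$ln1_b)
      h1 <- ad_relu(tape, ad_add_bias(tape, ad_matmul(tape, x, w$ffn_W1),
                                      w$ffn_b1))
      h2 <- ad_add_bias(tape, ad_matmul(tape, h1, w$ffn_W2), w$ffn_b2)
      h2 <- ad_dropout(tape, h2, dr, training)
      x <- ad_layernorm(tape, ad_add(tape, x, h2), w$ln2_g, w$ln2_b)
      pooled <- ad_select_rows(tape, x, seq_len(B) * N)
      hid <- ad_relu(tape, ad_add_bias(tape, ad_matmul(tape, pooled, w$hid_W),
                                       w$hid_b))
      hid <- ad_dropout(tape, hid, dr, training)
      logits <- ad_add_bias(tape, ad_matmul(tape, hid, w$out_W), w$out_b)
      list(logits = logits, attn = att$attn, leaves = w)
    },
    rnn = {
      x <- ad_dropout(tape, ad_embedding(tape, w$emb, flat_ids), dr, training)
      g1 <- ad_gru(tape, x, w$gru1_W, w$gru1_U, w$gru1_bi, w$gru1_br,
                   B, N, return_sequences = TRUE)
      g2 <- ad_gru(tape, g1, w$gru2_W, w$gru2_U, w$gru2_bi, w$gru2_br,
                   B, N, return_sequences = FALSE)
      g2 <- ad_dropout(tape, g2, dr, training)
      logits <- ad_add_bias(tape, ad_matmul(tape, g2, w$out_W), w$out_b)
      list(logits = logits, attn = NULL, leaves = w)
    },
    cnn = {
      x <- ad_dropout(tape, ad_embedding(tape, w$emb, flat_ids), dr, training)
      feat <- ad_conv_relu_pool_flatten(tape, x, w$conv_K, w$conv_b, B, N,
                                        cfg$conv_kernel[1], cfg$conv_kernel[2],
                                        pool = cfg$pool)
      hid <- ad_relu(tape, ad_add_bias(tape, ad_matmul(tape, feat, w$dense_W),
                                       w$dense_b))
      hid <- ad_dropout(tape, hid, dr, training)
      logits <- ad_add_bias(tape, ad_matmul(tape, hid, w$out_W), w$out_b)
      list(logits = logits, attn = NULL, leaves = w)
    },
    dnn = {
      x <- ad_dropout(tape, ad_embedding(tape, w$emb, flat_ids), dr, training)
      flat <- ad_flatten_seq(tape, x, B, N)
      h1 <- ad_relu(tape, ad_add_bias(tape, ad_matmul(tape, flat, w$d1_W),
                                      w$d1_b))
      h2 <- ad_relu(tape, ad_add_bias(tape, ad_matmul(tape, h1, w$d2_W),
                                      w$d2_b))
      h2 <- ad_dropout(tape, h2, dr, training)
      logits <- ad_add_bias(tape, ad_matmul(tape, h2, w$out_W), w$out_b)
      list(logits = logits, attn = NULL, leaves = w)
    }
  )
}

#' Predict sigmoid scores for encoded inputs
#'
#' @param object A `flowrec_model`.
#' @param input_ids Integer matrix (rows = samples, `max_len` columns,
#'   0 = padding) or a single integer vector.
#' @param ... Unused.
#' @return Matrix of sigmoid scores, one row per sample, `vocab_out`
#'   columns (column 1 is the unused padding slot). All values lie
#'   strictly in (0, 1).
#' @export
predict.flowrec_model <- function(object, input_ids, ...) {
  if (is.vector(input_ids)) input_ids <- matrix(input_ids, nrow = 1)
  fw <- model_forward(object, input_ids, ad_tape(), training = FALSE)
  stats::plogis(fw$logits$value)
}

#' @export
print.flowrec_model <- function(x, ...) {
  cat("<flowrec ", x$arch, " model>  ",
      format(count_trainable_parameters(x), big.mark = ","),
      " trainable parameters, vocab ", x$config$vocab_size,
      ", max length ", x$config$max_len, "\n", sep = "")
  invisible(x)
}

#' Extract self-attention weights for one encoded input
#'
#' Runs the transformer forward on one encoded prefix and returns the
#' post-softmax attention weights of the encoder block: one `N x N`
#' matrix per head plus their arithmetic mean. Padded key positions are
#' masked out, so each row sums to 1 over the unmasked keys and padded
#' keys carry zero weight.
#'
#' @param model A transformer `flowrec_model` (or a loaded bundle's
#'   model).
#' @param input_ids Integer vector of length `max_len` (0 = padding),
#'   e.g. from [encode_and_pad()].
#' @param vocab Optional [build_vocabulary()] result used to label the
#'   positions with tool names; padding positions are labelled "PAD".
#' @return A `flowrec_attention` object: list with `heads` (list of
#'   `N x N` matrices), `mean`, `labels`, and `key_pad`.
#' @export
attention_matrix <- function(model, input_ids, vocab = NULL) {
  if (!inherits(model, "flowrec_model") || model$arch != "transformer") {
    stop("attention weights are only defined for the transformer ",
         "architecture", call. = FALSE)
  }
  ids <- matrix(as.integer(input_ids), nrow = 1)
  fw <- model_forward(model, ids, ad_tape(), training = FALSE)
  heads <- fw$attn[[1]]
  avg <- Reduce(`+`, heads) / length(heads)
  labels <- if (is.null(vocab)) {
    ifelse(ids[1, ] == 0L, "PAD", paste0("tool_", ids[1, ]))
  } else {
    ifelse(ids[1, ] == 0L, "PAD", vocab$tool_of[ids[1, ]])
  }
  structure(
    list(heads = heads, mean = avg, labels = labels, key_pad = ids[1, ] == 0L),
    class = "flowrec_attention"
  )
}
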
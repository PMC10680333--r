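# Adam optimiser state and update (Kingma & Ba), keras-style defaults
adam_init <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0),
       t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(weights = weights, state = state)
}

#' Train a recommender model
#'
#' Runs the training protocol: per iteration one frequency-balanced
#' batch is drawn from the training split and one Adam step is taken on
#' the element-wise binary cross-entropy of the sigmoid outputs against
#' the multi-hot labels (the unused padding slot of the label dimension
#' is excluded from the loss). The test split is evaluated with mean
#' precision@k at a configurable cadence and never mutated.
#' Reproducible under `seed`.
#'
#' @param model A freshly built `flowrec_model` (its output dimension
#'   must match the vocabulary of the samples).
#' @param split A [split_train_test()] result.
#' @param bins A [assign_frequency_bins()] result.
#' @param iterations Optimiser steps; defaults to the configuration's
#'   `iterations`.
#' @param eval_every Evaluation cadence in iterations.
#' @param seed Integer seed governing batch sampling and dropout.
#' @param k Precision@k policy passed to [evaluate_model()]: `"labels"`
#'   (k = number of true labels, the default) or a fixed integer.
#' @param verbose Print progress to stderr.
#' @return A `flowrec_training_run`: list with the trained `model`, a
#'   `history` tibble (iteration, loss, precision_at_k), `seed`,
#'   `iterations` and the configuration.
#' @export
train <- function(model, split, bins, iterations = NULL, eval_every = 50L,
                  seed = 1L, k = "labels", verbose = FALSE) {
  stopifnot(inherits(model, "flowrec_model"),
            inherits(split, "flowrec_split"),
            inherits(bins, "flowrec_bins"))
  cfg <- model$config
  iterations <- as.integer(iterations %||% cfg$iterations)
  stopifnot(iterations >= 1)
  max_label <- max(unlist(split$train$labels), unlist(split$test$labels))
  if (max_label + 1L > cfg$vocab_out) {
    stop("label index ", max_label, " exceeds the model's output ",
         "dimension (", cfg$vocab_out, ")", call. = FALSE)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  elig <- bin_eligibility(split$train, bins)
  n_empty <- sum(lengths(elig) == 0)
  if (n_empty > 0 && n_empty < 4) {
    warning("balanced sampling skips ", n_empty,
            " frequency bin(s) with no eligible samples", call. = FALSE)
  }
  col_keep <- c(FALSE, rep(TRUE, cfg$vocab_out - 1L))
  state <- adam_init(model$weights)
  hist_it <- integer(0); hist_loss <- numeric(0); hist_prec <- numeric(0)
  for (it in seq_len(iterations)) {
    batch <- sample_balanced_batch(split$train, bins, cfg$batch_size,
                                   eligibility = elig, warn_empty = FALSE)
    ids <- do.call(rbind, batch$input_ids)
    y <- multi_hot_matrix(batch$labels, cfg$vocab_out)
    tape <- ad_tape()
    fw <- model_forward(model, ids, tape, training = TRUE)
    loss <- ad_bce_mean(tape, fw$logits, y, col_keep)
    if (!is.finite(loss$value)) {
      stop("non-finite loss at iteration ", it,
           " (learning rate ", cfg$learning_rate, ")", call. = FALSE)
    }
    ad_backward(tape, loss)
    grads <- lapply(fw$leaves, function(l) l$grad)
    upd <- adam_step(model$weights, grads, state, cfg$learning_rate)
    model$weights <- upd$weights
    state <- upd$state
    if (it %% eval_every == 0L || it == iterations) {
      prec <- evaluate_model(model, split$test, k = k)$mean_precision
      hist_it <- c(hist_it, it)
      hist_loss <- c(hist_loss, loss$value)
      hist_prec <- c(hist_prec, prec)
      if (verbose) {
        message(sprintf("iter %6d  loss %.4f  precision@k %.4f",
                        it, loss$value, prec))
      }
    }
  }
  structure(list(
    model = model,
    history = tibble::tibble(iteration = hist_it, loss = hist_loss,
                             precision_at_k = hist_prec),
    config = cfg, seed = as.integer(seed), iterations = iterations
  ), class = "flowrec_training_run")
}

#' @export
print.flowrec_training_run <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat("<training run> ", x$config$arch, ", ", x$iterations,
      " iterations (seed ", x$seed, "); final loss ",
      signif(last$loss, 4), ", test precision@k ",
      signif(last$precision_at_k, 4), "\n", sep = "")
  invisible(x)
}

#' Write a training history as TSV
#'
#' Columns `iteration`, `loss`, `precision_at_k`, tab-separated with a
#' header.
#'
#' @param run A `flowrec_training_run`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_history <- function(run, path) {
  utils::write.table(run$history, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
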
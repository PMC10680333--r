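test_that("full-scale configurations reproduce the published parameter counts", {
  cfg_t <- model_config(2354, "transformer")
  expect_equal(cfg_t$vocab_in, 2355)
  expect_equal(cfg_t$vocab_out, 2355)
  expect_equal(param_count(cfg_t), 922291)
  cfg_c <- model_config(2354, "cnn")
  expect_equal(cfg_c$vocab_in, 2356)
  expect_equal(param_count(cfg_c), 5772723)
  cfg_d <- model_config(2354, "dnn")
  expect_equal(param_count(cfg_d), 1031603)
})

test_that("tiny transformer parameter count matches a hand-summed layer total", {
  cfg <- tiny_config("transformer", vocab_size = 4, d_model = 2, n_heads = 1,
                     head_dim = 2, ffn_dims = c(2, 2), hidden_dense_dim = 2,
                     max_len = 3)
  # embeddings: 5*2 + 3*2; q/k/v: 3*(2*2+2); attn out: 2*2+2; LN1: 4;
  # ffn: (2*2+2)*2; LN2: 4; hidden: 2*2+2; output: 2*5+5
  hand <- (5 * 2 + 3 * 2) + 3 * (2 * 2 + 2) + (2 * 2 + 2) + 4 +
    2 * (2 * 2 + 2) + 4 + (2 * 2 + 2) + (2 * 5 + 5)
  expect_equal(param_count(cfg), hand)
  set.seed(1)
  expect_equal(count_trainable_parameters(build_model(cfg)), hand)
})

test_that("tiny GRU parameter count matches the reset-after closed form", {
  cfg <- tiny_config("rnn", vocab_size = 5, d_model = 3, gru_units = 4)
  d <- 3; u <- 4
  hand <- 7 * d +                            # embedding (V+2 rows)
    3 * (d * u + u^2 + 2 * u) +              # GRU layer 1
    3 * (u * u + u^2 + 2 * u) +              # GRU layer 2
    (u * 6 + 6)                              # output (V+1 units)
  expect_equal(param_count(cfg), hand)
  set.seed(1)
  expect_equal(count_trainable_parameters(build_model(cfg)), hand)
})

test_that("CNN shape arithmetic: 25x128 image, 16x3 kernel, 2x2 pool", {
  cfg <- model_config(2354, "cnn")
  # valid conv: (10, 126); pool: (5, 63); flatten: 5*63*128
  expect_equal(flowrec:::cnn_flat_dim(cfg), 5 * 63 * 128)
  cfg_tiny <- tiny_config("cnn", vocab_size = 5, d_model = 4, max_len = 5,
                          conv_kernel = c(2, 2), conv_filters = 3)
  hand <- 7 * 4 + (2 * 2 * 3 + 3) + ((2 * 1 * 3) * 4 + 4) + (4 * 6 + 6)
  expect_equal(param_count(cfg_tiny), hand)
  set.seed(1)
  expect_equal(count_trainable_parameters(build_model(cfg_tiny)), hand)
})

test_that("DNN weight shapes and tiny count match the closed form", {
  cfg <- model_config(2354, "dnn")
  set.seed(1)
  m <- build_dnn(cfg)
  expect_equal(dim(m$weights$d1_W), c(25 * 128, 128))
  cfg_tiny <- tiny_config("dnn", vocab_size = 5)
  hand <- 7 * 4 + (5 * 4 * 4 + 4) + (4 * 4 + 4) + (4 * 6 + 6)
  expect_equal(param_count(cfg_tiny), hand)
})

test_that("framework count equals the closed form for random small configs", {
  set.seed(20)
  for (i in 1:20) {
    arch <- sample(c("transformer", "rnn", "cnn", "dnn"), 1)
    d <- sample(3:8, 1)
    cfg <- tiny_config(arch, vocab_size = sample(4:30, 1), d_model = d,
                       n_heads = sample(1:2, 1), head_dim = sample(2:5, 1),
                       ffn_dims = c(sample(2:6, 1), d),
                       hidden_dense_dim = sample(2:6, 1),
                       max_len = sample(4:8, 1),
                       conv_kernel = c(2, 2), conv_filters = sample(2:4, 1),
                       gru_units = sample(2:6, 1))
    m <- build_model(cfg)
    expect_equal(count_trainable_parameters(m), param_count(cfg),
                 info = paste(arch, "config", i))
  }
})

test_that("parameter count is invariant under weight re-initialisation", {
  cfg <- tiny_config("transformer")
  set.seed(1); m1 <- build_model(cfg)
  set.seed(999); m2 <- build_model(cfg)
  expect_false(identical(m1$weights$Wq, m2$weights$Wq))
  expect_equal(count_trainable_parameters(m1),
               count_trainable_parameters(m2))
})

test_that("forward passes are finite, in (0,1), and deterministic", {
  for (arch in c("transformer", "rnn", "cnn", "dnn")) {
    cfg <- tiny_config(arch)
    set.seed(3)
    m <- build_model(cfg)
    all_pad <- matrix(0L, 1, cfg$max_len)
    s <- predict(m, all_pad)
    expect_length(s, cfg$vocab_out)
    expect_true(all(is.finite(s)))
    expect_true(all(s > 0 & s < 1))
    ids <- rbind(c(0L, 0L, 1L, 2L, 3L))
    expect_identical(predict(m, ids), predict(m, ids))
  }
})

test_that("positional embeddings make the transformer order-sensitive", {
  cfg <- tiny_config("transformer", vocab_size = 8, max_len = 6)
  set.seed(14)
  m <- build_model(cfg)
  a <- predict(m, c(0L, 0L, 1L, 2L, 3L, 4L))
  b <- predict(m, c(0L, 0L, 2L, 1L, 3L, 4L))
  expect_gt(max(abs(a - b)), 1e-8)
})

test_that("backpropagated gradients match finite differences", {
  # spot-check the autodiff engine end to end for each architecture
  for (arch in c("transformer", "rnn", "cnn", "dnn")) {
    cfg <- tiny_config(arch)
    set.seed(5)
    m <- build_model(cfg)
    ids <- rbind(c(0L, 0L, 1L, 2L, 3L), c(0L, 4L, 5L, 6L, 1L))
    y <- matrix(0, 2, cfg$vocab_out)
    y[1, 3] <- 1; y[2, 5] <- 1; y[2, 7] <- 1
    keep <- c(FALSE, rep(TRUE, cfg$vocab_out - 1))
    loss_at <- function(weights) {
      m2 <- m; m2$weights <- weights
      tp <- flowrec:::ad_tape()
      fw <- flowrec:::model_forward(m2, ids, tp, training = FALSE)
      flowrec:::ad_bce_mean(tp, fw$logits, y, keep)$value
    }
    tp <- flowrec:::ad_tape()
    fw <- flowrec:::model_forward(m, ids, tp, training = FALSE)
    loss <- flowrec:::ad_bce_mean(tp, fw$logits, y, keep)
    flowrec:::ad_backward(tp, loss)
    set.seed(6)
    for (nm in sample(names(m$weights), 4)) {
      g <- fw$leaves[[nm]]$grad
      i <- sample(length(m$weights[[nm]]), 1)
      eps <- 1e-5
      wp <- m$weights; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- m$weights; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
      ana <- if (is.null(g)) 0 else as.vector(g)[i]
      expect_lt(abs(num - ana), 1e-4 * max(1, abs(num)))
    }
  }
})

test_that("attention rows are a distribution over unmasked keys only", {
  cfg <- tiny_config("transformer", vocab_size = 10, max_len = 25)
  set.seed(8)
  m <- build_model(cfg)
  ids <- c(rep(0L, 22), 1L, 2L, 3L)   # 3 real tools, 22 pads
  am <- attention_matrix(m, ids)
  expect_length(am$heads, cfg$n_heads)
  for (h in am$heads) {
    expect_equal(dim(h), c(25, 25))
    expect_true(all(h >= 0))
    expect_true(all(abs(rowSums(h) - 1) < 1e-5))
    expect_true(all(h[, am$key_pad] == 0))
  }
  expect_equal(am$mean, Reduce(`+`, am$heads) / length(am$heads))
  expect_equal(am$labels[23:25], paste0("tool_", 1:3))
  expect_equal(am$labels[1], "PAD")

  set.seed(9)
  rnn <- build_model(tiny_config("rnn"))
  expect_error(attention_matrix(rnn, c(0L, 0L, 1L, 2L, 3L)),
               "transformer")
})
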
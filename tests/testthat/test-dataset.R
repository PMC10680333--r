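test_that("vocabulary indices follow frequency with lexicographic ties", {
  v <- build_vocabulary(seq_tbl(c("A", "B"), c("A", "C")))
  expect_equal(v$index_of, c(A = 1L, B = 2L, C = 3L))
  expect_equal(v$tool_of, c("A", "B", "C"))

  v2 <- build_vocabulary(seq_tbl(c("A", "B")))
  expect_equal(v2$size, 2)
  expect_error(build_vocabulary(seq_tbl()[0, ]), "empty")
})

test_that("vocabulary of a synthetic corpus equals the tools the walks visited", {
  st <- tiny_study(seed = 2)
  expect_setequal(st$vocab$tool_of,
                  unique(unlist(lapply(st$corpus, function(g) g$nodes))))
  expect_true(all(st$vocab$tool_of %in% st$grammar$tools))
})

test_that("encoding left-pads, truncates to the recent window, and decodes back", {
  v <- build_vocabulary(seq_tbl(c("A", "B", "C")))
  expect_equal(encode_and_pad(c("A", "B", "C"), v, 5),
               c(0L, 0L, unname(v$index_of[c("A", "B", "C")])))
  # boundary: prefix of exactly N tools has no padding
  e <- encode_and_pad(c("A", "B", "C"), v, 3)
  expect_false(any(e == 0))
  # over-length prefixes keep the last N tools
  long <- rep(c("A", "B", "C", "B"), 7)   # 28 tools
  e28 <- encode_and_pad(long, v, 25)
  expect_equal(decode_ids(e28, v), utils::tail(long, 25))
  expect_error(encode_and_pad(c("A", "Z"), v, 5), "Z")

  # decode(encode(p)) recovers the truncated prefix for random prefixes
  set.seed(42)
  for (i in 1:25) {
    p <- sample(c("A", "B", "C"), sample(1:8, 1), replace = TRUE)
    expect_equal(decode_ids(encode_and_pad(p, v, 5), v), utils::tail(p, 5))
  }
})

test_that("multi-hot vectors carry exactly one 1 per label at the right slots", {
  v <- build_vocabulary(seq_tbl(c("A", "B", "C", "D")))
  mh <- to_multi_hot("B", v)
  expect_length(mh, v$size + 1)
  expect_equal(which(mh == 1), unname(v$index_of["B"]) + 1L)
  expect_equal(sum(to_multi_hot(c("C", "D"), v)), 2)
  expect_equal(mh[1], 0)  # padding slot never set
  expect_error(to_multi_hot(character(0), v), "empty")
  set.seed(7)
  for (i in 1:20) {
    lab <- sample(v$tool_of, sample(1:4, 1))
    expect_equal(sum(to_multi_hot(lab, v)), length(lab))
  }
})

test_that("prefix samples take the corpus-wide union of successors", {
  v <- build_vocabulary(seq_tbl(c("A", "B", "C"), c("A", "B", "D")))
  s1 <- derive_labeled_samples(seq_tbl(c("A", "B", "C")), v, 25)
  expect_equal(nrow(s1), 2)
  expect_equal(s1$raw_prefix, list("A", c("A", "B")))
  expect_equal(v$tool_of[s1$labels[[1]]], "B")
  expect_equal(v$tool_of[s1$labels[[2]]], "C")

  # one prefix, two labels when workflows diverge
  s2 <- derive_labeled_samples(seq_tbl(c("A", "B", "C"), c("A", "B", "D")),
                               v, 25)
  lab_ab <- s2$labels[[which(vapply(s2$raw_prefix, paste, character(1),
                                    collapse = " ") == "A B")]]
  expect_setequal(v$tool_of[lab_ab], c("C", "D"))

  s3 <- derive_labeled_samples(seq_tbl(c("A", "B")), v, 25)
  expect_equal(nrow(s3), 1)
})

test_that("sample derivation agrees with the brute-force successor-scan oracle", {
  set.seed(31)
  for (rep in 1:10) {
    g <- generate_grammar(sample(8:20, 1), branching_factor = 2,
                          seed = rep, max_depth = 5)
    corpus <- generate_workflow_corpus(g, sample(5:25, 1),
                                       length_range = c(2, 5),
                                       branch_prob = 0.4, seed = rep + 100)
    seqs <- enumerate_linear_sequences(corpus)
    if (nrow(seqs) == 0) next
    v <- build_vocabulary(seqs)
    N <- sample(3:6, 1)
    got <- derive_labeled_samples(seqs, v, N)
    want <- oracle_samples(seqs, N)
    expect_equal(got$raw_prefix, want$prefixes)
    expect_equal(lapply(got$labels, function(l) sort(v$tool_of[l])),
                 want$labels)
  }
})

test_that("train/test split is disjoint, sized 80/20 and seed-reproducible", {
  st <- tiny_study(seed = 4)
  n <- nrow(st$samples)
  sp <- st$split
  expect_equal(nrow(sp$train) + nrow(sp$test), n)
  expect_lte(abs(nrow(sp$train) - 0.8 * n), 1)
  keys <- function(s) vapply(s$raw_prefix, paste, character(1),
                             collapse = "\r")
  expect_length(intersect(keys(sp$train), keys(sp$test)), 0)

  sp2 <- split_train_test(st$samples, 0.8, seed = st$split$seed)
  expect_identical(sp$train, sp2$train)

  # 10 samples at 0.8 give an 8/2 split
  sp10 <- split_train_test(st$samples[1:10, ], 0.8, seed = 1)
  expect_equal(nrow(sp10$train), 8)

  sp_a <- split_train_test(st$samples, 0.8, seed = 1)
  sp_b <- split_train_test(st$samples, 0.8, seed = 2)
  expect_false(identical(keys(sp_a$train), keys(sp_b$train)))
  expect_error(split_train_test(st$samples[1, ], 0.8, 1), "at least 2")
})

test_that("frequency bins partition tools at the label-frequency quartiles", {
  # label frequencies 1,1,10,10,100,100,1000,1000 over 8 tools
  freqs <- c(1, 1, 10, 10, 100, 100, 1000, 1000)
  tools <- paste0("t", 1:8)
  seqs <- tibble::tibble(workflow_id = "w",
                         tools = list(c(tools, "src"))) # vocab incl. all
  v <- build_vocabulary(seqs)
  labels <- unlist(lapply(1:8, function(i) {
    rep(unname(v$index_of[tools[i]]), freqs[i])
  }))
  samples <- tibble::tibble(
    raw_prefix = as.list(paste0("p", seq_along(labels))),
    input_ids = replicate(length(labels), c(0L, 1L), simplify = FALSE),
    labels = as.list(as.integer(labels))
  )
  bins <- assign_frequency_bins(samples, v)
  tb <- bins$tools[match(tools, bins$tools$tool), ]
  expect_equal(tb$bin, rep(1:4, each = 2))
  # a never-labelled tool joins the rarest bin
  expect_equal(bins$tools$bin[bins$tools$tool == "src"], 1L)
  expect_true(all(bins$tools$bin %in% 1:4))
})

test_that("rare synthetic tools land in the lowest-frequency bin", {
  st <- tiny_study(seed = 8, n_tools = 24, max_depth = 6, n_workflows = 20)
  lab_freq <- table(unlist(st$split$train$labels))
  rarest <- as.integer(names(lab_freq)[which.min(lab_freq)])
  expect_equal(st$bins$tools$bin[st$bins$tools$index == rarest], 1L)
})

test_that("balanced batches pick bins uniformly and stay inside the split", {
  # 4 tools, one per bin, single-label samples so the bin choice is
  # observable from the drawn sample
  tools <- paste0("t", 1:4)
  v <- build_vocabulary(tibble::tibble(workflow_id = "w",
                                       tools = list(tools)))
  freqs <- c(2, 8, 40, 200)
  labels <- unlist(lapply(1:4, function(i) {
    rep(unname(v$index_of[tools[i]]), freqs[i])
  }))
  samples <- tibble::tibble(
    raw_prefix = as.list(paste0("p", seq_along(labels))),
    input_ids = replicate(length(labels), c(0L, 1L), simplify = FALSE),
    labels = as.list(as.integer(labels))
  )
  bins <- assign_frequency_bins(samples, v)
  expect_equal(sort(unique(bins$tools$bin)), 1:4)

  batch <- sample_balanced_batch(samples, bins, 10000, seed = 99)
  expect_equal(nrow(batch), 10000)
  drawn_bin <- bins$tools$bin[match(unlist(batch$labels), bins$tools$index)]
  p_hat <- as.vector(table(factor(drawn_bin, levels = 1:4))) / 10000
  se3 <- 3 * sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(p_hat - 0.25) <= se3))

  # batch members always come from the given samples
  expect_true(all(unlist(batch$labels) %in% unlist(samples$labels)))

  # degenerate: all labels in one bin reduces to uniform sampling
  uni <- samples[labels == labels[1], ]
  expect_warning(b1 <- sample_balanced_batch(uni, bins, 16, seed = 1),
                 "skipping")
  expect_equal(nrow(b1), 16)

  # exact batch size at the training protocol's 512
  expect_equal(nrow(sample_balanced_batch(samples, bins, 512, seed = 2)),
               512)
})

test_that("dataset containers round-trip and are byte-identical per seed", {
  st <- tiny_study(seed = 6)
  tf1 <- withr::local_tempfile(fileext = ".json")
  tf2 <- withr::local_tempfile(fileext = ".json")
  save_dataset(st$split, st$vocab, tf1, max_len = st$max_len)
  save_dataset(st$split, st$vocab, tf2, max_len = st$max_len)
  expect_identical(readLines(tf1), readLines(tf2))
  back <- load_dataset(tf1)
  expect_equal(back$vocab$tool_of, st$vocab$tool_of)
  expect_equal(back$split$train$input_ids, st$split$train$input_ids)
  expect_equal(back$split$test$labels, st$split$test$labels)
  expect_equal(back$max_len, st$max_len)
})
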
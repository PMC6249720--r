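test_that("Huffman codes order by frequency and handle degenerate vocab", {
  # two words: one bit each
  t2 <- build_huffman(c(`1` = 3, `2` = 5), q = 4)
  expect_equal(lengths(t2$codes), c(1L, 1L))
  expect_equal(nrow(t2$theta), 1)

  # frequencies a:5 b:3 c:1 d:1 -> len(a) <= len(b) <= len(c) = len(d)
  t4 <- build_huffman(c(`1` = 5, `2` = 3, `3` = 1, `4` = 1), q = 2)
  len <- lengths(t4$codes)
  expect_true(len[1] <= len[2])
  expect_true(len[2] <= len[3])
  expect_equal(len[3], len[4])
  expect_equal(nrow(t4$theta), 3)  # |V| - 1 internal nodes

  # prefix-free: no code is a prefix of another
  codes <- vapply(t4$codes, paste, character(1), collapse = "")
  for (i in 1:3) for (j in (i + 1):4) {
    expect_false(startsWith(codes[i], codes[j]) || startsWith(codes[j], codes[i]))
  }

  # degenerate single-word vocabulary: empty code, probability 1
  t1 <- build_huffman(c(`7` = 4), q = 3)
  expect_length(t1$codes[[1]], 0)
  expect_equal(p_word_given_ctx(t1, rnorm(3), 7), 1)
})

test_that("Huffman expected code length is optimal (exhaustive, |V| <= 5)", {
  set.seed(71)
  profiles <- c(
    list(c(5, 3, 1, 1), c(1, 1, 1, 1), c(10, 1, 1), c(2, 3), c(8, 4, 2, 1, 1)),
    lapply(1:5, function(i) sample(1:9, sample(2:5, 1), replace = TRUE))
  )
  for (freq in profiles) {
    names(freq) <- seq_along(freq)
    tr <- build_huffman(freq, q = 2)
    huff_cost <- sum(freq * lengths(tr$codes))
    expect_equal(huff_cost, min_prefix_code_cost(freq))
    # a maximal-frequency word attains the minimal code length
    len <- lengths(tr$codes)
    expect_equal(min(len[freq == max(freq)]), min(len))
    # expected path length <= ceil(log2 |V|) + 1
    expect_lte(sum(freq * lengths(tr$codes)) / sum(freq),
               ceiling(log2(length(freq))) + 1)
  }
})

test_that("hierarchical softmax is a probability distribution over words", {
  set.seed(72)
  for (V in c(2, 3, 5, 9, 16)) {
    freq <- sample(1:20, V, replace = TRUE)
    names(freq) <- seq_len(V)
    tree <- build_huffman(freq, q = 6)
    for (rep in 1:20) {
      tree$theta <- matrix(rnorm(length(tree$theta), sd = 2), nrow(tree$theta))
      ctx <- rnorm(6, sd = 2)
      p <- vapply(seq_len(V), function(w) p_word_given_ctx(tree, ctx, w), 1)
      expect_true(all(p >= 0 & p <= 1))  # saturated sigmoids may hit the ends in float
      expect_lt(abs(sum(p) - 1), 1e-10)
    }
  }
  # zero parameters: every branch is a coin flip -> p(w) = 2^-codelength
  tree <- build_huffman(c(`1` = 5, `2` = 3, `3` = 1, `4` = 1), q = 3)
  for (w in 1:4) {
    expect_equal(p_word_given_ctx(tree, rnorm(3), w),
                 2^(-length(tree$codes[[w]])), tolerance = 1e-12)
  }
  # two-word vocabulary sums exactly to 1
  t2 <- build_huffman(c(`1` = 1, `2` = 1), q = 2)
  t2$theta[] <- rnorm(2)
  ctx <- rnorm(2)
  expect_equal(p_word_given_ctx(t2, ctx, 1) + p_word_given_ctx(t2, ctx, 2), 1)

  expect_error(p_word_given_ctx(t2, ctx, 99), "not in the vocabulary")
})

test_that("context vectors average (or concatenate) the surrounding words", {
  emb <- rbind(`1` = c(1, 0), `2` = c(0, 1), `3` = c(4, 4))
  cfg <- context_config(window = 1, q = 2)
  s <- eeg_sentence(c(1, 3, 2), "r")
  expect_equal(context_vector(emb, s, 2, cfg), c(0.5, 0.5))  # mean of v1, v2

  # all context words identical -> that word's vector
  s2 <- eeg_sentence(c(3, 1, 3), "r")
  expect_equal(context_vector(emb, s2, 2, cfg), c(4, 4))

  # concat mode has length 2k*q and preserves order
  ccfg <- context_config(window = 1, integration = "concat", q = 2)
  expect_equal(context_vector(emb, s, 2, ccfg), c(1, 0, 0, 1))

  # positions without a full window are skipped, not an error
  expect_null(context_vector(emb, s, 1, cfg))
  expect_null(context_vector(emb, s, 3, cfg))
})

test_that("CBOW training raises the corpus objective (20 seeds, >= 18)", {
  set.seed(73)
  # structured corpus: deterministic word patterns per 'state'
  make_corpus <- function(seed) {
    set.seed(seed)
    lapply(1:6, function(i) {
      base <- sample(1:3, 1)
      eeg_sentence(rep(c(base, base + 3, base), 8), paste0("r", i))
    })
  }
  wins <- 0
  for (s in 1:20) {
    e <- train_embeddings(make_corpus(s),
                          context_config(window = 2, q = 6, epochs = 5,
                                         learning_rate = 0.2, seed = s))
    if (e$objective_final >= e$objective_init) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("one SGD example touches only context vectors and path nodes", {
  # one sentence with exactly one interior position (window 2, length 5);
  # two epochs: node parameters start at zero, so the context-vector
  # gradient is nonzero only from the second pass onwards
  s <- eeg_sentence(c(1, 2, 3, 4, 5), "r")
  cfg <- context_config(window = 2, q = 4, epochs = 2, learning_rate = 0.1,
                        seed = 9)
  e <- train_embeddings(list(s), cfg)
  # reconstruct the initial embeddings under the same seed
  set.seed(9)
  emb0 <- matrix(runif(5 * 4, -0.5 / 4, 0.5 / 4), 5)
  rownames(emb0) <- rownames(e$embeddings)
  moved <- rowSums(abs(e$embeddings - emb0)) > 0
  # centre word 3 must be untouched; the four context words must move
  expect_false(moved[rownames(e$embeddings) == "3"])
  expect_true(all(moved[rownames(e$embeddings) != "3"]))
  # theta rows off the centre word's path stay at their zero init
  wpos <- match(3L, e$tree$word_ids)
  off_path <- setdiff(seq_len(nrow(e$tree$theta)), e$tree$paths[[wpos]])
  if (length(off_path) > 0) {
    expect_true(all(e$tree$theta[off_path, ] == 0))
  }
  expect_true(any(e$tree$theta[e$tree$paths[[wpos]], ] != 0))
})

test_that("words sharing contexts embed closer than random pairs", {
  set.seed(74)
  # words 1 and 2 occur in identical contexts: both surround centre word 20.
  # Distractor words 3..6 each surround their own centre.
  sentences <- list()
  for (i in 1:40) {
    w <- sample(1:2, 1)
    sentences[[length(sentences) + 1]] <- eeg_sentence(c(w, 20, w), paste0("a", i))
    d <- sample(3:6, 1)
    sentences[[length(sentences) + 1]] <- eeg_sentence(c(d, 20 + d, d), paste0("b", i))
  }
  e <- train_embeddings(sentences,
                        context_config(window = 1, q = 8, epochs = 20,
                                       learning_rate = 0.3, seed = 4))
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  E <- e$embeddings
  target <- cosine(E["1", ], E["2", ])
  ids <- rownames(E)
  pairs <- t(combn(ids, 2))
  pairs <- pairs[!(pairs[, 1] %in% c("1", "2") & pairs[, 2] %in% c("1", "2")), ]
  ref <- apply(pairs, 1, function(p) cosine(E[p[1], ], E[p[2], ]))
  expect_gt(target, stats::quantile(ref, 0.95))
})

test_that("embedding training is reproducible and validates its inputs", {
  sents <- lapply(1:4, function(i) eeg_sentence(rep(1:4, 5), paste0("r", i)))
  cfg <- context_config(window = 2, q = 5, epochs = 3, seed = 11)
  e1 <- train_embeddings(sents, cfg)
  e2 <- train_embeddings(sents, cfg)
  expect_identical(e1$embeddings, e2$embeddings)
  expect_identical(e1$tree$theta, e2$tree$theta)

  # all sentences too short for any interior position
  short <- list(eeg_sentence(c(1, 2), "r"))
  expect_error(train_embeddings(short, cfg), "interior")
})

test_that("temporal features return (or average) word vectors", {
  emb <- rbind(`1` = c(1, 2), `61` = c(3, 4))
  expect_equal(temporal_feature(emb, 1L), c(1, 2))
  expect_equal(temporal_feature(emb, c(1L, 61L)), c(2, 3))     # channel mean
  expect_equal(temporal_feature(emb, c(1L, 1L)), c(1, 2))      # equal words
  expect_error(temporal_feature(emb, 99L), "not in the embedding vocabulary")
  expect_equal(temporal_feature(emb, c(1L, 99L), oov = "zero"), c(0.5, 1))

  expect_equal(global_word_id(5, 2, 60), 65L)
  expect_equal(global_word_id(1, 1, 60), 1L)
})

test_that("embeddings persist in the word2vec-style text format", {
  sents <- lapply(1:3, function(i) eeg_sentence(rep(c(1, 2, 61, 62), 4), "r"))
  e <- train_embeddings(sents, context_config(window = 1, q = 4, epochs = 2,
                                              seed = 1))
  f <- withr::local_tempfile(fileext = ".txt")
  write_embeddings(e, f, vocab_per_channel = 60)
  lines <- readLines(f)
  expect_equal(lines[1], "4 4")
  fields <- strsplit(lines[-1], " ")
  expect_equal(vapply(fields, `[`, "", 1), c("1", "2", "61", "62"))  # global ids
  expect_equal(vapply(fields, `[`, "", 2), c("1", "1", "2", "2"))    # channels
  expect_equal(as.numeric(fields[[1]][4:7]), unname(e$embeddings["1", ]),
               tolerance = 1e-6)
})
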
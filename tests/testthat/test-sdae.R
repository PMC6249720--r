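test_that("masking corruption obeys its fraction", {
  x <- runif(10)
  expect_identical(corrupt(x, corruption_config(fraction = 0, seed = 1)), x)
  expect_equal(corrupt(x, corruption_config(fraction = 1, seed = 1)), rep(0, 10))

  big <- rep(1, 1e5)
  zeroed <- mean(corrupt(big, corruption_config(fraction = 0.3, seed = 7)) == 0)
  expect_lt(abs(zeroed - 0.3), 0.01)  # binomial concentration at n = 1e5

  # seeded corruption is reproducible
  expect_identical(corrupt(big, corruption_config(0.3, seed = 5)),
                   corrupt(big, corruption_config(0.3, seed = 5)))
})

test_that("dae_forward computes the sigmoid encoder/decoder pass", {
  layer <- list(W_enc = matrix(0, 4, 3), b_enc = rep(0, 4),
                W_dec = matrix(0, 3, 4), b_dec = rep(0, 3))
  fw <- dae_forward(layer, c(0.2, 0.8, 0.5))
  expect_equal(fw$h, rep(0.5, 4))
  expect_equal(fw$y, rep(0.5, 3))

  # independent matrix-arithmetic re-computation on random weights
  set.seed(13)
  layer <- list(W_enc = matrix(rnorm(15), 5, 3), b_enc = rnorm(5),
                W_dec = matrix(rnorm(15), 3, 5), b_dec = rnorm(3))
  x <- runif(3)
  fw <- dae_forward(layer, x)
  h_ref <- 1 / (1 + exp(-(layer$W_enc %*% x + layer$b_enc)))
  y_ref <- 1 / (1 + exp(-(layer$W_dec %*% h_ref + layer$b_dec)))
  expect_equal(fw$h, drop(h_ref), tolerance = 1e-12)
  expect_equal(fw$y, drop(y_ref), tolerance = 1e-12)
  expect_true(all(fw$h > 0 & fw$h < 1))
  expect_true(all(fw$y > 0 & fw$y < 1))

  expect_error(dae_forward(layer, runif(7)), "dimension")
})

test_that("cross-entropy loss matches arithmetic and finite differences", {
  expect_equal(dae_loss(c(0, 1), c(0.5, 0.5)), 2 * log(2), tolerance = 1e-12)

  # binary x with y approaching x: loss -> 0
  expect_lt(dae_loss(c(0, 1, 1), c(1e-9, 1 - 1e-9, 1 - 1e-9)), 1e-7)

  # gradient wrt y vs central finite differences
  set.seed(5)
  x <- runif(6); y <- runif(6, 0.1, 0.9)
  analytic <- -(x / y - (1 - x) / (1 - y))
  h <- 1e-6
  fd <- vapply(seq_along(y), function(k) {
    yp <- y; ym <- y
    yp[k] <- y[k] + h; ym[k] <- y[k] - h
    (dae_loss(x, yp) - dae_loss(x, ym)) / (2 * h)
  }, numeric(1))
  expect_equal(fd, analytic, tolerance = 1e-5)

  expect_warning(dae_loss(c(0, 1), c(0, 1)), "clamped")
  expect_error(dae_loss(c(-0.1, 0.5), c(0.5, 0.5)), "\\[0, 1\\]")
})

test_that("SDAE training reduces per-layer loss and respects default dims", {
  set.seed(30)
  X <- matrix(runif(50 * 256), 50, 256)
  m <- train_sdae(X, sizes = c(80, 60), tc = train_config(epochs = 3, seed = 1))
  expect_equal(dim(m$layers[[1]]$W_enc), c(80, 256))
  expect_equal(dim(m$layers[[2]]$W_enc), c(60, 80))
  expect_length(sdae_encode(m, X[1, ]), 60)
  for (l in 1:2) {
    expect_lte(utils::tail(m$loss_log[[l]], 1), m$loss_log[[l]][1])
  }
})

test_that("SDAE training is seed-reproducible and greedy stacking freezes layer 1", {
  set.seed(8)
  X <- matrix(runif(40 * 32), 40, 32)
  m1 <- train_sdae(X, sizes = c(8, 4), tc = train_config(epochs = 5, seed = 3))
  m2 <- train_sdae(X, sizes = c(8, 4), tc = train_config(epochs = 5, seed = 3))
  expect_identical(m1$layers, m2$layers)

  # training the second layer must not touch the first: a single-layer run
  # under the same seed produces bitwise-identical layer-1 parameters
  m0 <- train_sdae(X, sizes = 8, tc = train_config(epochs = 5, seed = 3))
  expect_identical(m0$layers[[1]], m1$layers[[1]])
})

test_that("trained models reconstruct held-out data better than random init", {
  set.seed(99)
  # structured inputs: smooth low-rank patterns plus noise, in [0,1]
  make_data <- function(n, seed) {
    set.seed(seed)
    basis <- outer(seq_len(n), 1:3, function(i, k) sin(k * i / 4))
    Z <- matrix(runif(40 * 3), 40, 3) %*% t(basis) + 0.1 * rnorm(40 * n)
    (Z - min(Z)) / (max(Z) - min(Z))
  }
  wins <- 0
  for (s in 1:20) {
    train <- make_data(24, s)
    heldout <- make_data(24, 1000 + s)
    m <- train_sdae(train, sizes = 10,
                    tc = train_config(epochs = 20, seed = s))
    trained_loss <- mean(dae_loss(heldout, dae_forward(m$layers[[1]], heldout)$y))
    set.seed(s)  # the same seed train_sdae draws its initial weights under
    layer0 <- ctxseize:::init_layer(24, 10)
    init_loss <- mean(dae_loss(heldout, dae_forward(layer0, heldout)$y))
    if (trained_loss < init_loss) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("channel-wise encoding concatenates per-channel codes in order", {
  set.seed(17)
  X1 <- matrix(runif(30 * 16), 30, 16)
  X2 <- matrix(runif(30 * 16), 30, 16)
  m1 <- train_sdae(X1, sizes = c(6, 4), tc = train_config(epochs = 2, seed = 1),
                   channel_id = 1)
  m2 <- train_sdae(X2, sizes = c(6, 4), tc = train_config(epochs = 2, seed = 2),
                   channel_id = 2)
  v1 <- X1[1, ]; v2 <- X2[1, ]
  feat <- encode_channelwise(list(m1, m2), list(v1, v2))
  expect_length(feat, 8)
  expect_equal(feat, c(sdae_encode(m1, v1), sdae_encode(m2, v2)))

  # permuting channels permutes the blocks
  swapped <- encode_channelwise(list(m2, m1), list(v2, v1))
  expect_equal(swapped, c(feat[5:8], feat[1:4]))

  expect_error(encode_channelwise(list(m1), list(v1, v2)), "mismatch")
})

test_that("translate_to_word is argmax pooling with lowest-index ties", {
  # hand-built model whose last hidden layer activations we control
  layer <- list(W_enc = diag(3) * 10, b_enc = c(-1, 5, 0),
                W_dec = matrix(0, 3, 3), b_dec = rep(0, 3))
  m <- structure(list(layers = list(layer), sizes = 3L, channel_id = 2L),
                 class = "sdae_model")
  w <- translate_to_word(m, c(0, 0, 0))
  expect_equal(w$word_id, 2)  # activations sigmoid(c(-1, 5, 0)) peak at unit 2
  expect_equal(w$channel_id, 2)

  tie <- list(W_enc = matrix(0, 2, 3), b_enc = c(0, 0),
              W_dec = matrix(0, 3, 2), b_dec = rep(0, 3))
  mt <- structure(list(layers = list(tie), sizes = 2L, channel_id = 1L),
                  class = "sdae_model")
  expect_equal(translate_to_word(mt, runif(3))$word_id, 1)  # exact tie -> lowest
})
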
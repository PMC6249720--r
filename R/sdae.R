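#' Masking-noise corruption configuration
#'
#' @param fraction Probability of zeroing each input coordinate (default 0.3).
#' @param seed Optional seed applied when [corrupt()] is called directly;
#'   inside training the corruption draws from the (seeded) training stream.
#' @return An object of class `corruption_config`.
#' @export
corruption_config <- function(fraction = 0.3, seed = NULL) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  structure(list(kind = "masking", fraction = fraction, seed = seed),
            class = "corruption_config")
}

#' Training configuration for denoising autoencoders
#'
#' @param epochs Passes over the training data per layer.
#' @param batch_size Mini-batch size.
#' @param learning_rate SGD learning rate.
#' @param l2_penalty Weight-decay coefficient on the weight matrices.
#' @param seed Integer seed covering initialisation, shuffling, corruption.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 30, batch_size = 16, learning_rate = 0.5,
                         l2_penalty = 1e-4, seed = 1) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, l2_penalty >= 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, l2_penalty = l2_penalty,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Corrupt an input vector with masking noise
#'
#' Each coordinate is independently set to 0 with probability
#' `cfg$fraction`, otherwise left unchanged -- the stochastic corruption
#' step a denoising autoencoder reconstructs through.
#'
#' @param x Numeric vector or matrix (rows = samples) with entries in `[0,1]`.
#' @param cfg A [corruption_config()].
#' @return Corrupted copy of `x`.
#' @export
corrupt <- function(x, cfg = corruption_config()) {
  stopifnot(inherits(cfg, "corruption_config"))
  with_seed(cfg$seed, {
    if (cfg$fraction == 0) return(x)
    mask <- stats::runif(length(x)) < cfg$fraction
    x[mask] <- 0
    x
  })
}

# Glorot-style uniform init scaled for sigmoid units
init_layer <- function(n_vis, n_hid) {
  r <- 4 * sqrt(6 / (n_vis + n_hid))
  list(
    W_enc = matrix(stats::runif(n_hid * n_vis, -r, r), n_hid, n_vis),
    b_enc = rep(0, n_hid),
    W_dec = matrix(stats::runif(n_vis * n_hid, -r, r), n_vis, n_hid),
    b_dec = rep(0, n_vis)
  )
}

#' Forward pass through one denoising autoencoder layer
#'
#' `h = f(W_enc x + b_enc)`, `y = f(W_dec h + b_dec)` with the logistic
#' sigmoid `f(z) = 1/(1 + exp(-z))`; decoder weights are untied from the
#' encoder's.
#'
#' @param layer A DAE layer (list with `W_enc`, `b_enc`, `W_dec`, `b_dec`).
#' @param x Input vector, or matrix with one sample per row.
#' @return List with `h` (hidden activations) and `y` (reconstruction), in
#'   the same orientation as the input; all entries strictly inside (0, 1).
#' @export
dae_forward <- function(layer, x) {
  vec <- is.vector(x)
  if (vec) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(layer$W_enc)) {
    stop(sprintf("input dimension %d does not match layer visible size %d",
                 ncol(x), ncol(layer$W_enc)))
  }
  h <- sigmoid(sweep(x %*% t(layer$W_enc), 2, layer$b_enc, "+"))
  y <- sigmoid(sweep(h %*% t(layer$W_dec), 2, layer$b_dec, "+"))
  if (vec) list(h = drop(h), y = drop(y)) else list(h = h, y = y)
}

#' Cross-entropy reconstruction loss
#'
#' `-sum_k [x_k log y_k + (1 - x_k) log(1 - y_k)]`, the reconstruction
#' error of a sigmoid-output autoencoder on inputs in `[0,1]`, with the
#' convention `0 * log 0 = 0`. Reconstructions at exactly 0 or 1 are clamped
#' to `[1e-12, 1 - 1e-12]` with a warning.
#'
#' @param x Clean input vector, or matrix (rows = samples), entries in `[0,1]`.
#' @param y Reconstruction of the same shape, entries in `(0,1)`.
#' @return For vectors, a non-negative scalar; for matrices, one loss per row.
#' @export
dae_loss <- function(x, y) {
  if (any(x < 0 | x > 1)) stop("x must lie in [0, 1]")
  eps <- 1e-12
  if (any(y <= 0 | y >= 1)) {
    warning("reconstruction values at {0,1} clamped by 1e-12")
    y <- pmin(pmax(y, eps), 1 - eps)
  }
  term <- function(xx, yy) ifelse(xx == 0, 0, xx * log(yy)) +
    ifelse(xx == 1, 0, (1 - xx) * log(1 - yy))
  if (is.matrix(x)) rowSums(-term(x, y)) else sum(-term(x, y))
}

# One DAE trained by mini-batch SGD on cross-entropy. X rows = samples in
# [0,1]. Returns the layer plus a per-epoch mean-loss log; uses the current
# RNG stream (seeded by the caller).
train_dae <- function(X, n_hid, corr, tc) {
  n <- nrow(X); d <- ncol(X)
  layer <- init_layer(d, n_hid)
  lr <- tc$learning_rate; l2 <- tc$l2_penalty
  log_loss <- numeric(tc$epochs + 1)
  clean_loss <- function() {
    fw <- dae_forward(layer, X)
    mean(dae_loss(X, fw$y))
  }
  log_loss[1] <- clean_loss()
  for (ep in seq_len(tc$epochs)) {
    ord <- sample.int(n)
    for (b in seq(1, n, by = tc$batch_size)) {
      idx <- ord[b:min(b + tc$batch_size - 1, n)]
      xb <- X[idx, , drop = FALSE]
      xc <- xb
      if (corr$fraction > 0) {
        xc[stats::runif(length(xb)) < corr$fraction] <- 0
      }
      fw <- dae_forward(layer, xc)
      m <- length(idx)
      # sigmoid + cross-entropy: output delta is (y - x)
      d_out <- fw$y - xb
      g_Wdec <- crossprod(d_out, fw$h) / m + l2 * layer$W_dec
      g_bdec <- colMeans(d_out)
      d_hid <- (d_out %*% layer$W_dec) * fw$h * (1 - fw$h)
      g_Wenc <- crossprod(d_hid, xc) / m + l2 * layer$W_enc
      g_benc <- colMeans(d_hid)
      if (!all(is.finite(g_Wdec)) || !all(is.finite(g_Wenc))) {
        stop("non-finite gradient during DAE training; lower the learning rate")
      }
      layer$W_dec <- layer$W_dec - lr * g_Wdec
      layer$b_dec <- layer$b_dec - lr * g_bdec
      layer$W_enc <- layer$W_enc - lr * g_Wenc
      layer$b_enc <- layer$b_enc - lr * g_benc
    }
    log_loss[ep + 1] <- clean_loss()
    if (!is.finite(log_loss[ep + 1])) stop("non-finite training loss; aborting")
  }
  list(layer = layer, loss = log_loss)
}

#' Train a stacked denoising autoencoder for one channel
#'
#' Greedy layer-wise training: the first DAE learns on the raw scalogram
#' vectors; its clean (uncorrupted) hidden codes become the training data of
#' the second DAE, with earlier layers frozen while later layers train.
#' Corruption is applied only to the input of the layer currently training.
#'
#' @param X Matrix of scalogram vectors, one fragment per row, entries in
#'   `[0,1]`.
#' @param sizes Hidden sizes per layer (default `c(80, 60)`).
#' @param corr A [corruption_config()].
#' @param tc A [train_config()]; its `seed` makes the whole run reproducible.
#' @param channel_id Integer channel tag stored in the model.
#' @return An `sdae_model`: list of layers plus sizes, channel id, and a
#'   per-layer training-loss log (element 1 = loss at initialisation).
#' @export
train_sdae <- function(X, sizes = c(80, 60), corr = corruption_config(),
                       tc = train_config(), channel_id = 1L) {
  if (is.list(X) && !is.matrix(X)) {
    X <- do.call(rbind, lapply(X, function(v) {
      if (inherits(v, "scalogram_vector")) v$values else v
    }))
  }
  stopifnot(is.matrix(X))
  if (nrow(X) < tc$batch_size) stop("need at least batch_size training samples")
  if (any(X < 0 | X > 1)) stop("inputs must lie in [0, 1]")
  with_seed(tc$seed, {
    layers <- vector("list", length(sizes))
    loss_log <- vector("list", length(sizes))
    input <- X
    for (l in seq_along(sizes)) {
      fit <- train_dae(input, sizes[l], corr, tc)
      layers[[l]] <- fit$layer
      loss_log[[l]] <- fit$loss
      input <- dae_forward(fit$layer, input)$h   # clean codes feed the next layer
    }
    structure(list(layers = layers, sizes = as.integer(sizes),
                   channel_id = as.integer(channel_id),
                   loss_log = loss_log),
              class = "sdae_model")
  })
}

#' Last-hidden-layer code of an SDAE on clean input
#'
#' @param model An `sdae_model`.
#' @param x Input vector or matrix (rows = samples); no corruption applied.
#' @return Activations of the final hidden layer.
#' @export
sdae_encode <- function(model, x) {
  if (inherits(x, "scalogram_vector")) x <- x$values
  for (layer in model$layers) x <- dae_forward(layer, x)$h
  x
}

#' Concatenate channel-wise SDAE features for one fragment
#'
#' @param models List of `sdae_model`, one per channel, ordered by channel.
#' @param frag_vectors List (same order) of that fragment's per-channel
#'   scalogram vectors.
#' @return Numeric vector: per-channel last-layer codes concatenated in
#'   channel order (length `C * last hidden size` under defaults).
#' @export
encode_channelwise <- function(models, frag_vectors) {
  if (length(models) != length(frag_vectors)) {
    stop("channel count mismatch between models and fragment vectors")
  }
  unlist(lapply(seq_along(models), function(c) {
    sdae_encode(models[[c]], frag_vectors[[c]])
  }), use.names = FALSE)
}

#' Translate a fragment into an EEG word
#'
#' Max-probability pooling over the dictionary of learned scalogram
#' patterns: the word is the index of the maximally activated unit of the
#' last hidden layer (ties broken toward the lowest index). Word ids are
#' 1-based.
#'
#' @param model An `sdae_model`.
#' @param v The fragment's scalogram vector for this model's channel.
#' @return An `eeg_word`: list with `word_id` (1-based, `<=` last hidden
#'   size) and `channel_id`.
#' @export
translate_to_word <- function(model, v) {
  h <- sdae_encode(model, v)
  structure(list(word_id = which.max(h), channel_id = model$channel_id),
            class = "eeg_word")
}
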
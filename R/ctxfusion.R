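#' Fit a multi-context wavelet-fusion seizure detector
#'
#' End-to-end fit of the multi-context pipeline on a collection of annotated
#' EEG records: sliding-window segmentation and ictal labelling, Morlet CWT
#' scalogram vectors, class balancing and a stratified 4:1 hold-out split,
#' then three unsupervised feature extractors fitted on the training fold
#' only -- global PCA over all-channel scalograms, per-channel stacked
#' denoising autoencoders, and CBOW EEG-word embeddings over the SDAE
#' dictionary -- whose outputs are concatenated and fed to an SVM. The test
#' fold yields the returned evaluation metrics.
#'
#' @param records List of [eeg_record()] objects (equal channel counts and
#'   sampling rates) with seizure annotations.
#' @param window_s,step_s Segmentation window and step, seconds (3 / 1).
#' @param wavelet A [wavelet_config()].
#' @param grid Scalogram pooling grid (default `c(16, 16)`; SDAE input
#'   dimension `prod(grid)`).
#' @param contexts Subset of `c("global", "channelwise", "temporal")`;
#'   dropping blocks gives the reduced ablation models.
#' @param k_global Number of global principal components (default 10).
#' @param sizes SDAE hidden sizes (default `c(80, 60)`); the last size is
#'   the per-channel EEG-word dictionary size.
#' @param corruption_fraction Masking-noise probability for DAE training.
#' @param sdae_epochs,sdae_batch,sdae_lr SDAE training settings.
#' @param embed_window,embed_dim,embed_epochs,embed_lr CBOW settings
#'   (context half-width, embedding dimension q, epochs, learning rate).
#' @param detector A [detector_config()].
#' @param ratio Train share of the balanced fragments (default 0.8).
#' @param n_per_class Optional cap on balanced fragments per class.
#' @param min_overlap_fraction Ictal labelling rule, see [label_fragments()].
#' @param seed Master integer seed; all component seeds derive from it.
#' @param verbose Print stage progress.
#' @return An object of class `ctxfusion` with elements `models` (gpca,
#'   sdaes, embedding), `detector`, `metrics` (test-fold `metrics_report`),
#'   `split` (fragment provenance of each fold), `config`, and `seed`.
#' @seealso [predict.ctxfusion()], [plot.ctxfusion()]
#' @export
ctxfusion <- function(records,
                      window_s = 3, step_s = 1,
                      wavelet = wavelet_config(), grid = c(16, 16),
                      contexts = c("global", "channelwise", "temporal"),
                      k_global = 10, sizes = c(80, 60),
                      corruption_fraction = 0.3,
                      sdae_epochs = 30, sdae_batch = 16, sdae_lr = 0.5,
                      embed_window = 2, embed_dim = 20,
                      embed_epochs = 10, embed_lr = 0.05,
                      detector = detector_config(),
                      ratio = 0.8, n_per_class = NULL,
                      min_overlap_fraction = 0,
                      seed = 1, verbose = FALSE) {
  contexts <- match.arg(contexts, several.ok = TRUE)
  if (inherits(records, "eeg_record")) records <- list(records)
  stopifnot(length(records) >= 1)
  fs <- records[[1]]$fs
  say <- function(...) if (verbose) message(sprintf(...))

  say("segmenting %d record(s)", length(records))
  fragments <- unlist(lapply(records, function(r) {
    seq <- segment_record(r, window_s = window_s, step_s = step_s)
    label_fragments(seq, r$annotations, record_duration_s = record_duration(r),
                    min_overlap_fraction = min_overlap_fraction)
  }), recursive = FALSE)

  split <- balance_and_split(fragments, ratio = ratio, seed = seed,
                             n_per_class = n_per_class)
  say("balanced split: %d train / %d test fragments",
      length(split$train), length(split$test))

  say("computing scalogram vectors")
  feats_tr <- scalogram_features(split$train, fs, wavelet, grid)
  feats_te <- scalogram_features(split$test, fs, wavelet, grid)
  C <- length(feats_tr$per_channel)
  vocab_size <- sizes[length(sizes)]

  models <- list(gpca = NULL, sdaes = NULL, embedding = NULL)

  if ("global" %in% contexts) {
    say("fitting global PCA (k = %d)", k_global)
    models$gpca <- fit_gpca(feats_tr$concat, k = k_global)
  }
  if (any(c("channelwise", "temporal") %in% contexts)) {
    say("training %d per-channel SDAEs", C)
    corr <- corruption_config(fraction = corruption_fraction)
    models$sdaes <- lapply(seq_len(C), function(c) {
      tc <- train_config(epochs = sdae_epochs, batch_size = sdae_batch,
                         learning_rate = sdae_lr, seed = seed + 100L + c)
      train_sdae(feats_tr$per_channel[[c]], sizes = sizes, corr = corr,
                 tc = tc, channel_id = c)
    })
  }
  if ("temporal" %in% contexts) {
    say("translating training fragments and training EEG embeddings")
    words_tr <- fragment_words(models$sdaes, feats_tr$per_channel, vocab_size)
    sentences <- build_sentences(split$train, words_tr, C)
    ecfg <- context_config(window = embed_window, q = embed_dim,
                           epochs = embed_epochs, learning_rate = embed_lr,
                           seed = seed + 200L)
    models$embedding <- train_embeddings(sentences, ecfg)
  }

  cfg <- list(window_s = window_s, step_s = step_s, wavelet = wavelet,
              grid = grid, contexts = contexts, k_global = k_global,
              sizes = sizes, embed_dim = embed_dim,
              vocab_size = vocab_size, fs = fs)

  Xtr <- featurize_fragments(models, feats_tr, cfg)
  Xte <- featurize_fragments(models, feats_te, cfg)

  say("training the SVM detector")
  dcfg <- detector
  dcfg$seed <- seed + 300L
  det <- train_detector(Xtr, fragment_labels(split$train), dcfg)
  metrics <- evaluate_detector(det, Xte, fragment_labels(split$test))

  frag_tag <- function(fr) vapply(fr, function(f)
    sprintf("%s#%d", f$record_id, f$index_in_record), character(1))
  structure(list(models = models, detector = det, metrics = metrics,
                 split = list(train = frag_tag(split$train),
                              test = frag_tag(split$test),
                              train_labels = fragment_labels(split$train),
                              test_labels = fragment_labels(split$test)),
                 config = cfg, seed = as.integer(seed)),
            class = "ctxfusion")
}

# per-channel word matrix: one (global id) word per fragment per channel
fragment_words <- function(sdaes, per_channel, vocab_size) {
  n <- nrow(per_channel[[1]])
  out <- matrix(0L, n, length(sdaes))
  for (c in seq_along(sdaes)) {
    H <- sdae_encode(sdaes[[c]], per_channel[[c]])
    out[, c] <- global_word_id(max.col(H, ties.method = "first"), c, vocab_size)
  }
  out
}

# group fragments of one fold by record, keep temporal order, one sentence
# per record per channel
build_sentences <- function(fragments, words, C) {
  rec <- vapply(fragments, function(f) f$record_id, character(1))
  idx <- vapply(fragments, function(f) f$index_in_record, 1L)
  sentences <- list()
  for (r in unique(rec)) {
    rows <- which(rec == r)
    rows <- rows[order(idx[rows])]
    for (c in seq_len(C)) {
      sentences[[length(sentences) + 1]] <-
        eeg_sentence(words[rows, c], record_id = r, channel_id = c)
    }
  }
  sentences
}

# assemble the fused feature matrix for a fragment set
featurize_fragments <- function(models, feats, cfg) {
  n <- nrow(feats$concat)
  blocks <- list()
  if ("global" %in% cfg$contexts) {
    blocks$global <- transform_gpca(models$gpca, feats$concat)
  }
  if ("channelwise" %in% cfg$contexts) {
    blocks$channelwise <- do.call(cbind, lapply(seq_along(models$sdaes),
      function(c) sdae_encode(models$sdaes[[c]], feats$per_channel[[c]])))
  }
  if ("temporal" %in% cfg$contexts) {
    words <- fragment_words(models$sdaes, feats$per_channel, cfg$vocab_size)
    known <- as.integer(rownames(models$embedding$embeddings))
    if (!all(unique(as.vector(words)) %in% known)) {
      warning("fragment(s) mapped to EEG words unseen in training; using zero temporal vectors for them")
    }
    blocks$temporal <- t(apply(words, 1, function(w)
      temporal_feature(models$embedding, w, oov = "zero")))
  }
  X <- do.call(cbind, blocks)
  ends <- cumsum(vapply(blocks, ncol, 1L))
  spans <- Map(function(from, to) c(from = from, to = to),
               c(1, utils::head(ends, -1) + 1), ends)
  names(spans) <- names(blocks)
  attr(X, "block_spans") <- spans
  X
}

#' @export
print.ctxfusion <- function(x, ...) {
  cat("Multi-context wavelet-fusion seizure detector\n")
  cat(sprintf("  contexts: %s\n", paste(x$config$contexts, collapse = " + ")))
  spans <- x$detector$block_spans
  dims <- vapply(spans, function(s) s["to"] - s["from"] + 1, numeric(1))
  cat(sprintf("  fused feature: %d dims (%s)\n",
              sum(dims), paste(names(spans), dims, sep = "=", collapse = ", ")))
  cat(sprintf("  train/test fragments: %d / %d (seed %d)\n",
              length(x$split$train), length(x$split$test), x$seed))
  cat(sprintf("  test F1 %.4f | accuracy %.4f | AUC-ROC %.4f | AUC-PR %.4f\n",
              x$metrics$f1, x$metrics$accuracy, x$metrics$auc_roc,
              x$metrics$auc_pr))
  invisible(x)
}

#' @export
summary.ctxfusion <- function(object, ...) {
  print(object)
  cat("\nTest-fold metrics report:\n")
  print(object$metrics)
  cat(sprintf("\nSVM: kernel %s, cost %g%s\n", object$detector$kernel,
              object$detector$cost,
              if (!is.null(object$detector$gamma))
                sprintf(", gamma %g", object$detector$gamma) else ""))
  invisible(object)
}

#' Plot ROC and PR curves of a fitted detector
#'
#' @param x A `ctxfusion` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ctxfusion <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  roc <- x$metrics$curves$roc
  graphics::plot(roc$fpr, roc$tpr, type = "l", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("ROC (AUC %.3f)", x$metrics$auc_roc), ...)
  graphics::abline(0, 1, lty = 3)
  pr <- x$metrics$curves$pr
  graphics::plot(pr$recall, pr$precision, type = "l", ylim = c(0, 1),
                 xlab = "Recall", ylab = "Precision",
                 main = sprintf("PR (AUC %.3f)", x$metrics$auc_pr), ...)
  invisible(x)
}

#' Predict seizure labels for new EEG data
#'
#' Segments new records with the fitted window settings, recomputes the
#' scalogram features with the stored models, and scores every fragment with
#' the trained SVM.
#'
#' @param object A fitted `ctxfusion` model.
#' @param newdata An [eeg_record()], a list of them, or a list of fragments
#'   from [segment_record()].
#' @param ... Unused.
#' @return Data frame with one row per fragment: `record_id`, `start_s`,
#'   `class` (`ictal`/`non_ictal`), `score` (larger = ictal).
#' @export
predict.ctxfusion <- function(object, newdata, ...) {
  cfg <- object$config
  if (inherits(newdata, "eeg_record")) newdata <- list(newdata)
  if (length(newdata) > 0 && inherits(newdata[[1]], "eeg_record")) {
    fragments <- unlist(lapply(newdata, function(r)
      segment_record(r, cfg$window_s, cfg$step_s)), recursive = FALSE)
  } else {
    fragments <- newdata
  }
  if (length(fragments) == 0) stop("no fragments to predict on")
  feats <- scalogram_features(fragments, cfg$fs, cfg$wavelet, cfg$grid)
  X <- featurize_fragments(object$models, feats, cfg)
  pred <- predict(object$detector, X)
  data.frame(record_id = vapply(fragments, function(f) f$record_id, character(1)),
             start_s = vapply(fragments, function(f) f$start_s, numeric(1)),
             class = pred$class, score = pred$score,
             stringsAsFactors = FALSE)
}
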
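#' An EEG sentence: the word sequence of one record (one channel)
#'
#' @param words Integer vector of (global) EEG word ids, in temporal order.
#' @param record_id,channel_id Provenance tags.
#' @return An `eeg_sentence`.
#' @export
eeg_sentence <- function(words, record_id = "record", channel_id = 1L) {
  words <- as.integer(words)
  if (length(words) < 1) stop("a sentence needs at least one word")
  structure(list(words = words, record_id = record_id,
                 channel_id = as.integer(channel_id)),
            class = "eeg_sentence")
}

#' Build the word-frequency vocabulary of a sentence collection
#'
#' @param sentences List of [eeg_sentence()] objects.
#' @return A `vocabulary`: list with `word_ids` (sorted unique ids), `freq`
#'   (aligned counts, all >= 1), and `total` token count.
#' @export
build_vocabulary <- function(sentences) {
  toks <- unlist(lapply(sentences, function(s) s$words), use.names = FALSE)
  if (length(toks) == 0) stop("no tokens in the sentence collection")
  tab <- table(toks)
  structure(list(word_ids = as.integer(names(tab)),
                 freq = as.integer(tab),
                 total = length(toks)),
            class = "vocabulary")
}

#' Build the Huffman tree for hierarchical softmax
#'
#' Classical Huffman construction on word frequencies: the two lowest-weight
#' nodes are merged repeatedly, so the most frequent word receives the
#' shortest root-to-leaf path. Ties are broken deterministically by
#' (weight, smallest word id contained in the subtree); at each merge the
#' lower-ranked child takes code bit 0. Each of the `|V| - 1` internal nodes
#' carries a parameter vector `theta` in `R^q`, initialised to zero.
#'
#' @param vocab A [build_vocabulary()] result (or named frequency vector
#'   whose names are word ids).
#' @param q Embedding dimensionality of the node parameters (default 20).
#' @return A `huffman_tree`: list with `word_ids`; `codes` and `paths`
#'   (per word: 0/1 bit vector and the aligned internal-node indices from the
#'   root); `theta` (`(|V|-1) x q` matrix, zero rows for a degenerate
#'   single-word vocabulary); `freq`.
#' @export
build_huffman <- function(vocab, q = 20) {
  if (!inherits(vocab, "vocabulary")) {
    vocab <- structure(list(word_ids = as.integer(names(vocab)),
                            freq = as.integer(vocab),
                            total = sum(vocab)),
                       class = "vocabulary")
  }
  V <- length(vocab$word_ids)
  if (any(vocab$freq < 1)) stop("all vocabulary frequencies must be >= 1")
  if (V == 1) {
    return(structure(list(word_ids = vocab$word_ids,
                          codes = list(integer(0)),
                          paths = list(integer(0)),
                          theta = matrix(0, 0, q),
                          freq = vocab$freq),
                     class = "huffman_tree"))
  }
  # active nodes: leaves 1..V then internal V+1..2V-1
  n_nodes <- 2L * V - 1L
  weight <- c(vocab$freq, rep(NA_real_, V - 1L))
  tiebreak <- c(vocab$word_ids, rep(NA_integer_, V - 1L))  # min word id in subtree
  left <- right <- integer(n_nodes)
  active <- seq_len(V)
  nxt <- V
  while (length(active) > 1) {
    ord <- order(weight[active], tiebreak[active])
    a <- active[ord[1]]; b <- active[ord[2]]
    nxt <- nxt + 1L
    weight[nxt] <- weight[a] + weight[b]
    tiebreak[nxt] <- min(tiebreak[a], tiebreak[b])
    left[nxt] <- a; right[nxt] <- b      # left child (lower rank) takes bit 0
    active <- c(active[-ord[1:2]], nxt)
  }
  root <- active
  codes <- vector("list", V)
  paths <- vector("list", V)
  walk <- function(node, bits, nodes_on_path) {
    if (node <= V) {
      codes[[node]] <<- bits
      paths[[node]] <<- nodes_on_path
    } else {
      idx <- node - V  # internal node parameter row
      walk(left[node], c(bits, 0L), c(nodes_on_path, idx))
      walk(right[node], c(bits, 1L), c(nodes_on_path, idx))
    }
  }
  walk(root, integer(0), integer(0))
  structure(list(word_ids = vocab$word_ids, codes = codes, paths = paths,
                 theta = matrix(0, V - 1L, q), freq = vocab$freq),
            class = "huffman_tree")
}

#' Context training configuration for EEG embeddings
#'
#' @param window Context half-width k: the 2k words at offsets
#'   `-k..-1, +1..+k` form the context (default 2).
#' @param integration `"average"` (default, keeps the node parameters in
#'   `R^q`) or `"concat"`.
#' @param q Embedding dimensionality (default 20).
#' @param epochs,learning_rate,seed SGD settings.
#' @return A `context_config`.
#' @export
context_config <- function(window = 2, integration = c("average", "concat"),
                           q = 20, epochs = 10, learning_rate = 0.05,
                           seed = 1) {
  integration <- match.arg(integration)
  if (window < 1) stop("window must be >= 1")
  structure(list(window = as.integer(window), integration = integration,
                 q = as.integer(q), epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "context_config")
}

# interior positions of a sentence: full context on both sides
interior_positions <- function(T, k) {
  if (T < 2 * k + 1) return(integer(0))
  (k + 1):(T - k)
}

#' Integrated context vector at one sentence position
#'
#' Averages (default) or concatenates the embedding vectors of the 2k words
#' around position `t`, excluding the centre word itself. Positions without
#' a full context window are skipped (return `NULL`), matching the interior
#' summation range of the training objective.
#'
#' @param emb Embedding matrix, one row per vocabulary word; rownames are
#'   word ids.
#' @param sentence An [eeg_sentence()].
#' @param t Position (1-based) within the sentence.
#' @param cfg A [context_config()].
#' @return Numeric vector (`q`, or `2k*q` for concat mode), or `NULL` when
#'   `t` is not interior.
#' @export
context_vector <- function(emb, sentence, t, cfg = context_config()) {
  k <- cfg$window
  T <- length(sentence$words)
  if (t < k + 1 || t > T - k) return(NULL)
  ctx_ids <- sentence$words[c((t - k):(t - 1), (t + 1):(t + k))]
  rows <- emb[as.character(ctx_ids), , drop = FALSE]
  if (cfg$integration == "average") colMeans(rows) else as.vector(t(rows))
}

#' Hierarchical-softmax probability of a word given a context vector
#'
#' Walks the word's Huffman path, multiplying the binary sub-softmax factors
#' `f(theta' ctx)^(1-d) * (1 - f(theta' ctx))^d` with `f` the logistic
#' sigmoid and `d` the path's code bits. Summed over the vocabulary these
#' probabilities total 1.
#'
#' @param tree A [build_huffman()] tree.
#' @param ctx Context vector of length matching the tree's `theta` columns.
#' @param w Word id (must be in the vocabulary).
#' @return Probability in `(0, 1]` (exactly 1 for a one-word vocabulary).
#' @export
p_word_given_ctx <- function(tree, ctx, w) {
  pos <- match(as.integer(w), tree$word_ids)
  if (is.na(pos)) stop(sprintf("word %s is not in the vocabulary", w))
  bits <- tree$codes[[pos]]
  if (length(bits) == 0) return(1)
  nodes <- tree$paths[[pos]]
  f <- sigmoid(as.vector(tree$theta[nodes, , drop = FALSE] %*% ctx))
  prod(ifelse(bits == 0L, f, 1 - f))
}

# average log-probability objective over the interior positions of a corpus
corpus_log_prob <- function(emb, tree, sentences, cfg) {
  total <- 0; count <- 0
  for (s in sentences) {
    for (t in interior_positions(length(s$words), cfg$window)) {
      ctx <- context_vector(emb, s, t, cfg)
      total <- total + log(p_word_given_ctx(tree, ctx, s$words[t]))
      count <- count + 1
    }
  }
  if (count == 0) stop("no interior positions: all sentences are shorter than 2*window + 1")
  total / count
}

#' Train EEG word embeddings (CBOW, hierarchical softmax)
#'
#' Stochastic gradient ascent on the average log probability of each
#' interior word given its averaged context vectors, with the flat softmax
#' replaced by sigmoid decisions along the word's Huffman path. Per training
#' example only the path's node parameters and the 2k context word vectors
#' are updated. Embeddings are initialised uniformly in `[-0.5/q, 0.5/q]`
#' and node parameters at zero; the run is fully reproducible from
#' `cfg$seed`.
#'
#' @param sentences List of [eeg_sentence()] objects; at least one must be
#'   longer than `2 * window`.
#' @param cfg A [context_config()]. Training requires the default
#'   `"average"` integration.
#' @return An `eeg_embedding`: list with `embeddings` (`|V| x q`, rownames =
#'   word ids), `tree`, `vocab`, `cfg`, and the objective value before and
#'   after training (`objective_init`, `objective_final`).
#' @export
train_embeddings <- function(sentences, cfg = context_config()) {
  if (cfg$integration != "average") {
    stop("training is implemented for integration = 'average'")
  }
  vocab <- build_vocabulary(sentences)
  if (all(vapply(sentences, function(s) length(s$words), 1L) < 2 * cfg$window + 1)) {
    stop("no interior positions: all sentences are shorter than 2*window + 1")
  }
  tree <- build_huffman(vocab, q = cfg$q)
  k <- cfg$window; q <- cfg$q; lr <- cfg$learning_rate
  with_seed(cfg$seed, {
    emb <- matrix(stats::runif(length(vocab$word_ids) * q, -0.5 / q, 0.5 / q),
                  nrow = length(vocab$word_ids))
    rownames(emb) <- as.character(vocab$word_ids)
    obj0 <- corpus_log_prob(emb, tree, sentences, cfg)
    for (ep in seq_len(cfg$epochs)) {
      for (s in sentences) {
        T <- length(s$words)
        for (t in interior_positions(T, k)) {
          ctx_pos <- match(as.character(s$words[c((t - k):(t - 1), (t + 1):(t + k))]),
                           rownames(emb))
          u <- colMeans(emb[ctx_pos, , drop = FALSE])
          wpos <- match(s$words[t], tree$word_ids)
          nodes <- tree$paths[[wpos]]
          bits <- tree$codes[[wpos]]
          e <- numeric(q)
          for (j in seq_along(nodes)) {
            th <- tree$theta[nodes[j], ]
            g <- lr * ((1 - bits[j]) - sigmoid(sum(th * u)))
            e <- e + g * th
            tree$theta[nodes[j], ] <- th + g * u
          }
          # d u / d v_c = 1/(2k); distribute the context gradient evenly
          upd <- e / (2 * k)
          for (p in ctx_pos) emb[p, ] <- emb[p, ] + upd
        }
      }
    }
    structure(list(embeddings = emb, tree = tree, vocab = vocab, cfg = cfg,
                   objective_init = obj0,
                   objective_final = corpus_log_prob(emb, tree, sentences, cfg)),
              class = "eeg_embedding")
  })
}

#' Temporal feature of one fragment from its EEG word(s)
#'
#' Single channel: the fragment's word embedding `v_w`. Multiple channels:
#' the mean over channels of each channel's word vector (length stays `q`).
#'
#' @param emb An `eeg_embedding` from [train_embeddings()], or a bare
#'   embedding matrix with word-id rownames.
#' @param words Integer vector of global word ids (one per channel), or a
#'   list of `eeg_word` objects already mapped to global ids.
#' @param oov `"error"` (default) stops on a word missing from the
#'   vocabulary; `"zero"` substitutes a zero vector for it (used by the
#'   pipeline, where a test fragment can activate a pattern never seen in
#'   training).
#' @return Numeric vector of length `q`.
#' @export
temporal_feature <- function(emb, words, oov = c("error", "zero")) {
  oov <- match.arg(oov)
  E <- if (inherits(emb, "eeg_embedding")) emb$embeddings else emb
  if (is.list(words)) words <- vapply(words, function(w) w$word_id, 1L)
  rows <- match(as.character(as.integer(words)), rownames(E))
  if (anyNA(rows)) {
    if (oov == "error") {
      stop(sprintf("word(s) %s not in the embedding vocabulary",
                   paste(words[is.na(rows)], collapse = ", ")))
    }
    out <- matrix(0, length(words), ncol(E))
    out[!is.na(rows), ] <- E[rows[!is.na(rows)], , drop = FALSE]
    return(colMeans(out))
  }
  colMeans(E[rows, , drop = FALSE])
}

#' Map per-channel word ids to global ids
#'
#' Channel `c`'s local word `u` becomes `(c - 1) * vocab_per_channel + u`,
#' so one embedding space covers all channels while preserving channel
#' identity.
#'
#' @param word_id Local (1-based) word id(s).
#' @param channel_id Channel number(s), 1-based.
#' @param vocab_per_channel Dictionary size per channel (last SDAE hidden
#'   size, default 60).
#' @return Integer global word id(s).
#' @export
global_word_id <- function(word_id, channel_id, vocab_per_channel = 60) {
  as.integer((channel_id - 1L) * vocab_per_channel + word_id)
}

#' Write embeddings in a word2vec-style text format
#'
#' Header line `<n_words> <q>`, then one line per word:
#' `global_id channel_id local_id` followed by `q` floats.
#'
#' @param emb An `eeg_embedding`.
#' @param path Output file.
#' @param vocab_per_channel Per-channel dictionary size used to factor the
#'   global id back into `(channel_id, local_id)`.
#' @return Invisibly, `path`.
#' @export
write_embeddings <- function(emb, path, vocab_per_channel = 60) {
  E <- emb$embeddings
  ids <- as.integer(rownames(E))
  ch <- (ids - 1L) %/% vocab_per_channel + 1L
  loc <- (ids - 1L) %% vocab_per_channel + 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(E), ncol(E)), con)
  for (i in seq_len(nrow(E))) {
    writeLines(paste(c(ids[i], ch[i], loc[i],
                       formatC(E[i, ], format = "g", digits = 9)),
                     collapse = " "), con)
  }
  invisible(path)
}
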
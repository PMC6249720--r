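#' Fit global PCA over concatenated all-channel scalogram vectors
#'
#' Standard centered principal component analysis; the top-k components of
#' the all-channel scalogram vectors form the "global" feature view,
#' stripping redundant and irrelevant inter-channel variation.
#'
#' @param X Matrix, one fragment per row (`d = C * rows * cols` columns).
#' @param k Number of components to keep; must satisfy `k < min(nrow(X), d)`.
#' @return A `gpca_model`: list with `mean`, `components` (`k x d`,
#'   orthonormal rows), `explained_variance` (nonincreasing), `k`.
#' @export
fit_gpca <- function(X, k = 10) {
  stopifnot(is.matrix(X))
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (k >= min(nrow(X), ncol(X))) {
    stop(sprintf("k = %d must be below min(n = %d, d = %d)", k, nrow(X), ncol(X)))
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = k)
  ev <- (sv$d^2) / (nrow(X) - 1)
  structure(list(mean = mu, components = t(sv$v),
                 explained_variance = ev[seq_len(k)], k = k),
            class = "gpca_model")
}

#' Project a vector onto the fitted global components
#'
#' @param model A `gpca_model` from [fit_gpca()].
#' @param x Vector of length `d`, or a matrix with one row per fragment.
#' @return Score vector of length `k` (matrix input: `n x k` score matrix).
#' @export
transform_gpca <- function(model, x) {
  vec <- is.vector(x)
  if (vec) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$mean)) {
    stop(sprintf("input dimension %d does not match the model dimension %d",
                 ncol(x), length(model$mean)))
  }
  scores <- sweep(x, 2, model$mean) %*% t(model$components)
  if (vec) drop(scores) else scores
}

# stratified fold assignment, seeded by the caller
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Select the number of global components by validation
#'
#' Fits a linear SVM probe on the top-k scores for each candidate k and
#' returns the k with the highest mean validation accuracy. The default
#' protocol is stratified 5-fold cross-validation; exact leave-one-out is
#' available via `protocol = "loo"`. Ties go to the smallest k.
#'
#' @param X Matrix of concatenated scalogram vectors (rows = fragments).
#' @param labels Class labels (`ictal` / `non_ictal`), one per row.
#' @param candidates Integer vector of candidate k values (>= 1 candidate).
#' @param protocol `"cv5"` (default) or `"loo"`.
#' @param seed Integer seed for the fold assignment.
#' @return The selected k.
#' @export
select_k <- function(X, labels, candidates, protocol = c("cv5", "loo"),
                     seed = 1) {
  protocol <- match.arg(protocol)
  candidates <- sort(unique(as.integer(candidates)))
  if (length(candidates) == 1) return(candidates)
  labels <- factor(labels)
  with_seed(seed, {
    fold <- if (protocol == "loo") seq_len(nrow(X)) else stratified_folds(labels, 5)
    acc <- vapply(candidates, function(k) {
      correct <- 0; total <- 0
      for (f in unique(fold)) {
        tr <- fold != f; te <- !tr
        if (length(unique(labels[tr])) < 2) {
          warning(sprintf("fold %d has a single class in training; skipped", f))
          next
        }
        pm <- fit_gpca(X[tr, , drop = FALSE], k)
        str <- transform_gpca(pm, X[tr, , drop = FALSE])
        ste <- transform_gpca(pm, X[te, , drop = FALSE])
        probe <- e1071::svm(str, labels[tr], kernel = "linear", scale = FALSE)
        pred <- stats::predict(probe, ste)
        correct <- correct + sum(pred == labels[te])
        total <- total + sum(te)
      }
      if (total == 0) return(NA_real_)
      correct / total
    }, numeric(1))
    candidates[which.max(acc)]  # which.max takes the first (smallest k) on ties
  })
}
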
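#' Concatenate the three context feature blocks
#'
#' Fuses the per-fragment features in the fixed order global,
#' channel-wise, temporal, recording the span of each block so downstream
#' consumers can validate or slice the fused vector. Reduced (ablation)
#' models must name their active blocks explicitly through `contexts`;
#' an empty active block is an error.
#'
#' @param global,channelwise,temporal Numeric vectors (or `NULL` for a
#'   block disabled via `contexts`).
#' @param contexts Character subset of
#'   `c("global", "channelwise", "temporal")` naming the active blocks.
#' @return A `fused_feature`: numeric vector with attribute `block_spans`
#'   (named list of `c(from, to)` index pairs).
#' @export
fuse <- function(global, channelwise, temporal,
                 contexts = c("global", "channelwise", "temporal")) {
  contexts <- match.arg(contexts, several.ok = TRUE)
  blocks <- list(global = global, channelwise = channelwise,
                 temporal = temporal)[contexts]
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (is.null(b) || length(b) == 0) {
      stop(sprintf("context block '%s' is empty; disable it explicitly via 'contexts'", nm))
    }
    if (!all(is.finite(b))) stop(sprintf("context block '%s' contains non-finite values", nm))
  }
  values <- unlist(blocks, use.names = FALSE)
  ends <- cumsum(lengths(blocks))
  spans <- Map(function(from, to) c(from = from, to = to),
               c(1, utils::head(ends, -1) + 1), ends)
  names(spans) <- names(blocks)
  structure(values, block_spans = spans, class = "fused_feature")
}

#' SVM configuration for the seizure detector
#'
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param cost,gamma Fixed hyperparameters; `NULL` selects them by a small
#'   grid search with stratified cross-validation inside the training fold.
#' @param cost_grid,gamma_grid Candidate grids for the search.
#' @param n_folds Folds of the inner CV (default 3).
#' @param seed Seed for the fold assignment.
#' @return A `detector_config`.
#' @export
detector_config <- function(kernel = c("radial", "linear"), cost = NULL,
                            gamma = NULL, cost_grid = c(0.1, 1, 10),
                            gamma_grid = c(0.01, 0.1, 1), n_folds = 3,
                            seed = 1) {
  kernel <- match.arg(kernel)
  structure(list(kernel = kernel, cost = cost, gamma = gamma,
                 cost_grid = cost_grid, gamma_grid = gamma_grid,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "detector_config")
}

fused_matrix <- function(X) {
  if (is.list(X) && !is.matrix(X)) {
    spans <- attr(X[[1]], "block_spans")
    X <- do.call(rbind, lapply(X, as.numeric))
    attr(X, "block_spans") <- spans
  }
  X
}

# decision scores oriented so that larger = ictal
svm_scores <- function(fit, X) {
  pred <- stats::predict(fit, X, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  s <- dv[, 1]
  if (!grepl("^ictal", colnames(dv)[1])) s <- -s
  list(class = as.character(pred), score = unname(s))
}

#' Train the fused-feature SVM seizure detector
#'
#' Standardizes every feature dimension (z-score with mean/sd estimated on
#' the training fold only), selects SVM hyperparameters by stratified
#' cross-validated grid search when they are not fixed, and fits the final
#' SVM on the full training fold. Decision scores (larger = ictal) are kept
#' available for ROC/PR analysis.
#'
#' @param X List of [fuse()]d features or a numeric matrix (rows =
#'   fragments) carrying a `block_spans` attribute.
#' @param y Labels, coercible to factor with levels `non_ictal`, `ictal`;
#'   both classes must be present.
#' @param cfg A [detector_config()].
#' @return A `detector_model` with the fitted SVM, the scaling parameters,
#'   the chosen hyperparameters, and the expected `block_spans`.
#' @export
train_detector <- function(X, y, cfg = detector_config()) {
  X <- fused_matrix(X)
  spans <- attr(X, "block_spans")
  y <- factor(as.character(y), levels = c("non_ictal", "ictal"))
  if (anyNA(y)) stop("labels must be 'ictal' or 'non_ictal'")
  if (nlevels(droplevels(y)) < 2) {
    stop("training data contains a single class; both ictal and non_ictal are required")
  }
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd_, "/")

  cost <- cfg$cost; gamma <- cfg$gamma
  need_gamma <- cfg$kernel == "radial"
  if (is.null(cost) || (need_gamma && is.null(gamma))) {
    grid <- expand.grid(cost = if (is.null(cost)) cfg$cost_grid else cost,
                        gamma = if (need_gamma && is.null(gamma))
                          cfg$gamma_grid else (if (need_gamma) gamma else NA))
    fold <- with_seed(cfg$seed, stratified_folds(y, cfg$n_folds))
    cv_acc <- apply(grid, 1, function(g) {
      correct <- 0
      for (f in seq_len(cfg$n_folds)) {
        tr <- fold != f
        fit <- e1071::svm(Xs[tr, , drop = FALSE], y[tr], kernel = cfg$kernel,
                          cost = g[["cost"]],
                          gamma = if (need_gamma) g[["gamma"]] else 1 / ncol(Xs),
                          scale = FALSE)
        correct <- correct + sum(stats::predict(fit, Xs[!tr, , drop = FALSE]) == y[!tr])
      }
      correct / length(y)
    })
    best <- which.max(cv_acc)
    cost <- grid$cost[best]
    if (need_gamma) gamma <- grid$gamma[best]
  }
  fit <- e1071::svm(Xs, y, kernel = cfg$kernel, cost = cost,
                    gamma = if (need_gamma) gamma else 1 / ncol(Xs),
                    scale = FALSE)
  structure(list(fit = fit, mean = mu, sd = sd_, cost = cost, gamma = gamma,
                 kernel = cfg$kernel, block_spans = spans, seed = cfg$seed),
            class = "detector_model")
}

#' Predict seizure labels and decision scores
#'
#' @param object A `detector_model`.
#' @param newdata Fused-feature matrix or list; its `block_spans` must match
#'   the spans the detector was trained with.
#' @param ... Unused.
#' @return Data frame with columns `class` and `score` (larger = ictal).
#' @export
predict.detector_model <- function(object, newdata, ...) {
  X <- fused_matrix(newdata)
  spans <- attr(X, "block_spans")
  if (!is.null(object$block_spans)) {
    if (is.null(spans) || !identical(spans, object$block_spans)) {
      stop("feature block_spans do not match the detector's training layout")
    }
  }
  Xs <- sweep(sweep(X, 2, object$mean), 2, object$sd, "/")
  out <- svm_scores(object$fit, Xs)
  data.frame(class = out$class, score = out$score, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Metrics

#' Classification metrics from a confusion matrix
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' F1 `2PR/(P+R)`, accuracy `(TP+TN)/(TP+TN+FP+FN)`. A zero denominator
#' yields 0 with a warning.
#'
#' @param tp,fp,fn,tn Nonnegative integer counts.
#' @return Named list with `precision`, `recall`, `f1`, `accuracy`.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reported as 0", what))
      return(0)
    }
    num / den
  }
  p <- safe_div(tp, tp + fp, "precision")
  r <- safe_div(tp, tp + fn, "recall")
  f1 <- safe_div(2 * p * r, p + r, "F1")
  acc <- safe_div(tp + tn, tp + tn + fp + fn, "accuracy")
  list(precision = p, recall = r, f1 = f1, accuracy = acc)
}

trap_auc <- function(x, y) {
  ord <- order(x)
  sum(diff(x[ord]) * (utils::head(y[ord], -1) + utils::tail(y[ord], -1)) / 2)
}

#' ROC curve from decision scores
#'
#' Thresholds sweep the unique score values from high to low (tied scores
#' collapse onto one operating point), tracing (FPR, TPR) from (0,0) to
#' (1,1).
#'
#' @param scores Numeric decision scores, larger = positive.
#' @param labels Logical or `ictal`/`non_ictal` labels.
#' @return Data frame with columns `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  pos <- as_positive(labels)
  ord <- order(scores, decreasing = TRUE)
  pos <- pos[ord]; sc <- scores[ord]
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- !duplicated(sc, fromLast = TRUE)   # one point per distinct threshold
  P <- sum(pos); N <- length(pos) - P
  fpr <- c(0, fp[last] / max(N, 1))
  tpr <- c(0, tp[last] / max(P, 1))
  data.frame(fpr = fpr, tpr = tpr)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  as.character(labels) == "ictal"
}

#' Precision-recall curve from decision scores
#'
#' @inheritParams roc_curve
#' @return Data frame with columns `recall`, `precision`, starting at
#'   recall 0 with the precision of the highest-score operating point.
#' @export
pr_curve <- function(scores, labels) {
  pos <- as_positive(labels)
  ord <- order(scores, decreasing = TRUE)
  pos <- pos[ord]; sc <- scores[ord]
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- !duplicated(sc, fromLast = TRUE)
  P <- sum(pos)
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / max(P, 1)
  data.frame(recall = c(0, rec), precision = c(prec[1], prec))
}

#' AUC of an ROC or PR curve by the trapezoidal rule
#'
#' @param curve Data frame from [roc_curve()] or [pr_curve()] (first column
#'   = x axis, second = y axis).
#' @return Area in `[0, 1]`.
#' @export
curve_auc <- function(curve) {
  trap_auc(curve[[1]], curve[[2]])
}

#' Evaluate a seizure detector on a test fold
#'
#' Hard predictions at the SVM's default decision boundary populate the
#' confusion matrix and the threshold metrics; the continuous decision
#' scores trace the ROC and PR curves, whose areas are computed by the
#' trapezoidal rule.
#'
#' @param model A `detector_model`.
#' @param X_test Fused test features (matrix or list).
#' @param y_test Test labels (both classes required).
#' @return A `metrics_report`: list with `confusion` (tp/fp/fn/tn),
#'   `precision`, `recall`, `f1`, `accuracy`, `auc_roc`, `auc_pr`, and the
#'   two `curves`.
#' @export
evaluate_detector <- function(model, X_test, y_test) {
  y <- factor(as.character(y_test), levels = c("non_ictal", "ictal"))
  if (length(y) == 0) stop("empty test set")
  if (nlevels(droplevels(y)) < 2) stop("test set must contain both classes")
  pred <- predict(model, X_test)
  pos <- as_positive(y)
  phat <- pred$class == "ictal"
  tp <- sum(phat & pos); fp <- sum(phat & !pos)
  fn <- sum(!phat & pos); tn <- sum(!phat & !pos)
  m <- confusion_metrics(tp, fp, fn, tn)
  roc <- roc_curve(pred$score, pos)
  pr <- pr_curve(pred$score, pos)
  structure(list(confusion = list(tp = tp, fp = fp, fn = fn, tn = tn),
                 precision = m$precision, recall = m$recall, f1 = m$f1,
                 accuracy = m$accuracy,
                 auc_roc = curve_auc(roc), auc_pr = curve_auc(pr),
                 curves = list(roc = roc, pr = pr),
                 scores = pred$score, labels = as.character(y)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  confusion: TP=%d FP=%d FN=%d TN=%d\n",
              x$confusion$tp, x$confusion$fp, x$confusion$fn, x$confusion$tn))
  cat(sprintf("  precision %.4f | recall %.4f | F1 %.4f | accuracy %.4f\n",
              x$precision, x$recall, x$f1, x$accuracy))
  cat(sprintf("  AUC-ROC %.4f | AUC-PR %.4f\n", x$auc_roc, x$auc_pr))
  invisible(x)
}
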
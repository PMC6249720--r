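test_that("fuse concatenates blocks in fixed order with recoverable spans", {
  g <- rnorm(10); cw <- rnorm(1380); tf <- rnorm(20)
  f <- fuse(g, cw, tf)
  expect_length(f, 1410)
  spans <- attr(f, "block_spans")
  expect_equal(names(spans), c("global", "channelwise", "temporal"))
  expect_equal(unname(f[spans$global["from"]:spans$global["to"]]), g)
  expect_equal(unname(f[spans$channelwise["from"]:spans$channelwise["to"]]), cw)
  expect_equal(unname(f[spans$temporal["from"]:spans$temporal["to"]]), tf)

  # reduced models must be requested explicitly
  expect_error(fuse(NULL, cw, tf), "empty")
  r <- fuse(NULL, cw, tf, contexts = c("channelwise", "temporal"))
  expect_length(r, 1400)
  expect_equal(names(attr(r, "block_spans")), c("channelwise", "temporal"))
})

test_that("the detector separates separable data and never leaks test scale", {
  set.seed(81)
  n <- 60
  y <- rep(c("ictal", "non_ictal"), each = n / 2)
  X <- matrix(rnorm(2 * n), n, 2) + ifelse(y == "ictal", 3, -3)
  cfg <- detector_config(kernel = "linear", cost = 1, seed = 2)
  m <- train_detector(X, y, cfg)
  pred <- predict(m, X)
  expect_equal(mean(pred$class == y), 1.0)
  expect_true(all(pred$score[y == "ictal"] > pred$score[y == "non_ictal"]))

  # determinism
  m2 <- train_detector(X, y, cfg)
  expect_identical(predict(m2, X), pred)

  # standardization parameters come from the training data only
  expect_equal(m$mean, colMeans(X))
  expect_equal(m$sd, apply(X, 2, sd))

  expect_error(train_detector(X, rep("ictal", n), cfg), "single class")
})

test_that("detector grid search runs and block spans are validated", {
  set.seed(82)
  n <- 40
  y <- rep(c("ictal", "non_ictal"), each = n / 2)
  X <- matrix(rnorm(3 * n), n, 3) + ifelse(y == "ictal", 2, -2)
  attr(X, "block_spans") <- list(global = c(from = 1, to = 3))
  m <- train_detector(X, y, detector_config(seed = 1))
  expect_true(m$cost %in% c(0.1, 1, 10))
  expect_true(m$gamma %in% c(0.01, 0.1, 1))

  X2 <- X
  attr(X2, "block_spans") <- list(temporal = c(from = 1, to = 3))
  expect_error(predict(m, X2), "block_spans")
})

test_that("confusion metrics match the standard definitions", {
  m <- confusion_metrics(tp = 3, fp = 1, fn = 1, tn = 5)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(m$accuracy, 0.8)

  w <- capture_warnings(z <- confusion_metrics(0, 0, 3, 7))
  expect_match(w, "precision", all = FALSE)  # F1 also degenerates to 0 here
  expect_equal(z$precision, 0)
  expect_equal(z$f1, 0)
})

test_that("metric identities hold over all confusion matrices with total <= 12", {
  for (total in 1:12) {
    parts <- expand.grid(tp = 0:total, fp = 0:total, fn = 0:total)
    parts <- parts[rowSums(parts) <= total, ]
    for (r in seq_len(nrow(parts))) {
      tp <- parts$tp[r]; fp <- parts$fp[r]; fn <- parts$fn[r]
      tn <- total - tp - fp - fn
      m <- suppressWarnings(confusion_metrics(tp, fp, fn, tn))
      expect_equal(m$accuracy, (tp + tn) / total)
      if (tp + fp > 0 && tp + fn > 0 && m$precision + m$recall > 0) {
        expect_equal(m$f1,
                     2 * m$precision * m$recall / (m$precision + m$recall))
      }
      expect_true(all(unlist(m) >= 0 & unlist(m) <= 1))
    }
  }
})

test_that("trapezoidal ROC AUC equals the pairwise concordance statistic", {
  set.seed(83)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    scores <- round(rnorm(n), sample(c(1, 2, 8), 1))  # coarse rounding forces ties
    auc <- curve_auc(roc_curve(scores, pos))
    expect_equal(auc, concordance_auc(scores, pos), tolerance = 1e-12)
  }

  # perfect ordering
  pos <- c(rep(TRUE, 5), rep(FALSE, 5))
  sc <- 10:1
  expect_equal(curve_auc(roc_curve(sc, pos)), 1.0)
  expect_equal(curve_auc(pr_curve(sc, pos)), 1.0)
})

test_that("ROC AUC is invariant under strictly monotone score transforms", {
  set.seed(84)
  pos <- runif(50) < 0.5
  pos[1:2] <- c(TRUE, FALSE)
  s <- rnorm(50)
  a0 <- curve_auc(roc_curve(s, pos))
  expect_equal(curve_auc(roc_curve(exp(s), pos)), a0, tolerance = 1e-12)
  expect_equal(curve_auc(roc_curve(3 * s + 7, pos)), a0, tolerance = 1e-12)
})

test_that("evaluate_detector assembles the full metrics report", {
  set.seed(85)
  n <- 50
  y <- rep(c("ictal", "non_ictal"), each = n / 2)
  X <- matrix(rnorm(2 * n), n, 2) + ifelse(y == "ictal", 2.5, -2.5)
  m <- train_detector(X, y, detector_config(kernel = "linear", cost = 1))
  rep_ <- evaluate_detector(m, X, y)
  expect_s3_class(rep_, "metrics_report")
  with(rep_$confusion, expect_equal(tp + fp + fn + tn, n))
  expect_equal(rep_$f1,
               2 * rep_$precision * rep_$recall / (rep_$precision + rep_$recall))
  expect_true(rep_$auc_roc >= 0 && rep_$auc_roc <= 1)
  expect_equal(nrow(rep_$curves$roc) > 1, TRUE)
  expect_error(evaluate_detector(m, X, rep("ictal", n)), "both classes")
})
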
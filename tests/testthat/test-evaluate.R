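test_that("the confusion matrix reproduces a worked example cell-by-cell", {
  # 26 true falls: 20 recognized, 6 confused as lie; plus some other clips
  truth <- c(rep("falling", 26), rep("lie", 10), rep("standing", 5))
  pred <- c(
    rep("falling", 20), rep("lie", 6),
    rep("lie", 9), "falling",
    rep("standing", 5)
  )
  cm <- confusion_matrix(truth, pred)
  expect_identical(cm["falling", "falling"], 20L)
  expect_identical(cm["falling", "lie"], 6L)
  expect_identical(cm["lie", "falling"], 1L)
  expect_identical(sum(cm), length(truth))
  # row sums are per-class supports
  expect_identical(unname(rowSums(cm)[c("falling", "lie", "standing")]), c(26, 10, 5))
  expect_error(confusion_matrix(c("falling"), c("jogging")), "unknown label")
  expect_error(confusion_matrix(c("falling", "lie"), "falling"), "equal length")
})

test_that("precision/recall/F1 match a hand-computed example", {
  # falling: TP 4, FP 1, FN 4 -> P = 0.8, R = 0.5, F1 = 8/13
  truth <- c(rep("falling", 8), "standing")
  pred <- c(rep("falling", 4), rep("standing", 4), "falling")
  m <- precision_recall_f1(confusion_matrix(truth, pred))
  fall <- m[m$class == "falling", ]
  expect_equal(fall$precision, 0.8, tolerance = 1e-12)
  expect_equal(fall$recall, 0.5, tolerance = 1e-12)
  expect_equal(fall$f1, 2 * 0.8 * 0.5 / 1.3, tolerance = 1e-12)
  expect_identical(fall$support, 8)
  # classes never seen are flagged undefined with zero scores
  lie <- m[m$class == "lie", ]
  expect_true(lie$undefined)
  expect_identical(lie$f1, 0)
})

test_that("metrics agree with brute-force tallies on random label sets", {
  set.seed(200)
  voc <- posture_classes()
  for (rep_i in 1:20) {
    n <- sample(30:120, 1)
    truth <- sample(voc, n, replace = TRUE)
    pred <- sample(voc, n, replace = TRUE)
    cm <- confusion_matrix(truth, pred)
    # brute-force confusion counts
    for (a in voc) {
      for (b in voc) {
        expect_identical(cm[a, b], sum(truth == a & pred == b))
      }
    }
    m <- precision_recall_f1(cm)
    for (a in voc) {
      tp <- sum(truth == a & pred == a)
      fp <- sum(truth != a & pred == a)
      fn <- sum(truth == a & pred != a)
      p_exp <- if (tp + fp == 0) 0 else tp / (tp + fp)
      r_exp <- if (tp + fn == 0) 0 else tp / (tp + fn)
      row <- m[m$class == a, ]
      expect_equal(row$precision, p_exp, tolerance = 1e-12)
      expect_equal(row$recall, r_exp, tolerance = 1e-12)
    }
    # macro = unweighted mean; micro recall = overall accuracy
    percls <- m[m$class != "macro", ]
    mac <- m[m$class == "macro", ]
    expect_equal(mac$precision, mean(percls$precision), tolerance = 1e-12)
    expect_equal(mac$f1, mean(percls$f1), tolerance = 1e-12)
    expect_equal(attr(m, "micro_recall"), mean(truth == pred), tolerance = 1e-12)
  }
})

test_that("ROC/AUC handle the canonical extremes", {
  truth <- c(rep("falling", 5), rep("standing", 5))
  # perfect separation
  r <- fall_binary_roc(truth, c(runif(5, 0.6, 1), runif(5, 0, 0.4)))
  expect_equal(r$auc, 1, tolerance = 1e-12)
  # all scores tied: chance
  r2 <- fall_binary_roc(truth, rep(0.5, 10))
  expect_equal(r2$auc, 0.5, tolerance = 1e-12)
  # curve endpoints are (0,0) and (1,1), monotone in both axes
  expect_identical(c(r$roc$fpr[1], r$roc$tpr[1]), c(0, 0))
  expect_identical(c(
    r$roc$fpr[nrow(r$roc)],
    r$roc$tpr[nrow(r$roc)]
  ), c(1, 1))
  expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
  expect_error(fall_binary_roc(rep("falling", 4), runif(4)), "positive and one negative")
  expect_error(fall_binary_roc(truth, c(runif(9), 1.2)), "\\[0, 1\\]")
})

test_that("trapezoidal AUC equals the rank statistic on random scores", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    truth <- sample(c("falling", "lie"), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(truth)) < 2) next
    s <- round(runif(n), sample(c(1, 2, 7), 1)) # induce ties sometimes
    r <- fall_binary_roc(truth, s)
    y <- truth == "falling"
    sp <- s[y]
    sn <- s[!y]
    u <- 0
    for (a in sp) u <- u + sum(a > sn) + 0.5 * sum(a == sn)
    expect_equal(r$auc, u / (length(sp) * length(sn)), tolerance = 1e-9)
    # score reversal flips the AUC around 1/2
    rr <- fall_binary_roc(truth, 1 - s)
    expect_equal(rr$auc, 1 - r$auc, tolerance = 1e-9)
  }
})

test_that("AUC agrees with an independent reference implementation", {
  set.seed(7)
  truth <- sample(posture_classes(), 300, replace = TRUE)
  s <- runif(300)
  s[truth == "falling"] <- pmin(1, s[truth == "falling"] + 0.3)
  ours <- fall_binary_roc(truth, s)$auc
  ref <- suppressMessages(pROC::auc(
    pROC::roc(truth == "falling", s, quiet = TRUE, direction = "<")
  ))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-9)
})

test_that("evaluate_classifier assembles a coherent report with tidy/glance", {
  feats <- make_feats(10L, classes = posture_classes()[1:3], sep = 3, seed = 9L)
  m <- build_transformer(4L, 6L, transformer_config(
    num_blocks = 1L, num_heads = 2L, key_dim = 4L, d_model = 8L,
    ff_conv_filters = 8L, dropout_rate = 0, mlp_units = 6L, num_classes = 3L
  ), seed = 1L)
  cfg <- train_config(
    base_learning_rate = 5e-3, max_epochs = 30L,
    early_stopping_patience = 30L, batch_size = 10L, seed = 0L
  )
  fit <- train_classifier(m, feats, feats, cfg)
  rep <- evaluate_classifier(fit, feats)
  expect_s3_class(rep, "eval_report")
  expect_identical(rep$n, 30L)
  expect_identical(sum(rep$confusion), 30L)
  expect_equal(rep$accuracy, attr(rep$metrics, "micro_recall"), tolerance = 1e-12)
  g <- glance(rep)
  expect_identical(nrow(g), 1L)
  expect_identical(
    names(g),
    c("n", "accuracy", "macro_precision", "macro_recall", "macro_f1", "fall_auc")
  )
  expect_identical(tidy(rep), rep$metrics)
  expect_output(print(rep), "eval_report")
})

test_that("run_benchmark returns a deterministic preset-by-seed grid", {
  feats <- make_feats(8L, T_len = 4L, D = 3L, classes = posture_classes(), sep = 1.5, seed = 12L)
  res <- run_benchmark(feats, c("transformer1", "gru1"),
    seeds = 0L,
    max_epochs = 2L, early_stopping_patience = 2L
  )
  expect_identical(nrow(res), 2L)
  expect_identical(res$preset, c("transformer1", "gru1"))
  expect_true(all(res$macro_f1 >= 0 & res$macro_f1 <= 1))
  expect_true(all(res$fall_auc >= 0 & res$fall_auc <= 1))
  res2 <- run_benchmark(feats, c("transformer1", "gru1"),
    seeds = 0L,
    max_epochs = 2L, early_stopping_patience = 2L
  )
  expect_identical(res, res2)
})
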
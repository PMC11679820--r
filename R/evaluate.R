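#' Multiclass confusion matrix
#'
#' Rows are true classes, columns predicted classes, in vocabulary
#' order; entry (i, j) counts items of true class i predicted as j.
#'
#' @param truth,predicted Vectors of labels (character or factor).
#' @param vocabulary Class order; default the seven-posture vocabulary.
#' @return A K x K integer matrix of class `fall_confusion`.
#' @export
confusion_matrix <- function(truth, predicted, vocabulary = posture_classes()) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) stop("truth and predicted must have equal length")
  bad <- setdiff(unique(c(truth, predicted)), vocabulary)
  if (length(bad) > 0L) stop("unknown label(s): ", paste(bad, collapse = ", "))
  cm <- table(
    factor(truth, levels = vocabulary),
    factor(predicted, levels = vocabulary)
  )
  out <- matrix(as.integer(cm), nrow = length(vocabulary),
    dimnames = list(truth = vocabulary, predicted = vocabulary)
  )
  class(out) <- c("fall_confusion", class(out))
  out
}

#' Per-class precision, recall and F1
#'
#' For class k: TP is the diagonal entry, FP the rest of column k, FN
#' the rest of row k; precision = TP/(TP+FP), recall = TP/(TP+FN), F1
#' their harmonic mean. Empty denominators yield 0 (flagged in
#' `undefined`). Macro averages are unweighted class means; the
#' `micro_recall` attribute (= overall accuracy) is also attached.
#'
#' @param cm A confusion matrix from [confusion_matrix()].
#' @return Tibble with one row per class plus a `"macro"` row:
#'   `class`, `precision`, `recall`, `f1`, `support`, `undefined`.
#' @export
precision_recall_f1 <- function(cm) {
  cm <- unclass(cm)
  k <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  recall <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(precision + recall == 0, 0,
    2 * precision * recall / (precision + recall)
  )
  out <- tibble::tibble(
    class = rownames(cm),
    precision = unname(precision), recall = unname(recall), f1 = unname(f1),
    support = unname(rowSums(cm)),
    undefined = unname(tp + fp == 0 | tp + fn == 0)
  )
  out <- dplyr::bind_rows(out, tibble::tibble(
    class = "macro",
    precision = mean(precision), recall = mean(recall), f1 = mean(f1),
    support = sum(cm), undefined = any(out$undefined)
  ))
  attr(out, "micro_recall") <- sum(tp) / sum(cm)
  out
}

#' Fall-vs-rest ROC curve and AUC
#'
#' Binarizes the problem as falling vs. all other classes and sweeps a
#' threshold over the distinct predicted fall probabilities, tracing the
#' true-positive rate against the false-positive rate (tied scores are
#' grouped); AUC by the trapezoidal rule.
#'
#' @param truth Vector of true labels.
#' @param fall_probabilities Predicted probability of the falling class,
#'   in \[0, 1\].
#' @param positive_class Label treated as positive (default `"falling"`).
#' @return List with `roc` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
fall_binary_roc <- function(truth, fall_probabilities, positive_class = "falling") {
  y <- as.character(truth) == positive_class
  s <- as.numeric(fall_probabilities)
  if (any(s < 0 | s > 1)) stop("probabilities must lie in [0, 1]")
  if (all(y) || !any(y)) stop("need at least one positive and one negative example")
  np <- sum(y)
  nn <- sum(!y)
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(s >= t & y) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(s >= t & !y) / nn, numeric(1))
  roc <- tibble::tibble(
    threshold = c(Inf, thr),
    fpr = c(0, fpr), tpr = c(0, tpr)
  )
  if (roc$fpr[nrow(roc)] < 1 || roc$tpr[nrow(roc)] < 1) {
    roc <- dplyr::bind_rows(roc, tibble::tibble(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Evaluate a classifier on a feature set
#'
#' Computes the full report: confusion matrix, per-class and macro
#' precision/recall/F1, and the fall-vs-rest ROC/AUC.
#'
#' @param model A trained `fall_classifier`.
#' @param features Nested feature tibble (normalized like the training
#'   data).
#' @return An `eval_report` list: `confusion`, `metrics`, `roc`, `auc`,
#'   `accuracy`, `n`.
#' @export
evaluate_classifier <- function(model, features) {
  probs <- predict(model, features, type = "prob")
  pred <- model$classes[max.col(as.matrix(probs[, model$classes]))]
  truth <- features$label
  cm <- confusion_matrix(truth, pred, vocabulary = model$classes)
  metrics <- precision_recall_f1(cm)
  roc <- fall_binary_roc(truth, probs$falling)
  structure(
    list(
      confusion = cm, metrics = metrics, roc = roc$roc, auc = roc$auc,
      accuracy = attr(metrics, "micro_recall"), n = length(truth)
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report: n = %d, accuracy %.3f, macro-F1 %.3f, fall AUC %.3f>\n",
    x$n, x$accuracy, x$metrics$f1[x$metrics$class == "macro"], x$auc
  ))
  invisible(x)
}

#' Per-class metrics of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return The per-class + macro metrics tibble.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$metrics

#' One-row summary of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One-row tibble: n, accuracy, macro precision/recall/F1, AUC.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  mac <- x$metrics[x$metrics$class == "macro", ]
  tibble::tibble(
    n = x$n, accuracy = x$accuracy,
    macro_precision = mac$precision, macro_recall = mac$recall,
    macro_f1 = mac$f1, fall_auc = x$auc
  )
}

#' Benchmark a set of presets over seeds
#'
#' For each preset and seed: split the feature set, fit min-max
#' normalization on the training split, train, and evaluate on the test
#' split; returns the grid of results.
#'
#' @param features Nested feature tibble (un-normalized).
#' @param presets Character vector of preset names (see [preset_config()]).
#' @param seeds Integer vector of seeds.
#' @param max_epochs,early_stopping_patience Training-schedule settings
#'   applied to every preset.
#' @param verbose Print progress?
#' @return Tibble: preset, seed, epochs, macro F1/precision/recall,
#'   accuracy, fall AUC.
#' @export
run_benchmark <- function(features, presets, seeds = 0L,
                          max_epochs = 40L, early_stopping_patience = 8L,
                          verbose = FALSE) {
  rows <- list()
  d_in <- length(feature_channels(features))
  T_len <- attr(features, "n_frames")
  for (preset in presets) {
    for (seed in seeds) {
      pc <- preset_config(preset,
        max_epochs = max_epochs,
        early_stopping_patience = early_stopping_patience, seed = seed
      )
      sp <- split_clips(features, pc$train_cfg)
      np <- fit_minmax(sp$train)
      model <- if (inherits(pc$model_cfg, "transformer_config")) {
        build_transformer(d_in, T_len, pc$model_cfg, seed = seed)
      } else {
        build_recurrent(d_in, T_len, pc$model_cfg, seed = seed)
      }
      model <- train_classifier(
        model, apply_minmax(sp$train, np), apply_minmax(sp$val, np),
        pc$train_cfg
      )
      rep <- evaluate_classifier(model, apply_minmax(sp$test, np))
      g <- glance(rep)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        preset = preset, seed = seed, epochs = nrow(model$history),
        macro_f1 = g$macro_f1, macro_precision = g$macro_precision,
        macro_recall = g$macro_recall, accuracy = g$accuracy,
        fall_auc = g$fall_auc
      )
      if (verbose) {
        message(sprintf(
          "%s seed %d: macro-F1 %.3f acc %.3f auc %.3f",
          preset, seed, g$macro_f1, g$accuracy, g$fall_auc
        ))
      }
    }
  }
  dplyr::bind_rows(rows)
}
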
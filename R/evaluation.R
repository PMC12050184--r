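# Evaluation: ROC/AUC by the rank (pair-counting) definition, Youden
# threshold selection, confusion matrices, stratified k-fold assignment,
# and the cross-validated feature-count study.

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counted one half (the rank / pair-counting
#' definition, equivalent to the Wilcoxon statistic).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (logical, or 0/1); both classes must be
#'   present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stopf("scores and labels must have equal length")
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stopf("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-optimal decision threshold
#'
#' Scans the midpoints of adjacent sorted unique scores and returns the
#' threshold maximizing Youden's J = sensitivity + specificity - 1, where
#' a sample is called positive when its score strictly exceeds the
#' threshold. Ties are resolved to the lowest such threshold. If all
#' scores are identical there is no candidate cutoff and the common score
#' is returned (all decisions negative).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels; both classes must be present.
#' @return The selected threshold.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stopf("scores and labels must have equal length")
  if (!any(labels) || all(labels))
    stopf("both classes must be present to select a threshold")
  u <- sort(unique(scores))
  if (length(u) == 1L) return(u)
  cand <- (u[-length(u)] + u[-1]) / 2
  J <- vapply(cand, function(th) {
    mean(scores[labels] > th) + mean(scores[!labels] <= th) - 1
  }, 0)
  cand[which.max(J)]
}

#' Confusion matrix
#'
#' @param truth True class labels.
#' @param predicted Predicted class labels.
#' @param classes Ordered class vocabulary; labels outside it are an
#'   error.
#' @return Square integer matrix, entry (i, j) = count of true class i
#'   predicted as class j.
#' @export
confusion_matrix <- function(truth, predicted, classes = GROUP_LEVELS) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) == 0L) stopf("empty input")
  if (length(truth) != length(predicted))
    stopf("truth and predicted must have equal length")
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad))
    stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  tt <- table(factor(truth, classes), factor(predicted, classes))
  m <- matrix(as.integer(tt), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

#' Stratified k-fold assignment
#'
#' Shuffles each class independently (seeded) and deals its members to the
#' folds round-robin, so per-class counts across folds differ by at most
#' one; classes with fewer than k members simply occupy fewer folds per
#' round.
#'
#' @param labels Class labels.
#' @param k Number of folds (2 <= k <= N).
#' @param seed RNG seed.
#' @return Integer vector of fold ids in 1..k, one per sample.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  n <- length(labels)
  if (k < 2 || k > n) stopf("k must satisfy 2 <= k <= N (N = %d)", n)
  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  folds <- integer(n)
  offset <- 0L
  for (cl in unique(as.character(labels))) {
    idx <- which(as.character(labels) == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- (offset + length(idx)) %% k
  }
  folds
}

#' Cross-validated feature-count study
#'
#' For each requested feature count F: per fold, trains the classifier on
#' the k-1 training folds using the first F features, computes the
#' per-class one-vs-rest AUC on the training folds, selects per-class
#' decision thresholds by Youden's J on the training folds (leakage-free;
#' set `leaky_thresholds = TRUE` to select them on the held-out fold, the
#' protocol variant in which thresholds come from the test ROC), then
#' evaluates arg-max accuracy and the confusion matrix on the held-out
#' fold.
#'
#' @param features N x F_max numeric matrix of shape coefficients
#'   (unscaled; columns are divided by `feature_scale`).
#' @param labels Class labels drawn from `classes`.
#' @param F_counts Feature counts to study (default `c(5, 10, 15)`).
#' @param k Number of folds (default 4).
#' @param seed Seed for fold assignment and per-fold training.
#' @param config A [train_config]; its seed is re-derived per fold.
#' @param hidden_size Hidden-layer width (default 10).
#' @param classes Ordered class vocabulary.
#' @param feature_scale Optional positive divisors per feature column
#'   (e.g. `sqrt(lambda_k)`); default: standard deviation of each training
#'   fold column.
#' @param leaky_thresholds Select thresholds on the held-out fold instead
#'   of the training folds (default FALSE).
#' @return A `crossval_report`: per feature count, a list with `auc`
#'   (k x classes, training folds), `auc_test` (held-out fold, NA when a
#'   class is absent from it), `thresholds` (k x classes), `accuracy`
#'   (length k), `confusion` (per fold + `total`), and the means
#'   `mean_auc`, `mean_auc_test`, `mean_thresholds`, `mean_accuracy`.
#' @export
cross_validate <- function(features, labels, F_counts = c(5, 10, 15),
                           k = 4L, seed = 1L, config = train_config(),
                           hidden_size = 10L, classes = GROUP_LEVELS,
                           feature_scale = NULL, leaky_thresholds = FALSE) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (any(F_counts > ncol(features)))
    stopf("feature count %d exceeds the available %d components",
          max(F_counts), ncol(features))
  if (any(F_counts < 1)) stopf("feature counts must be positive")
  folds <- stratified_kfold(labels, k, seed)
  reports <- lapply(F_counts, function(FF) {
    auc <- matrix(NA_real_, k, length(classes),
                  dimnames = list(paste0("k_", seq_len(k)), classes))
    thr <- auc
    auc_test <- auc
    acc <- numeric(k)
    conf <- vector("list", k)
    for (fold in seq_len(k)) {
      tr <- folds != fold
      Xtr <- features[tr, seq_len(FF), drop = FALSE]
      Xte <- features[!tr, seq_len(FF), drop = FALSE]
      scale <- if (!is.null(feature_scale)) feature_scale[seq_len(FF)]
      else apply(Xtr, 2, sd)
      scale[!is.finite(scale) | scale <= 0] <- 1
      Xtr <- sweep(Xtr, 2, scale, `/`)
      Xte <- sweep(Xte, 2, scale, `/`)
      fold_seed <- (seed * 131L + fold * 17L + FF) %% .Machine$integer.max
      model <- init_classifier(FF, hidden_size = hidden_size,
                               classes = classes, seed = fold_seed,
                               feature_scale = scale)
      cfg <- config
      cfg$seed <- fold_seed
      model <- train_sgd(model, Xtr, labels[tr], cfg)$model
      Ptr <- nn_forward(model, Xtr)
      Pte <- nn_forward(model, Xte)
      for (ci in seq_along(classes)) {
        pos_tr <- labels[tr] == classes[ci]
        pos_te <- labels[!tr] == classes[ci]
        auc[fold, ci] <- roc_auc(Ptr[, ci], pos_tr)
        auc_test[fold, ci] <- if (length(unique(pos_te)) == 2)
          roc_auc(Pte[, ci], pos_te) else NA_real_
        thr[fold, ci] <- if (leaky_thresholds)
          youden_threshold(Pte[, ci], pos_te)
        else youden_threshold(Ptr[, ci], pos_tr)
      }
      pred <- classes[max.col(Pte, ties.method = "first")]
      acc[fold] <- mean(pred == labels[!tr])
      conf[[fold]] <- confusion_matrix(labels[!tr], pred, classes)
    }
    total <- Reduce(`+`, conf)
    list(F = FF, auc = auc, auc_test = auc_test, thresholds = thr,
         accuracy = acc, confusion = c(conf, list(total = total)),
         mean_auc = colMeans(auc),
         mean_auc_test = colMeans(auc_test, na.rm = TRUE),
         mean_thresholds = colMeans(thr), mean_accuracy = mean(acc))
  })
  names(reports) <- paste0("F", F_counts)
  structure(list(reports = reports, k = as.integer(k), seed = seed,
                 classes = classes, folds = folds),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  for (rep in x$reports) {
    cat(sprintf("F = %d: mean accuracy %.3f, mean AUC %.3f\n", rep$F,
                rep$mean_accuracy, mean(rep$mean_auc)))
    cat("  per-class mean AUC: ",
        paste(sprintf("%s %.3f", names(rep$mean_auc), rep$mean_auc),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
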
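# Three-layer sigmoid neural network trained by stochastic gradient
# descent on cross-entropy: the classifier that maps the leading SSM
# coefficients to four class probabilities. Written in plain matrix
# algebra; hidden activations H = sigmoid(W' x + B), outputs
# P = sigmoid(V' H + C). Outputs are independent sigmoids (not normalized
# across classes), which is what makes per-class ROC decision thresholds
# meaningful.

sigmoid <- function(z) 1 / (1 + exp(-z))

PROB_CLIP <- 1e-12

#' Training configuration for the classifier
#'
#' @param learning_rate SGD step size (default 0.01).
#' @param max_epochs Epoch cap (default 2000).
#' @param batch_size Samples per update (default 1, i.e. stochastic).
#' @param tol Stop when the epoch-mean loss changes by less than this
#'   (default 1e-6).
#' @param seed RNG seed controlling initialization-free shuffling.
#' @param loss `"binary"` (per-class binary cross-entropy, the default) or
#'   `"target"` (pure `-sum L log P`).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.01, max_epochs = 2000L,
                         batch_size = 1L, tol = 1e-6, seed = 1L,
                         loss = c("binary", "target")) {
  stopifnot(learning_rate > 0, max_epochs >= 0, batch_size >= 1, tol >= 0)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), tol = tol,
                 seed = as.integer(seed), loss = match.arg(loss)),
            class = "train_config")
}

#' Initialize a classifier
#'
#' Weights are drawn uniformly in +/- sqrt(6 / (fan_in + fan_out))
#' (Glorot), biases start at zero; the draw is reproducible per seed.
#'
#' @param t Input feature count (number of SSM coefficients used).
#' @param hidden_size Hidden-layer width (default 10).
#' @param classes Ordered class labels (default
#'   normal/barton/colles/smith).
#' @param seed RNG seed.
#' @param feature_scale Optional per-feature divisors (e.g.
#'   `sqrt(lambda_k)`) recorded with the model; entries must be positive.
#' @return An `nn_classifier` with weight matrices `W` (t x h), `V`
#'   (h x o), biases `B`, `C`, and empty `thresholds`.
#' @export
init_classifier <- function(t, hidden_size = 10L, classes = GROUP_LEVELS,
                            seed = 1L, feature_scale = NULL) {
  t <- as.integer(t); hidden_size <- as.integer(hidden_size)
  if (t < 1L) stopf("t must be positive")
  if (hidden_size < 1L) stopf("hidden_size must be positive")
  n_classes <- length(classes)
  if (n_classes < 2L) stopf("need at least 2 classes")
  if (!is.null(feature_scale)) {
    if (length(feature_scale) != t || any(feature_scale <= 0))
      stopf("feature_scale must have %d positive entries", t)
  }
  old <- globalenv()$.Random.seed
  set.seed(seed)
  lim1 <- sqrt(6 / (t + hidden_size))
  lim2 <- sqrt(6 / (hidden_size + n_classes))
  W <- matrix(runif(t * hidden_size, -lim1, lim1), t, hidden_size)
  V <- matrix(runif(hidden_size * n_classes, -lim2, lim2), hidden_size,
              n_classes)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(W = W, B = numeric(hidden_size), V = V,
                 C = numeric(n_classes), t = t, hidden_size = hidden_size,
                 classes = as.character(classes),
                 feature_scale = feature_scale, thresholds = NULL),
            class = "nn_classifier")
}

#' @export
print.nn_classifier <- function(x, ...) {
  cat(sprintf("nn_classifier: %d -> %d -> %d (classes: %s)%s\n", x$t,
              x$hidden_size, length(x$classes),
              paste(x$classes, collapse = ", "),
              if (!is.null(x$thresholds)) " [thresholds set]" else ""))
  invisible(x)
}

as_feature_matrix <- function(model, features) {
  X <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  if (ncol(X) != model$t)
    stopf("expected %d features, got %d", model$t, ncol(X))
  X
}

#' Forward pass
#'
#' Computes the per-class probabilities `P = sigmoid(V' H + C)` with
#' `H = sigmoid(W' x + B)`. Inputs are assumed already scaled (see
#' `feature_scale` in [init_classifier]). Deterministic given the weights.
#'
#' @param model An `nn_classifier`.
#' @param features Length-t vector or N x t matrix.
#' @return N x n_classes matrix of probabilities in (0, 1).
#' @export
nn_forward <- function(model, features) {
  stopifnot(inherits(model, "nn_classifier"))
  X <- as_feature_matrix(model, features)
  H <- sigmoid(sweep(X %*% model$W, 2, model$B, `+`))
  P <- sigmoid(sweep(H %*% model$V, 2, model$C, `+`))
  colnames(P) <- model$classes
  P
}

#' Cross-entropy loss
#'
#' `"binary"` (default): per-class binary cross-entropy
#' `-sum(L log P + (1 - L) log(1 - P))`, the formulation matching
#' independent sigmoid outputs. `"target"`: the bare `-sum(L log P)` term
#' only. Probabilities are clipped to `[1e-12, 1 - 1e-12]`. Summed over
#' samples and classes.
#'
#' @param labels One-hot matrix (or vector) of true labels.
#' @param probs Matching matrix (or vector) of predicted probabilities.
#' @param type `"binary"` or `"target"`.
#' @return Scalar loss.
#' @export
nn_loss <- function(labels, probs, type = c("binary", "target")) {
  type <- match.arg(type)
  L <- if (is.matrix(labels)) labels else matrix(labels, nrow = 1)
  P <- if (is.matrix(probs)) probs else matrix(probs, nrow = 1)
  if (!all(dim(L) == dim(P))) stopf("labels and probs dimensions differ")
  if (!all(L %in% c(0, 1)) || !all(rowSums(L) == 1))
    stopf("labels must be one-hot (exactly one 1 per row)")
  P <- pmin(pmax(P, PROB_CLIP), 1 - PROB_CLIP)
  out <- -sum(L * log(P))
  if (type == "binary") out <- out - sum((1 - L) * log(1 - P))
  out
}

# One-hot encode a label factor/character vector against the model classes.
one_hot <- function(labels, classes) {
  idx <- match(as.character(labels), classes)
  if (anyNA(idx))
    stopf("unknown label(s): %s",
          paste(unique(labels[is.na(idx)]), collapse = ", "))
  L <- matrix(0, length(idx), length(classes))
  L[cbind(seq_along(idx), idx)] <- 1
  colnames(L) <- classes
  L
}

# Analytic gradients of the loss for one mini-batch (rows of X/L).
nn_gradients <- function(model, X, L, type = "binary") {
  H <- sigmoid(sweep(X %*% model$W, 2, model$B, `+`))
  P <- sigmoid(sweep(H %*% model$V, 2, model$C, `+`))
  Pc <- pmin(pmax(P, PROB_CLIP), 1 - PROB_CLIP)
  d2 <- if (type == "binary") Pc - L else -L * (1 - Pc)
  dV <- crossprod(H, d2)
  dC <- colSums(d2)
  d1 <- (d2 %*% t(model$V)) * H * (1 - H)
  dW <- crossprod(X, d1)
  dB <- colSums(d1)
  list(W = dW, B = dB, V = dV, C = dC)
}

#' Train by stochastic gradient descent
#'
#' Per-sample (or mini-batch) gradient steps in a freshly shuffled order
#' each epoch, seeded for reproducibility. Training stops at `max_epochs`
#' or when the epoch-mean training loss changes by less than `tol`.
#'
#' @param model An `nn_classifier` (see [init_classifier]).
#' @param features N x t matrix of (already scaled) inputs.
#' @param labels Class labels (character/factor) or one-hot matrix; every
#'   class must be present and N must be at least the class count.
#' @param config A [train_config].
#' @return List with `model` (trained) and `history` (epoch-mean losses).
#' @export
train_sgd <- function(model, features, labels, config = train_config()) {
  stopifnot(inherits(model, "nn_classifier"), inherits(config, "train_config"))
  X <- as_feature_matrix(model, features)
  L <- if (is.matrix(labels)) labels else one_hot(labels, model$classes)
  if (nrow(L) != nrow(X)) stopf("labels and features row counts differ")
  if (nrow(X) < length(model$classes))
    stopf("need at least as many samples (%d) as classes (%d)", nrow(X),
          length(model$classes))
  if (any(colSums(L) == 0))
    stopf("every class must be present in the training labels (missing: %s)",
          paste(model$classes[colSums(L) == 0], collapse = ", "))
  n <- nrow(X)
  lr <- config$learning_rate
  history <- numeric(0)
  prev <- Inf
  if (config$max_epochs > 0) {
    old <- globalenv()$.Random.seed
    set.seed(config$seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      for (s in starts) {
        rows <- ord[s:min(s + config$batch_size - 1L, n)]
        g <- nn_gradients(model, X[rows, , drop = FALSE],
                          L[rows, , drop = FALSE], config$loss)
        model$W <- model$W - lr * g$W
        model$B <- model$B - lr * g$B
        model$V <- model$V - lr * g$V
        model$C <- model$C - lr * g$C
      }
      ep_loss <- nn_loss(L, nn_forward(model, X), config$loss) / n
      if (!is.finite(ep_loss))
        stopf(paste("training diverged (non-finite loss at epoch %d);",
                    "try a smaller learning_rate"), epoch)
      history <- c(history, ep_loss)
      if (abs(prev - ep_loss) < config$tol) break
      prev <- ep_loss
    }
  }
  list(model = model, history = history)
}

#' Set per-class decision thresholds
#'
#' @param model An `nn_classifier`.
#' @param thresholds Named or ordered numeric vector in (0, 1), one per
#'   class.
#' @return The model with thresholds recorded.
#' @export
set_thresholds <- function(model, thresholds) {
  stopifnot(inherits(model, "nn_classifier"))
  if (length(thresholds) != length(model$classes))
    stopf("need one threshold per class")
  if (any(thresholds <= 0 | thresholds >= 1))
    stopf("thresholds must lie in (0, 1)")
  if (!is.null(names(thresholds)))
    thresholds <- thresholds[model$classes]
  model$thresholds <- as.numeric(thresholds)
  model
}

#' Predict class labels and per-class decisions
#'
#' The single predicted label is the arg-max class (ties resolved to the
#' first class in the declared order). With `use_thresholds = TRUE` the
#' per-class binary decisions `P_i > threshold_i` are additionally
#' evaluated (e.g. "deemed normal if P > 0.333").
#'
#' @param object A trained `nn_classifier`.
#' @param features Length-t vector or N x t matrix (already scaled).
#' @param use_thresholds Apply the stored per-class thresholds.
#' @param ... Unused.
#' @return List with `label` (character vector), `decisions` (N x classes
#'   logical matrix or NULL) and `probs`.
#' @export
predict.nn_classifier <- function(object, features, use_thresholds = FALSE,
                                  ...) {
  P <- nn_forward(object, features)
  lab <- object$classes[max.col(P, ties.method = "first")]
  decisions <- NULL
  if (use_thresholds) {
    if (is.null(object$thresholds))
      stopf("no thresholds stored; call set_thresholds() first")
    decisions <- sweep(P, 2, object$thresholds, `>`)
    colnames(decisions) <- object$classes
  }
  list(label = lab, decisions = decisions, probs = P)
}
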
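# The statistical shape model: shape-matrix assembly, PCA via the
# centered-data singular value decomposition (equivalent to the
# eigendecomposition of the 1/(N-1) covariance), cumulative variance
# contribution, bounded shape synthesis, and projection to coefficients.

#' Assemble a shape dataset from corresponded clouds
#'
#' Each cloud becomes one row vector `(x1, y1, z1, ..., xM, yM, zM)` of
#' length 3M. All clouds must share the point count and point order
#' (i.e., be post-correspondence).
#'
#' @param clouds List of [point_cloud]s with identical M.
#' @param labels Optional group labels (one per cloud).
#' @param subject_ids Optional subject identifiers; defaults to the clouds'
#'   own ids.
#' @return A `shape_dataset` with fields `X` (N x 3M matrix), `N`, `M`,
#'   `labels`, `subject_ids`.
#' @export
build_shape_matrix <- function(clouds, labels = NULL, subject_ids = NULL) {
  if (!length(clouds)) stopf("no clouds supplied")
  stopifnot(all(vapply(clouds, inherits, TRUE, "point_cloud")))
  Ms <- vapply(clouds, n_points, 1L)
  if (length(unique(Ms)) != 1L) {
    bad <- which(Ms != Ms[1])
    stopf("clouds have mismatched point counts (subject(s) %s differ from subject 1)",
          paste(bad, collapse = ", "))
  }
  if (is.null(subject_ids))
    subject_ids <- vapply(clouds, function(cl)
      if (nzchar(cl$subject_id)) cl$subject_id else NA_character_, "")
  if (!is.null(labels) && length(labels) != length(clouds))
    stopf("labels must have one entry per cloud")
  X <- t(vapply(clouds, function(cl) as.numeric(t(cl$points)),
                numeric(3L * Ms[1])))
  structure(list(X = X, N = length(clouds), M = Ms[1], labels = labels,
                 subject_ids = subject_ids),
            class = "shape_dataset")
}

#' Fit a statistical shape model
#'
#' Computes the mean shape and the eigenpairs of the sample covariance
#' `S = 1/(N-1) * sum_i (T_i - Tbar)(T_i - Tbar)'` via the singular value
#' decomposition of the centered data matrix, which agrees with the direct
#' eigendecomposition to numerical precision. Eigenvector sign is fixed by
#' making the largest-magnitude component positive so results are
#' reproducible across linear-algebra backends. The retained component
#' count `t` is the smallest number of leading modes whose cumulative
#' variance contribution exceeds `alpha`.
#'
#' @param dataset A `shape_dataset` (see [build_shape_matrix]) or an
#'   N x 3M numeric matrix.
#' @param alpha Retained-variance target in (0, 1]; default 0.75.
#' @return A `shape_model` with fields `mean_shape`, `eigenvalues`
#'   (descending, length r), `eigenvectors` (3M x r orthonormal columns),
#'   `total_variance`, `rank`, `alpha`, `t`, `M`, `N`.
#' @export
fit_ssm <- function(dataset, alpha = 0.75) {
  X <- if (inherits(dataset, "shape_dataset")) dataset$X else as.matrix(dataset)
  if (!(alpha > 0 && alpha <= 1)) stopf("alpha must lie in (0, 1]")
  N <- nrow(X)
  if (N < 2L) stopf("model fitting needs at least 2 shapes (got %d)", N)
  mean_shape <- colMeans(X)
  Xc <- sweep(X, 2, mean_shape)
  sv <- svd(Xc, nu = 0)
  lambda_all <- sv$d^2 / (N - 1)
  total_variance <- sum(lambda_all)
  if (total_variance == 0) {
    model <- structure(list(mean_shape = mean_shape, eigenvalues = numeric(0),
                            eigenvectors = matrix(0, ncol(X), 0),
                            total_variance = 0, rank = 0L, alpha = alpha,
                            t = 0L, M = ncol(X) / 3L, N = N),
                       class = "shape_model")
    return(model)
  }
  r <- sum(lambda_all > lambda_all[1] * 1e-12)
  lambda <- lambda_all[seq_len(r)]
  V <- sv$v[, seq_len(r), drop = FALSE]
  for (k in seq_len(r)) {
    if (V[which.max(abs(V[, k])), k] < 0) V[, k] <- -V[, k]
  }
  cum <- cumsum(lambda) / total_variance
  t <- which(cum > alpha)[1]
  if (is.na(t)) t <- r
  structure(list(mean_shape = mean_shape, eigenvalues = lambda,
                 eigenvectors = V, total_variance = total_variance,
                 rank = as.integer(r), alpha = alpha, t = as.integer(t),
                 M = ncol(X) / 3L, N = N),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf(
    "shape_model: N = %d shapes, 3M = %d dims, rank %d, t = %d modes (alpha = %.2f)\n",
    x$N, length(x$mean_shape), x$rank, x$t, x$alpha))
  if (x$rank > 0)
    cat(sprintf("leading eigenvalues: %s\n",
                paste(signif(utils::head(x$eigenvalues, 5), 4),
                      collapse = ", ")))
  invisible(x)
}

#' Cumulative variance contribution
#'
#' The fraction of total shape variance captured by the first `t` modes,
#' `sum_{k<=t} lambda_k / lambda_T`. Returns 1 whenever `t` is at or above
#' the model rank (the saturation that makes small groups reach 100%).
#'
#' @param model A `shape_model`.
#' @param t Number of leading modes (non-negative integer).
#' @return Proportion in \[0, 1\].
#' @export
cumulative_contribution <- function(model, t) {
  stopifnot(inherits(model, "shape_model"), t >= 0)
  if (model$total_variance == 0)
    stopf("cumulative contribution is undefined for a zero-variance model")
  if (t == 0) return(0)
  sum(model$eigenvalues[seq_len(min(t, model$rank))]) / model$total_variance
}

#' Synthesize a shape from model coefficients
#'
#' Reconstructs `Tbar + sum_k b_k * phi_k`. With `enforce_bounds = TRUE`,
#' coefficients are required to satisfy `|b_k| <= c_limit * sqrt(lambda_k)`
#' (the plausibility box that keeps generated shapes similar to the
#' training population); violations raise an error rather than being
#' silently clamped. The bound is expressed in standard-deviation units
#' (`sqrt(lambda_k)`) since `lambda_k` is a variance and the conventional
#' `|c| <= 3` limit is a three-sigma rule.
#'
#' @param model A `shape_model`.
#' @param b Coefficient vector of length at most the model rank.
#' @param enforce_bounds Check the plausibility bounds (default FALSE).
#' @param c_limit Bound multiplier (default 3).
#' @return Numeric shape vector of length 3M.
#' @export
synthesize_shape <- function(model, b, enforce_bounds = FALSE, c_limit = 3) {
  stopifnot(inherits(model, "shape_model"))
  b <- as.numeric(b)
  if (length(b) > model$rank)
    stopf("coefficient vector longer (%d) than model rank (%d)", length(b),
          model$rank)
  if (enforce_bounds && length(b)) {
    lim <- c_limit * sqrt(model$eigenvalues[seq_along(b)])
    bad <- which(abs(b) > lim)
    if (length(bad))
      stopf("coefficient(s) %s exceed the +/- %g * sqrt(lambda) bound",
            paste(bad, collapse = ", "), c_limit)
  }
  out <- model$mean_shape
  if (length(b))
    out <- out + as.numeric(model$eigenvectors[, seq_along(b), drop = FALSE]
                            %*% b)
  out
}

#' Project a shape onto the model modes
#'
#' Returns the coefficients `b_k = phi_k' (shape - Tbar)` for the first `t`
#' modes; by orthonormality this inverts [synthesize_shape] exactly for
#' shapes in the model span.
#'
#' @param model A `shape_model`.
#' @param shape Numeric vector of length 3M.
#' @param t Number of leading modes (default `model$t`).
#' @return Numeric coefficient vector of length `t`.
#' @export
project_shape <- function(model, shape, t = model$t) {
  stopifnot(inherits(model, "shape_model"))
  if (length(shape) != length(model$mean_shape))
    stopf("shape length %d does not match model dimension %d", length(shape),
          length(model$mean_shape))
  if (t > model$rank)
    stopf("t (%d) exceeds model rank (%d)", t, model$rank)
  if (t == 0) return(numeric(0))
  as.numeric(crossprod(model$eigenvectors[, seq_len(t), drop = FALSE],
                       shape - model$mean_shape))
}

# Convert a 3M shape vector back to an M x 3 point matrix.
shape_to_points <- function(shape) {
  matrix(shape, ncol = 3, byrow = TRUE)
}
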
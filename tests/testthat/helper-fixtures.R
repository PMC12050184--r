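# Shared fixtures and independent oracles used across test files.

# A small asymmetric cloud with distinct principal axes and non-zero skew
# along each (so principal-axis sign disambiguation is well-defined).
asymmetric_cloud <- function(n = 300, seed = 1) {
  set.seed(seed)
  P <- cbind(rexp(n, rate = 1 / 4), rexp(n, rate = 1 / 2), rexp(n, 1))
  point_cloud(P)
}

# Rotation angle (degrees) of the rigid motion best mapping centered X to
# centered Y (Kabsch); the independent oracle for applied rotations.
kabsch_angle <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Xc, Yc))
  R <- s$v %*% diag(c(1, 1, det(s$v %*% t(s$u)))) %*% t(s$u)
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

# Affine (A, b) composition of a list of rigid transforms applied left to
# right; oracle for "composes to identity" checks.
compose_affine <- function(tfs) {
  A <- diag(3)
  b <- c(0, 0, 0)
  for (tf in tfs) {
    af <- radssm:::transform_affine(tf)
    A <- af$A %*% A
    b <- as.numeric(af$A %*% b) + af$b
  }
  list(A = A, b = b)
}

# Exhaustive pair-counting AUC: the definitional oracle.
auc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Exhaustive Youden threshold scan over midpoints of adjacent sorted
# unique scores (lowest maximizer).
youden_scan <- function(scores, labels) {
  labels <- as.logical(labels)
  u <- sort(unique(scores))
  cand <- (u[-length(u)] + u[-1]) / 2
  J <- sapply(cand, function(th)
    mean(scores[labels] > th) + mean(scores[!labels] <= th) - 1)
  cand[which.max(J)]
}

# Definitional one-way ANOVA F from the sums-of-squares decomposition.
anova_f_oracle <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  (ssb / df1) / (ssw / df2)
}

# Numeric gradient of the training loss by central finite differences.
numeric_gradients <- function(model, X, L, type, eps = 1e-6) {
  f <- function(m) radssm:::nn_loss(L, nn_forward(m, X), type)
  out <- list()
  for (nm in c("W", "B", "V", "C")) {
    g <- model[[nm]]
    gn <- g
    for (i in seq_along(g)) {
      mp <- model; mp[[nm]][i] <- g[i] + eps
      mm <- model; mm[[nm]][i] <- g[i] - eps
      gn[i] <- (f(mp) - f(mm)) / (2 * eps)
    }
    out[[nm]] <- gn
  }
  out
}
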
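# ROC/AUC, Youden thresholds, confusion matrices, stratified folds and
# the cross-validated feature study.

test_that("AUC equals the exhaustive pair-counting oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.8, 0.3), c(1, 1, 0, 0)), 0.75)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")

  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(4:60, 1)
    s <- round(runif(n), sample(1:3, 1))  # induce ties
    l <- sample(c(0, 1), n, TRUE)
    if (length(unique(l)) < 2) l[1:2] <- c(0, 1)
    expect_equal(roc_auc(s, l), auc_pairs(s, l), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(30)
  s <- rnorm(50)
  l <- sample(c(0, 1), 50, TRUE)
  l[1:2] <- c(0, 1)
  base <- roc_auc(s, l)
  expect_equal(roc_auc(exp(s), l), base)
  expect_equal(roc_auc(qlogis(plogis(s)), l), base, tolerance = 1e-12)
  expect_equal(roc_auc(s * 100 - 7, l), base)
})

test_that("Youden threshold maximizes J over score midpoints", {
  # clean separation: midpoint of the adjacent unique scores 0.2 and 0.8
  expect_equal(youden_threshold(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0)), 0.5)
  # single positive and negative: their midpoint
  expect_equal(youden_threshold(c(0.7, 0.3), c(1, 0)), 0.5)
  expect_error(youden_threshold(c(1, 2), c(1, 1)), "both classes")

  # exhaustive-scan oracle on random score sets
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:40, 1)
    s <- round(runif(n), 2)
    l <- sample(c(0, 1), n, TRUE)
    if (length(unique(l)) < 2) l[1:2] <- c(0, 1)
    if (length(unique(s)) < 2) next
    expect_equal(youden_threshold(s, l), youden_scan(s, l))
  }
  # interleaved case, expected value frozen from the exhaustive scan
  expect_equal(youden_threshold(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)),
               youden_scan(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))
  expect_equal(youden_threshold(c(0.1, 0.4, 0.35, 0.8), c(0, 1, 0, 1)),
               0.375)
})

test_that("confusion matrices count true-by-predicted pairs", {
  truth <- c("normal", "normal", "colles", "smith")
  pred <- c("normal", "colles", "colles", "smith")
  m <- confusion_matrix(truth, pred)
  expect_equal(sum(m), 4)
  expect_equal(m["normal", "normal"], 1L)
  expect_equal(m["normal", "colles"], 1L)
  expect_equal(sum(diag(m)) / sum(m), 0.75)

  perfect <- confusion_matrix(truth, truth)
  expect_equal(sum(diag(perfect)), 4L)
  expect_error(confusion_matrix(character(0), character(0)), "empty")
  expect_error(confusion_matrix("normal", "greenstick"), "unknown")

  # accuracy identity on random inputs
  classes <- c("normal", "barton", "colles", "smith")
  for (seed in 1:5) {
    set.seed(seed)
    t <- sample(classes, 30, TRUE)
    p <- sample(classes, 30, TRUE)
    m <- confusion_matrix(t, p)
    expect_equal(sum(diag(m)) / sum(m), mean(t == p))
    expect_equal(rowSums(m), table(factor(t, classes))[rownames(m)],
                 ignore_attr = TRUE)
  }
})

test_that("stratified folds balance classes and partition the cohort", {
  y <- rep(c("normal", "colles", "barton", "smith"), c(43, 17, 12, 8))
  f <- stratified_kfold(y, 4, seed = 3)
  expect_equal(as.numeric(table(f)), rep(20, 4))
  for (cl in unique(y)) {
    per <- table(factor(f[y == cl], levels = 1:4))
    expect_lte(diff(range(per)), 1)
  }
  expect_equal(as.numeric(table(f[y == "smith"])), rep(2, 4))
  expect_identical(f, stratified_kfold(y, 4, seed = 3))
  expect_false(identical(f, stratified_kfold(y, 4, seed = 4)))
  expect_error(stratified_kfold(y, 1), "k must")
  expect_error(stratified_kfold(y, 100), "k must")
  # every sample in exactly one fold
  expect_true(all(f %in% 1:4))
  expect_length(f, length(y))
})

test_that("cross-validation reports fold tables and stays honest on null data", {
  set.seed(41)
  n <- 48
  y <- rep(c("normal", "barton", "colles", "smith"), each = n / 4)
  X <- matrix(rnorm(n * 6), n, 6)  # no class signal at all
  cfg <- train_config(max_epochs = 60, seed = 1)
  aucs <- sapply(1:6, function(s) {
    r <- cross_validate(X, y, F_counts = 6, k = 4, seed = s, config = cfg)
    mean(r$reports$F6$auc_test, na.rm = TRUE)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)

  r <- cross_validate(X, y, F_counts = c(3, 6), k = 4, seed = 2,
                      config = cfg)
  expect_named(r$reports, c("F3", "F6"))
  rep6 <- r$reports$F6
  expect_equal(dim(rep6$auc), c(4, 4))
  expect_equal(rownames(rep6$auc), paste0("k_", 1:4))
  expect_true(all(rep6$auc >= 0 & rep6$auc <= 1))
  expect_true(all(rep6$thresholds > 0 & rep6$thresholds < 1))
  expect_length(rep6$accuracy, 4)
  expect_equal(sum(rep6$confusion$total), n)
  # confusion row sums equal per-class test counts
  expect_equal(as.numeric(rowSums(rep6$confusion$total)),
               as.numeric(table(factor(y, r$classes))))
  expect_error(cross_validate(X, y, F_counts = 10, k = 4, seed = 1),
               "exceeds")
})

test_that("strong class separation yields near-perfect cross-validation", {
  set.seed(42)
  n <- 48
  y <- rep(c("normal", "barton", "colles", "smith"), each = n / 4)
  centers <- matrix(rnorm(4 * 4, sd = 6), 4, 4)
  X <- centers[as.integer(factor(y, unique(y))), ] + matrix(rnorm(n * 4),
                                                            n, 4)
  r <- cross_validate(X, y, F_counts = 4, k = 4, seed = 1,
                      config = train_config(max_epochs = 300, seed = 1))
  expect_gte(r$reports$F4$mean_accuracy, 0.9)
  expect_gte(mean(r$reports$F4$auc), 0.95)
})
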
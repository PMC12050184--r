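# The three-layer sigmoid network and its SGD training.

test_that("initialization is seeded and validated", {
  m1 <- init_classifier(5, hidden_size = 8, seed = 42)
  m2 <- init_classifier(5, hidden_size = 8, seed = 42)
  m3 <- init_classifier(5, hidden_size = 8, seed = 43)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$V, m2$V)
  expect_false(identical(m1$W, m3$W))
  expect_equal(m1$B, rep(0, 8))
  # Glorot range
  expect_lte(max(abs(m1$W)), sqrt(6 / (5 + 8)))
  expect_error(init_classifier(5, hidden_size = 0), "positive")
  expect_error(init_classifier(0), "positive")
})

test_that("forward pass equals hand-evaluated sigmoids", {
  m <- init_classifier(1, hidden_size = 1, classes = c("a", "b"), seed = 1)
  m$W[] <- 0; m$V[] <- 0; m$B[] <- 0; m$C[] <- 0
  expect_equal(as.numeric(nn_forward(m, 0)), c(0.5, 0.5))

  # W = 1, B = 0, V = 1, C = 0, input 0: H = 0.5, P = sigmoid(0.5)
  m$W[] <- 1; m$V[1, 1] <- 1
  p <- nn_forward(m, 0)
  expect_equal(as.numeric(p[1, "a"]), 1 / (1 + exp(-0.5)),
               tolerance = 1e-12)
  expect_equal(as.numeric(p[1, "a"]), 0.6225, tolerance = 1e-4)

  # monotonicity: increasing a positive output weight raises that output
  m2 <- m; m2$V[1, 1] <- 2
  expect_gt(nn_forward(m2, 0)[1, "a"], p[1, "a"])

  # deterministic given weights
  x <- matrix(rnorm(5), 5, 1)
  expect_identical(nn_forward(m, x), nn_forward(m, x))
  expect_error(nn_forward(m, c(1, 2)), "expected 1 features")
})

test_that("cross-entropy loss matches logarithm arithmetic", {
  expect_lt(nn_loss(c(1, 0), c(1, 0)), 1e-10)  # clipped perfect prediction
  expect_equal(nn_loss(c(1, 0), c(0.5, 0.5), type = "target"), log(2),
               tolerance = 1e-12)
  expect_equal(nn_loss(c(1, 0), c(0.5, 0.5), type = "binary"), 2 * log(2),
               tolerance = 1e-12)
  # moving toward the label lowers the loss coordinate-wise
  expect_lt(nn_loss(c(1, 0), c(0.6, 0.5)), nn_loss(c(1, 0), c(0.5, 0.5)))
  expect_lt(nn_loss(c(1, 0), c(0.5, 0.4)), nn_loss(c(1, 0), c(0.5, 0.5)))
  expect_error(nn_loss(c(1, 1), c(0.5, 0.5)), "one-hot")
  expect_error(nn_loss(c(0.3, 0.7), c(0.5, 0.5)), "one-hot")
})

test_that("analytic gradients agree with central finite differences", {
  for (seed in 1:4) {
    set.seed(seed)
    type <- if (seed %% 2) "binary" else "target"
    m <- init_classifier(3, hidden_size = 4, classes = c("a", "b"),
                         seed = seed)
    X <- matrix(rnorm(15), 5, 3)
    L <- radssm:::one_hot(sample(c("a", "b"), 5, TRUE,
                                 prob = c(0.6, 0.4)), c("a", "b"))
    if (all(L[, 1] == L[1, 1])) L[1, ] <- 1 - L[1, ]
    ga <- radssm:::nn_gradients(m, X, L, type)
    gn <- numeric_gradients(m, X, L, type)
    for (nm in c("W", "B", "V", "C")) {
      denom <- pmax(abs(gn[[nm]]), 1e-4)
      expect_lt(max(abs(ga[[nm]] - gn[[nm]]) / denom), 1e-5)
    }
  }
})

test_that("SGD leaves weights unchanged at zero epochs and learns blobs", {
  m <- init_classifier(2, hidden_size = 4, classes = c("a", "b"), seed = 7)
  X <- matrix(rnorm(20), 10, 2)
  y <- rep(c("a", "b"), 5)
  out <- train_sgd(m, X, y, train_config(max_epochs = 0))
  expect_identical(out$model$W, m$W)
  expect_length(out$history, 0)

  # two Gaussian blobs separated by 6 sigma: perfect training accuracy
  set.seed(99)
  n <- 40
  X <- rbind(matrix(rnorm(n, 0, 1), n / 2, 2),
             matrix(rnorm(n, 6, 1), n / 2, 2))
  y <- rep(c("a", "b"), each = n / 2)
  m <- init_classifier(2, hidden_size = 4, classes = c("a", "b"), seed = 7)
  fit <- train_sgd(m, X, y, train_config(max_epochs = 500, seed = 7))
  pred <- predict(fit$model, X)
  expect_equal(mean(pred$label == y), 1)
  # final epoch loss no worse than the first
  expect_lte(fit$history[length(fit$history)], fit$history[1])
})

test_that("training validates labels and class coverage", {
  m <- init_classifier(2, hidden_size = 3, classes = c("a", "b", "c"))
  X <- matrix(rnorm(8), 4, 2)
  expect_error(train_sgd(m, X, c("a", "a", "b", "b")), "missing: c")
  expect_error(train_sgd(m, X[1:2, ], c("a", "b")), "as many samples")
  expect_error(train_sgd(m, X, c("a", "b", "c", "zz")), "unknown label")
})

test_that("prediction applies arg-max, tie and threshold rules", {
  m <- init_classifier(2, hidden_size = 3, seed = 5) # 4 default classes
  # the decision rules on a crafted probability row
  P <- matrix(c(0.9, 0.1, 0.1, 0.1), 1, 4,
              dimnames = list(NULL, m$classes))
  lab <- m$classes[max.col(P, ties.method = "first")]
  expect_equal(lab, "normal")
  expect_equal(as.logical(P > 0.333), c(TRUE, FALSE, FALSE, FALSE))

  # through the real forward pass: ties resolve to the first class
  mz <- init_classifier(2, hidden_size = 3, seed = 5)
  mz$W[] <- 0; mz$B[] <- 0; mz$V[] <- 0; mz$C[] <- 0
  pr <- predict(mz, c(0, 0))
  expect_equal(unique(as.numeric(pr$probs)), 0.5)
  expect_equal(pr$label, "normal")

  # per-class threshold decision can disagree with the arg-max label
  mz$C <- c(-1.4, -1.1, -0.85, -1.1)  # probs approx (.198, .25, .30, .25)
  mz <- set_thresholds(mz, c(0.333, 0.197, 0.286, 0.197))
  out <- predict(mz, c(0, 0), use_thresholds = TRUE)
  expect_equal(out$label, "colles")
  expect_true(out$decisions[1, "barton"])
  expect_false(out$decisions[1, "normal"])

  expect_error(predict(init_classifier(2), c(0, 0), use_thresholds = TRUE),
               "thresholds")
})
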
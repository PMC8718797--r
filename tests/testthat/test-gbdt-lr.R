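test_that("the initial score is the halved log class ratio", {
  expect_equal(init_score(c(1, 1, 0, 0)), 0)
  expect_equal(init_score(c(1, 1, 1, 0)), 0.5 * log(3))
  expect_equal(init_score(c(1, 0, 0, 0)), -0.5 * log(3))
  expect_error(init_score(c(1, 1)), "both classes")
  expect_error(init_score(c(1, 2, 0)), "0/1")
})

test_that("residuals follow the negative log-loss gradient", {
  expect_equal(gbdt_residuals(1, 0), 0.5)
  expect_equal(gbdt_residuals(-1, 0), -0.5)
  expect_equal(gbdt_residuals(1, 50), 0, tolerance = 1e-12)
  expect_equal(gbdt_residuals(c(1, -1), c(1, 2)),
               c(1 / (1 + exp(1)), -1 / (1 + exp(-2))))
})

test_that("tree fitting finds the exhaustive best split deterministically", {
  # residuals perfectly split by feature 1 at 0.5
  X <- cbind(c(0, 0, 0.9, 1, 0.1, 1), c(5, 1, 3, 2, 4, 0))
  r <- c(-1, -1, 1, 1, -1, 1)
  tree <- fit_tree(X, r, max_depth = 2, min_leaf = 1)
  expect_equal(tree$feature[1], 1L)
  expect_equal(tree$threshold[1], 0.5)

  # exhaustive-search oracle on random data
  set.seed(33)
  for (rep in 1:10) {
    Xr <- matrix(runif(14 * 3), 14, 3)
    rr <- rnorm(14)
    stump <- fit_tree(Xr, rr, max_depth = 1, min_leaf = 2)
    expect_lte(sum(stump$leaf), 2)
    if (sum(stump$leaf) < 2) next
    # oracle: best SSE reduction over all features/thresholds
    best <- -Inf; arg <- NULL
    for (f in 1:3) {
      v <- sort(unique(Xr[, f]))
      for (t in (v[-1] + v[-length(v)]) / 2) {
        L <- rr[Xr[, f] <= t]; R <- rr[Xr[, f] > t]
        if (length(L) < 2 || length(R) < 2) next
        gain <- sum(rr^2) - sum(rr)^2 / 14 -
          (sum(L^2) - sum(L)^2 / length(L)) -
          (sum(R^2) - sum(R)^2 / length(R))
        if (gain > best + 1e-12) { best <- gain; arg <- c(f, t) }
      }
    }
    expect_equal(stump$feature[1], as.integer(arg[1]))
    expect_equal(stump$threshold[1], arg[2])
  }

  # constant residuals give a single leaf; depth 1 gives at most 2 leaves
  expect_equal(nrow(fit_tree(X, rep(1, 6), max_depth = 3, min_leaf = 1)), 1)
  expect_lte(sum(fit_tree(X, r, max_depth = 1, min_leaf = 1)$leaf), 2)
})

test_that("leaf Newton values follow the prescribed one-step formula", {
  tree1 <- fit_tree(matrix(0, 1, 1), 0, max_depth = 1, min_leaf = 1)
  # single sample y = +1 at score 0: r = 0.5, c = 0.5 / (0.5 * 1.5)
  expect_equal(leaf_values(tree1, 1L, 1, 0), c(`1` = 2 / 3))
  # all-zero residuals give 0
  expect_equal(leaf_values(tree1, 1L, 1, 1e9), c(`1` = 0))
  # symmetric leaf cancels exactly
  tree2 <- fit_tree(matrix(0, 2, 1), c(0, 0), max_depth = 1, min_leaf = 1)
  expect_equal(leaf_values(tree2, c(1L, 1L), c(1, -1), c(0, 0)),
               c(`1` = 0))
})

test_that("boosting drives the training loss down and replays exactly", {
  set.seed(8)
  n <- 80
  X <- cbind(runif(n), runif(n))
  y <- as.integer(X[, 1] > 0.55)         # linearly separable
  ens <- boost(X, y, n_trees = 50, alpha = 0.1, max_depth = 2,
               min_leaf = 2)
  expect_length(ens$train_loss, 51)
  expect_true(all(diff(ens$train_loss) <= 1e-12))
  scores <- gbdt_score(ens, X)
  expect_equal(mean((scores > 0) == (y == 1)), 1)   # training accuracy 1

  # structural identity: score equals theta0 + alpha * sum of leaf values
  replay <- rep(ens$theta0, n)
  for (tree in ens$trees)
    replay <- replay + ens$alpha * tree$value[tree_apply(tree, X)]
  expect_identical(scores, replay)

  # AUC 1 on the separable toy
  expect_equal(roc_auc(scores, y)$auc, 1)
})

test_that("leaf codes are one-hot per tree and reproduce the worked layout", {
  # two hand-built trees with 3 and 2 leaves: a sample in leaf 1 of the
  # left tree and leaf 2 of the right codes as (1, 0, 0, 0, 1)
  t1 <- data.frame(feature = c(1L, 1L, NA, NA, NA),
                   threshold = c(0.5, 0.2, NA, NA, NA),
                   left = c(2L, 3L, NA, NA, NA),
                   right = c(5L, 4L, NA, NA, NA),
                   leaf = c(FALSE, FALSE, TRUE, TRUE, TRUE),
                   value = 0)
  t2 <- data.frame(feature = c(1L, NA, NA), threshold = c(0.7, NA, NA),
                   left = c(2L, NA, NA), right = c(3L, NA, NA),
                   leaf = c(FALSE, TRUE, TRUE), value = 0)
  ens <- structure(list(theta0 = 0, alpha = 0.1, trees = list(t1, t2),
                        train_loss = numeric(0)),
                   class = "gbdt_ensemble")
  x <- matrix(0.8, 1, 1)   # left tree: >0.5 -> leaf node 5 ... adjust
  code <- encode_leaves(ens, matrix(0.1, 1, 1))
  # x = 0.1: left tree 0.1 <= 0.5 -> node 2, 0.1 <= 0.2 -> leaf 3 (first
  # leaf in order); right tree 0.1 <= 0.7 -> leaf 2 (first leaf)
  expect_equal(as.integer(code), c(1L, 0L, 0L, 1L, 0L))
  # x = 0.8: first tree leaf 5 (third leaf), second tree leaf 3 (second)
  code2 <- encode_leaves(ens, x)
  expect_equal(as.integer(code2), c(0L, 0L, 1L, 0L, 1L))
  expect_equal(sum(code2), 2)             # exactly T ones
  # same leaves -> identical codes
  expect_equal(encode_leaves(ens, matrix(0.75, 1, 1)), code2)
})

test_that("the logistic head fits codes and behaves like a sigmoid", {
  expect_equal(lncDNet:::sigmoid(0), 0.5)
  # theta = 0 loss is log 2
  set.seed(2)
  Z <- matrix(rbinom(40, 1, 0.5), 20, 2)
  y <- as.integer(Z[, 1] == 1)
  h0 <- lr_fit(Z, y, l2 = 0, max_steps = 0)
  expect_equal(h0$loss[["initial"]], log(2))
  # separable codes reach training accuracy 1 at threshold 0.5
  h <- lr_fit(Z, y, l2 = 1e-4, max_steps = 2000)
  p <- lncDNet:::sigmoid(cbind(1, Z) %*% h$theta)
  expect_equal(as.integer(p >= 0.5), y)
  expect_lte(h$loss[["final"]], h$loss[["initial"]])
  expect_error(lr_fit(Z, y + 1), "0/1")
})

test_that("cross-check: logistic head agrees with glm on a dense problem", {
  set.seed(6)
  X <- matrix(rnorm(200), 50, 4)
  y <- as.integer(X %*% c(1, -1, 0.5, 0) + rnorm(50, sd = 0.5) > 0)
  ours <- lr_fit(X, y, l2 = 0, max_steps = 20000)
  ref <- suppressWarnings(glm.fit(cbind(1, X), y,
                                  family = binomial()))$coefficients
  expect_equal(ours$theta, unname(ref), tolerance = 1e-3)
})

test_that("cascade probabilities are proper and monotone in the weights", {
  set.seed(5)
  X <- matrix(runif(60), 30, 2)
  y <- as.integer(X[, 1] > 0.5)
  model <- gbdt_lr_fit(X, y, n_trees = 10, alpha = 0.2, max_depth = 2,
                       min_leaf = 2, max_steps = 500)
  p <- predict(model, X)
  expect_true(all(p > 0 & p < 1))
  # zero-weight head predicts 0.5 everywhere
  m0 <- model; m0$head$theta[] <- 0
  expect_equal(predict(m0, X), rep(0.5, 30))
  # increasing a positively weighted bit raises the probability
  w <- model$head$theta[-1]
  bit <- which(w > 0)[1]
  z0 <- z1 <- numeric(length(w)); z1[bit] <- 1
  pr <- function(z) lncDNet:::sigmoid(sum(model$head$theta * c(1, z)))
  expect_gt(pr(z1), pr(z0))
  expect_equal(pr(z1) + (1 - pr(z1)), 1)
})

test_that("model serialization round-trips predictions bit-exactly", {
  set.seed(10)
  X <- matrix(runif(100), 50, 2)
  y <- as.integer(X[, 1] + 0.2 * X[, 2] > 0.6)
  model <- gbdt_lr_fit(X, y, n_trees = 15, alpha = 0.1, max_depth = 2,
                       min_leaf = 2, max_steps = 300)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_gbdt_lr(model, path)
  back <- read_gbdt_lr(path)
  expect_identical(predict(back, X), predict(model, X))
})

test_that("the grid tuner ranks hyperparameters by held-out AUC", {
  set.seed(19)
  X <- matrix(runif(160), 80, 2)
  y <- as.integer(X[, 1] > 0.5)
  tuned <- tune_gbdt_lr(X, y, n_trees = c(5, 20), max_depth = 2,
                        alpha = 0.1, folds = 3, max_steps = 100)
  expect_equal(nrow(tuned), 2)
  expect_true(!is.unsorted(rev(tuned$mean_auc)))
  expect_true(all(tuned$mean_auc >= 0 & tuned$mean_auc <= 1))
})

test_that("the end-to-end cascade is deterministic", {
  set.seed(44)
  X <- matrix(runif(120), 60, 2)
  y <- as.integer(X[, 1] > 0.5)
  m1 <- gbdt_lr_fit(X, y, n_trees = 10, max_steps = 200)
  m2 <- gbdt_lr_fit(X, y, n_trees = 10, max_steps = 200)
  expect_identical(predict(m1, X), predict(m2, X))
})
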
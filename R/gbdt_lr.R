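#' Initial boosting score from the class balance
#'
#' `theta0 = 0.5 * log(sum(y) / sum(1 - y))` with labels in `{0, 1}`. Note
#' the 0.5 factor halves the conventional log-odds initialization; it is
#' kept as the method defines it (the first trees absorb the difference).
#'
#' @param labels 0/1 label vector with both classes present.
#' @return Numeric scalar.
#' @export
init_score <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  np <- sum(labels); nn <- sum(1 - labels)
  if (np == 0 || nn == 0) stop("both classes must be present")
  0.5 * log(np / nn)
}

#' Negative-gradient residuals of the boosting log-loss
#'
#' For labels `y` in `{-1, +1}` and current scores `theta`:
#' `r_i = y_i / (1 + exp(y_i * theta_i))`.
#'
#' @param y_pm labels in `{-1, +1}`.
#' @param scores current ensemble scores.
#' @return Numeric residual vector in `(-1, 1)`.
#' @export
gbdt_residuals <- function(y_pm, scores) {
  stopifnot(length(y_pm) == length(scores), all(y_pm %in% c(-1, 1)))
  y_pm / (1 + exp(y_pm * scores))
}

# Tree nodes are rows of a data frame: feature/threshold for internal
# nodes, value for leaves, left/right child row indices.
new_tree <- function() {
  data.frame(feature = integer(0), threshold = numeric(0),
             left = integer(0), right = integer(0), leaf = logical(0),
             value = numeric(0))
}

#' Fit one regression tree on residuals (structure only)
#'
#' Greedy CART with squared-error-reduction splits on the residuals;
#' thresholds are midpoints between adjacent distinct values, ties broken
#' by lowest feature index then lowest threshold, so the structure is
#' deterministic. Leaf values are assigned separately by [leaf_values()].
#'
#' @param X numeric feature matrix.
#' @param r residual vector.
#' @param max_depth depth cap (default 3; 1 gives a stump).
#' @param min_leaf minimum samples per leaf (default 5).
#' @return A `gbdt_tree`: node table plus the training-row leaf
#'   assignment in attribute `"assign"`.
#' @export
fit_tree <- function(X, r, max_depth = 3, min_leaf = 5) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(r))
  nodes <- list()
  assign_vec <- integer(nrow(X))
  grow <- function(rows, depth) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(feature = NA_integer_, threshold = NA_real_,
                         left = NA_integer_, right = NA_integer_,
                         leaf = TRUE, value = 0)
    if (depth < max_depth && length(rows) >= 2 * min_leaf) {
      sp <- best_split_cpp(X, r, rows, as.integer(min_leaf))
      if (sp[1] > 0) {
        f <- as.integer(sp[1]); thr <- sp[2]
        go_left <- X[rows, f] <= thr
        lid <- grow(rows[go_left], depth + 1L)
        rid <- grow(rows[!go_left], depth + 1L)
        nodes[[id]] <<- list(feature = f, threshold = thr, left = lid,
                             right = rid, leaf = FALSE, value = 0)
        return(id)
      }
    }
    assign_vec[rows] <<- id
    id
  }
  grow(seq_len(nrow(X)), 0L)
  tab <- do.call(rbind, lapply(nodes, as.data.frame))
  structure(tab, class = c("gbdt_tree", class(tab)), assign = assign_vec)
}

#' Leaf reached by each row of X in a fitted tree
#'
#' @param tree a [fit_tree()] result.
#' @param X feature matrix.
#' @return Integer vector of node-table row indices (leaves).
#' @export
tree_apply <- function(tree, X) {
  X <- as.matrix(X)
  vapply(seq_len(nrow(X)), function(i) {
    id <- 1L
    while (!tree$leaf[id])
      id <- if (X[i, tree$feature[id]] <= tree$threshold[id])
        tree$left[id] else tree$right[id]
    id
  }, integer(1))
}

#' Leaf values by one Newton step on the log-loss
#'
#' Per leaf, `c = sum(r) / sum(|r| * (2 - |r|))` over the member samples -
#' the standard one-step approximation to the in-leaf minimizer of the
#' boosting log-loss. A leaf with all-zero residuals gets 0.
#'
#' @param tree a [fit_tree()] result.
#' @param assign leaf assignment of the training rows (from
#'   `attr(tree, "assign")` or [tree_apply()]).
#' @param y_pm labels in `{-1, +1}`.
#' @param scores current ensemble scores.
#' @return Named numeric vector of leaf values, names = leaf node ids.
#' @export
leaf_values <- function(tree, assign, y_pm, scores) {
  r <- gbdt_residuals(y_pm, scores)
  leaves <- which(tree$leaf)
  vapply(leaves, function(id) {
    rr <- r[assign == id]
    den <- sum(abs(rr) * (2 - abs(rr)))
    if (den == 0) 0 else sum(rr) / den
  }, numeric(1)) -> v
  names(v) <- leaves
  v
}

#' Gradient-boosted regression-tree ensemble on the log-loss
#'
#' Starts from the class-balance score, then for `T` rounds fits a CART
#' tree to the negative-gradient residuals, sets its leaf values by the
#' Newton step, and adds `alpha` times the leaf value to each sample's
#' score. Training log-loss per round is recorded.
#'
#' @param X numeric feature matrix.
#' @param labels 0/1 labels (mapped to -1/+1 internally).
#' @param n_trees rounds `T` (default 100).
#' @param alpha shrinkage (default 0.1).
#' @param max_depth tree depth (default 3).
#' @param min_leaf minimum samples per leaf (default 5).
#' @return A `gbdt_ensemble`: `theta0`, `alpha`, `trees` (each with a
#'   `values` column filled in), `train_loss` (length `T + 1`, including
#'   the baseline loss).
#' @export
boost <- function(X, labels, n_trees = 100, alpha = 0.1, max_depth = 3,
                  min_leaf = 5) {
  X <- as.matrix(X)
  theta0 <- init_score(labels)
  y_pm <- ifelse(labels == 1, 1, -1)
  scores <- rep(theta0, nrow(X))
  logloss <- function(sc) mean(log(1 + exp(-y_pm * sc)))
  trees <- vector("list", n_trees)
  train_loss <- numeric(n_trees + 1)
  train_loss[1] <- logloss(scores)
  for (t in seq_len(n_trees)) {
    r <- gbdt_residuals(y_pm, scores)
    tree <- fit_tree(X, r, max_depth = max_depth, min_leaf = min_leaf)
    assign <- attr(tree, "assign")
    v <- leaf_values(tree, assign, y_pm, scores)
    tree$value[as.integer(names(v))] <- v
    attr(tree, "assign") <- NULL
    trees[[t]] <- tree
    scores <- scores + alpha * tree$value[assign]
    train_loss[t + 1] <- logloss(scores)
  }
  structure(list(theta0 = theta0, alpha = alpha, trees = trees,
                 train_loss = train_loss),
            class = "gbdt_ensemble")
}

#' @export
print.gbdt_ensemble <- function(x, ...) {
  cat(sprintf("gbdt_ensemble: %d trees, alpha=%.3g, theta0=%.4f, final train loss %.4f\n",
              length(x$trees), x$alpha, x$theta0,
              x$train_loss[length(x$train_loss)]))
  invisible(x)
}

#' Raw ensemble score
#'
#' `theta(x) = theta0 + alpha * sum_t (leaf value of x in tree t)`.
#'
#' @param ensemble a [boost()] result.
#' @param X feature matrix.
#' @return Numeric score vector.
#' @export
gbdt_score <- function(ensemble, X) {
  X <- as.matrix(X)
  s <- rep(ensemble$theta0, nrow(X))
  for (tree in ensemble$trees)
    s <- s + ensemble$alpha * tree$value[tree_apply(tree, X)]
  s
}

#' One-hot leaf encoding of the ensemble
#'
#' Concatenates, tree by tree, a one-hot indicator of the leaf each sample
#' falls in; the code has exactly one 1 per tree.
#'
#' @param ensemble a [boost()] result.
#' @param X feature matrix.
#' @return Binary matrix, `sum_t N_t` columns.
#' @export
encode_leaves <- function(ensemble, X) {
  X <- as.matrix(X)
  blocks <- lapply(ensemble$trees, function(tree) {
    leaves <- which(tree$leaf)
    hit <- match(tree_apply(tree, X), leaves)
    b <- matrix(0L, nrow(X), length(leaves))
    b[cbind(seq_len(nrow(X)), hit)] <- 1L
    b
  })
  do.call(cbind, blocks)
}

#' Logistic-regression head on the leaf codes
#'
#' Minimizes the mean cross-entropy plus a small L2 penalty (intercept
#' unpenalized) by accelerated gradient descent with a Lipschitz step
#' size; stops when the gradient norm falls below `1e-6` or at the step
#' cap.
#'
#' @param codes binary code matrix from [encode_leaves()].
#' @param labels 0/1 labels.
#' @param l2 L2 strength (default 1e-4; the codes are separable without
#'   it).
#' @param max_steps step cap (default 2000).
#' @return A `logistic_head`: `theta` (intercept first), `l2`, `steps`,
#'   `loss` (initial and final), `converged`.
#' @export
lr_fit <- function(codes, labels, l2 = 1e-4, max_steps = 2000) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  Z <- cbind(1, as.matrix(codes))
  y <- as.numeric(labels)
  m <- nrow(Z)
  theta <- numeric(ncol(Z))
  pen <- c(0, rep(l2, ncol(Z) - 1))
  loss_fn <- function(th) {
    p <- sigmoid(Z %*% th)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p)) + sum(pen * th ^ 2) / 2
  }
  grad_fn <- function(th) {
    p <- sigmoid(as.numeric(Z %*% th))
    as.numeric(crossprod(Z, p - y)) / m + pen * th
  }
  # Lipschitz constant of the gradient: lambda_max(Z'Z) / (4 m) + l2
  v <- rep(1, ncol(Z))
  for (i in 1:30) { v <- crossprod(Z, Z %*% v); v <- v / sqrt(sum(v ^ 2)) }
  lmax <- as.numeric(t(v) %*% crossprod(Z, Z %*% v))
  step <- 1 / (lmax / (4 * m) + l2)
  loss0 <- loss_fn(theta)
  th_prev <- theta
  converged <- FALSE
  steps <- 0L
  for (it in seq_len(max_steps)) {
    mom <- theta + (it - 1) / (it + 2) * (theta - th_prev)  # Nesterov
    g <- grad_fn(mom)
    th_prev <- theta
    theta <- mom - step * g
    steps <- it
    if (sqrt(sum(grad_fn(theta) ^ 2)) < 1e-6) { converged <- TRUE; break }
  }
  structure(list(theta = as.numeric(theta), l2 = l2, steps = steps,
                 loss = c(initial = loss0, final = loss_fn(theta)),
                 converged = converged),
            class = "logistic_head")
}

#' Cascade probability of a positive association
#'
#' `Pr(y = 1 | x) = sigmoid(theta . [1, encode_leaves(x)])`.
#'
#' @param ensemble a [boost()] result.
#' @param head a [lr_fit()] result.
#' @param X feature matrix.
#' @return Probabilities in (0, 1).
#' @export
predict_pair <- function(ensemble, head, X) {
  Z <- cbind(1, encode_leaves(ensemble, as.matrix(X)))
  as.numeric(sigmoid(Z %*% head$theta))
}

#' Fit the full GBDT-to-LR cascade
#'
#' @inheritParams boost
#' @inheritParams lr_fit
#' @return A `gbdt_lr_model`: `ensemble`, `head`.
#' @export
gbdt_lr_fit <- function(X, labels, n_trees = 100, alpha = 0.1,
                        max_depth = 3, min_leaf = 5, l2 = 1e-4,
                        max_steps = 2000) {
  ensemble <- boost(X, labels, n_trees = n_trees, alpha = alpha,
                    max_depth = max_depth, min_leaf = min_leaf)
  head <- lr_fit(encode_leaves(ensemble, X), labels, l2 = l2,
                 max_steps = max_steps)
  structure(list(ensemble = ensemble, head = head),
            class = "gbdt_lr_model")
}

#' @export
print.gbdt_lr_model <- function(x, ...) {
  print(x$ensemble)
  cat(sprintf("logistic head: %d weights, final loss %.4f (%d steps)\n",
              length(x$head$theta), x$head$loss[["final"]], x$head$steps))
  invisible(x)
}

#' Predict with a fitted cascade
#'
#' @param object a [gbdt_lr_fit()] model.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return Probabilities in (0, 1).
#' @export
predict.gbdt_lr_model <- function(object, newdata, ...) {
  predict_pair(object$ensemble, object$head, newdata)
}

#' Serialize a cascade model as JSON text
#'
#' Full-precision structured text (trees, initial score, shrinkage, head
#' weights); [read_gbdt_lr()] reproduces predictions bit-exactly.
#'
#' @param model a [gbdt_lr_fit()] model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gbdt_lr <- function(model, path) {
  obj <- list(theta0 = model$ensemble$theta0, alpha = model$ensemble$alpha,
              train_loss = model$ensemble$train_loss,
              trees = lapply(model$ensemble$trees, function(t)
                as.data.frame(unclass(t))),
              head = list(theta = model$head$theta, l2 = model$head$l2))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' Load a cascade model written by [write_gbdt_lr()]
#'
#' @param path JSON path.
#' @return A `gbdt_lr_model`.
#' @export
read_gbdt_lr <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trees <- if (is.data.frame(obj$trees)) list(obj$trees) else obj$trees
  trees <- lapply(trees, function(t) {
    t$feature <- as.integer(t$feature)
    t$left <- as.integer(t$left); t$right <- as.integer(t$right)
    t$leaf <- as.logical(t$leaf)
    structure(t, class = c("gbdt_tree", class(t)))
  })
  ensemble <- structure(list(theta0 = obj$theta0, alpha = obj$alpha,
                             trees = trees,
                             train_loss = obj$train_loss),
                        class = "gbdt_ensemble")
  head <- structure(list(theta = obj$head$theta, l2 = obj$head$l2,
                         steps = NA_integer_, loss = NULL,
                         converged = NA),
                    class = "logistic_head")
  structure(list(ensemble = ensemble, head = head),
            class = "gbdt_lr_model")
}

#' Cross-validated grid search over cascade hyperparameters
#'
#' Optional tuner: evaluates every combination of `n_trees`, `max_depth`
#' and `alpha` by k-fold AUC of the full cascade and returns the grid
#' with its scores, best first.
#'
#' @param X feature matrix.
#' @param labels 0/1 labels.
#' @param n_trees,max_depth,alpha candidate values (vectors).
#' @param folds CV folds (default 5).
#' @param seed split seed.
#' @param ... passed through to [gbdt_lr_fit()] (`min_leaf`, `l2`,
#'   `max_steps`).
#' @return Data frame of combinations with a `mean_auc` column, sorted
#'   decreasing.
#' @export
tune_gbdt_lr <- function(X, labels, n_trees = c(50, 100),
                         max_depth = c(2, 3), alpha = c(0.05, 0.1),
                         folds = 5, seed = 1, ...) {
  grid <- expand.grid(n_trees = n_trees, max_depth = max_depth,
                      alpha = alpha)
  fold <- kfold_split(labels, folds = folds, seed = seed)
  grid$mean_auc <- vapply(seq_len(nrow(grid)), function(i) {
    aucs <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      m <- gbdt_lr_fit(X[tr, , drop = FALSE], labels[tr],
                       n_trees = grid$n_trees[i],
                       max_depth = grid$max_depth[i],
                       alpha = grid$alpha[i], ...)
      roc_auc(predict(m, X[!tr, , drop = FALSE]), labels[!tr])$auc
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  grid[order(-grid$mean_auc), ]
}

#' Pair features from node embeddings
#'
#' Classifier input for a pair: the Hadamard (elementwise) product of the
#' lncRNA and disease embedding vectors (default), or their
#' concatenation. The product makes the pair interaction directly
#' readable by the downstream model (a weighted dot product is a linear
#' function of it), whereas concatenation leaves the interaction for the
#' trees to reconstruct.
#'
#' @param emb embedding matrix (nodes x d, rownames = ids) or an
#'   `embedding_table`.
#' @param pairs data frame of lncRNA and disease ids.
#' @param combine `"hadamard"` (length d) or `"concat"` (length 2d).
#' @return Numeric feature matrix, one row per pair.
#' @export
embedding_pair_features <- function(emb, pairs,
                                    combine = c("hadamard", "concat")) {
  combine <- match.arg(combine)
  if (inherits(emb, "embedding_table")) emb <- emb$psi
  pairs <- as.data.frame(pairs)
  el <- emb[as.character(pairs[[1]]), , drop = FALSE]
  ed <- emb[as.character(pairs[[2]]), , drop = FALSE]
  if (anyNA(el) || anyNA(ed)) stop("pair ids missing from the embedding")
  if (combine == "concat") cbind(el, ed) else el * ed
}
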
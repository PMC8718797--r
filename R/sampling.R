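#' Pair feature vectors for clustering unknown pairs
#'
#' For a pair (lncRNA `m`, disease `j`) the feature vector concatenates, in
#' order: the m-th row of `SL` (length nl), the j-th column of `A` (length
#' nl), the m-th row of `A` (length nd), and the j-th row of `SD` (length
#' nd) - total length `2 (nl + nd)`.
#'
#' @param SL,SD fused [similarity_matrix()] objects.
#' @param A an [association_matrix()].
#' @param pairs data frame (or 2-column matrix) of lncRNA and disease ids
#'   or indices.
#' @return Numeric matrix, one row per pair, `2 (nl + nd)` columns.
#' @export
build_pair_features <- function(SL, SD, A, pairs) {
  pairs <- as.data.frame(pairs)[, 1:2]
  m <- if (is.numeric(pairs[[1]])) as.integer(pairs[[1]])
       else match(as.character(pairs[[1]]), rownames(A))
  j <- if (is.numeric(pairs[[2]])) as.integer(pairs[[2]])
       else match(as.character(pairs[[2]]), colnames(A))
  if (anyNA(m) || anyNA(j) || any(m < 1) || any(m > nrow(A)) ||
      any(j < 1) || any(j > ncol(A)))
    stop("pair indices out of range")
  cbind(unclass(SL)[m, , drop = FALSE],
        t(unclass(A))[j, , drop = FALSE],
        unclass(A)[m, , drop = FALSE],
        unclass(SD)[j, , drop = FALSE])
}

# Random initial centers drawn from the points: first uniform, the rest
# D^2-weighted (k-means++), which makes the best-of-restarts objective
# reliable on small instances where plain uniform draws can miss the
# optimal basin.
init_centers <- function(x, k) {
  n <- nrow(x)
  idx <- sample.int(n, 1)
  if (k > 1) {
    d2min <- rep(Inf, n)
    for (c in seq_len(k - 1)) {
      last <- x[idx[length(idx)], ]
      d2min <- pmin(d2min, rowSums(sweep(x, 2, last)^2))
      w <- d2min
      w[idx] <- 0
      if (sum(w) == 0) w <- as.numeric(!seq_len(n) %in% idx)
      idx <- c(idx, sample.int(n, 1, prob = w))
    }
  }
  x[idx, , drop = FALSE]
}

# One Lloyd run from random initial centers chosen among the points.
lloyd_once <- function(x, k, max_iter) {
  n <- nrow(x)
  centers <- init_centers(x, k)
  assign_prev <- rep(0L, n)
  objective_trace <- numeric(0)
  converged <- FALSE
  xsq <- rowSums(x ^ 2)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- outer(xsq, rowSums(centers ^ 2), `+`) - 2 * tcrossprod(x, centers)
    assign_new <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: reseed from the point farthest from its centroid
    for (c in which(tabulate(assign_new, k) == 0)) {
      far <- which.max(d2[cbind(seq_len(n), assign_new)])
      assign_new[far] <- c
      centers[c, ] <- x[far, ]
      d2[, c] <- xsq + sum(centers[c, ] ^ 2) - 2 * x %*% centers[c, ]
    }
    objective_trace <- c(objective_trace,
                         sum(pmax(d2[cbind(seq_len(n), assign_new)], 0)))
    if (identical(assign_new, assign_prev)) { converged <- TRUE; break }
    assign_prev <- assign_new
    for (c in seq_len(k))
      centers[c, ] <- colMeans(x[assign_new == c, , drop = FALSE])
    if (iter >= max_iter) break
  }
  list(centers = centers, cluster = assign_new, iterations = iter,
       objective = objective_trace[length(objective_trace)],
       objective_trace = objective_trace, converged = converged)
}

#' K-means clustering of pair feature vectors (Lloyd's algorithm)
#'
#' Centroid-based partition of the unknown pairs: random initial centers
#' drawn from the points (the first uniformly, the rest weighted by
#' squared distance to the centers already chosen, so restarts cover the
#' optimum's basin), assignment to the nearest center (Euclidean),
#' centroid recomputation as the within-cluster mean, iterated until the
#' assignment stabilizes or `max_iter` is hit. Empty clusters are reseeded
#' from the point farthest from its current centroid. Several restarts are
#' run from seed-derived sub-seeds and the lowest-objective solution kept.
#'
#' @param x numeric matrix of points (rows).
#' @param k number of clusters (default 10).
#' @param seed RNG seed.
#' @param max_iter iteration cap per restart (default 300).
#' @param restarts independent restarts (default 10).
#' @return A `kmeans_model`: `centers`, `cluster`, `iterations`,
#'   `objective`, `objective_trace`, `converged`.
#' @export
kmeans_cluster <- function(x, k = 10, seed = 1, max_iter = 300,
                           restarts = 10) {
  x <- as.matrix(x)
  if (nrow(x) < k) stop("fewer points than clusters")
  subseeds <- vapply(seq_len(restarts), function(r) derive_seed(seed, r),
                     integer(1))
  best <- NULL
  for (s in subseeds) {
    run <- with_seed(s, lloyd_once(x, k, max_iter))
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  structure(best, class = "kmeans_model", k = k, seed = seed)
}

#' @export
print.kmeans_model <- function(x, ...) {
  cat(sprintf("kmeans_model: k=%d, n=%d, objective=%.4g, %s in %d iter\n",
              nrow(x$centers), length(x$cluster), x$objective,
              if (x$converged) "converged" else "iteration cap",
              x$iterations))
  invisible(x)
}

# Largest-remainder apportionment of n draws across cluster sizes.
proportional_quota <- function(sizes, n) {
  if (sum(sizes) < n) stop("not enough points for the requested quota")
  raw <- n * sizes / sum(sizes)
  q <- floor(raw)
  rem <- n - sum(q)
  if (rem > 0) {
    ord <- order(-(raw - q), seq_along(sizes))  # ties: lower cluster id
    q[ord[seq_len(rem)]] <- q[ord[seq_len(rem)]] + 1
  }
  # cap at cluster size, pushing overflow to clusters with spare capacity
  over <- sum(pmax(q - sizes, 0))
  q <- pmin(q, sizes)
  while (over > 0) {
    cap <- which(q < sizes)
    take <- cap[order(-(sizes[cap] - q[cap]))][1]
    q[take] <- q[take] + 1
    over <- over - 1
  }
  as.integer(q)
}

#' Select balanced negatives from the K-means partition
#'
#' Draws a negative sample of size `n_needed` from the clustered unknown
#' pairs: each cluster contributes a quota proportional to its size
#' (largest-remainder rounding; `allocation = "equal"` gives every cluster
#' the same quota instead), sampled uniformly without replacement within
#' the cluster. Deterministic given the seed.
#'
#' @param model a [kmeans_cluster()] result over `unknown_pairs`.
#' @param unknown_pairs data frame of the clustered pairs (lncRNA id,
#'   disease id), row order matching `model$cluster`.
#' @param n_needed number of negatives (usually the positive count).
#' @param seed RNG seed.
#' @param allocation `"proportional"` (default) or `"equal"`.
#' @return Data frame `lncRNA_id`, `disease_id`, `label` (0), `cluster`.
#' @export
select_negatives <- function(model, unknown_pairs, n_needed, seed = 1,
                             allocation = c("proportional", "equal")) {
  allocation <- match.arg(allocation)
  unknown_pairs <- as.data.frame(unknown_pairs)[, 1:2]
  names(unknown_pairs) <- c("lncRNA_id", "disease_id")
  if (n_needed > nrow(unknown_pairs))
    stop("n_needed exceeds the number of unknown pairs")
  k <- nrow(model$centers)
  sizes <- tabulate(model$cluster, k)
  quota <- if (allocation == "proportional") {
    proportional_quota(sizes, n_needed)
  } else {
    q <- rep(n_needed %/% k, k)
    if (n_needed %% k > 0)
      q[seq_len(n_needed %% k)] <- q[seq_len(n_needed %% k)] + 1L
    q <- pmin(q, sizes)
    short <- n_needed - sum(q)       # top up when equal split hits small clusters
    while (short > 0) {
      cap <- which(q < sizes)[1]
      q[cap] <- q[cap] + 1L
      short <- short - 1
    }
    as.integer(q)
  }
  idx <- with_seed(seed, {
    unlist(lapply(seq_len(k), function(c) {
      members <- which(model$cluster == c)
      if (quota[c] == 0) return(integer(0))
      members[sample.int(length(members), quota[c])]
    }), use.names = FALSE)
  })
  out <- unknown_pairs[idx, , drop = FALSE]
  out$label <- 0L
  out$cluster <- model$cluster[idx]
  rownames(out) <- NULL
  out
}

#' Assemble the balanced labelled training set
#'
#' All known associations labelled 1 plus the selected negatives labelled
#' 0; the negatives must be disjoint from the positives and equal in
#' number.
#'
#' @param A an [association_matrix()].
#' @param negatives data frame from [select_negatives()].
#' @return Data frame `lncRNA_id`, `disease_id`, `label`, `cluster` (NA
#'   for positives).
#' @export
assemble_training_set <- function(A, negatives) {
  idx <- which(unclass(A) == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("association matrix has no positives")
  pos <- data.frame(lncRNA_id = rownames(A)[idx[, 1]],
                    disease_id = colnames(A)[idx[, 2]],
                    label = 1L, cluster = NA_integer_)
  key <- function(d) paste(d$lncRNA_id, d$disease_id, sep = "\r")
  if (any(key(negatives) %in% key(pos)))
    stop("negatives overlap known positives")
  if (anyDuplicated(key(negatives)))
    stop("duplicate negative pairs")
  rbind(pos, negatives[, c("lncRNA_id", "disease_id", "label", "cluster")])
}

#' All unknown (zero) pairs of an association matrix
#'
#' @param A an [association_matrix()].
#' @return Data frame `lncRNA_id`, `disease_id` of every `A == 0` pair.
#' @export
unknown_pairs <- function(A) {
  idx <- which(unclass(A) == 0L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(lncRNA_id = rownames(A)[idx[, 1]],
             disease_id = colnames(A)[idx[, 2]])
}
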
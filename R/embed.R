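#' Enumerate skip-gram context pairs of a walk corpus
#'
#' Emits every ordered pair of distinct nodes whose positions within a walk
#' differ by at most the window size `b`; the empirical distribution of
#' these pairs is the co-occurrence distribution the embedding objective
#' models.
#'
#' @param corpus a [generate_corpus()] result (or list of id vectors).
#' @param b window size (default 5).
#' @return Two-column character matrix (`center`, `context`).
#' @export
context_pairs <- function(corpus, b = 5) {
  stopifnot(b >= 1)
  out <- lapply(corpus, function(w) {
    L <- length(w)
    if (L < 2) return(NULL)
    idx <- do.call(rbind, lapply(seq_len(L), function(i) {
      j <- max(1, i - b):min(L, i + b)
      j <- j[j != i]
      cbind(i, j)
    }))
    cbind(w[idx[, 1]], w[idx[, 2]])
  })
  m <- do.call(rbind, out)
  if (is.null(m)) m <- matrix(character(0), 0, 2)
  colnames(m) <- c("center", "context")
  m
}

#' Initialize an embedding table
#'
#' Input vectors `Psi` start at small uniform noise in
#' `(-0.5/d, 0.5/d)`; output (context) vectors `Phi` start at zero, the
#' word2vec convention.
#'
#' @param ids node ids.
#' @param types named character vector of node types for (at least) `ids`.
#' @param d embedding dimension (default 64).
#' @param seed RNG seed.
#' @return An `embedding_table`: list with matrices `psi`, `phi`
#'   (nodes x d) and `types`.
#' @export
embedding_init <- function(ids, types, d = 64, seed = 1) {
  stopifnot(d >= 2, all(ids %in% names(types)))
  psi <- with_seed(seed, matrix(runif(length(ids) * d, -0.5 / d, 0.5 / d),
                                length(ids), d))
  rownames(psi) <- ids
  phi <- matrix(0, length(ids), d, dimnames = list(ids, NULL))
  structure(list(psi = psi, phi = phi, types = types[ids], d = d),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("embedding_table: %d nodes x d=%d\n", nrow(x$psi), x$d))
  invisible(x)
}

# Negative-sampling loss of one (center, context) pair given negatives:
# -log sigma(phi_j . psi_i) - sum_u log sigma(-phi_u . psi_i)
sgns_pair_loss <- function(table, i, j, negs) {
  s <- sum(table$phi[j, ] * table$psi[i, ])
  l <- -log(sigmoid(s))
  for (u in negs)
    l <- l - log(sigmoid(-sum(table$phi[u, ] * table$psi[i, ])))
  l
}

# Per-type negative-sampling noise distribution (unigram^0.75 over corpus
# counts by default, or uniform over the type's nodes).
noise_distribution <- function(corpus, types, noise = c("unigram75",
                                                        "uniform")) {
  noise <- match.arg(noise)
  cnt <- table(factor(unlist(corpus, use.names = FALSE),
                      levels = names(types)))
  lapply(split(names(types), types), function(ids) {
    w <- as.numeric(cnt[ids])
    w <- if (noise == "unigram75") w ^ 0.75 else rep(1, length(ids))
    if (sum(w) == 0) w <- rep(1, length(ids))
    stats::setNames(w / sum(w), ids)
  })
}

#' One stochastic skip-gram update with type-constrained negatives
#'
#' Draws `U` negative nodes of the same type as the context node (from the
#' per-type noise distribution), computes the gradient of the
#' negative-sampling loss, and takes one gradient-descent step of size
#' `lambda` on `Psi(center)` and on the `Phi` vectors of the context and
#' the negatives. Used one pair at a time for testing; [train_embeddings()]
#' runs the identical update in compiled code.
#'
#' @param table an [embedding_init()] table.
#' @param center,context node ids of the co-occurring pair.
#' @param lambda learning rate.
#' @param U number of negative samples (default 5).
#' @param noise_dist per-type noise distribution from
#'   [noise_distribution()]; uniform over the context's type when `NULL`.
#' @param negs optional explicit negative node ids (overrides sampling;
#'   used by the gradient tests).
#' @return The updated table, with the pair loss before the update in
#'   attribute `"loss"`.
#' @export
sgns_update <- function(table, center, context, lambda, U = 5,
                        noise_dist = NULL, negs = NULL) {
  ty <- table$types[[context]]
  if (is.null(negs)) {
    cand <- names(table$types)[table$types == ty]
    cand <- setdiff(cand, context)
    if (!length(cand)) {
      warning("no candidate negatives of type ", ty, "; pair skipped")
      return(table)
    }
    pr <- if (is.null(noise_dist)) NULL else noise_dist[[ty]][cand]
    negs <- sample(cand, U, replace = TRUE, prob = pr)
  }
  loss <- sgns_pair_loss(table, center, context, negs)
  psi_i <- table$psi[center, ]
  grad_psi <- numeric(table$d)
  s <- sigmoid(sum(table$phi[context, ] * psi_i))
  grad_psi <- grad_psi - (1 - s) * table$phi[context, ]
  table$phi[context, ] <- table$phi[context, ] + lambda * (1 - s) * psi_i
  for (u in negs) {
    su <- sigmoid(sum(table$phi[u, ] * psi_i))
    grad_psi <- grad_psi + su * table$phi[u, ]
    table$phi[u, ] <- table$phi[u, ] - lambda * su * psi_i
  }
  table$psi[center, ] <- psi_i - lambda * grad_psi
  attr(table, "loss") <- loss
  table
}

#' Train heterogeneous skip-gram embeddings on a walk corpus
#'
#' Learns a d-dimensional vector per network node by sliding a window of
#' size `b` over every walk and, for each (center, context) pair, taking a
#' negative-sampling gradient step in which the `U` noise nodes share the
#' context node's type (the type-conditioned softmax approximation). The
#' learning rate decays linearly from `lambda` to `lambda_min` over all
#' updates. The inner loop runs in compiled code; results are deterministic
#' given the seed.
#'
#' @param corpus a [generate_corpus()] result.
#' @param types named node-type vector covering all corpus nodes (nodes
#'   never visited still receive their initial vectors).
#' @param d embedding dimension (default 64).
#' @param b window size (default 5).
#' @param U negative samples per context (default 5).
#' @param epochs passes over the corpus (default 5).
#' @param lambda,lambda_min initial and final learning rate.
#' @param noise `"unigram75"` (default) or `"uniform"` within-type noise.
#' @param seed RNG seed.
#' @return An `embedding_table` with an `"epoch_loss"` attribute (mean
#'   pair loss per epoch).
#' @export
train_embeddings <- function(corpus, types, d = 64, b = 5, U = 5,
                             epochs = 5, lambda = 0.025, lambda_min = 1e-4,
                             noise = c("unigram75", "uniform"), seed = 1) {
  stopifnot(length(corpus) > 0, b >= 1, U >= 1, lambda > 0, epochs >= 1)
  noise <- match.arg(noise)
  ids <- names(types)
  miss <- setdiff(unique(unlist(corpus, use.names = FALSE)), ids)
  if (length(miss)) stop("corpus nodes missing from types: ",
                         paste(head(miss, 5), collapse = ", "))
  table <- embedding_init(ids, types, d = d, seed = seed)
  walks_i <- lapply(corpus, function(w) match(w, ids) - 1L)
  type_i <- match(table$types, sort(unique(table$types))) - 1L
  nd <- noise_distribution(corpus, table$types, noise)
  type_names <- sort(unique(table$types))
  type_nodes <- lapply(type_names, function(tn)
    match(names(nd[[tn]]), ids) - 1L)
  type_cum <- lapply(type_names, function(tn) cumsum(nd[[tn]]))
  res <- with_seed(seed, sgns_train_cpp(
    walks_i, type_i, type_nodes, type_cum,
    t(table$psi), t(table$phi), as.integer(b), as.integer(U),
    lambda, lambda_min, as.integer(epochs)))
  table$psi <- t(res$psi); rownames(table$psi) <- ids
  table$phi <- t(res$phi); rownames(table$phi) <- ids
  attr(table, "epoch_loss") <- res$epoch_loss
  table
}

#' Exact type-conditioned softmax over context nodes
#'
#' For a center node, the modelled probability of each context node of a
#' given type: `exp(phi_u . psi_v) / sum over nodes of that type`. Feasible
#' only on small networks; used as an oracle for the negative-sampling
#' estimator.
#'
#' @param table an `embedding_table`.
#' @param center node id.
#' @param type node type of the contexts.
#' @return Named probability vector over nodes of `type` (sums to 1).
#' @export
type_softmax <- function(table, center, type) {
  ids <- names(table$types)[table$types == type]
  s <- as.numeric(table$phi[ids, , drop = FALSE] %*% table$psi[center, ])
  e <- exp(s - max(s))
  stats::setNames(e / sum(e), ids)
}

#' Write embeddings in word2vec text format
#'
#' First line `count dim`, then one `node_id v1 ... vd` line per node.
#'
#' @param table an `embedding_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(table$psi), table$d), con)
  writeLines(paste(rownames(table$psi),
                   apply(table$psi, 1, function(v)
                     paste(format(v, digits = 17, scientific = TRUE,
                                  trim = TRUE), collapse = " "))), con)
  invisible(path)
}

#' Read embeddings from word2vec text format
#'
#' @param path file written by [write_embeddings()].
#' @return Numeric matrix (nodes x d) with node ids as rownames.
#' @export
read_embeddings <- function(path) {
  ln <- readLines(path)
  hdr <- as.integer(strsplit(ln[1], " ")[[1]])
  tok <- strsplit(ln[-1], " ")
  m <- t(vapply(tok, function(t) as.numeric(t[-1]), numeric(hdr[2])))
  rownames(m) <- vapply(tok, `[[`, character(1), 1)
  m
}
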
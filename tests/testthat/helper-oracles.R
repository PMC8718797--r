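# Independent brute-force oracles used across the suite. These never call
# the implementation paths they check.

# Max over all descending paths of delta^length: contribution of ancestor
# `u` to disease `d` by explicit path enumeration (DAGs of <= ~8 nodes).
oracle_contribution <- function(parents, d, u, delta) {
  if (d == u) return(1)
  best <- -Inf
  walk <- function(node, len) {
    for (p in parents[[node]] %||% character(0)) {
      if (p == u) best <<- max(best, delta ^ (len + 1))
      walk(p, len + 1)
    }
  }
  walk(d, 0)
  if (is.finite(best)) best else NA_real_
}

# Exact next-node distribution of one metagraph-guided step by direct
# enumeration over the typed adjacency (independent of transition_probs).
oracle_transition <- function(G, mg, pos, v) {
  pos <- if (pos == mg$target) mg$source else pos
  out <- mg$edges[mg$edges$from == pos, , drop = FALSE]
  ets <- unique(out$edge_type)
  avail <- ets[vapply(ets, function(et)
    length(G$adj[[v]][[et]]) > 0, logical(1))]
  probs <- list()
  for (et in avail) {
    nb <- G$adj[[v]][[et]]
    for (x in nb)
      probs[[x]] <- (probs[[x]] %||% 0) + 1 / (length(avail) * length(nb))
  }
  unlist(probs) %||% numeric(0)
}

# AUC by explicit positive x negative pair counting (ties count 1/2).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Central finite differences of the SGNS pair loss wrt one coordinate.
fd_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small deterministic association fixture: 4 lncRNAs x 5 diseases.
tiny_assoc <- function() {
  A <- matrix(0L, 4, 5,
              dimnames = list(paste0("L", 1:4), paste0("D", 1:5)))
  A[cbind(c(1, 1, 2, 3, 4), c(1, 2, 2, 3, 5))] <- 1L
  suppressWarnings(association_matrix(A))
}

# Ontology fixture: D1..D5 with D1->R, D2->R, D3->D2, a root R.
tiny_ontology <- function() {
  disease_dag_set(data.frame(child = c("D1", "D2", "D3"),
                             parent = c("R", "R", "D2")),
                  diseases = paste0("D", 1:5))
}

# Random small DAG over n nodes as child->parent edges (acyclic by
# construction: parents always have smaller index in a random order).
random_dag <- function(n, p_edge = 0.4) {
  ids <- paste0("n", seq_len(n))
  ord <- sample(ids)
  edges <- list()
  for (i in seq_len(n)[-1]) {
    anc <- ord[seq_len(i - 1)]
    pick <- anc[runif(length(anc)) < p_edge]
    if (length(pick))
      edges[[length(edges) + 1]] <- data.frame(child = ord[i], parent = pick)
  }
  list(edges = if (length(edges)) do.call(rbind, edges)
       else data.frame(child = character(0), parent = character(0)),
       ids = ids)
}
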
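#' Assemble the global heterogeneous network
#'
#' Stacks the fused similarity networks and the association matrix into the
#' block matrix `U = [[SL, A], [A^T, SD]]` of dimension
#' `(nl + nd) x (nl + nd)`, and derives the walkable typed edge sets:
#' * `LD` / `DL` edges are exactly the 1-entries of `A` / `A^T`;
#' * `LL` (resp. `DD`) edges connect each node to its `top_k`
#'   highest-similarity neighbours with positive similarity (self excluded),
#'   symmetrized by union, so the walk graph stays sparse and unweighted
#'   while preserving local similarity structure.
#'
#' @param SL,SD fused [similarity_matrix()] objects.
#' @param A an [association_matrix()] with matching ids.
#' @param top_k neighbours kept per node in the similarity layers
#'   (default 10).
#' @return A `het_network`: list with `nodes` (data frame `id`, `type`),
#'   `adj` (per node, neighbour ids per edge type), and the dense matrix
#'   `U`.
#' @export
build_network <- function(SL, SD, A, top_k = 10) {
  if (!identical(rownames(SL), rownames(A)) ||
      !identical(rownames(SD), colnames(A)))
    stop("dimension/id mismatch between SL, SD and A")
  if (top_k < 1) stop("top_k must be >= 1")
  lnc <- rownames(A); dis <- colnames(A)
  if (length(intersect(lnc, dis)))
    stop("lncRNA and disease ids overlap; node ids must be unique")
  U <- rbind(cbind(unclass(SL), unclass(A)),
             cbind(t(unclass(A)), unclass(SD)))
  dimnames(U) <- list(c(lnc, dis), c(lnc, dis))

  topk_edges <- function(S) {
    n <- nrow(S)
    adj <- lapply(seq_len(n), function(i) {
      s <- S[i, ]; s[i] <- -Inf
      ord <- order(-s, seq_len(n))          # deterministic tie-break
      ord <- ord[seq_len(min(top_k, n - 1))]
      ord[s[ord] > 0]
    })
    # symmetrize by union
    for (i in seq_len(n)) for (j in adj[[i]])
      if (!i %in% adj[[j]]) adj[[j]] <- c(adj[[j]], i)
    lapply(adj, function(ix) rownames(S)[sort(ix)])
  }
  ll <- topk_edges(unclass(SL))
  dd <- topk_edges(unclass(SD))
  names(ll) <- lnc; names(dd) <- dis
  ld <- lapply(seq_along(lnc), function(m) dis[A[m, ] == 1L])
  dl <- lapply(seq_along(dis), function(j) lnc[A[, j] == 1L])
  names(ld) <- lnc; names(dl) <- dis

  adj <- c(lapply(lnc, function(l) list(LL = ll[[l]], LD = ld[[l]])),
           lapply(dis, function(d) list(DD = dd[[d]], DL = dl[[d]])))
  names(adj) <- c(lnc, dis)
  structure(list(
    nodes = data.frame(id = c(lnc, dis),
                       type = rep(c("lncRNA", "disease"),
                                  c(length(lnc), length(dis)))),
    adj = adj, U = U), class = "het_network")
}

#' @export
print.het_network <- function(x, ...) {
  nn <- table(x$nodes$type)
  ne <- vapply(c("LL", "LD", "DL", "DD"), function(et)
    sum(vapply(x$adj, function(a) length(a[[et]] %||% character(0)),
               integer(1))), numeric(1))
  cat(sprintf("het_network: %d lncRNAs + %d diseases; directed edges LL=%d LD=%d DL=%d DD=%d\n",
              nn[["lncRNA"]], nn[["disease"]], ne[1], ne[2], ne[3], ne[4]))
  invisible(x)
}

#' Named node-type vector of a heterogeneous network
#'
#' @param G a [build_network()] result.
#' @return Named character vector mapping node id to type.
#' @export
node_types <- function(G) stats::setNames(G$nodes$type, G$nodes$id)

edge_type_of <- function(from_type, to_type) {
  paste0(ifelse(from_type == "lncRNA", "L", "D"),
         ifelse(to_type == "lncRNA", "L", "D"))
}

#' Metagraph walk schema
#'
#' A metagraph is a small DAG over typed schema nodes with a source and a
#' target of the same node type; its recursive unrolling (restarting at the
#' source whenever the target is reached) constrains which typed edges a
#' random walk may traverse. Unlike a metapath it can branch.
#'
#' @param nodes data frame with columns `name`, `type`
#'   (`"lncRNA"`/`"disease"`).
#' @param edges data frame with columns `from`, `to` (schema node names).
#' @param source,target schema node names; must share a node type.
#' @return A `metagraph` object.
#' @export
metagraph <- function(nodes, edges, source, target) {
  nodes <- as.data.frame(nodes); edges <- as.data.frame(edges)
  stopifnot(all(c("name", "type") %in% names(nodes)),
            all(c("from", "to") %in% names(edges)))
  if (anyDuplicated(nodes$name)) stop("duplicate schema node names")
  if (!all(nodes$type %in% c("lncRNA", "disease")))
    stop("schema node types must be lncRNA or disease")
  if (!all(c(edges$from, edges$to, source, target) %in% nodes$name))
    stop("schema edge endpoints must be declared nodes")
  ty <- stats::setNames(nodes$type, nodes$name)
  if (ty[[source]] != ty[[target]])
    stop("source and target must have the same node type")
  # acyclicity via Kahn
  indeg <- table(factor(edges$to, levels = nodes$name))
  q <- nodes$name[indeg == 0]; seen <- 0L; rem <- indeg
  while (length(q)) {
    u <- q[[1]]; q <- q[-1]; seen <- seen + 1L
    for (v in edges$to[edges$from == u]) {
      rem[[v]] <- rem[[v]] - 1L
      if (rem[[v]] == 0L) q <- c(q, v)
    }
  }
  if (seen < nrow(nodes)) stop("metagraph must be acyclic")
  edges$edge_type <- edge_type_of(ty[edges$from], ty[edges$to])
  structure(list(nodes = nodes, edges = edges, source = source,
                 target = target, types = ty), class = "metagraph")
}

#' Default diamond metagraph
#'
#' The union of the metapaths lncRNA-disease-lncRNA and
#' lncRNA-disease-disease-lncRNA: schema nodes `L1 -> D1 -> L2` and
#' `D1 -> D2 -> L2`, source `L1`, target `L2`. The branch at `D1` is what
#' makes it a genuine metagraph rather than a metapath.
#'
#' @return A [metagraph()].
#' @export
default_metagraph <- function() {
  metagraph(
    nodes = data.frame(name = c("L1", "D1", "D2", "L2"),
                       type = c("lncRNA", "disease", "disease", "lncRNA")),
    edges = data.frame(from = c("L1", "D1", "D1", "D2"),
                       to   = c("D1", "L2", "D2", "L2")),
    source = "L1", target = "L2")
}

#' Read a metagraph schema file
#'
#' Line-oriented key-value format: `node <name> <type>`,
#' `edge <from> <to>`, `source <name>`, `target <name>`; `#` comments.
#'
#' @param path schema file path.
#' @return A [metagraph()].
#' @export
read_metagraph <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  tok <- strsplit(ln, "[[:space:]]+")
  key <- vapply(tok, `[[`, character(1), 1)
  get2 <- function(k, i) vapply(tok[key == k], `[[`, character(1), i)
  metagraph(nodes = data.frame(name = get2("node", 2),
                               type = get2("node", 3)),
            edges = data.frame(from = get2("edge", 2), to = get2("edge", 3)),
            source = get2("source", 2)[1], target = get2("target", 2)[1])
}

# Effective schema position under the recursive unrolling: reaching the
# target wraps back to the source (they share a node type).
mg_wrap <- function(mg, pos) if (pos == mg$target) mg$source else pos

# Outgoing schema edges from a position, after wrapping.
mg_out_edges <- function(mg, pos) {
  pos <- mg_wrap(mg, pos)
  mg$edges[mg$edges$from == pos, , drop = FALSE]
}

#' Edge types legal at a walk state
#'
#' Returns the edge types of outgoing schema edges at the current metagraph
#' position that have at least one realization among `v`'s neighbours; the
#' size of this set is the `NUM` factor of the two-stage transition rule.
#'
#' @param mg a [metagraph()].
#' @param pos current schema node name.
#' @param v current network node id.
#' @param G a [build_network()] result.
#' @return Character vector of edge types (possibly empty).
#' @export
legal_edge_types <- function(mg, pos, v, G) {
  out <- mg_out_edges(mg, pos)
  ets <- unique(out$edge_type)
  ets[vapply(ets, function(et) length(G$adj[[v]][[et]] %||% character(0)) > 0,
             logical(1))]
}

#' Exact transition distribution of one metagraph-guided step
#'
#' Probability of each neighbour as the next node: a legal edge type is
#' chosen uniformly (probability `1/NUM`), then a neighbour uniformly among
#' those reachable by that type, so a neighbour's probability is the product
#' of the two uniform factors.
#'
#' @inheritParams legal_edge_types
#' @return Named numeric vector of next-node probabilities (empty when the
#'   walk terminates at this state).
#' @export
transition_probs <- function(mg, pos, v, G) {
  ets <- legal_edge_types(mg, pos, v, G)
  if (!length(ets)) return(stats::setNames(numeric(0), character(0)))
  p <- numeric(0)
  for (et in ets) {
    nb <- G$adj[[v]][[et]]
    q <- rep(1 / (length(ets) * length(nb)), length(nb))
    names(q) <- nb
    p <- c(p, q)
  }
  # a neighbour reachable via two edge types accumulates both contributions
  tapply(p, names(p), sum)[unique(names(p))]
}

#' One metagraph-guided walk step
#'
#' Two-stage uniform sampling: edge type, then neighbour of that type. The
#' schema position advances along the chosen schema edge (the first
#' outgoing schema edge of the chosen type, in declaration order) and wraps
#' to the source upon reaching the target. Returns `NULL` when no legal
#' edge type remains (the walk terminates).
#'
#' @inheritParams legal_edge_types
#' @return `list(node, pos)` or `NULL` on termination.
#' @export
walk_step <- function(mg, pos, v, G) {
  ets <- legal_edge_types(mg, pos, v, G)
  if (!length(ets)) return(NULL)
  et <- if (length(ets) == 1) ets else ets[sample.int(length(ets), 1)]
  nb <- G$adj[[v]][[et]]
  v2 <- if (length(nb) == 1) nb else nb[sample.int(length(nb), 1)]
  out <- mg_out_edges(mg, pos)
  pos2 <- out$to[out$edge_type == et][1]
  list(node = v2, pos = mg_wrap(mg, pos2))
}

#' Generate a metagraph-guided walk corpus
#'
#' Launches `walks_per_node` walks of maximum length `L` from every network
#' node whose type matches the schema source type. Walks may terminate
#' early when no schema-legal edge type has a realization.
#'
#' @param G a [build_network()] result.
#' @param mg a [metagraph()]; default [default_metagraph()].
#' @param walks_per_node walks started per source-type node (default 10).
#' @param L maximum walk length in nodes (default 80).
#' @param seed RNG seed; corpora are reproducible given the seed.
#' @return A `walk_corpus`: list of character vectors of node ids, with
#'   `start` and `seed` attributes.
#' @export
generate_corpus <- function(G, mg = default_metagraph(), walks_per_node = 10,
                            L = 80, seed = 1) {
  stopifnot(walks_per_node >= 1, L >= 2)
  src_type <- mg$types[[mg$source]]
  starts <- G$nodes$id[G$nodes$type == src_type]
  if (!length(starts)) stop("no node of the schema source type")
  walks <- with_seed(seed, {
    out <- vector("list", length(starts) * walks_per_node)
    k <- 0L
    for (r in seq_len(walks_per_node)) {
      for (v0 in starts) {
        w <- character(L); w[1] <- v0
        pos <- mg_wrap(mg, mg$source)
        v <- v0; len <- 1L
        while (len < L) {
          st <- walk_step(mg, pos, v, G)
          if (is.null(st)) break
          len <- len + 1L
          w[len] <- st$node
          v <- st$node; pos <- st$pos
        }
        k <- k + 1L
        out[[k]] <- w[seq_len(len)]
      }
    }
    out
  })
  structure(walks, class = "walk_corpus",
            start = rep(starts, walks_per_node), seed = seed)
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat(sprintf("walk_corpus: %d walks, lengths %d-%d (seed %s)\n",
              length(x), min(lengths(x)), max(lengths(x)),
              format(attr(x, "seed"))))
  invisible(x)
}

#' Write a walk corpus in word2vec corpus convention
#'
#' One walk per line, whitespace-separated node ids.
#'
#' @param corpus a [generate_corpus()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(vapply(corpus, paste, character(1), collapse = " "), path)
  invisible(path)
}
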
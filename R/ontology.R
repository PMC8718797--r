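#' Disease ancestor DAGs from a child-to-parent edge list
#'
#' The disease ontology is encoded as one global directed graph with edges
#' pointing from a disease to its parent (more general) term. Each disease's
#' own DAG is its ancestor closure `Z(i)`: the disease plus everything
#' reachable through parent edges. The graph must be acyclic.
#'
#' @param edges data frame (or 2-column matrix) of `child`, `parent` ids.
#' @param diseases optional character vector of diseases that must be
#'   covered; ids absent from `edges` get the trivial one-node DAG.
#' @return A `disease_dag_set`: list with `parents` (named list of parent
#'   ids per node) and `nodes`.
#' @export
disease_dag_set <- function(edges, diseases = NULL) {
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- data.frame(child = character(0), parent = character(0))
  } else {
    edges <- as.data.frame(edges)[, 1:2]
    names(edges) <- c("child", "parent")
    edges$child <- as.character(edges$child)
    edges$parent <- as.character(edges$parent)
    edges <- unique(edges)
    if (any(edges$child == edges$parent))
      stop("self-loop in ontology (cycle detected)")
  }
  nodes <- unique(c(edges$child, edges$parent, as.character(diseases)))
  parents <- split(edges$parent, factor(edges$child, levels = nodes))
  # Kahn topological check over child -> parent edges
  indeg <- lengths(split(edges$child, factor(edges$parent, levels = nodes)))
  children <- split(edges$child, factor(edges$parent, levels = nodes))
  outdeg <- lengths(parents)
  queue <- nodes[outdeg == 0]
  seen <- 0L
  remaining <- outdeg
  while (length(queue)) {
    u <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in children[[u]]) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(nodes)) stop("cycle detected in ontology graph")
  structure(list(parents = parents, nodes = nodes),
            class = "disease_dag_set")
}

#' Read a child-to-parent ontology edge list (TSV)
#'
#' @param path TSV file with columns `child_id<TAB>parent_id`, header
#'   optional.
#' @param diseases optional disease universe passed to [disease_dag_set()].
#' @return A [disease_dag_set()].
#' @export
read_ontology <- function(path, diseases = NULL) {
  df <- tryCatch(read.delim(path, header = FALSE, colClasses = "character"),
                 error = function(e) data.frame())
  if (nrow(df) && grepl("child|dis", df[1, 1], ignore.case = TRUE) &&
      grepl("parent|anc", df[1, 2], ignore.case = TRUE))
    df <- df[-1, , drop = FALSE]
  disease_dag_set(df, diseases)
}

#' Write an ontology edge list as TSV
#'
#' @param dags a [disease_dag_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(dags, path) {
  child <- rep(names(dags$parents), lengths(dags$parents))
  df <- data.frame(child_id = child, parent_id = unlist(dags$parents,
                                                        use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Ancestor closure Z(i) with hop distance from the disease itself.
ancestor_closure <- function(dags, disease) {
  if (!disease %in% dags$nodes)
    stop("disease DAG missing for: ", disease)
  dist <- c(0L); names(dist) <- disease
  frontier <- disease
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(dags$parents[intersect(frontier,
                                                names(dags$parents))],
                         use.names = FALSE))
    nxt <- setdiff(nxt, names(dist))
    if (length(nxt)) {
      dd <- rep(d, length(nxt)); names(dd) <- nxt
      dist <- c(dist, dd)
    }
    frontier <- nxt
  }
  dist
}

#' Semantic contribution of each ancestor of a disease
#'
#' The contribution of a disease to its own semantic value is 1; each
#' ancestor `u` contributes `delta` times the maximum contribution among the
#' DAG nodes one step closer to the disease (the children of `u` on paths
#' from the disease). Evaluated by dynamic programming outward from the
#' disease, this equals `delta ^ h` where `h` is the shortest hop distance
#' from the disease to `u` along parent edges, so contributions decay with
#' ontological distance.
#'
#' @param dags a [disease_dag_set()].
#' @param disease disease id.
#' @param delta semantic contribution decay factor in (0, 1); default 0.5.
#' @return Named numeric vector: contribution per node of `Z(i)`, value 1
#'   for the disease itself.
#' @export
compute_contributions <- function(dags, disease, delta = 0.5) {
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0 || delta >= 1)
    stop("delta must lie strictly between 0 and 1")
  dist <- ancestor_closure(dags, disease)
  stats::setNames(delta ^ as.numeric(dist), names(dist))
}

#' Semantic value of a disease
#'
#' Sum of the contributions over the disease's ancestor closure; at least 1
#' because the disease contributes 1 to itself.
#'
#' @param cmap named contribution vector from [compute_contributions()].
#' @return Numeric scalar `>= 1`.
#' @export
semantic_value <- function(cmap) {
  if (!length(cmap)) stop("empty contribution map")
  sum(cmap)
}

#' Disease semantic similarity matrix (SSD)
#'
#' Two diseases are semantically similar in proportion to the contribution
#' mass their ancestor closures share:
#' `SSD(i, j) = sum_{u in Z(i) and Z(j)} (C_i(u) + C_j(u)) / (C(i) + C(j))`.
#' The diagonal is exactly 1 and disjoint DAGs score 0.
#'
#' @param dags a [disease_dag_set()].
#' @param diseases character vector of disease ids (row/column order).
#' @param delta decay factor, see [compute_contributions()].
#' @return A [similarity_matrix()] with role `"SSD"`.
#' @export
disease_semantic_similarity <- function(dags, diseases, delta = 0.5) {
  diseases <- as.character(diseases)
  missing <- setdiff(diseases, dags$nodes)
  if (length(missing))
    stop("disease DAG missing for: ", paste(missing, collapse = ", "))
  cmaps <- lapply(diseases, compute_contributions, dags = dags,
                  delta = delta)
  names(cmaps) <- diseases
  cvals <- vapply(cmaps, semantic_value, numeric(1))
  univ <- unique(unlist(lapply(cmaps, names), use.names = FALSE))
  # M[i, u] = C_i(u) on the common node universe; 0 outside Z(i).
  M <- matrix(0, length(diseases), length(univ),
              dimnames = list(diseases, univ))
  for (i in seq_along(diseases))
    M[i, names(cmaps[[i]])] <- cmaps[[i]]
  Ind <- (M > 0) + 0
  # sum over shared u of C_i(u) + C_j(u)  =  M_i . I_j + I_i . M_j
  num <- M %*% t(Ind)
  num <- num + t(num)
  ssd <- num / outer(cvals, cvals, `+`)
  diag(ssd) <- 1
  similarity_matrix(ssd, role = "SSD")
}
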
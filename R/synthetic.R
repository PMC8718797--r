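#' Planted-block synthetic world
#'
#' Describes a synthetic lncRNA-disease system with community structure:
#' lncRNAs and diseases are split into `B` communities; a pair inside one
#' community associates with probability `p_in`, across communities with
#' `p_out < p_in`. A fraction of the sampled associations is held out as
#' recoverable ground truth, and a shallow disease ancestor forest (most
#' parents drawn from the same community) gives the ontology the block
#' structure that makes semantic similarity informative. Defaults mirror a
#' curated lncRNA-disease catalogue of 112 lncRNAs x 150 diseases.
#'
#' @param nl,nd numbers of lncRNAs and diseases (defaults 112, 150).
#' @param B communities (default 4).
#' @param p_in,p_out within/between-community association probabilities
#'   (defaults 0.3, 0.02).
#' @param holdout fraction of associations held out as truth (default
#'   0.2).
#' @param max_parents per-disease parent cap in the ancestor forest
#'   (default 3).
#' @param same_community_bias probability a parent is drawn from the same
#'   community (default 0.8).
#' @param max_depth ancestor forest depth cap (default 4).
#' @param seed RNG seed.
#' @return A `planted_world` parameter object.
#' @export
planted_world <- function(nl = 112, nd = 150, B = 4, p_in = 0.3,
                          p_out = 0.02, holdout = 0.2, max_parents = 3,
                          same_community_bias = 0.8, max_depth = 4,
                          seed = 1) {
  stopifnot(nl >= 2 * B, nd >= 2 * B, p_out >= 0, p_out < p_in, p_in <= 1,
            holdout >= 0, holdout < 1)
  structure(list(nl = nl, nd = nd, B = B, p_in = p_in, p_out = p_out,
                 holdout = holdout, max_parents = max_parents,
                 same_community_bias = same_community_bias,
                 max_depth = max_depth, seed = seed),
            class = "planted_world")
}

#' Sample a dataset from a planted world
#'
#' Draws the binary association matrix from the block model, removes the
#' held-out fraction of its 1-entries (the recoverable truth), and builds
#' the disease ancestor forest: in a random topological order each disease
#' picks 0-3 parents among earlier diseases of depth below the cap, mostly
#' from its own community (parent count probabilities 0.15 / 0.6 / 0.2 /
#' 0.05 - most ontology terms have one parent). Deterministic given the
#' seed; if sampling leaves no positive association the seed is
#' incremented and the draw repeated (at most 10 times).
#'
#' @param world a [planted_world()].
#' @return List: `A` (training [association_matrix()] after holdout),
#'   `dags` ([disease_dag_set()]), `truth` (held-out positive pairs),
#'   `communities` (list `lncRNA`, `disease`), `world`.
#' @export
generate_planted_data <- function(world) {
  stopifnot(inherits(world, "planted_world"))
  for (try in 0:9) {
    out <- with_seed(world$seed + try, sample_world(world))
    if (sum(out$A) > 0) return(out)
  }
  stop("no positive association after 10 attempts; raise p_in")
}

sample_world <- function(world) {
  lnc <- sprintf("l%03d", seq_len(world$nl))
  dis <- sprintf("d%03d", seq_len(world$nd))
  cl <- rep_len(seq_len(world$B), world$nl)
  cd <- rep_len(seq_len(world$B), world$nd)
  P <- matrix(world$p_out, world$nl, world$nd)
  P[outer(cl, cd, `==`)] <- world$p_in
  Afull <- matrix(rbinom(length(P), 1L, P), world$nl, world$nd,
                  dimnames = list(lnc, dis))
  ones <- which(Afull == 1L)
  nh <- floor(world$holdout * length(ones))
  held <- if (nh > 0) sort(ones[sample.int(length(ones), nh)]) else integer(0)
  A <- Afull
  A[held] <- 0L
  truth <- data.frame(
    lncRNA_id = lnc[(held - 1) %% world$nl + 1],
    disease_id = dis[(held - 1) %/% world$nl + 1])

  # ancestor forest over a random topological order of the diseases
  ord <- sample.int(world$nd)
  depth <- rep(1L, world$nd)
  edges <- list()
  for (pos in seq_along(ord)) {
    if (pos == 1) next
    d <- ord[pos]
    np <- sample(0:3, 1, prob = c(0.15, 0.6, 0.2, 0.05))
    np <- min(np, world$max_parents, pos - 1)
    if (np == 0) next
    earlier <- ord[seq_len(pos - 1)]
    eligible <- earlier[depth[earlier] < world$max_depth]
    if (!length(eligible)) next
    same <- eligible[cd[eligible] == cd[d]]
    picked <- integer(0)
    for (s in seq_len(np)) {
      pool <- if (length(same) && runif(1) < world$same_community_bias)
        setdiff(same, picked) else setdiff(eligible, picked)
      if (!length(pool)) pool <- setdiff(eligible, picked)
      if (!length(pool)) break
      picked <- c(picked, pool[sample.int(length(pool), 1)])
    }
    if (length(picked)) {
      edges[[length(edges) + 1]] <-
        data.frame(child = dis[d], parent = dis[picked])
      depth[d] <- max(depth[picked]) + 1L
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(child = character(0), parent = character(0))
  list(A = association_matrix(A),
       dags = disease_dag_set(edges, diseases = dis),
       truth = truth,
       communities = list(lncRNA = stats::setNames(cl, lnc),
                          disease = stats::setNames(cd, dis)),
       world = world)
}

#' Write a generated world in the pipeline's input formats
#'
#' Emits the association TSV, ontology TSV and a truth TSV of the
#' held-out pairs.
#'
#' @param data a [generate_planted_data()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the three paths.
#' @export
write_planted_data <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(associations = file.path(dir, "associations.tsv"),
             ontology = file.path(dir, "ontology.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_associations(data$A, paths[["associations"]])
  write_ontology(data$dags, paths[["ontology"]])
  write.table(data$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}
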
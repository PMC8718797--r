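# Small fully-specified network used throughout: path graph L1 - D1 - L2
# (one association each) with identity similarity -> no LL/DD edges.
path_network <- function() {
  A <- suppressWarnings(association_matrix(
    matrix(c(1L, 1L), 2, 1, dimnames = list(c("L1x", "L2x"), "D1x"))))
  SL <- similarity_matrix(diag(2), role = "SL", ids = rownames(A))
  SD <- similarity_matrix(matrix(1, 1, 1), role = "SD", ids = "D1x")
  build_network(SL, SD, A)
}

test_that("the heterogeneous network assembles blockwise with typed edges", {
  A <- tiny_assoc()
  SL <- similarity_matrix(diag(4), role = "SL", ids = rownames(A))
  SD <- similarity_matrix(diag(5), role = "SD", ids = colnames(A))
  G <- build_network(SL, SD, A, top_k = 2)
  # U = [[SL, A], [A^T, SD]] with dimension (nl + nd)^2
  expect_equal(dim(G$U), c(9, 9))
  expect_equal(G$U[1:4, 5:9], unclass(A), ignore_attr = TRUE)
  expect_equal(G$U[5:9, 1:4], t(unclass(A)), ignore_attr = TRUE)
  # identity similarity: no LL/DD walkable edges, LD/DL exactly the 1s
  expect_true(all(vapply(rownames(A), function(l)
    length(G$adj[[l]]$LL) == 0, logical(1))))
  expect_equal(G$adj[["L1"]]$LD, c("D1", "D2"))
  expect_equal(G$adj[["D2"]]$DL, c("L1", "L2"))
  # LD and DL are transposes of each other
  ld <- unlist(lapply(rownames(A), function(l)
    paste(rep(l, length(G$adj[[l]]$LD)), G$adj[[l]]$LD)), use.names = FALSE)
  dl <- unlist(lapply(colnames(A), function(d)
    paste(G$adj[[d]]$DL, rep(d, length(G$adj[[d]]$DL)))), use.names = FALSE)
  expect_setequal(ld, dl)
  expect_error(build_network(SL, SD, t(unclass(A))), "mismatch")
})

test_that("top_k sparsification keeps argmax neighbours, symmetrized", {
  ids <- c("a", "b", "c")
  S <- matrix(c(1, 0.9, 0.2, 0.9, 1, 0.1, 0.2, 0.1, 1), 3, 3,
              dimnames = list(ids, ids))
  SL <- similarity_matrix(S, role = "SL")
  A <- suppressWarnings(association_matrix(
    matrix(c(1L, 0L, 0L), 3, 1, dimnames = list(ids, "d1"))))
  SD <- similarity_matrix(matrix(1, 1, 1), role = "SD", ids = "d1")
  G <- build_network(SL, SD, A, top_k = 1)
  # argmax pairs: a<->b (0.9); c's best is a (0.2), symmetrized into a
  expect_setequal(G$adj[["a"]]$LL, c("b", "c"))
  expect_equal(G$adj[["b"]]$LL, "a")
  expect_equal(G$adj[["c"]]$LL, "a")
  # top_k = n-1 with strictly positive similarity: complete graph
  Sp <- similarity_matrix(matrix(pmax(S, 0.05), 3, 3,
                                 dimnames = list(ids, ids)), role = "SL")
  Gp <- build_network(Sp, SD, A, top_k = 2)
  expect_true(all(vapply(ids, function(i)
    length(Gp$adj[[i]]$LL) == 2, logical(1))))
})

test_that("legal edge types respect the schema and the realized edges", {
  G <- path_network()
  mg <- default_metagraph()
  # from the source position an lncRNA may only leave via LD here
  expect_equal(legal_edge_types(mg, "L1", "L1x", G), "LD")
  # at D1 the schema allows DL and DD; only DL is realized
  expect_equal(legal_edge_types(mg, "D1", "D1x", G), "DL")
  # an isolated node has no legal type
  A <- suppressWarnings(association_matrix(
    matrix(c(1L, 0L), 2, 1, dimnames = list(c("La", "Lb"), "Da"))))
  SL <- similarity_matrix(diag(2), role = "SL", ids = rownames(A))
  SD <- similarity_matrix(matrix(1, 1, 1), role = "SD", ids = "Da")
  G2 <- build_network(SL, SD, A)
  expect_length(legal_edge_types(mg, "L1", "Lb", G2), 0)
})

test_that("transition probabilities are the two-stage uniform product", {
  # 2 legal edge types, chosen type with several neighbours -> 1/(2 * n_t)
  A <- suppressWarnings(association_matrix(
    matrix(c(1L, 1L, 1L, 0L, 0L, 0L), 3, 2,
           dimnames = list(c("u", "v", "w"), c("p", "q")))))
  S <- matrix(0.5, 3, 3, dimnames = list(rownames(A), rownames(A)))
  diag(S) <- 1
  SL <- similarity_matrix(S, role = "SL")
  SD <- similarity_matrix(diag(2), role = "SD", ids = colnames(A))
  G <- build_network(SL, SD, A)
  # schema: after one step we sit at D1 wrapped... use source position L1:
  # u has LL neighbours {v, w} and LD neighbour {p}: NUM = 2
  pr <- transition_probs(metagraph(
    nodes = data.frame(name = c("L1", "D1", "L2"),
                       type = c("lncRNA", "disease", "lncRNA")),
    edges = data.frame(from = c("L1", "L1", "D1"),
                       to = c("D1", "L2", "L2")),
    source = "L1", target = "L2"), "L1", "u", G)
  expect_equal(pr[["p"]], 1 / 2)          # 1/NUM x 1/1
  expect_equal(pr[["v"]], 1 / 4)          # 1/NUM x 1/2
  expect_equal(sum(pr), 1)
})

test_that("exact transitions match the brute-force oracle everywhere", {
  set.seed(21)
  mg <- default_metagraph()
  for (rep in 1:10) {
    nl <- sample(2:5, 1); nd <- sample(2:5, 1)
    A <- suppressWarnings(association_matrix(
      matrix(rbinom(nl * nd, 1, 0.5), nl, nd,
             dimnames = list(paste0("l", seq_len(nl)),
                             paste0("d", seq_len(nd))))))
    SLv <- matrix(runif(nl * nl), nl, nl); SLv <- (SLv + t(SLv)) / 2
    diag(SLv) <- 1
    SDv <- matrix(runif(nd * nd), nd, nd); SDv <- (SDv + t(SDv)) / 2
    diag(SDv) <- 1
    G <- build_network(similarity_matrix(SLv, "SL", rownames(A)),
                       similarity_matrix(SDv, "SD", colnames(A)),
                       A, top_k = 2)
    for (pos in mg$nodes$name) {
      vs <- G$nodes$id[G$nodes$type == mg$types[[pos]]]
      for (v in vs) {
        got <- transition_probs(mg, pos, v, G)
        want <- oracle_transition(G, mg, pos, v)
        expect_equal(length(got), length(want))
        if (length(want)) {
          expect_setequal(names(got), names(want))
          expect_equal(as.numeric(got[names(want)]), as.numeric(want))
          expect_equal(sum(got), 1)
        }
      }
    }
  }
})

test_that("sampled steps follow the exact distribution (3 SE)", {
  A <- suppressWarnings(association_matrix(
    matrix(c(1L, 1L, 1L, 0L, 0L, 0L), 3, 2,
           dimnames = list(c("u", "v", "w"), c("p", "q")))))
  S <- matrix(0.5, 3, 3, dimnames = list(rownames(A), rownames(A)))
  diag(S) <- 1
  G <- build_network(similarity_matrix(S, "SL"),
                     similarity_matrix(diag(2), "SD", colnames(A)), A)
  mg <- default_metagraph()
  pr <- transition_probs(mg, "L1", "u", G)
  n <- 2e5
  set.seed(99)
  draws <- vapply(seq_len(n), function(i)
    walk_step(mg, "L1", "u", G)$node, character(1))
  freq <- table(factor(draws, levels = names(pr))) / n
  for (nm in names(pr)) {
    se <- sqrt(pr[[nm]] * (1 - pr[[nm]]) / n)
    expect_lt(abs(freq[[nm]] - pr[[nm]]), 3 * se + 1e-12)
  }
})

test_that("walk corpora type-check, respect counts, and are reproducible", {
  G <- path_network()
  mg <- default_metagraph()
  corpus <- generate_corpus(G, mg, walks_per_node = 10, L = 3, seed = 4)
  expect_length(corpus, 20)               # 2 source nodes x 10
  # on the path graph every walk is the legal alternation L - D - L
  for (w in corpus) {
    expect_lte(length(w), 3)
    types <- ifelse(startsWith(w, "L"), "lncRNA", "disease")
    expect_true(all(types == rep(c("lncRNA", "disease"),
                                 length.out = length(w))))
  }
  # determinism
  corpus2 <- generate_corpus(G, mg, walks_per_node = 10, L = 3, seed = 4)
  expect_identical(unclass(corpus), unclass(corpus2))
  expect_error(generate_corpus(G, metagraph(
    nodes = data.frame(name = c("D1", "D2"),
                       type = c("disease", "disease")),
    edges = data.frame(from = "D1", to = "D2"),
    source = "D1", target = "D2"),
    walks_per_node = 1, L = 2, seed = 1), NA)
})

test_that("every corpus step uses a schema-legal realized edge", {
  set.seed(31)
  A <- suppressWarnings(association_matrix(
    matrix(rbinom(30, 1, 0.4), 5, 6,
           dimnames = list(paste0("l", 1:5), paste0("d", 1:6)))))
  SLv <- matrix(runif(25), 5, 5); SLv <- (SLv + t(SLv)) / 2; diag(SLv) <- 1
  SDv <- matrix(runif(36), 6, 6); SDv <- (SDv + t(SDv)) / 2; diag(SDv) <- 1
  G <- build_network(similarity_matrix(SLv, "SL", rownames(A)),
                     similarity_matrix(SDv, "SD", colnames(A)), A,
                     top_k = 2)
  mg <- default_metagraph()
  corpus <- generate_corpus(G, mg, walks_per_node = 3, L = 12, seed = 8)
  ty <- node_types(G)
  for (w in corpus) {
    if (length(w) < 2) next
    for (i in seq_len(length(w) - 1)) {
      et <- paste0(ifelse(ty[[w[i]]] == "lncRNA", "L", "D"),
                   ifelse(ty[[w[i + 1]]] == "lncRNA", "L", "D"))
      # edge must exist in the typed adjacency
      expect_true(w[i + 1] %in% G$adj[[w[i]]][[et]],
                  info = paste(w[i], "->", w[i + 1], et))
    }
  }
})
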
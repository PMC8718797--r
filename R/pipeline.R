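PIPELINE_DEFAULTS <- list(
  delta = 0.5,            # semantic contribution decay per ontology level
  gip_bandwidth_l = 1,    # base kernel bandwidth, lncRNA profiles
  gip_bandwidth_d = 1,    # base kernel bandwidth, disease profiles
  top_k = 10,             # similarity neighbours kept per node
  walks_per_node = 10,
  walk_length = 80,
  dim = 64,               # embedding dimension
  window = 5,
  negative = 5,           # negative samples per context pair
  epochs = 5,
  lambda = 0.025,         # initial skip-gram learning rate
  lambda_min = 1e-4,
  noise = "unigram75",
  kmeans_k = 10,
  kmeans_restarts = 10,
  kmeans_max_iter = 300,
  allocation = "proportional",
  combine = "hadamard",   # pair features from embeddings
  n_trees = 100,
  max_depth = 3,
  alpha = 0.1,            # boosting shrinkage
  min_leaf = 5,
  l2 = 1e-4,
  lr_steps = 2000,
  folds = 10,
  stratified = TRUE,
  seed = 1
)

#' Pipeline configuration with validated defaults
#'
#' All tunables of the pipeline in one validated list; unknown keys are
#' rejected. Defaults: semantic decay 0.5, unit base kernel bandwidths,
#' k = 10 clusters for negative selection, 5 negative samples per context
#' pair, 10 similarity neighbours per node, walks 10 x 80, embedding
#' dimension 64, window 5, 100 depth-3 trees with shrinkage 0.1, 10-fold
#' evaluation.
#'
#' @param ... name = value overrides of the defaults.
#' @return A `pipeline_config` (named list).
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("config overrides must be named")
  unknown <- setdiff(names(over), names(PIPELINE_DEFAULTS))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, over)
  stopifnot(cfg$delta > 0, cfg$delta < 1, cfg$gip_bandwidth_l > 0,
            cfg$gip_bandwidth_d > 0, cfg$top_k >= 1,
            cfg$walks_per_node >= 1, cfg$walk_length >= 2, cfg$dim >= 2,
            cfg$window >= 1, cfg$negative >= 1, cfg$epochs >= 1,
            cfg$lambda > 0, cfg$kmeans_k >= 1, cfg$n_trees >= 1,
            cfg$max_depth >= 1, cfg$alpha > 0, cfg$min_leaf >= 1,
            cfg$folds >= 2)
  cfg$noise <- match.arg(cfg$noise, c("unigram75", "uniform"))
  cfg$allocation <- match.arg(cfg$allocation, c("proportional", "equal"))
  cfg$combine <- match.arg(cfg$combine, c("hadamard", "concat"))
  structure(cfg, class = "pipeline_config")
}

#' Read a key: value configuration file
#'
#' One `key: value` per line, `#` comments; values are parsed as numbers
#' or logicals where possible. Keys must be known configuration keys.
#'
#' @param path config file.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  kv <- regmatches(ln, regexec("^([^:]+):[[:space:]]*(.*)$", ln))
  if (any(lengths(kv) != 3)) stop("malformed config line")
  vals <- lapply(kv, function(m) {
    v <- m[3]
    if (grepl("^(TRUE|FALSE)$", v)) as.logical(v)
    else if (grepl("^-?[0-9.eE+-]+$", v)) as.numeric(v)
    else v
  })
  names(vals) <- trimws(vapply(kv, `[[`, character(1), 2))
  do.call(pipeline_config, vals)
}

#' Write a resolved configuration (all defaults materialized)
#'
#' @param cfg a [pipeline_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  writeLines(sprintf("%s: %s", names(cfg),
                     vapply(cfg, function(v) format(v, digits = 17),
                            character(1))), path)
  invisible(path)
}

#' Run the full association-prediction pipeline
#'
#' Executes the six stages in order: deduplicated association matrix;
#' disease semantic and lncRNA functional similarity; interaction-profile
#' kernels; fused SL / SD networks; heterogeneous network, metagraph
#' walks and skip-gram embeddings; K-means selection of balanced
#' negatives; GBDT-to-LR training with cross-validated metrics; and a
#' ranked score for every unknown pair. Per-stage seeds are derived from
#' `config$seed`, so a rerun with the same inputs and seed reproduces the
#' prediction table exactly.
#'
#' @param associations an [association_matrix()] or path to an
#'   association TSV.
#' @param ontology a [disease_dag_set()] or path to a child-parent TSV.
#' @param config a [pipeline_config()].
#' @param mg walk schema (default [default_metagraph()]).
#' @param outdir optional output directory; when given, the resolved
#'   config, seeds, similarity matrices, embeddings, training set, model,
#'   CV report and ranked predictions are written there.
#' @param verbose log each stage (default TRUE).
#' @return List: `A`, `similarities` (SL, SD, SSD, FSL, GSL, GSD),
#'   `network`, `corpus`, `embeddings`, `kmeans`, `training_set`,
#'   `model`, `cv`, `predictions` (ranked unknown pairs), `config`,
#'   `seeds`.
#' @export
run_pipeline <- function(associations, ontology,
                         config = pipeline_config(),
                         mg = default_metagraph(), outdir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- vapply(c(walk = 1L, embed = 2L, kmeans = 3L, negatives = 4L,
                    cv = 5L), function(i) derive_seed(config$seed, i),
                  integer(1))
  A <- if (is.character(associations)) read_associations(associations)
       else associations
  dags <- if (is.character(ontology))
    read_ontology(ontology, diseases = colnames(A)) else ontology
  stage_log("associations", sprintf("%d lncRNAs x %d diseases, %d positives",
                                    nrow(A), ncol(A), sum(A)),
            verbose = verbose)

  SSD <- disease_semantic_similarity(dags, colnames(A), delta = config$delta)
  FSL <- lncrna_functional_similarity(A, SSD)
  GSL <- gip_similarity(A, "lncRNA", config$gip_bandwidth_l)
  GSD <- gip_similarity(A, "disease", config$gip_bandwidth_d)
  SL <- fuse(FSL, GSL)
  SD <- fuse(SSD, GSD)
  stage_log("similarity", "SSD/FSL/GSL/GSD computed and fused into SL/SD",
            verbose = verbose)

  G <- build_network(SL, SD, A, top_k = config$top_k)
  corpus <- generate_corpus(G, mg, walks_per_node = config$walks_per_node,
                            L = config$walk_length, seed = seeds[["walk"]])
  stage_log("walks", sprintf("%d walks (max length %d)", length(corpus),
                             config$walk_length), verbose = verbose)
  emb <- train_embeddings(corpus, node_types(G), d = config$dim,
                          b = config$window, U = config$negative,
                          epochs = config$epochs, lambda = config$lambda,
                          lambda_min = config$lambda_min,
                          noise = config$noise, seed = seeds[["embed"]])
  stage_log("embedding", sprintf("d=%d, final epoch loss %.4f", config$dim,
                                 tail(attr(emb, "epoch_loss"), 1)),
            verbose = verbose)

  unk <- unknown_pairs(A)
  feats_unk <- build_pair_features(SL, SD, A, unk)
  km <- kmeans_cluster(feats_unk, k = config$kmeans_k,
                       seed = seeds[["kmeans"]],
                       max_iter = config$kmeans_max_iter,
                       restarts = config$kmeans_restarts)
  negs <- select_negatives(km, unk, n_needed = sum(A),
                           seed = seeds[["negatives"]],
                           allocation = config$allocation)
  train_set <- assemble_training_set(A, negs)
  stage_log("sampling", sprintf("%d unknown pairs in %d clusters; %d negatives selected",
                                nrow(unk), config$kmeans_k, nrow(negs)),
            verbose = verbose)

  Xtrain <- embedding_pair_features(emb, train_set[, 1:2],
                                    combine = config$combine)
  cv <- cross_validate(Xtrain, train_set$label, folds = config$folds,
                       seed = seeds[["cv"]], stratified = config$stratified,
                       n_trees = config$n_trees, alpha = config$alpha,
                       max_depth = config$max_depth,
                       min_leaf = config$min_leaf, l2 = config$l2,
                       max_steps = config$lr_steps)
  stage_log("cv", sprintf("%d-fold mean AUC %.3f ACC %.3f", config$folds,
                          cv$mean[["AUC"]], cv$mean[["ACC"]]),
            verbose = verbose)

  model <- gbdt_lr_fit(Xtrain, train_set$label, n_trees = config$n_trees,
                       alpha = config$alpha, max_depth = config$max_depth,
                       min_leaf = config$min_leaf, l2 = config$l2,
                       max_steps = config$lr_steps)
  Xunk <- embedding_pair_features(emb, unk, combine = config$combine)
  preds <- data.frame(unk, score = predict(model, Xunk))
  preds <- preds[order(-preds$score, preds$lncRNA_id, preds$disease_id), ]
  rownames(preds) <- NULL
  stage_log("predict", sprintf("%d candidate pairs scored", nrow(preds)),
            verbose = verbose)

  res <- list(A = A,
              similarities = list(SL = SL, SD = SD, SSD = SSD, FSL = FSL,
                                  GSL = GSL, GSD = GSD),
              network = G, corpus = corpus, embeddings = emb, kmeans = km,
              training_set = train_set, model = model, cv = cv,
              predictions = preds, config = config, seeds = seeds)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_config(res$config, file.path(outdir, "config.resolved"))
  writeLines(sprintf("%s: %d", names(res$seeds), res$seeds),
             file.path(outdir, "seeds"))
  for (nm in names(res$similarities))
    write_matrix_tsv(res$similarities[[nm]],
                     file.path(outdir, paste0(nm, ".tsv")))
  write_embeddings(res$embeddings, file.path(outdir, "embeddings.w2v"))
  write.table(res$training_set, file.path(outdir, "training_set.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_gbdt_lr(res$model, file.path(outdir, "model.json"))
  write_cv_report(res$cv, file.path(outdir, "cv_metrics.tsv"))
  write.table(res$predictions, file.path(outdir, "predictions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
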
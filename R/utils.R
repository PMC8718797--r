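#' @useDynLib lncDNet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rbinom optimize cor quantile median approx
#' @importFrom utils read.delim write.table head tail modifyList
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never disturbs user RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Derive a per-stage sub-seed from a master seed; result stays in [1, 2^31).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- (as.double(seed) * 48271 + stage * 16807) %% 2147483647
  as.integer(h) + 1L
}

stage_log <- function(stage, ..., verbose = TRUE) {
  if (isTRUE(verbose))
    message(sprintf("[%s] %s | %s", format(Sys.time(), "%H:%M:%S"),
                    stage, paste0(...)))
  invisible(NULL)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

`%||%` <- function(a, b) if (is.null(a)) b else a
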
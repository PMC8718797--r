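SIM_ROLES <- c("FSL", "SSD", "GSL", "GSD", "SL", "SD")
UNIT_DIAG_ROLES <- c("SSD", "GSL", "GSD", "SL", "SD")

#' Role-tagged similarity matrix
#'
#' Square symmetric matrix with entries in `[0, 1]`, tagged with its role in
#' the pipeline: `FSL` (lncRNA functional), `SSD` (disease semantic), `GSL`
#' / `GSD` (interaction-profile kernels), `SL` / `SD` (fused networks). All
#' roles except `FSL` must have unit diagonal (an lncRNA with no known
#' disease has undefined functional self-similarity).
#'
#' @param values numeric square matrix; dimnames used as ids.
#' @param role one of `"FSL"`, `"SSD"`, `"GSL"`, `"GSD"`, `"SL"`, `"SD"`.
#' @param ids optional labels overriding dimnames.
#' @param tol symmetry tolerance.
#' @return A `similarity_matrix` (numeric matrix with a `role` attribute).
#' @export
similarity_matrix <- function(values, role, ids = rownames(values),
                              tol = 1e-10) {
  role <- match.arg(role, SIM_ROLES)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("similarity matrix must be square")
  if (is.null(ids)) stop("ids are required")
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate ids")
  if (max(abs(values - t(values))) > tol)
    stop(role, " matrix is not symmetric")
  values <- (values + t(values)) / 2
  if (min(values) < -tol || max(values) > 1 + tol)
    stop(role, " entries outside [0, 1]")
  values[values < 0] <- 0
  values[values > 1] <- 1
  if (role %in% UNIT_DIAG_ROLES && max(abs(diag(values) - 1)) > tol)
    stop(role, " must have unit diagonal")
  dimnames(values) <- list(ids, ids)
  structure(values, role = role, class = c("similarity_matrix", "matrix",
                                           "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix [%s]: %d x %d, mean off-diagonal %.4f\n",
              attr(x, "role"), nrow(x), ncol(x),
              mean(x[row(x) != col(x)])))
  invisible(x)
}

#' lncRNA functional similarity (FSL)
#'
#' Two lncRNAs are functionally similar when the diseases they are known to
#' associate with are semantically similar. With disease sets `DL1` (size
#' `x`) and `DL2` (size `y`),
#' `FSL = (sum_{d in DL2} maxS(d, DL1) + sum_{d in DL1} maxS(d, DL2)) / (x + y)`
#' where `maxS(d, DL)` is the best semantic similarity between `d` and any
#' disease of `DL`. lncRNAs with no known disease get 0 off-diagonal (the
#' fused network falls back to the interaction-profile kernel there) and a
#' warning; the diagonal is 1 for lncRNAs with a nonempty disease set.
#'
#' @param A an [association_matrix()].
#' @param SSD disease semantic [similarity_matrix()] covering all diseases
#'   of `A`.
#' @return A [similarity_matrix()] with role `"FSL"`.
#' @export
lncrna_functional_similarity <- function(A, SSD) {
  if (!all(colnames(A) %in% rownames(SSD)))
    stop("SSD does not cover all diseases of the association matrix")
  S <- unclass(SSD)[colnames(A), colnames(A), drop = FALSE]
  nl <- nrow(A)
  dsets <- lapply(seq_len(nl), function(m) which(A[m, ] == 1L))
  empty <- lengths(dsets) == 0
  if (any(empty))
    warning("lncRNAs with no known disease: ",
            paste(rownames(A)[empty], collapse = ", "),
            " (functional similarity set to 0)")
  fsl <- matrix(0, nl, nl, dimnames = list(rownames(A), rownames(A)))
  for (m in seq_len(nl)) {
    if (empty[m]) next
    for (n in m:nl) {
      if (empty[n]) next
      D1 <- dsets[[m]]; D2 <- dsets[[n]]
      Ssub <- S[D1, D2, drop = FALSE]
      val <- (sum(apply(Ssub, 2, max)) + sum(apply(Ssub, 1, max))) /
        (length(D1) + length(D2))
      fsl[m, n] <- fsl[n, m] <- val
    }
    fsl[m, m] <- 1  # self-similarity convention for nonempty disease sets
  }
  similarity_matrix(fsl, role = "FSL")
}

#' Interaction-profile kernel bandwidth
#'
#' Normalizes a base bandwidth by the mean squared norm of the binary
#' association profiles: `delta = delta' / mean(||profile||^2)`.
#'
#' @param profiles numeric matrix, one profile per row.
#' @param base_bandwidth positive base bandwidth `delta'` (default 1).
#' @return Positive scalar bandwidth.
#' @export
gip_bandwidth <- function(profiles, base_bandwidth = 1) {
  if (!is.numeric(base_bandwidth) || base_bandwidth <= 0)
    stop("base bandwidth must be positive")
  if (NROW(profiles) == 0) stop("no profiles")
  msq <- mean(rowSums(as.matrix(profiles) ^ 2))
  if (msq == 0)
    stop("all association profiles are zero; bandwidth undefined")
  base_bandwidth / msq
}

#' Gaussian interaction-profile kernel similarity (GSL / GSD)
#'
#' `GSL(m, n) = exp(-delta_l * ||A[m, ] - A[n, ]||^2)` over lncRNA rows, and
#' analogously `GSD` over disease columns, with the bandwidth of
#' [gip_bandwidth()]. Entities with identical profiles score 1.
#'
#' @param A an [association_matrix()].
#' @param axis `"lncRNA"` (rows, role `GSL`) or `"disease"` (columns, role
#'   `GSD`).
#' @param base_bandwidth base bandwidth `delta'` (default 1).
#' @return A [similarity_matrix()] with role `"GSL"` or `"GSD"`.
#' @export
gip_similarity <- function(A, axis = c("lncRNA", "disease"),
                           base_bandwidth = 1) {
  axis <- match.arg(axis)
  P <- if (axis == "lncRNA") unclass(A) else t(unclass(A))
  storage.mode(P) <- "double"
  delta <- gip_bandwidth(P, base_bandwidth)
  sq <- rowSums(P ^ 2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(P)
  d2[d2 < 0] <- 0
  K <- exp(-delta * d2)
  diag(K) <- 1
  similarity_matrix(K, role = if (axis == "lncRNA") "GSL" else "GSD")
}

#' Fuse a primary similarity with a kernel fallback (SL / SD)
#'
#' Elementwise: keep the primary (functional or semantic) similarity where
#' it is nonzero, otherwise substitute the interaction-profile kernel value.
#' Zero in the primary matrix is a structural statement (no shared semantic
#' overlap), so the comparison is exact, not a numeric tolerance.
#'
#' @param primary `FSL` or `SSD` [similarity_matrix()].
#' @param fallback `GSL` or `GSD` [similarity_matrix()] on the same ids in
#'   the same order.
#' @return A [similarity_matrix()] with role `"SL"` (lncRNA inputs) or
#'   `"SD"` (disease inputs).
#' @export
fuse <- function(primary, fallback) {
  if (!identical(rownames(primary), rownames(fallback)))
    stop("id mismatch between primary and fallback similarity")
  out <- ifelse(unclass(primary) != 0, unclass(primary), unclass(fallback))
  diag(out) <- 1
  role_p <- attr(primary, "role") %||% "FSL"
  role <- if (role_p %in% c("FSL", "GSL", "SL")) "SL" else "SD"
  similarity_matrix(out, role = role)
}
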
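#' Binary lncRNA-disease association matrix
#'
#' Builds the incidence matrix `A` with one row per lncRNA and one column per
#' disease; `A[m, j] = 1` when the pair is a known association. The matrix is
#' the anchor of the whole pipeline: it drives the interaction-profile
#' kernels, the LD/DL edges of the heterogeneous network, and the positive
#' training labels.
#'
#' @param values numeric matrix of 0/1 entries.
#' @param lncrna_ids,disease_ids character vectors of unique row/column
#'   labels matching `values` dimensions. Defaults to the dimnames of
#'   `values`.
#' @return An `assoc_matrix`: a 0/1 integer matrix with dimnames.
#' @export
association_matrix <- function(values,
                               lncrna_ids = rownames(values),
                               disease_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(lncrna_ids) || is.null(disease_ids))
    stop("lncRNA and disease labels are required")
  lncrna_ids <- as.character(lncrna_ids)
  disease_ids <- as.character(disease_ids)
  if (anyDuplicated(lncrna_ids)) stop("duplicate lncRNA ids")
  if (anyDuplicated(disease_ids)) stop("duplicate disease ids")
  if (length(lncrna_ids) != nrow(values) ||
      length(disease_ids) != ncol(values))
    stop("label lengths do not match matrix dimensions")
  if (!all(values %in% c(0, 1))) stop("association entries must be 0/1")
  storage.mode(values) <- "integer"
  dimnames(values) <- list(lncrna_ids, disease_ids)
  if (any(rowSums(values) == 0) || any(colSums(values) == 0))
    warning("isolated lncRNAs or diseases (no known association) present")
  structure(values, class = c("assoc_matrix", class(values)))
}

#' Read a two-column association list
#'
#' Reads a TSV with columns `lncRNA_id<TAB>disease_id` (header optional,
#' detected by name), drops duplicate pairs, and returns the binary
#' association matrix over the sorted id sets.
#'
#' @param path file path of the TSV edge list.
#' @return An [association_matrix()].
#' @export
read_associations <- function(path) {
  df <- read.delim(path, header = FALSE, colClasses = "character",
                   blank.lines.skip = TRUE)
  if (ncol(df) < 2) stop("association list must have two columns")
  df <- df[, 1:2]
  if (grepl("lnc", df[1, 1], ignore.case = TRUE) &&
      grepl("dis", df[1, 2], ignore.case = TRUE))
    df <- df[-1, , drop = FALSE]
  if (nrow(df) == 0) stop("no associations in ", path)
  df <- unique(df)
  lnc <- sort(unique(df[[1]]))
  dis <- sort(unique(df[[2]]))
  A <- matrix(0L, length(lnc), length(dis), dimnames = list(lnc, dis))
  A[cbind(match(df[[1]], lnc), match(df[[2]], dis))] <- 1L
  association_matrix(A)
}

#' Write an association matrix back to a two-column TSV
#'
#' @param A an [association_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(A, path) {
  idx <- which(A == 1L, arr.ind = TRUE)
  df <- data.frame(lncRNA_id = rownames(A)[idx[, 1]],
                   disease_id = colnames(A)[idx[, 2]])
  df <- df[order(df$lncRNA_id, df$disease_id), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("assoc_matrix: %d lncRNAs x %d diseases, %d associations\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Export a labelled matrix as TSV with a role sidecar
#'
#' Writes `values` with row and column headers; if the matrix carries a
#' similarity `role` attribute it is recorded in `<path>.meta`.
#'
#' @param m matrix with dimnames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  role <- attr(m, "role")
  if (!is.null(role))
    writeLines(paste0("role: ", role), paste0(path, ".meta"))
  invisible(path)
}
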
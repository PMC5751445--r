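#' ssgc: semi-supervised graph cut prediction of drug-disease treatments
#'
#' Fuses drug-drug and disease-disease similarities from three data layers
#' (chemical structure / disease phenotype, gene association profiles, known
#' treatments) into comprehensive similarity matrices, builds an implicit
#' weighted graph over all drug-disease pairs, and propagates the sparse
#' positive treatment labels to rank unknown pairs.
#'
#' Entity sets (drugs, diseases, genes) are represented as character id
#' vectors; association matrices as binary matrices with id dimnames;
#' similarity matrices as symmetric unit-diagonal matrices with id dimnames;
#' pair score fields as drugs x diseases real matrices.
#'
#' @name ssgc-package
#' @keywords internal
"_PACKAGE"

# ---- validators -----------------------------------------------------------

#' Validate a similarity matrix
#'
#' Checks that `S` is square with matching id dimnames, symmetric, has a unit
#' diagonal and values in \[0, 1\]. Small numerical noise (asymmetry up to
#' `tol`, values within 1e-9 of the bounds) is repaired; anything larger is
#' an error.
#'
#' @param S numeric matrix with identical row/column id dimnames.
#' @param tol tolerance for symmetry and diagonal checks.
#' @return the validated (repaired) matrix, symmetric to machine precision,
#'   diagonal exactly 1.
#' @export
validate_similarity_matrix <- function(S, tol = 1e-6) {
  if (!is.matrix(S) || !is.numeric(S)) stop("similarity must be a numeric matrix")
  if (nrow(S) != ncol(S)) stop("similarity matrix must be square")
  ids <- rownames(S)
  if (is.null(ids) || is.null(colnames(S)) || !identical(ids, colnames(S)))
    stop("similarity matrix needs identical row and column id names")
  if (anyDuplicated(ids)) stop("duplicate ids in similarity matrix")
  if (any(!is.finite(S))) stop("non-finite similarity values")
  asym <- max(abs(S - t(S)))
  if (asym > tol) stop(sprintf("similarity matrix asymmetric (max |S - t(S)| = %.3g)", asym))
  if (nrow(S) > 0 && max(abs(diag(S) - 1)) > tol)
    stop("similarity matrix diagonal must be 1")
  lo <- min(S); hi <- max(S)
  if (lo < -1e-9 || hi > 1 + 1e-9)
    stop(sprintf("similarity values outside [0,1]: range [%.6g, %.6g]", lo, hi))
  S <- (S + t(S)) / 2
  S[S < 0] <- 0
  S[S > 1] <- 1
  diag(S) <- 1
  S
}

#' @keywords internal
check_binary_matrix <- function(A, what = "association matrix") {
  if (!is.matrix(A) || !is.numeric(A)) stop(what, " must be a numeric matrix")
  if (!all(A %in% c(0, 1))) stop(what, " must be binary (0/1)")
  invisible(A)
}

#' @keywords internal
check_registry <- function(ids, what = "registry") {
  if (!is.character(ids) || length(ids) == 0) stop(what, " must be a non-empty character vector")
  if (anyDuplicated(ids)) stop("duplicate ids in ", what)
  if (any(!nzchar(ids))) stop("empty id in ", what)
  invisible(ids)
}

# ---- edge lists -----------------------------------------------------------

#' Read a two-column edge list into a binary association matrix
#'
#' The file is TSV (or comma-separated) with two id columns and an optional
#' `#`-prefixed header line. Duplicate edges collapse to a single 1. When
#' `row_ids` / `col_ids` are omitted, the registries are built from the file
#' in first-appearance order.
#'
#' @param path file path.
#' @param row_ids,col_ids optional character registries; if supplied every id
#'   in the file must be present in them.
#' @return binary matrix with `row_ids` x `col_ids` dimnames.
#' @export
read_edge_list <- function(path, row_ids = NULL, col_ids = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  parts <- strsplit(lines, "[\t,]")
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad))
    stop(sprintf("malformed edge at line %d of %s (need 2 fields)", lineno[bad[1]], path))
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", 2L)
  if (is.null(row_ids)) row_ids <- unique(from) else {
    check_registry(row_ids, "row registry")
    miss <- setdiff(from, row_ids)
    if (length(miss)) stop("edge list ids not in row registry: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  if (is.null(col_ids)) col_ids <- unique(to) else {
    check_registry(col_ids, "column registry")
    miss <- setdiff(to, col_ids)
    if (length(miss)) stop("edge list ids not in column registry: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  A <- matrix(0, length(row_ids), length(col_ids), dimnames = list(row_ids, col_ids))
  A[cbind(match(from, row_ids), match(to, col_ids))] <- 1
  A
}

#' Write an association matrix as a two-column edge list
#' @param A binary matrix with dimnames.
#' @param path output file path.
#' @param header logical; write a `#`-prefixed header line.
#' @export
write_edge_list <- function(A, path, header = TRUE) {
  check_binary_matrix(A)
  idx <- which(A == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- paste(rownames(A)[idx[, 1]], colnames(A)[idx[, 2]], sep = "\t")
  if (header) out <- c("#from\tto", out)
  writeLines(out, path)
}

# ---- similarity matrices --------------------------------------------------

#' Read a square similarity matrix from TSV
#'
#' Expects an id header row and a first column of ids (row ids must equal
#' column ids). Values within 1e-9 of the \[0,1\] bounds are clipped; values
#' further outside, asymmetry beyond 1e-6, or a non-unit diagonal are errors.
#'
#' @param path file path.
#' @return validated similarity matrix.
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          row.names = 1, comment.char = "")
  S <- as.matrix(df)
  if (nrow(S) != ncol(S)) stop("similarity file is not square: ", path)
  if (!identical(rownames(S), colnames(S)))
    stop("row ids and column ids differ in ", path)
  storage.mode(S) <- "double"
  validate_similarity_matrix(S)
}

#' Write a similarity matrix as TSV (id header row and column)
#'
#' Round-trips losslessly through [read_similarity_matrix()] at 12
#' significant digits.
#'
#' @param S similarity matrix with id dimnames.
#' @param path output file path.
#' @export
write_similarity_matrix <- function(S, path) {
  S <- validate_similarity_matrix(S)
  ids <- rownames(S)
  rows <- vapply(seq_len(nrow(S)), function(i)
    paste(c(ids[i], formatC(S[i, ], digits = 12, format = "g")), collapse = "\t"), "")
  writeLines(c(paste(c("id", ids), collapse = "\t"), rows), path)
}

# ---- fingerprints ---------------------------------------------------------

#' Read 2D fingerprints as per-drug bit-index sets
#'
#' Format: one drug per line, `drug_id<TAB>comma-separated bit indices`; an
#' empty second field means an empty fingerprint.
#'
#' @param path file path.
#' @return named list of sorted unique integer bit-index vectors.
#' @export
read_fingerprints <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t")
  ids <- vapply(parts, `[[`, "", 1L)
  check_registry(ids, "fingerprint drug registry")
  bits <- lapply(parts, function(p) {
    if (length(p) < 2L || !nzchar(p[2L])) return(integer(0))
    sort(unique(as.integer(strsplit(p[2L], ",")[[1]])))
  })
  names(bits) <- ids
  bits
}

#' Write fingerprints in the format read by [read_fingerprints()]
#' @param fps named list of integer bit-index vectors.
#' @param path output file path.
#' @export
write_fingerprints <- function(fps, path) {
  check_registry(names(fps), "fingerprint drug registry")
  writeLines(vapply(names(fps), function(id)
    paste0(id, "\t", paste(fps[[id]], collapse = ",")), ""), path)
}

# ---- pair scores ----------------------------------------------------------

#' Rank drug-disease pairs by score
#'
#' Orders all (or a masked subset of) pairs by descending score, breaking
#' ties by (drug id, disease id) in C-locale lexicographic order.
#'
#' @param scores drugs x diseases numeric matrix with id dimnames.
#' @param mask optional logical matrix; only `TRUE` pairs are ranked.
#' @return data.frame with columns drug, disease, score in rank order.
#' @export
rank_pairs <- function(scores, mask = NULL) {
  stopifnot(is.matrix(scores))
  drug <- rownames(scores)[row(scores)]
  disease <- colnames(scores)[col(scores)]
  df <- data.frame(drug = c(drug), disease = c(disease), score = c(scores),
                   stringsAsFactors = FALSE)
  if (!is.null(mask)) df <- df[c(mask), , drop = FALSE]
  df <- df[order(-df$score, df$drug, df$disease, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write ranked pair scores as three-column TSV
#'
#' Rows are (drug_id, disease_id, score), sorted by descending score with
#' ties broken lexicographically by (drug_id, disease_id).
#'
#' @param scores drugs x diseases numeric matrix with id dimnames.
#' @param path output file path.
#' @param top_k optional; keep only the first `top_k` rows.
#' @export
write_pair_scores <- function(scores, path, top_k = NULL) {
  df <- rank_pairs(scores)
  if (!is.null(top_k)) df <- utils::head(df, top_k)
  out <- paste(df$drug, df$disease, formatC(df$score, digits = 12, format = "g"),
               sep = "\t")
  writeLines(c("#drug\tdisease\tscore", out), path)
}

#' Read pair scores written by [write_pair_scores()]
#' @param path file path.
#' @return data.frame with columns drug, disease, score.
#' @export
read_pair_scores <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          col.names = c("drug", "disease", "score"),
                          colClasses = c("character", "character", "numeric"))
  df
}
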
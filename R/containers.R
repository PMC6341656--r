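## Matrix-backed input containers. Analysis functions return tibbles; these
## objects carry the aligned matrices (values, masks, ids) between stages.

#' Construct a drug response matrix
#'
#' Bundles a cell line x drug matrix of measured responses (activity area,
#' IC50, or any per-pair sensitivity summary) together with an observation
#' mask and the direction of the response scale. Missing entries (`NA`) are
#' allowed and tracked in the mask; all downstream estimators sum over
#' observed entries only.
#'
#' @param x A numeric matrix with cell lines as rows and drugs as columns
#'   (dimnames required), or a data frame whose first column holds cell-line
#'   identifiers and whose remaining columns are drug responses.
#' @param direction `"higher_is_sensitive"` (e.g. activity area) or
#'   `"lower_is_sensitive"` (e.g. IC50). Normalization reorients
#'   `lower_is_sensitive` data so that internally higher always means more
#'   sensitive.
#'
#' @return An object of class `cdcn_response` with fields `values` (numeric
#'   matrix), `observed` and `imputed` (logical matrices), `direction`, and
#'   `normalized`.
#' @examples
#' m <- matrix(c(1, 2, NA, 4), 2, 2,
#'             dimnames = list(c("C1", "C2"), c("D1", "D2")))
#' rm <- response_matrix(m, direction = "higher_is_sensitive")
#' sum(rm$observed)
#' @export
response_matrix <- function(x,
                            direction = c("higher_is_sensitive",
                                          "lower_is_sensitive")) {
  direction <- match.arg(direction)
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    vals <- as.matrix(x[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- ids
    x <- vals
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("`x` must be a numeric matrix or a data frame with an ID column.")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("response matrix needs cell-line rownames and drug colnames.")
  }
  check_unique_ids(rownames(x), "cell line")
  check_unique_ids(colnames(x), "drug")
  observed <- is.finite(x)
  if (!any(observed)) abort("response matrix has no observed entries.")
  if (any(!is.na(x) & !is.finite(x))) {
    abort("non-finite (Inf/-Inf) response values are not allowed.")
  }
  structure(
    list(values = x,
         observed = observed,
         imputed = matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x)),
         direction = direction,
         normalized = FALSE),
    class = "cdcn_response"
  )
}

#' Construct a gene expression matrix
#'
#' @param x A numeric matrix with genes as rows and cell lines as columns
#'   (dimnames required), or a data frame whose first column holds gene
#'   identifiers.
#' @return An object of class `cdcn_expression` wrapping the matrix.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("C1", "C2")))
#' em <- expression_matrix(m)
#' @export
expression_matrix <- function(x) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    vals <- as.matrix(x[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- ids
    x <- vals
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("`x` must be a numeric matrix or a data frame with an ID column.")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("expression matrix needs gene rownames and cell-line colnames.")
  }
  check_unique_ids(rownames(x), "gene")
  check_unique_ids(colnames(x), "cell line")
  if (any(!is.finite(x))) abort("expression values must all be finite.")
  if (nrow(x) < 2) {
    abort("need at least 2 genes (Pearson correlation is undefined otherwise).")
  }
  structure(list(values = x), class = "cdcn_expression")
}

#' Construct a molecular fingerprint set
#'
#' A fixed-length binary substructure fingerprint per drug, the input to
#' Tanimoto similarity.
#'
#' @param x A 0/1 matrix with drugs as rows (rownames required), or a named
#'   character vector of bitstrings (names = drug IDs).
#' @return An object of class `cdcn_fingerprints` with fields `bits`
#'   (integer matrix) and `n_bits`.
#' @examples
#' fingerprint_set(c(D1 = "1100", D2 = "1010"))
#' @export
fingerprint_set <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x))) abort("bitstring vector must be named by drug ID.")
    lens <- nchar(x)
    if (length(unique(lens)) != 1) {
      bad <- names(x)[lens != lens[1]][1]
      abort(paste0("ragged fingerprint length for drug '", bad, "'."))
    }
    chars <- strsplit(x, "", fixed = TRUE)
    ok <- vapply(chars, function(ch) all(ch %in% c("0", "1")), logical(1))
    if (!all(ok)) {
      abort(paste0("fingerprint for drug '", names(x)[!ok][1],
                   "' contains characters outside {0,1}."))
    }
    x <- do.call(rbind, lapply(chars, function(ch) as.integer(ch)))
    rownames(x) <- names(lens)
  }
  if (!is.matrix(x)) abort("`x` must be a 0/1 matrix or bitstring vector.")
  if (is.null(rownames(x))) abort("fingerprint matrix needs drug rownames.")
  check_unique_ids(rownames(x), "drug")
  storage.mode(x) <- "integer"
  if (any(!x %in% c(0L, 1L))) abort("fingerprint bits must be 0 or 1.")
  if (ncol(x) < 1) abort("n_bits must be >= 1.")
  structure(list(bits = x, n_bits = ncol(x)), class = "cdcn_fingerprints")
}

check_unique_ids <- function(ids, what) {
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    abort(paste0("duplicate ", what, " identifier: '", dup, "'."))
  }
  invisible(ids)
}

#' @export
print.cdcn_response <- function(x, ...) {
  cat("<cdcn_response> ", nrow(x$values), " cell lines x ",
      ncol(x$values), " drugs\n", sep = "")
  cat("  observed: ", sum(x$observed), "/", length(x$observed),
      "  imputed: ", sum(x$imputed), "\n", sep = "")
  cat("  direction: ", x$direction,
      if (x$normalized) "  (normalized)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
print.cdcn_expression <- function(x, ...) {
  cat("<cdcn_expression> ", nrow(x$values), " genes x ",
      ncol(x$values), " cell lines\n", sep = "")
  invisible(x)
}

#' @export
print.cdcn_fingerprints <- function(x, ...) {
  cat("<cdcn_fingerprints> ", nrow(x$bits), " drugs x ",
      x$n_bits, " bits\n", sep = "")
  invisible(x)
}

#' Tidy a response matrix into long format
#'
#' @param x A `cdcn_response`.
#' @param ... Unused.
#' @return A tibble with columns `cell_id`, `drug_id`, `response`,
#'   `observed`, `imputed`; unobserved, unimputed entries have `NA` response.
#' @exportS3Method tibble::as_tibble
as_tibble.cdcn_response <- function(x, ...) {
  tibble(
    cell_id = rep(rownames(x$values), times = ncol(x$values)),
    drug_id = rep(colnames(x$values), each = nrow(x$values)),
    response = as.vector(x$values),
    observed = as.vector(x$observed),
    imputed = as.vector(x$imputed)
  )
}

cell_ids <- function(x) UseMethod("cell_ids")
#' @export
cell_ids.cdcn_response <- function(x) rownames(x$values)
#' @export
cell_ids.cdcn_expression <- function(x) colnames(x$values)
drug_ids <- function(x) UseMethod("drug_ids")
#' @export
drug_ids.cdcn_response <- function(x) colnames(x$values)
#' @export
drug_ids.cdcn_fingerprints <- function(x) rownames(x$bits)
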
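## Delimited-text readers/writers for the three input files, plus response
## normalization. Layout: header row + first ID column, TSV by default.

MISSING_TOKENS <- c("", "na", "nan")

read_id_matrix <- function(path, delim, what_row, what_col) {
  ## header parsed by hand: readr would silently de-duplicate repeated
  ## column names, which must be a hard error here
  header <- strsplit(readr::read_lines(path, n_max = 1), delim,
                     fixed = TRUE)[[1]]
  if (length(header) < 2) {
    abort(paste0("malformed header in '", path,
                 "': need an ID column plus data columns."))
  }
  raw <- readr::read_delim(
    path, delim = delim, col_names = FALSE, skip = 1,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) != length(header)) {
    abort(paste0("malformed file '", path,
                 "': data rows do not match the header width."))
  }
  col_ids <- header[-1]
  row_ids <- as.character(raw[[1]])
  check_unique_ids(col_ids, what_col)
  check_unique_ids(row_ids, what_row)
  vals <- matrix(NA_real_, length(row_ids), length(col_ids),
                 dimnames = list(row_ids, col_ids))
  for (j in seq_along(col_ids)) {
    cells <- raw[[j + 1]]
    missing <- is.na(cells) | tolower(trimws(cells)) %in% MISSING_TOKENS
    parsed <- suppressWarnings(as.numeric(cells))
    bad <- !missing & is.na(parsed)
    if (any(bad)) {
      i <- which(bad)[1]
      abort(paste0("non-numeric value '", cells[i], "' at row '", row_ids[i],
                   "', column '", col_ids[j], "' in '", path, "'."))
    }
    parsed[missing] <- NA_real_
    vals[, j] <- parsed
  }
  vals
}

#' Read a cell line x drug response matrix from delimited text
#'
#' Expects a header row of drug IDs and a first column of cell-line IDs.
#' Empty cells, `NA` and `NaN` (case-insensitive) denote missing responses.
#'
#' @param path Path to the file.
#' @param direction Response scale orientation; see [response_matrix()].
#' @param delim Field delimiter (tab by default, use `","` for CSV).
#' @return A [response_matrix()] object.
#' @export
read_response_matrix <- function(path,
                                 direction = c("higher_is_sensitive",
                                               "lower_is_sensitive"),
                                 delim = "\t") {
  direction <- match.arg(direction)
  response_matrix(read_id_matrix(path, delim, "cell line", "drug"),
                  direction = direction)
}

#' Read a gene x cell line expression matrix from delimited text
#'
#' Header row = cell-line IDs, first column = gene IDs. All values must be
#' numeric and finite.
#'
#' @inheritParams read_response_matrix
#' @return An [expression_matrix()] object.
#' @export
read_expression_matrix <- function(path, delim = "\t") {
  vals <- read_id_matrix(path, delim, "gene", "cell line")
  if (any(is.na(vals))) abort("expression matrix may not contain missing values.")
  expression_matrix(vals)
}

#' Write a response (or similarity) matrix to delimited text
#'
#' Values are written at full double precision so that a write/read
#' round-trip is value-faithful; unobserved entries are written as `NA`.
#'
#' @param x A `cdcn_response`, `cdcn_similarity`, or plain numeric matrix.
#' @param path Output path.
#' @param delim Field delimiter.
#' @param id_col Name for the leading ID column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, delim = "\t", id_col = "id") {
  if (inherits(x, "cdcn_response")) {
    m <- x$values
    m[!(x$observed | x$imputed)] <- NA_real_
    id_col <- "cell_id"
  } else if (inherits(x, "cdcn_similarity")) {
    m <- x$sim
  } else {
    m <- x
  }
  df <- tibble::as_tibble(m, rownames = id_col)
  readr::write_delim(df, path, delim = delim, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read molecular fingerprints from a two-column file
#'
#' Two tab-separated columns without header: drug ID and either a bitstring
#' over `{0,1}` (`mode = "bitstring"`, the dependency-free canonical path) or
#' a SMILES string (`mode = "smiles"`, converted to an Open Babel FP2
#' path-based fingerprint via ChemmineR and folded to `n_bits` bits).
#'
#' @param path Path to the file.
#' @param mode `"bitstring"` or `"smiles"`.
#' @param n_bits Fingerprint length for the SMILES path (ignored for
#'   bitstrings, whose length defines it).
#' @return A [fingerprint_set()].
#' @export
read_fingerprints <- function(path, mode = c("bitstring", "smiles"),
                              n_bits = 1024) {
  mode <- match.arg(mode)
  raw <- readr::read_tsv(path, col_names = c("drug_id", "value"),
                         col_types = "cc", progress = FALSE)
  if (any(is.na(raw$value))) {
    abort(paste0("missing fingerprint field for drug '",
                 raw$drug_id[is.na(raw$value)][1], "'."))
  }
  check_unique_ids(raw$drug_id, "drug")
  if (mode == "bitstring") {
    fingerprint_set(setNames(raw$value, raw$drug_id))
  } else {
    smiles_fingerprints(setNames(raw$value, raw$drug_id), n_bits = n_bits)
  }
}

#' Compute path-based fingerprints from SMILES strings
#'
#' Uses Open Babel's FP2 linear-fragment fingerprint (through
#' ChemmineR/ChemmineOB) and folds the 1024-bit result down to `n_bits` by
#' OR-ing congruent positions. Identical molecules always map to identical
#' bit vectors.
#'
#' @param smiles Named character vector of SMILES (names = drug IDs).
#' @param n_bits Output fingerprint length.
#' @return A [fingerprint_set()].
#' @export
smiles_fingerprints <- function(smiles, n_bits = 1024) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    abort("SMILES mode needs the ChemmineR/ChemmineOB cheminformatics backend.")
  }
  if (is.null(names(smiles))) abort("`smiles` must be named by drug ID.")
  check_unique_ids(names(smiles), "drug")
  sdf <- tryCatch(ChemmineR::smiles2sdf(smiles),
                  error = function(e) abort(paste0(
                    "unparseable SMILES among drugs: ", conditionMessage(e))))
  ok <- ChemmineR::validSDF(sdf)
  if (!all(ok)) {
    abort(paste0("unparseable SMILES for drug '", names(smiles)[!ok][1], "'."))
  }
  fp <- ChemmineR::as.matrix(ChemmineR::fingerprintOB(sdf, "FP2"))
  storage.mode(fp) <- "integer"
  if (n_bits < ncol(fp)) {
    folded <- matrix(0L, nrow(fp), n_bits)
    idx <- (seq_len(ncol(fp)) - 1L) %% n_bits + 1L
    for (j in seq_len(ncol(fp))) {
      folded[, idx[j]] <- pmax(folded[, idx[j]], fp[, j])
    }
    fp <- folded
  }
  rownames(fp) <- names(smiles)
  fingerprint_set(fp)
}

#' Normalize drug responses to a common baseline and range
#'
#' Puts every drug on the same scale so that responses are comparable across
#' drugs: per drug column (over observed entries only), values are min-max
#' scaled to range exactly 1 and then mean-centred to baseline exactly 0.
#' For `lower_is_sensitive` input (IC50), values are negated first so that
#' after normalization higher always means more sensitive. With
#' `method = "zscore"` a plain per-drug standardization is used instead.
#'
#' @param rm A [response_matrix()].
#' @param method `"range"` (min-max to range 1, then centre; default) or
#'   `"zscore"`.
#' @param log_transform Apply `log()` before anything else (all observed
#'   values must be positive). Useful for raw IC50 scales.
#' @return A normalized `cdcn_response` with `direction =
#'   "higher_is_sensitive"`; the observation mask is unchanged.
#' @examples
#' m <- matrix(c(0, 5, 10), 3, 1, dimnames = list(paste0("C", 1:3), "D1"))
#' normalize_responses(response_matrix(m))$values  # -0.5, 0, 0.5
#' @export
normalize_responses <- function(rm, method = c("range", "zscore"),
                                log_transform = FALSE) {
  stopifnot(inherits(rm, "cdcn_response"))
  method <- match.arg(method)
  vals <- rm$values
  obs <- rm$observed
  if (log_transform) {
    if (any(vals[obs] <= 0)) {
      abort("log_transform requires strictly positive observed responses.")
    }
    vals[obs] <- log(vals[obs])
  }
  if (rm$direction == "lower_is_sensitive") vals <- -vals
  for (j in seq_len(ncol(vals))) {
    v <- vals[obs[, j], j]
    if (length(v) < 2) {
      abort(paste0("drug '", colnames(vals)[j],
                   "' has fewer than 2 observed responses."))
    }
    rng <- max(v) - min(v)
    if (rng == 0) {
      abort(paste0("drug '", colnames(vals)[j],
                   "' has constant observed responses (zero range)."))
    }
    if (method == "range") {
      scaled <- (v - min(v)) / rng
      scaled <- scaled - mean(scaled)
    } else {
      scaled <- (v - mean(v)) / sd(v)
    }
    vals[obs[, j], j] <- scaled
    vals[!obs[, j], j] <- NA_real_
  }
  out <- rm
  out$values <- vals
  out$direction <- "higher_is_sensitive"
  out$normalized <- TRUE
  out
}
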
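## The two similarity layers of the cell line-drug network: Pearson
## correlation of expression profiles between cell lines, and Tanimoto
## similarity of molecular fingerprints between drugs, plus the
## complete-linkage drug clustering used for the generalized observation.

new_similarity <- function(sim, type) {
  stopifnot(isSymmetric(unname(sim)))
  structure(list(ids = rownames(sim), sim = sim, type = type),
            class = "cdcn_similarity")
}

#' @export
print.cdcn_similarity <- function(x, ...) {
  cat("<cdcn_similarity> ", x$type, ", ", length(x$ids), " x ",
      length(x$ids), "\n", sep = "")
  invisible(x)
}

#' Cell-line similarity from expression profiles
#'
#' Pairwise Pearson correlation between the gene expression profiles of
#' every pair of cell lines, over all genes in the matrix.
#'
#' @param em An [expression_matrix()].
#' @return A `cdcn_similarity` of type `"cell"`: symmetric, unit diagonal,
#'   entries in `[-1, 1]`.
#' @export
cell_similarity <- function(em) {
  stopifnot(inherits(em, "cdcn_expression"))
  sds <- apply(em$values, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("cell line '", colnames(em$values)[sds == 0][1],
                 "' has zero expression variance; correlation undefined."))
  }
  rho <- cor(em$values)
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- 1
  new_similarity((rho + t(rho)) / 2, "cell")
}

#' Drug similarity from molecular fingerprints
#'
#' Tanimoto coefficient `T(i, j) = |bits_i AND bits_j| / |bits_i OR bits_j|`
#' for every drug pair; the associated structural distance is `d = 1 - T`.
#'
#' @param fp A [fingerprint_set()]. All-zero fingerprints are rejected
#'   (Tanimoto is undefined for them).
#' @return A `cdcn_similarity` of type `"drug"`: symmetric, unit diagonal,
#'   entries in `[0, 1]`.
#' @export
drug_similarity <- function(fp) {
  stopifnot(inherits(fp, "cdcn_fingerprints"))
  b <- fp$bits
  n_set <- rowSums(b)
  if (any(n_set == 0)) {
    abort(paste0("drug '", rownames(b)[n_set == 0][1],
                 "' has an all-zero fingerprint; Tanimoto undefined."))
  }
  inter <- tcrossprod(b)
  union <- outer(n_set, n_set, "+") - inter
  tani <- inter / union
  diag(tani) <- 1
  new_similarity((tani + t(tani)) / 2, "drug")
}

#' Structural distance between drugs
#'
#' @param dsm A drug `cdcn_similarity`.
#' @return The distance matrix `1 - Tanimoto`.
#' @export
drug_distance <- function(dsm) {
  stopifnot(inherits(dsm, "cdcn_similarity"), dsm$type == "drug")
  1 - dsm$sim
}

#' Complete-linkage clustering of drugs by structural distance
#'
#' Agglomerative clustering on `d = 1 - Tanimoto` with the "complete"
#' method: the distance between two clusters is the maximum pairwise drug
#' distance across them, so cutting the tree at height `h` yields clusters
#' whose within-cluster pairwise distances are all `<= h`.
#'
#' @param dsm A drug `cdcn_similarity` with at least 2 drugs.
#' @return An [stats::hclust] tree.
#' @export
cluster_drugs <- function(dsm) {
  stopifnot(inherits(dsm, "cdcn_similarity"), dsm$type == "drug")
  if (length(dsm$ids) < 2) abort("need at least 2 drugs to cluster.")
  hclust(as.dist(drug_distance(dsm)), method = "complete")
}

#' Export a drug dendrogram as Newick
#'
#' Branch lengths are derived from the complete-linkage merge heights.
#'
#' @param hc An [stats::hclust] tree from [cluster_drugs()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Newick export needs the 'ape' package.")
  }
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Partition cell-line and drug pairs into high/low similarity groups
#'
#' The motivating observation behind the network model compares response
#' correlations across four groups: cell-line pairs split at a Pearson
#' cutoff into high (`Hc`) and low (`Lc`) similarity, crossed with drug
#' pairs split at a Tanimoto/distance cutoff into `Hd` and `Ld`. All
#' inequalities are strict (`> rho_cut`, `> tani_cut`, `< dist_cut`); ties
#' fall into the low-similarity group. The Tanimoto and distance criteria
#' are redundant when `dist_cut = 1 - tani_cut` but both are exposed because
#' published analyses quote dataset-specific values for each.
#'
#' A drug belongs to the high-similarity drug *set* `Hd` if it appears in at
#' least one high-similarity drug pair; the remaining drugs form `Ld`.
#'
#' @param csm A cell `cdcn_similarity`.
#' @param dsm A drug `cdcn_similarity`.
#' @param rho_cut Pearson cutoff for cell pairs (default 0.9).
#' @param tani_cut Tanimoto cutoff for drug pairs (default 0.5).
#' @param dist_cut Structural distance cutoff for drug pairs (default 0.49).
#' @return A list of class `cdcn_partition`: `cell_pairs` and `drug_pairs`
#'   tibbles (pair, similarity, group) and a `drug_groups` tibble
#'   (`drug_id`, `group`).
#' @export
partition_pairs <- function(csm, dsm, rho_cut = 0.9, tani_cut = 0.5,
                            dist_cut = 0.49) {
  stopifnot(inherits(csm, "cdcn_similarity"), csm$type == "cell",
            inherits(dsm, "cdcn_similarity"), dsm$type == "drug")
  cell_pairs <- upper_pairs(csm$sim, "cell_i", "cell_j", "rho")
  cell_pairs$group <- ifelse(cell_pairs$rho > rho_cut, "Hc", "Lc")
  drug_pairs <- upper_pairs(dsm$sim, "drug_i", "drug_j", "tanimoto")
  drug_pairs$distance <- 1 - drug_pairs$tanimoto
  drug_pairs$group <- ifelse(
    drug_pairs$tanimoto > tani_cut & drug_pairs$distance < dist_cut,
    "Hd", "Ld")
  hd <- unique(c(drug_pairs$drug_i[drug_pairs$group == "Hd"],
                 drug_pairs$drug_j[drug_pairs$group == "Hd"]))
  drug_groups <- tibble(
    drug_id = dsm$ids,
    group = ifelse(dsm$ids %in% hd, "Hd", "Ld")
  )
  structure(list(cell_pairs = cell_pairs, drug_pairs = drug_pairs,
                 drug_groups = drug_groups,
                 cuts = c(rho = rho_cut, tanimoto = tani_cut,
                          distance = dist_cut)),
            class = "cdcn_partition")
}

#' @export
print.cdcn_partition <- function(x, ...) {
  cat("<cdcn_partition>\n")
  cat("  cell pairs: ", sum(x$cell_pairs$group == "Hc"), " Hc / ",
      sum(x$cell_pairs$group == "Lc"), " Lc\n", sep = "")
  cat("  drug pairs: ", sum(x$drug_pairs$group == "Hd"), " Hd / ",
      sum(x$drug_pairs$group == "Ld"), " Ld\n", sep = "")
  cat("  drug sets:  ", sum(x$drug_groups$group == "Hd"), " Hd / ",
      sum(x$drug_groups$group == "Ld"), " Ld drugs\n", sep = "")
  invisible(x)
}

upper_pairs <- function(sim, name_i, name_j, name_val) {
  ids <- rownames(sim)
  idx <- which(upper.tri(sim), arr.ind = TRUE)
  out <- tibble(i = ids[idx[, 1]], j = ids[idx[, 2]],
                val = sim[idx])
  names(out) <- c(name_i, name_j, name_val)
  out
}
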
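## Synthetic data with planted "similar cells x similar drugs => similar
## responses" structure: cell lines drawn around cluster centroids in gene
## space, drug fingerprints derived from cluster template bit vectors, and
## responses driven by a (cell cluster x drug group) base-effect table plus
## smooth within-cluster terms and i.i.d. noise. The last drug cluster is a
## pool of mutually dissimilar "background" compounds (each with its own
## template and its own base effects), emulating the unclustered singleton
## drugs seen in real screening panels; without them every drug would fall
## into the high-similarity group and the low-similarity drug set would be
## empty.

#' Configuration for the synthetic data generator
#'
#' @param n_cells,n_drugs,n_genes,n_bits Dimensions of the generated data.
#' @param n_cell_clusters Number of cell-line clusters (<= `n_cells`).
#' @param n_drug_clusters Number of drug groups (<= `n_drugs`); the last
#'   group is generated as mutually dissimilar background drugs.
#' @param noise_sd Standard deviation of the response noise; the smooth
#'   within-cluster response terms scale with it too, so `noise_sd = 0`
#'   gives cluster-pure responses (identical rows within a cell cluster).
#' @param expression_noise_sd Per-gene noise around the expression cluster
#'   centroids; 0.25 keeps within-cluster expression correlations near
#'   0.94, straddling the usual 0.9 high-similarity cutoff against
#'   near-zero between-cluster correlations.
#' @param bit_flip_prob Per-bit flip probability applied to a drug's cluster
#'   template; 0.05 keeps within-cluster Tanimoto near 0.8 while the
#'   independently drawn templates keep between-cluster Tanimoto near 1/3,
#'   straddling the usual 0.5 cutoff.
#' @param missing_fraction Fraction of response entries masked as missing,
#'   in `[0, 1)`.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_cells = 50, n_drugs = 12, n_genes = 200,
                         n_bits = 128, n_cell_clusters = 4,
                         n_drug_clusters = 3, noise_sd = 0.1,
                         expression_noise_sd = 0.25, bit_flip_prob = 0.05,
                         missing_fraction = 0.05, seed = 1) {
  stopifnot(n_cells >= 2, n_drugs >= 2, n_genes >= 2, n_bits >= 8,
            n_cell_clusters >= 1, n_cell_clusters <= n_cells,
            n_drug_clusters >= 1, n_drug_clusters <= n_drugs,
            noise_sd >= 0, expression_noise_sd >= 0,
            bit_flip_prob >= 0, bit_flip_prob < 0.5,
            missing_fraction >= 0, missing_fraction < 1)
  structure(as.list(environment()), class = "synth_config")
}

## Templates are i.i.d. Bernoulli(0.5) bit vectors, redrawn until every pair
## differs in at least a quarter of the bits (expected separation is half).
draw_templates <- function(n_templates, n_bits) {
  min_hamming <- ceiling(0.25 * n_bits)
  templates <- matrix(0L, n_templates, n_bits)
  for (t in seq_len(n_templates)) {
    repeat {
      cand <- as.integer(stats::runif(n_bits) < 0.5)
      if (sum(cand) == 0) next
      if (t == 1) break
      sep <- apply(templates[seq_len(t - 1), , drop = FALSE], 1,
                   function(prev) sum(prev != cand))
      if (min(sep) >= min_hamming) break
    }
    templates[t, ] <- cand
  }
  templates
}

#' Generate a synthetic expression/fingerprint/response dataset
#'
#' Produces the three inputs of the prediction workflow with planted
#' cluster structure: within-cluster expression correlations far above
#' between-cluster ones, within-cluster Tanimoto similarities far above
#' between-cluster ones, and responses determined by a cell-cluster x
#' drug-group base-effect table (rescaled per drug to range 1 and mean 0)
#' plus within-cluster variation and noise, both scaling with `noise_sd`.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `cdcn_synthetic`: `expression`
#'   ([expression_matrix()]), `fingerprints` ([fingerprint_set()]),
#'   `response` ([response_matrix()], with `missing_fraction` of entries
#'   masked), and `truth` (cluster assignments, base effects, the complete
#'   response matrix, and the hidden entries).
#' @examples
#' d <- generate_synthetic(synth_config(n_cells = 12, n_drugs = 6, seed = 7))
#' d$response
#' @export
generate_synthetic <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  cell_ids <- sprintf("C%03d", seq_len(cfg$n_cells))
  drug_ids <- sprintf("D%02d", seq_len(cfg$n_drugs))
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))

  ## --- cell lines: cluster centroids in gene space + noise -------------
  cell_cluster <- sort(rep_len(seq_len(cfg$n_cell_clusters), cfg$n_cells))
  centroids <- matrix(stats::rnorm(cfg$n_genes * cfg$n_cell_clusters),
                      cfg$n_genes, cfg$n_cell_clusters)
  expr <- centroids[, cell_cluster, drop = FALSE] +
    matrix(stats::rnorm(cfg$n_genes * cfg$n_cells,
                        sd = cfg$expression_noise_sd),
           cfg$n_genes, cfg$n_cells)
  dimnames(expr) <- list(gene_ids, cell_ids)

  ## --- drugs: template fingerprints + bit flips ------------------------
  drug_cluster <- sort(rep_len(seq_len(cfg$n_drug_clusters), cfg$n_drugs))
  background <- drug_cluster == cfg$n_drug_clusters & cfg$n_drug_clusters > 1
  ## response groups: one per structural cluster, one per background drug
  response_group <- drug_cluster
  response_group[background] <-
    cfg$n_drug_clusters - 1 + seq_len(sum(background))
  n_templates <- max(response_group)
  templates <- draw_templates(n_templates, cfg$n_bits)
  bits <- matrix(0L, cfg$n_drugs, cfg$n_bits,
                 dimnames = list(drug_ids, NULL))
  for (d in seq_len(cfg$n_drugs)) {
    repeat {
      flips <- stats::runif(cfg$n_bits) < cfg$bit_flip_prob
      fp <- templates[response_group[d], ]
      fp[flips] <- 1L - fp[flips]
      if (sum(fp) > 0) break
    }
    bits[d, ] <- fp
  }

  ## --- responses: base effects + smooth terms + noise ------------------
  base <- matrix(stats::rnorm(cfg$n_cell_clusters * n_templates),
                 cfg$n_cell_clusters, n_templates)
  cell_latent <- stats::rnorm(cfg$n_cells)
  drug_latent <- stats::rnorm(cfg$n_drugs)
  resp <- base[cell_cluster, response_group, drop = FALSE] +
    cfg$noise_sd * 0.5 * outer(cell_latent, drug_latent, "+") +
    matrix(stats::rnorm(cfg$n_cells * cfg$n_drugs, sd = cfg$noise_sd),
           cfg$n_cells, cfg$n_drugs)
  ## per-drug rescale to range 1, baseline 0 (the normalized scale)
  for (j in seq_len(cfg$n_drugs)) {
    rng <- max(resp[, j]) - min(resp[, j])
    if (rng > 0) {
      v <- (resp[, j] - min(resp[, j])) / rng
      resp[, j] <- v - mean(v)
    }
  }
  dimnames(resp) <- list(cell_ids, drug_ids)

  full <- resp
  n_missing <- round(cfg$missing_fraction * length(resp))
  hidden_idx <- if (n_missing > 0) {
    sample(seq_along(resp), n_missing)
  } else {
    integer(0)
  }
  resp[hidden_idx] <- NA_real_

  structure(list(
    expression = expression_matrix(expr),
    fingerprints = fingerprint_set(bits),
    response = response_matrix(resp, direction = "higher_is_sensitive"),
    truth = list(
      cell_cluster = setNames(cell_cluster, cell_ids),
      drug_cluster = setNames(drug_cluster, drug_ids),
      response_group = setNames(response_group, drug_ids),
      background_drug = setNames(background, drug_ids),
      base_effects = base,
      full_values = full,
      hidden = tibble(
        cell_id = cell_ids[row(full)[hidden_idx]],
        drug_id = drug_ids[col(full)[hidden_idx]],
        value = full[hidden_idx]),
      config = cfg)
  ), class = "cdcn_synthetic")
}

#' @export
print.cdcn_synthetic <- function(x, ...) {
  cfg <- x$truth$config
  cat("<cdcn_synthetic> ", cfg$n_cells, " cells x ", cfg$n_drugs,
      " drugs (", cfg$n_genes, " genes, ", cfg$n_bits, " bits)\n", sep = "")
  cat("  clusters: ", cfg$n_cell_clusters, " cell x ", cfg$n_drug_clusters,
      " drug; noise_sd = ", cfg$noise_sd, "; hidden = ",
      nrow(x$truth$hidden), " entries; seed = ", cfg$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to a directory in the standard text formats
#'
#' Writes `expression.tsv`, `fingerprints.tsv` (ID + bitstring),
#' `response.tsv`, and `truth.json` (cluster assignments and hidden
#' entries) to `dir`.
#'
#' @param x A `cdcn_synthetic` from [generate_synthetic()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(x, dir) {
  stopifnot(inherits(x, "cdcn_synthetic"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(x$expression$values, file.path(dir, "expression.tsv"),
               id_col = "gene_id")
  readr::write_tsv(
    tibble(drug_id = rownames(x$fingerprints$bits),
           bits = apply(x$fingerprints$bits, 1, paste, collapse = "")),
    file.path(dir, "fingerprints.tsv"), col_names = FALSE, progress = FALSE)
  write_matrix(x$response, file.path(dir, "response.tsv"))
  jsonlite::write_json(
    list(cell_cluster = as.list(x$truth$cell_cluster),
         drug_cluster = as.list(x$truth$drug_cluster),
         background_drug = as.list(x$truth$background_drug),
         hidden = x$truth$hidden,
         seed = x$truth$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
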
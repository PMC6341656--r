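## Independent oracles and fixture builders shared across the suite.

## Naive double-loop implementation of the kernel-weighted estimator:
## deliberately the most literal possible transcription, kept independent
## of the package's vectorized path.
naive_predict <- function(values, observed, rho, tani, alpha, tau,
                          model, ci, dj) {
  num <- 0
  den <- 0
  for (i in seq_len(nrow(values))) {
    for (j in seq_len(ncol(values))) {
      if (!observed[i, j]) next
      if (model == 1 && i == ci && j == dj) next
      if (model == 2 && (i == ci || j == dj)) next
      w <- exp(-(1 - rho[ci, i])^2 / (2 * alpha^2)) *
        exp(-(1 - tani[dj, j])^2 / (2 * tau^2))
      num <- num + w * values[i, j]
      den <- den + w
    }
  }
  if (den < 1e-300) NA_real_ else num / den
}

naive_predict_matrix <- function(rm, csm, dsm, alpha, tau, model) {
  rho <- csm$sim[rownames(rm$values), rownames(rm$values)]
  tani <- dsm$sim[colnames(rm$values), colnames(rm$values)]
  out <- rm$values * NA_real_
  for (ci in seq_len(nrow(out))) {
    for (dj in seq_len(ncol(out))) {
      out[ci, dj] <- naive_predict(rm$values, rm$observed, rho, tani,
                                   alpha, tau, model, ci, dj)
    }
  }
  out
}

## Random test instance: response matrix with missing entries plus valid
## similarity layers derived from random expression and fingerprints.
random_instance <- function(n_cells, n_drugs, seed, miss_prob = 0.2) {
  set.seed(seed)
  vals <- matrix(rnorm(n_cells * n_drugs), n_cells, n_drugs,
                 dimnames = list(sprintf("C%02d", seq_len(n_cells)),
                                 sprintf("D%02d", seq_len(n_drugs))))
  vals[runif(length(vals)) < miss_prob] <- NA_real_
  if (all(is.na(vals))) vals[1, 1] <- 0.5
  em <- expression_matrix(matrix(
    rnorm(10 * n_cells), 10, n_cells,
    dimnames = list(sprintf("G%02d", 1:10), rownames(vals))))
  bits <- matrix(rbinom(n_drugs * 32, 1, 0.5), n_drugs, 32,
                 dimnames = list(colnames(vals), NULL))
  bits[rowSums(bits) == 0, 1] <- 1L
  list(rm = response_matrix(vals),
       csm = cell_similarity(em),
       dsm = drug_similarity(fingerprint_set(bits)))
}

## Similarity object with prescribed entries (for controlled-kernel tests).
manual_similarity <- function(sim, type) {
  cdcn:::new_similarity(sim, type)
}

## Brute-force complete linkage: recompute the max inter-cluster distance
## at every step and merge the closest pair. Returns merge heights in order.
bf_complete_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        h <- max(d[clusters[[a]], clusters[[b]]])
        if (h < best_h) {
          best_h <- h
          best <- c(a, b)
        }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_h)
  }
  heights
}

## All set partitions of 1..n (Bell(n) of them).
set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in set_partitions(n - 1)) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out <- c(out, list(q))
    }
    out <- c(out, list(c(p, list(n))))
  }
  out
}

## Canonical form of a partition (sorted blocks) for comparison.
canon_partition <- function(blocks) {
  blocks <- lapply(blocks, function(b) sort(as.integer(b)))
  blocks[order(vapply(blocks, min, numeric(1)))]
}

membership_to_blocks <- function(m) {
  canon_partition(unname(split(seq_along(m), m)))
}

## Shared synthetic defaults used by the simulation-based checks.
default_synth <- function(seed) {
  generate_synthetic(synth_config(seed = seed))
}
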
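## Downstream assessment: sensitive/resistant classification and its
## metrics, ROC/AUC, goodness of fit, nearest-neighbour imputation baseline,
## random-deletion benchmarking, two-group comparison, and the generalized
## observation analysis that motivates the network model.

#' Classify cell lines as sensitive or resistant to one drug
#'
#' With at least `2 * top_n` cell lines, the `top_n` with the largest
#' responses are labelled sensitive and the `top_n` with the smallest
#' resistant; the rest are intermediate. With fewer cell lines the fallback
#' sign rule applies: responses above zero are sensitive, below zero
#' resistant, exactly zero intermediate (on the mean-centred normalized
#' scale, zero is the per-drug baseline). Values must be oriented so that
#' higher means more sensitive. Boundary ties are resolved by cell-ID order
#' so that group sizes are exactly `top_n`.
#'
#' @param values Named numeric vector of per-cell responses for one drug
#'   (names = cell IDs); `NA` entries are dropped (unlabelled).
#' @param top_n Group size for the top/bottom rule (default 200).
#' @return A tibble with `cell_id` and `label` (factor: sensitive,
#'   intermediate, resistant).
#' @export
classify_cells <- function(values, top_n = 200) {
  if (is.null(names(values))) abort("`values` must be named by cell ID.")
  values <- values[!is.na(values)]
  if (length(values) < 2) abort("need at least 2 labelled cells.")
  ids <- names(values)
  label <- rep("intermediate", length(values))
  if (length(values) >= 2 * top_n) {
    ## one total order (response desc, ID asc) drives both boundaries
    perm <- order(-values, ids)
    label[perm[seq_len(top_n)]] <- "sensitive"
    label[perm[seq(length(values) - top_n + 1, length(values))]] <- "resistant"
  } else {
    label[values > 0] <- "sensitive"
    label[values < 0] <- "resistant"
  }
  tibble(cell_id = ids,
         label = factor(label,
                        levels = c("sensitive", "intermediate", "resistant")))
}

#' Confusion-matrix metrics for sensitive/resistant labels
#'
#' Cells labelled intermediate in either label set are excluded pairwise;
#' sensitive is the positive class.
#'
#' @param true_labels,pred_labels Tibbles from [classify_cells()] (columns
#'   `cell_id`, `label`) on the same cells.
#' @return A one-row tibble: `accuracy`, `sensitivity`, `specificity`, and
#'   the counts `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_metrics <- function(true_labels, pred_labels) {
  joined <- dplyr::inner_join(true_labels, pred_labels, by = "cell_id",
                              suffix = c("_true", "_pred"))
  joined <- dplyr::filter(joined,
                          .data$label_true != "intermediate",
                          .data$label_pred != "intermediate")
  if (nrow(joined) == 0) {
    abort("no cells labelled sensitive/resistant in both label sets.")
  }
  tp <- sum(joined$label_true == "sensitive" & joined$label_pred == "sensitive")
  tn <- sum(joined$label_true == "resistant" & joined$label_pred == "resistant")
  fp <- sum(joined$label_true == "resistant" & joined$label_pred == "sensitive")
  fn <- sum(joined$label_true == "sensitive" & joined$label_pred == "resistant")
  tibble(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    tp = tp, tn = tn, fp = fp, fn = fn
  )
}

#' Goodness of fit between observed and predicted responses
#'
#' The coefficient of determination of the identity fit,
#' `R^2 = 1 - SS_res / SS_tot`, where `SS_res = sum((pred - obs)^2)` and
#' `SS_tot = sum((obs - mean(obs))^2)`. Can be negative when predictions
#' are worse than the observed mean.
#'
#' @param observed,predicted Numeric vectors of equal length, n >= 2.
#' @return A single number, or `NA` with a warning when the observed
#'   variance is zero.
#' @export
goodness_of_fit <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    warn("zero observed variance: goodness of fit undefined, reported NA.")
    return(NA_real_)
  }
  1 - sum((predicted - observed)^2) / ss_tot
}

#' Area under the ROC curve by the rank statistic
#'
#' The probability that a randomly chosen sensitive cell line outscores a
#' randomly chosen resistant one, with ties counting one half — computed
#' from the Wilcoxon rank sum of the positive class.
#'
#' @param scores Numeric prediction scores (higher = more sensitive).
#' @param labels Logical (`TRUE` = sensitive) or a factor/character vector
#'   in which `"sensitive"` marks the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (!is.logical(labels)) labels <- as.character(labels) == "sensitive"
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("roc_auc needs both a sensitive and a resistant class.")
  }
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Nearest-neighbour imputation of a single response
#'
#' Baseline imputation: the mean response, for the target cell line, of the
#' `k` drugs structurally nearest to the target drug (distance
#' `1 - Tanimoto`) among drugs with an observed response for that cell. If
#' fewer than `k` are available, all available are used. Distance ties at
#' the k-th neighbour are broken by drug-ID order.
#'
#' @param rm A [response_matrix()].
#' @param dsm A drug `cdcn_similarity`.
#' @param cell,drug Target identifiers.
#' @param k Number of neighbours (>= 1).
#' @return The imputed response.
#' @export
knn_impute <- function(rm, dsm, cell, drug, k = 1) {
  stopifnot(inherits(rm, "cdcn_response"),
            inherits(dsm, "cdcn_similarity"), dsm$type == "drug")
  if (k < 1) abort("`k` must be >= 1.")
  ci <- match(cell, rownames(rm$values))
  dj <- match(drug, colnames(rm$values))
  if (is.na(ci)) abort(paste0("unknown cell line '", cell, "'."))
  if (is.na(dj)) abort(paste0("unknown drug '", drug, "'."))
  drugs <- colnames(rm$values)
  if (!all(drugs %in% dsm$ids)) {
    abort(paste0("drug '", setdiff(drugs, dsm$ids)[1],
                 "' missing from the drug similarity matrix."))
  }
  avail <- which(rm$observed[ci, ] & drugs != drug)
  if (length(avail) == 0) {
    abort(paste0("no observed drug response for cell line '", cell, "'."))
  }
  d <- 1 - dsm$sim[drugs[dj], drugs[avail]]
  ord <- order(d, drugs[avail])
  take <- avail[ord][seq_len(min(k, length(avail)))]
  mean(rm$values[ci, take])
}

#' Fold change and Welch t-test between two response groups
#'
#' @param values_a,values_b Numeric vectors with at least 2 values each
#'   (e.g. responses of mutant vs wild-type cell lines to one drug).
#' @return A one-row tibble: `fold_change` (`mean(a) / mean(b)`; `NA` with a
#'   warning when `mean(b)` is zero), `t_statistic`, `p_value` (two-sided
#'   Welch two-sample t-test), `mean_a`, `mean_b`.
#' @export
group_comparison <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  tt <- t.test(values_a, values_b)
  fc <- if (mean(values_b) == 0) {
    warn("mean of group b is zero: fold change undefined, reported NA.")
    NA_real_
  } else {
    mean(values_a) / mean(values_b)
  }
  tibble(fold_change = fc,
         t_statistic = unname(tt$statistic),
         p_value = tt$p.value,
         mean_a = mean(values_a), mean_b = mean(values_b))
}

#' Response correlations across similarity groups (generalized observation)
#'
#' The empirical motivation of the network model: genetically similar cell
#' lines show higher response correlations over structurally similar drugs.
#' For every cell-line pair (labelled `Hc`/`Lc` by expression correlation)
#' and each drug group (`Hd`/`Ld` by structural similarity), the Pearson
#' correlation of the two cells' response vectors is computed over the
#' drugs of that group observed in both cells; pairs with fewer than
#' `min_overlap` shared drugs in a group are skipped for that group.
#'
#' @param rm A [response_matrix()].
#' @param partition A `cdcn_partition` from [partition_pairs()].
#' @param min_overlap Minimum shared observed drugs per group (default 3).
#' @return A tibble of class `cdcn_observation`: `cell_i`, `cell_j`,
#'   `cell_group`, `drug_group`, `n_overlap`, `r`. See
#'   [autoplot.cdcn_observation()].
#' @export
observation_analysis <- function(rm, partition, min_overlap = 3) {
  stopifnot(inherits(rm, "cdcn_response"),
            inherits(partition, "cdcn_partition"))
  drug_sets <- split(partition$drug_groups$drug_id,
                     partition$drug_groups$group)
  for (g in c("Hd", "Ld")) {
    n_in <- sum(drug_sets[[g]] %in% colnames(rm$values))
    if (is.null(drug_sets[[g]]) || n_in < min_overlap) {
      abort(paste0("drug group ", g, " has fewer than min_overlap (",
                   min_overlap, ") drugs in the response matrix."))
    }
  }
  cp <- partition$cell_pairs
  keep <- cp$cell_i %in% rownames(rm$values) &
    cp$cell_j %in% rownames(rm$values)
  cp <- cp[keep, ]
  out <- purrr::map_dfr(c("Hd", "Ld"), function(g) {
    cols <- match(intersect(drug_sets[[g]], colnames(rm$values)),
                  colnames(rm$values))
    vals <- rm$values[, cols, drop = FALSE]
    obs <- rm$observed[, cols, drop = FALSE]
    i <- match(cp$cell_i, rownames(rm$values))
    j <- match(cp$cell_j, rownames(rm$values))
    r <- vapply(seq_len(nrow(cp)), function(p) {
      both <- obs[i[p], ] & obs[j[p], ]
      if (sum(both) < min_overlap) return(NA_real_)
      a <- vals[i[p], both]
      b <- vals[j[p], both]
      if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
      cor(a, b)
    }, numeric(1))
    n_overlap <- vapply(seq_len(nrow(cp)), function(p) {
      sum(obs[i[p], ] & obs[j[p], ])
    }, integer(1))
    tibble(cell_i = cp$cell_i, cell_j = cp$cell_j,
           cell_group = cp$group, drug_group = g,
           n_overlap = n_overlap, r = r)
  })
  out <- out[!is.na(out$r), ]
  class(out) <- c("cdcn_observation", class(out))
  out
}

#' Benchmark imputation methods by random deletion
#'
#' Hides a random fraction of the observed responses, imputes them with the
#' network model (model 1) and with the nearest-neighbour baseline at each
#' requested `k`, and scores each method by the Pearson correlation between
#' the hidden truth and its imputations; repeated `n_repeats` times. The
#' whole procedure is reproducible bit-for-bit under a fixed `seed`.
#'
#' @inheritParams predict_pair
#' @param fraction Fraction of observed entries to hide, in `(0, 1)`.
#' @param n_repeats Number of deletion rounds (default 5).
#' @param seed Integer seed driving the random deletions.
#' @param ks Neighbour counts for the kNN baseline (default 1, 3, 5, 7).
#' @param methods Subset of `c("cdcn", "knn")`.
#' @return A list with `per_repeat` (tibble: method, k, repeat index, r,
#'   n_hidden) and `summary` (tibble: method, k, mean_r).
#' @export
random_deletion_benchmark <- function(rm, csm, dsm, alpha, tau,
                                      fraction = 0.1, n_repeats = 5,
                                      seed = 1, ks = c(1, 3, 5, 7),
                                      methods = c("cdcn", "knn")) {
  check_params(alpha, tau)
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must lie in (0, 1).")
  methods <- match.arg(methods, several.ok = TRUE)
  obs_idx <- which(rm$observed)
  n_hide <- round(fraction * length(obs_idx))
  if (n_hide < 3) abort("fewer than 3 entries would be hidden; correlation needs >= 3.")
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  rows <- row(rm$values)[obs_idx]
  cols <- col(rm$values)[obs_idx]
  per_repeat <- purrr::map_dfr(seq_len(n_repeats), function(rep_i) {
    hide <- sample(seq_along(obs_idx), n_hide)
    truth <- rm$values[obs_idx[hide]]
    masked <- rm
    masked$values[obs_idx[hide]] <- NA_real_
    masked$observed[obs_idx[hide]] <- FALSE
    res <- list()
    if ("cdcn" %in% methods) {
      imp <- suppressWarnings(
        impute_missing(masked, csm, dsm, alpha, tau, model = 1))
      est <- imp$values[obs_idx[hide]]
      est[!imp$imputed[obs_idx[hide]]] <- NA_real_
      ok <- !is.na(est)
      res$cdcn <- tibble(method = "cdcn", k = NA_integer_, rep = rep_i,
                         r = cor(truth[ok], est[ok]), n_hidden = n_hide)
    }
    if ("knn" %in% methods) {
      res$knn <- purrr::map_dfr(ks, function(k) {
        est <- vapply(seq_along(hide), function(h) {
          tryCatch(
            knn_impute(masked, dsm,
                       cell = rownames(rm$values)[rows[hide[h]]],
                       drug = colnames(rm$values)[cols[hide[h]]], k = k),
            error = function(e) NA_real_)
        }, numeric(1))
        ok <- !is.na(est)
        tibble(method = "knn", k = as.integer(k), rep = rep_i,
               r = cor(truth[ok], est[ok]), n_hidden = n_hide)
      })
    }
    dplyr::bind_rows(res)
  })
  summary <- dplyr::summarise(
    dplyr::group_by(per_repeat, .data$method, .data$k),
    mean_r = mean(.data$r), .groups = "drop")
  list(per_repeat = per_repeat, summary = summary)
}
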
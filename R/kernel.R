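## The network estimator. A prediction for a pair (C, D) is the
## kernel-weighted average of observed responses R(Ci, Dj),
##
##   Rhat(C, D) = sum_ij w(C, Ci) w(D, Dj) R(Ci, Dj) /
##                sum_ij w(C, Ci) w(D, Dj)
##
## with Gaussian weights w(C, Ci) = exp(-(1 - rho(C, Ci))^2 / (2 alpha^2))
## in the cell-line layer and the analogous Tanimoto-based weight with
## bandwidth tau in the drug layer. Model I sums over every observed pair
## except the target itself; model II additionally drops every pair sharing
## the target's cell line or drug (the "new drug to new cell line" setting).
##
## All predictions are computed for the whole matrix at once with weight
## matrices Wc (cells) and Wd (drugs), M = R * mask and K = mask. The
## exclusions are expressed through zero-diagonal weight matrices Wc0/Wd0
## (both layers have exact unit diagonals), so every contributing set is a
## plain sum of its own terms:
##   all pairs:                Wc M Wd
##   all but the target:       Wc0 M Wd + M Wd0   (i != c, plus i = c & j != d)
##   neither row nor column:   Wc0 M Wd0
## Subtracting the excluded terms from the full sum instead would cancel
## catastrophically whenever the remaining weights are small.

DENOM_TOL <- 1e-300

#' Gaussian similarity kernel weight
#'
#' `w(s) = exp(-(1 - s)^2 / (2 decay^2))`: equals 1 at similarity 1 and
#' decays as similarity drops, faster for small `decay`. Negative
#' similarities are used as-is; the quadratic exponent makes their weights
#' vanishingly small without truncation.
#'
#' @param similarity Similarity value(s): Pearson correlation for cell
#'   lines, Tanimoto coefficient for drugs.
#' @param decay Positive kernel bandwidth (alpha for cells, tau for drugs).
#' @return Weight(s) in `(0, 1]`.
#' @examples
#' cdcn_weight(0.9, 0.1)  # exp(-0.5)
#' @export
cdcn_weight <- function(similarity, decay) {
  if (!is.numeric(decay) || any(decay <= 0)) {
    abort("`decay` must be strictly positive.")
  }
  exp(-(1 - similarity)^2 / (2 * decay^2))
}

check_params <- function(alpha, tau) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0) {
    abort("`alpha` must be a single value > 0.")
  }
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0) {
    abort("`tau` must be a single value > 0.")
  }
}

check_model <- function(model) {
  m <- as.character(model)
  if (m %in% c("1", "I", "i")) return(1L)
  if (m %in% c("2", "II", "ii")) return(2L)
  abort("`model` must be 1 (\"I\") or 2 (\"II\").")
}

## Reorder similarity matrices to match the response matrix's id order.
align_network <- function(rm, csm, dsm) {
  stopifnot(inherits(rm, "cdcn_response"),
            inherits(csm, "cdcn_similarity"), csm$type == "cell",
            inherits(dsm, "cdcn_similarity"), dsm$type == "drug")
  cells <- rownames(rm$values)
  drugs <- colnames(rm$values)
  if (!all(cells %in% csm$ids)) {
    abort(paste0("cell line '", setdiff(cells, csm$ids)[1],
                 "' missing from the cell similarity matrix."))
  }
  if (!all(drugs %in% dsm$ids)) {
    abort(paste0("drug '", setdiff(drugs, dsm$ids)[1],
                 "' missing from the drug similarity matrix."))
  }
  list(rho = csm$sim[cells, cells, drop = FALSE],
       tani = dsm$sim[drugs, drugs, drop = FALSE])
}

## Matrix of predictions for every pair. `exclude` picks the contributing
## set: "target" drops only the target pair where observed (model I under
## LOOCV), "row_col" drops all pairs sharing the target's cell line or drug
## (model II), "none" uses the full observed set (model I, in-sample or for
## unobserved targets). Pairs whose contributing set is empty (or whose
## weights underflow to zero) get NA.
predict_matrix <- function(rm, net, alpha, tau, exclude) {
  M <- rm$values
  M[!rm$observed] <- 0
  K <- rm$observed * 1
  Wc0 <- cdcn_weight(net$rho, alpha)
  diag(Wc0) <- 0
  Wd0 <- cdcn_weight(net$tani, tau)
  diag(Wd0) <- 0
  if (exclude == "target") {
    N <- Wc0 %*% M %*% (Wd0 + diag(ncol(M))) + M %*% Wd0
    D <- Wc0 %*% K %*% (Wd0 + diag(ncol(M))) + K %*% Wd0
  } else if (exclude == "row_col") {
    N <- Wc0 %*% M %*% Wd0
    D <- Wc0 %*% K %*% Wd0
  } else {
    N <- (Wc0 %*% M + M) %*% Wd0 + (Wc0 %*% M + M)
    D <- (Wc0 %*% K + K) %*% Wd0 + (Wc0 %*% K + K)
  }
  pred <- N / D
  pred[D < DENOM_TOL] <- NA_real_
  dimnames(pred) <- dimnames(rm$values)
  pred
}

#' Predict the response of a single cell line-drug pair
#'
#' Model 1 averages every observed response except the target pair itself
#' (applicable to all prediction scenarios); model 2 restricts the sum to
#' pairs sharing neither the target's cell line nor its drug, which is the
#' estimator for a completely untested drug on a completely untested cell
#' line.
#'
#' @param rm A [response_matrix()].
#' @param csm,dsm Cell and drug `cdcn_similarity` objects covering the
#'   response matrix's identifiers.
#' @param cell,drug Target identifiers (must be present in `rm`).
#' @param alpha,tau Kernel bandwidths in `(0, 1]` for the cell-line and
#'   drug layers.
#' @param model `1` (or `"I"`) or `2` (or `"II"`).
#' @return The predicted response (a single number).
#' @export
predict_pair <- function(rm, csm, dsm, cell, drug, alpha, tau, model = 1) {
  check_params(alpha, tau)
  model <- check_model(model)
  net <- align_network(rm, csm, dsm)
  ci <- match(cell, rownames(rm$values))
  dj <- match(drug, colnames(rm$values))
  if (is.na(ci)) abort(paste0("unknown cell line '", cell, "'."))
  if (is.na(dj)) abort(paste0("unknown drug '", drug, "'."))
  wc <- cdcn_weight(net$rho[ci, ], alpha)
  wd <- cdcn_weight(net$tani[dj, ], tau)
  W <- outer(wc, wd)
  keep <- rm$observed
  if (model == 1L) {
    keep[ci, dj] <- FALSE
  } else {
    keep[ci, ] <- FALSE
    keep[, dj] <- FALSE
  }
  den <- sum(W[keep])
  if (!any(keep) || den < DENOM_TOL) {
    abort("no observed responses available for this prediction.")
  }
  sum(W[keep] * rm$values[keep]) / den
}

#' Leave-one-out cross-validated predictions with per-drug metrics
#'
#' Holds out each observed pair in turn, predicts it from the remaining
#' observations with the requested model, and summarises agreement per drug
#' (Pearson r, RMSE, NRMSE). Pairs whose contributing set is empty yield a
#' missing prediction, are excluded from the metrics, and are counted in a
#' warning.
#'
#' @inheritParams predict_pair
#' @param loocv If `FALSE`, model 1 predictions are in-sample (the target
#'   pair is not held out); model 2 excludes the target's row and column by
#'   construction, so the flag has no effect there.
#' @return A `cdcn_fit` object; see [tidy.cdcn_fit()] and
#'   [glance.cdcn_fit()] for tibble views.
#' @export
loocv_predict <- function(rm, csm, dsm, alpha, tau, model = 1, loocv = TRUE) {
  check_params(alpha, tau)
  model <- check_model(model)
  net <- align_network(rm, csm, dsm)
  exclude <- if (model == 2L) "row_col" else if (loocv) "target" else "none"
  pred <- predict_matrix(rm, net, alpha, tau, exclude)
  n_failed <- sum(rm$observed & is.na(pred))
  if (n_failed > 0) {
    warn(paste0(n_failed, " observed pair(s) had an empty contributing set",
                " and were excluded from the metrics."))
  }
  per_drug <- per_drug_metrics(rm, pred)
  structure(
    list(predicted = pred, observed = rm$observed, actual = rm$values,
         model = model, alpha = alpha, tau = tau, loocv = loocv,
         per_drug = per_drug, n_failed = n_failed),
    class = "cdcn_fit"
  )
}

per_drug_metrics <- function(rm, pred) {
  purrr::map_dfr(seq_len(ncol(rm$values)), function(j) {
    use <- rm$observed[, j] & !is.na(pred[, j])
    obs <- rm$values[use, j]
    est <- pred[use, j]
    n <- sum(use)
    r <- if (n >= 2 && sd(obs) > 0 && sd(est) > 0) cor(obs, est) else NA_real_
    e <- if (n >= 1) suppressWarnings(drug_rmse_nrmse(obs, est)) else
      tibble(rmse = NA_real_, nrmse = NA_real_)
    tibble(drug_id = colnames(rm$values)[j], n = n,
           pearson_r = r, rmse = e$rmse, nrmse = e$nrmse)
  })
}

#' RMSE and range-normalized RMSE between observed and predicted responses
#'
#' `RMSE = sqrt(mean((predicted - observed)^2))`;
#' `NRMSE = RMSE / (max(observed) - min(observed))`. The NRMSE is undefined
#' (returned as `NA` with a warning) when the observed range is zero.
#'
#' @param observed,predicted Numeric vectors of equal length (n >= 1).
#' @return A one-row tibble with columns `rmse` and `nrmse`.
#' @export
drug_rmse_nrmse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 1)
  rmse <- sqrt(mean((predicted - observed)^2))
  rng <- max(observed) - min(observed)
  if (length(observed) < 2 || rng == 0) {
    warn("zero observed range: NRMSE undefined, reported as NA.")
    nrmse <- NA_real_
  } else {
    nrmse <- rmse / rng
  }
  tibble(rmse = rmse, nrmse = nrmse)
}

#' Tune the kernel bandwidths by grid search
#'
#' Minimises the overall squared prediction error
#' `sum over observed pairs of (Rhat(C, D) - R(C, D))^2` over a regular grid
#' of bandwidth pairs `alpha, tau in {grid_step, 2 grid_step, ..., 1}`,
#' with `Rhat` computed by leave-one-out cross-validation (or in-sample for
#' model 1 when `loocv = FALSE`). The grid starts at `grid_step` rather than
#' zero because a zero bandwidth makes the Gaussian weight degenerate. Exact
#' ties in the error are broken towards the lexicographically smallest
#' `(alpha, tau)`.
#'
#' At very narrow bandwidths the weights of dissimilar pairs can underflow
#' to zero, leaving some targets with an empty contributing set and no
#' prediction. Error sums are only comparable across bandwidths on a common
#' prediction set, so grid points that predict fewer pairs than the
#' best-covering grid point are disqualified from the argmin (their error
#' is still reported on the surface, along with `n_ok`, the number of
#' pairs they predict).
#'
#' @inheritParams loocv_predict
#' @param grid_step Grid increment in `(0, 1)`; the published analyses use
#'   0.01.
#' @return A `cdcn_grid` object with elements `alpha`, `tau` (the argmin),
#'   `sse`, `surface` (tibble of the full error surface), `model`; see
#'   [tidy.cdcn_grid()] / [glance.cdcn_grid()].
#' @export
grid_search <- function(rm, csm, dsm, model = 1, grid_step = 0.01,
                        loocv = TRUE) {
  if (!is.numeric(grid_step) || grid_step <= 0 || grid_step >= 1) {
    abort("`grid_step` must lie in (0, 1).")
  }
  model <- check_model(model)
  net <- align_network(rm, csm, dsm)
  grid <- seq(grid_step, 1, by = grid_step)
  M <- rm$values
  M[!rm$observed] <- 0
  K <- rm$observed * 1
  exclude <- if (model == 2L) "row_col" else if (loocv) "target" else "none"
  Wd0_list <- lapply(grid, function(tau) {
    W <- cdcn_weight(net$tani, tau)
    diag(W) <- 0
    W
  })
  MWd0 <- lapply(Wd0_list, function(W) M %*% W)
  KWd0 <- lapply(Wd0_list, function(W) K %*% W)
  surface <- vector("list", length(grid))
  for (a in seq_along(grid)) {
    Wc0 <- cdcn_weight(net$rho, grid[a])
    diag(Wc0) <- 0
    P <- Wc0 %*% M
    Q <- Wc0 %*% K
    sse_row <- numeric(length(grid))
    n_ok_row <- integer(length(grid))
    for (t in seq_along(grid)) {
      Wd0 <- Wd0_list[[t]]
      if (exclude == "target") {
        N <- P %*% Wd0 + P + MWd0[[t]]
        D <- Q %*% Wd0 + Q + KWd0[[t]]
      } else if (exclude == "row_col") {
        N <- P %*% Wd0
        D <- Q %*% Wd0
      } else {
        N <- (P + M) %*% Wd0 + P + M
        D <- (Q + K) %*% Wd0 + Q + K
      }
      pred <- N / D
      ok <- rm$observed & D >= DENOM_TOL
      sse_row[t] <- sum((pred[ok] - rm$values[ok])^2)
      n_ok_row[t] <- sum(ok)
    }
    surface[[a]] <- tibble(alpha = grid[a], tau = grid, sse = sse_row,
                           n_ok = n_ok_row)
  }
  surface <- dplyr::bind_rows(surface)
  ## surface rows are in lexicographic (alpha, tau) order, so the first
  ## minimum among fully-covering grid points honours the tie-break.
  eligible <- surface$n_ok == max(surface$n_ok)
  best_sse <- min(surface$sse[eligible])
  best <- which(eligible & surface$sse == best_sse)[1]
  structure(
    list(alpha = surface$alpha[best], tau = surface$tau[best],
         sse = surface$sse[best], surface = surface, model = model,
         grid_step = grid_step, loocv = loocv),
    class = "cdcn_grid"
  )
}

#' Fill the missing entries of a response matrix
#'
#' Every unobserved cell is filled with the model prediction from all
#' observed responses; observed cells are untouched. Filled cells are
#' marked in the `imputed` mask (distinct from `observed`). Cells whose
#' contributing set is empty remain missing, with a warning.
#'
#' @inheritParams predict_pair
#' @return A `cdcn_response` with imputed values and updated `imputed` mask.
#' @export
impute_missing <- function(rm, csm, dsm, alpha, tau, model = 1) {
  check_params(alpha, tau)
  model <- check_model(model)
  net <- align_network(rm, csm, dsm)
  exclude <- if (model == 2L) "row_col" else "target"
  pred <- predict_matrix(rm, net, alpha, tau, exclude)
  out <- rm
  fill <- !rm$observed & !is.na(pred)
  out$values[fill] <- pred[fill]
  out$imputed <- out$imputed | fill
  left <- sum(!rm$observed & is.na(pred))
  if (left > 0) {
    warn(paste0(left, " missing entr(ies) had an empty contributing set",
                " and were left unfilled."))
  }
  out
}
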
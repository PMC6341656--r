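test_that("the Gaussian kernel weight matches its closed form", {
  expect_equal(cdcn_weight(1, 0.37), 1)
  expect_equal(cdcn_weight(0.9, 0.1), exp(-0.5), tolerance = 1e-15)
  s <- seq(-1, 1, by = 0.05)
  w <- cdcn_weight(s, 0.2)
  expect_true(all(diff(w) > 0))          # strictly increasing in similarity
  expect_true(all(w > 0 & w <= 1))
  expect_error(cdcn_weight(0.5, 0), "positive")
  expect_error(cdcn_weight(0.5, -1), "positive")
})

test_that("model I reduces to the mean under uniform weights and to the only
           contributor when a single pair is available", {
  ids <- list(paste0("C", 1:3), paste0("D", 1:3))
  vals <- matrix(1:9, 3, 3, dimnames = ids)
  rm <- response_matrix(vals)
  ones_c <- manual_similarity(
    matrix(1, 3, 3, dimnames = ids[c(1, 1)]), "cell")
  ones_d <- manual_similarity(
    matrix(1, 3, 3, dimnames = ids[c(2, 2)]), "drug")
  ## all similarities 1 -> all weights equal -> arithmetic mean of others
  expect_equal(predict_pair(rm, ones_c, ones_d, "C1", "D1", 0.3, 0.3),
               mean(vals[-1]), tolerance = 1e-12)

  ## a single other observed pair is returned verbatim whatever the weights
  vals2 <- matrix(NA_real_, 3, 3, dimnames = ids)
  vals2[1, 1] <- 5
  vals2[3, 2] <- 0.7
  rm2 <- response_matrix(vals2)
  inst <- random_instance(3, 3, seed = 41, miss_prob = 0)
  csm <- manual_similarity(
    `dimnames<-`(inst$csm$sim, ids[c(1, 1)]), "cell")
  dsm <- manual_similarity(
    `dimnames<-`(inst$dsm$sim, ids[c(2, 2)]), "drug")
  expect_equal(predict_pair(rm2, csm, dsm, "C1", "D1", 0.2, 0.9), 0.7,
               tolerance = 1e-12)
})

test_that("model II uses only pairs sharing neither cell line nor drug", {
  ids <- list(c("C1", "C2"), c("D1", "D2"))
  vals <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = ids)
  rm <- response_matrix(vals)
  inst <- random_instance(2, 2, seed = 42, miss_prob = 0)
  csm <- manual_similarity(`dimnames<-`(inst$csm$sim, ids[c(1, 1)]), "cell")
  dsm <- manual_similarity(`dimnames<-`(inst$dsm$sim, ids[c(2, 2)]), "drug")
  ## only R(C2, D2) is admissible for target (C1, D1)
  expect_equal(predict_pair(rm, csm, dsm, "C1", "D1", 0.5, 0.5, model = 2),
               vals["C2", "D2"])
  ## a fully observed row+column leaves model II with nothing
  vals2 <- matrix(c(1, 2, 3, NA), 2, 2, dimnames = ids)
  expect_error(
    predict_pair(response_matrix(vals2), csm, dsm, "C1", "D1", 0.5, 0.5,
                 model = 2),
    "no observed responses")
})

test_that("vectorized predictions equal the naive double-loop oracle", {
  for (seed in 1:10) {
    set.seed(seed + 100)
    n_c <- sample(3:8, 1)
    n_d <- sample(3:8, 1)
    inst <- random_instance(n_c, n_d, seed = seed)
    alpha <- runif(1, 0.05, 0.9)
    tau <- runif(1, 0.05, 0.9)
    for (model in 1:2) {
      fit <- suppressWarnings(
        loocv_predict(inst$rm, inst$csm, inst$dsm, alpha, tau, model))
      oracle <- naive_predict_matrix(inst$rm, inst$csm, inst$dsm,
                                     alpha, tau, model)
      obs <- inst$rm$observed
      expect_equal(fit$predicted[obs], oracle[obs], tolerance = 1e-12)
    }
  }
})

test_that("held-out LOOCV predictions equal the single-pair predictor", {
  inst <- random_instance(4, 3, seed = 7, miss_prob = 0.15)
  fit <- loocv_predict(inst$rm, inst$csm, inst$dsm, 0.3, 0.4, model = 1)
  idx <- which(inst$rm$observed, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    expect_equal(
      fit$predicted[idx[k, 1], idx[k, 2]],
      predict_pair(inst$rm, inst$csm, inst$dsm,
                   rownames(inst$rm$values)[idx[k, 1]],
                   colnames(inst$rm$values)[idx[k, 2]], 0.3, 0.4, model = 1),
      tolerance = 1e-12)
  }
})

test_that("constant responses are recovered exactly with zero error", {
  ids <- list(paste0("C", 1:4), paste0("D", 1:3))
  vals <- matrix(2.5, 4, 3, dimnames = ids)
  rm <- response_matrix(vals)
  inst <- random_instance(4, 3, seed = 8, miss_prob = 0)
  csm <- manual_similarity(`dimnames<-`(inst$csm$sim, ids[c(1, 1)]), "cell")
  dsm <- manual_similarity(`dimnames<-`(inst$dsm$sim, ids[c(2, 2)]), "drug")
  fit <- loocv_predict(rm, csm, dsm, 0.1, 0.1)
  expect_equal(unname(fit$predicted[rm$observed]),
               rep(2.5, sum(rm$observed)), tolerance = 1e-12)
  expect_equal(fit$per_drug$rmse, rep(0, 3), tolerance = 1e-12)
})

test_that("grid search equals exhaustive recomputation through the oracle", {
  inst <- random_instance(5, 4, seed = 9, miss_prob = 0.15)
  gs <- grid_search(inst$rm, inst$csm, inst$dsm, model = 1, grid_step = 0.1)
  grid <- seq(0.1, 1, by = 0.1)
  sse <- matrix(NA_real_, length(grid), length(grid))
  for (a in seq_along(grid)) {
    for (t in seq_along(grid)) {
      pred <- naive_predict_matrix(inst$rm, inst$csm, inst$dsm,
                                   grid[a], grid[t], model = 1)
      obs <- inst$rm$observed & !is.na(pred)
      sse[a, t] <- sum((pred[obs] - inst$rm$values[obs])^2)
    }
  }
  best <- which(sse == min(sse), arr.ind = TRUE)[1, ]
  expect_equal(gs$alpha, grid[best[1]])
  expect_equal(gs$tau, grid[best[2]])
  expect_equal(gs$sse, min(sse), tolerance = 1e-10)
  ## internal consistency: reported minimum is attained on the surface
  expect_equal(min(gs$surface$sse), gs$sse)
})

test_that("grid-search ties break to the smallest (alpha, tau)", {
  ## constant responses: every bandwidth pair predicts perfectly, SSE = 0
  ids <- list(paste0("C", 1:3), paste0("D", 1:3))
  vals <- matrix(1, 3, 3, dimnames = ids)
  inst <- random_instance(3, 3, seed = 10, miss_prob = 0)
  csm <- manual_similarity(`dimnames<-`(inst$csm$sim, ids[c(1, 1)]), "cell")
  dsm <- manual_similarity(`dimnames<-`(inst$dsm$sim, ids[c(2, 2)]), "drug")
  gs <- grid_search(response_matrix(vals), csm, dsm, grid_step = 0.1)
  expect_equal(c(gs$alpha, gs$tau), c(0.1, 0.1))
})

test_that("grid search disqualifies bandwidths that cannot predict all pairs", {
  ## two perfectly anti-correlated cells: at alpha = 0.05 the cross-cell
  ## weight underflows to zero and model II cannot predict anything, with
  ## a vacuous SSE of 0; such grid points must not win the argmin
  ids <- list(c("C1", "C2"), paste0("D", 1:3))
  rho <- matrix(c(1, -1, -1, 1), 2, 2, dimnames = ids[c(1, 1)])
  set.seed(13)
  tani <- drug_similarity(fingerprint_set(matrix(
    rbinom(3 * 16, 1, 0.6), 3, 16, dimnames = list(ids[[2]], NULL))))
  vals <- matrix(rnorm(6), 2, 3, dimnames = ids)
  gs <- grid_search(response_matrix(vals), manual_similarity(rho, "cell"),
                    tani, model = 2, grid_step = 0.05)
  surf <- tidy(gs)
  expect_true(any(surf$n_ok == 0))           # the degenerate region exists
  expect_equal(surf$sse[surf$alpha == 0.05][1], 0)
  expect_gte(gs$alpha, 0.1)                  # but is not selected
  expect_equal(surf$n_ok[surf$alpha == gs$alpha & surf$tau == gs$tau], 6L)
})

test_that("RMSE and NRMSE match hand computations and scale correctly", {
  e <- drug_rmse_nrmse(c(0, 1), c(1, 0))
  expect_equal(e$rmse, 1)
  expect_equal(e$nrmse, 1)
  expect_equal(drug_rmse_nrmse(c(1, 2, 3), c(1, 2, 3)),
               tibble::tibble(rmse = 0, nrmse = 0))
  set.seed(51)
  obs <- rnorm(10)
  est <- rnorm(10)
  base <- drug_rmse_nrmse(obs, est)
  scaled <- drug_rmse_nrmse(3 * obs, 3 * est)
  expect_equal(scaled$rmse, 3 * base$rmse, tolerance = 1e-12)
  expect_equal(scaled$nrmse, base$nrmse, tolerance = 1e-12)
  expect_warning(z <- drug_rmse_nrmse(c(1, 1), c(0, 2)), "range")
  expect_true(is.na(z$nrmse))
})

test_that("imputation fills only missing cells with the pair predictor", {
  inst <- random_instance(3, 3, seed = 12, miss_prob = 0)
  full <- impute_missing(inst$rm, inst$csm, inst$dsm, 0.2, 0.2)
  expect_identical(full$values, inst$rm$values)  # nothing to impute
  expect_false(any(full$imputed))

  vals <- inst$rm$values
  vals[2, 3] <- NA
  rm <- response_matrix(vals)
  imp <- impute_missing(rm, inst$csm, inst$dsm, 0.2, 0.2)
  expect_true(imp$imputed[2, 3])
  expect_equal(sum(imp$imputed), 1)
  expect_equal(imp$values[2, 3],
               predict_pair(rm, inst$csm, inst$dsm,
                            rownames(vals)[2], colnames(vals)[3], 0.2, 0.2),
               tolerance = 1e-12)
  ## convexity: the filled value lies inside the observed range
  expect_gte(imp$values[2, 3], min(vals, na.rm = TRUE))
  expect_lte(imp$values[2, 3], max(vals, na.rm = TRUE))
  ## observed cells untouched
  expect_identical(imp$values[rm$observed], rm$values[rm$observed])
})
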
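# cdcn

Kernel-weighted prediction of anticancer drug responses on a cell
line–drug network.

Pharmacogenomic screens (CCLE- or GDSC-style) measure a cell line × drug
response matrix — activity area or IC50 — that is incomplete and that one
would like to extend: to unmeasured entries, to new cell lines, to new
drugs, and even to pairs where *both* the cell line and the drug are
untested. `cdcn` is for computational biologists working with such
screens. It implements a simple two-parameter estimator built on the
observation that genetically similar cell lines respond similarly to
structurally similar drugs, together with the full evaluation pipeline:
normalization, similarity layers, bandwidth tuning, leave-one-out
cross-validation, imputation benchmarking, sensitive/resistant
classification, and a synthetic data generator so everything is testable
without external downloads.

## The model

Cell lines are compared by the Pearson correlation ρ of their expression
profiles; drugs by the Tanimoto coefficient T of their binary molecular
fingerprints. Each similarity s feeds a Gaussian kernel weight
w = exp(−(1−s)² / 2β²) with bandwidths β = α (cells) and β = τ (drugs),
and the response of a pair (C, D) is predicted as the weighted average

    R̂(C, D) = Σ w(C, Cᵢ) w(D, Dⱼ) R(Cᵢ, Dⱼ) / Σ w(C, Cᵢ) w(D, Dⱼ)

over a contributing set of observed pairs (Cᵢ, Dⱼ): every other observed
pair for **model I**, or only pairs sharing neither the cell line nor the
drug for **model II** (the new-drug-to-new-cell-line estimator). (α, τ)
are tuned by grid search on the leave-one-out squared error. Predictions
are convex combinations of observed responses; accuracy is summarised per
drug by Pearson r, RMSE and range-normalized RMSE, plus classification
metrics (accuracy, sensitivity, specificity, R², AUC).

## Worked example

```r
library(cdcn)

dat <- generate_synthetic(synth_config(seed = 1))   # 50 cells x 12 drugs
csm <- cell_similarity(dat$expression)
dsm <- drug_similarity(dat$fingerprints)

gs <- grid_search(dat$response, csm, dsm, model = 1, grid_step = 0.01)
gs
#> <cdcn_grid> model I, step 0.01
#>   best (alpha, tau) = (0.04, 0.16), SSE = 2.07342

fit <- loocv_predict(dat$response, csm, dsm, gs$alpha, gs$tau, model = 1)
glance(fit)
#> # A tibble: 1 × 10
#>   model alpha   tau loocv mean_r min_r max_r   rmse n_pairs n_failed
#>   <chr> <dbl> <dbl> <lgl>  <dbl> <dbl> <dbl>  <dbl>   <int>    <int>
#> 1 I      0.04  0.16 TRUE   0.981 0.962 0.994 0.0603     570        0
```

The tuned bandwidths are narrow in the cell-line layer (α = 0.04: only
closely correlated cell lines contribute appreciably) and wider in the
drug layer (τ = 0.16). Held-out predictions correlate with the truth at
r ≈ 0.98 per drug on these conditions. `tidy(fit)` gives the per-drug
table, `autoplot(fit)` the corresponding bar chart.

Imputation against a drug-space k-nearest-neighbour baseline:

```r
bench <- random_deletion_benchmark(dat$response, csm, dsm,
                                   gs$alpha, gs$tau, seed = 1)
bench$summary
#> # A tibble: 5 × 3
#>   method     k mean_r
#>   <chr>  <int>  <dbl>
#> 1 cdcn      NA  0.981
#> 2 knn        1  0.599
#> 3 knn        3  0.683
#> 4 knn        5  0.584
#> 5 knn        7  0.586
```

Hiding 10% of the observed entries over five rounds, the network
estimator recovers them at mean r ≈ 0.98, far above the baseline at any
k. Filling the matrix's genuinely missing entries is one call:
`impute_missing(dat$response, csm, dsm, gs$alpha, gs$tau)`.

A command-line wrapper (`exec/cdcn`) exposes the same pipeline as
`simulate`, `normalize`, `similarity`, `tune`, `predict`, `impute`,
`evaluate` and `benchmark` subcommands with TSV/JSON outputs and YAML
config support.

## Documentation

The methods vignette (`vignettes/cdcn-methods.Rmd`) describes the model
and its assumptions, the normalization and tuning choices, the numerical
safeguards (underflow handling, exact contributing-set sums), what the
synthetic generator does and does not emulate, and known limitations.
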
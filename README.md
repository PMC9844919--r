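# svrs — stable variable ranking and selection for severely imbalanced binary data

`svrs` selects influential covariates in logistic regression when the
positive class is rare (imbalance ratios of 1:50 to 1:1000 and beyond) and
the dataset is large. It is aimed at analysts of rare-event data —
epidemiology, wildfire occurrence, insurance claims — where a single
penalized fit gives unstable, high-false-discovery selections.

## The method

Keep all `n1` cases; repeatedly draw `n1` controls without replacement to
form `M` balanced datasets of size `n_b = 2 n1`. Fit a cross-validated
penalized logistic regression (Lasso, adaptive Lasso, or ridge) to each.
With standardized coefficients `β^Δ_i = sd(x_i) β_i` ranked within each fit
(rank `p` = largest `|β^Δ|`), aggregate

    Rank(X_i) = M⁻¹ Σ_j R_ij · 1[|β^Δ_ij| > 0]

so a covariate zeroed out by the penalty in a fit contributes nothing for
that fit. Sorted decreasing, the scores show a step between signal and
noise; a single mean-changepoint (AMOC, pooled-SSE minimization) places the
selection threshold automatically. Because every fit sees only `2 n1` rows,
the ensemble costs `2 n1 M / n` of a full-data fit — for a case study with
n = 10.7 million and n1 = 22,525, a full fit costs ≈ 238× one balanced fit
and ≈ 2.4× the entire M = 100 ensemble.

A synthetic-data module reproduces four benchmark generating models
(UNCOR-12/COR-12 with p = 100, UNCOR-24/COR-24 with p = 200), including
NORTA-based correlated nominal clusters and binary blocks, equicorrelated
Gaussian blocks, and intercept calibration to a target prevalence, with
exact case/control counts. See `vignette` source `vignettes/svrs-methods.Rmd`
for the full model description and design choices.

## Worked example

```r
library(svrs)

design <- sim_design("UNCOR-12", imbalance_I = 50, n_b_target = 1000, seed = 42)
sim <- simulate_dataset(design)          # 500 cases + 25,000 controls
print(sim$data)
#> labeled_design: 25500 rows, 100 covariates, 500 cases (0.0196 case fraction)

res <- run_svrs(sim$data, method = "lasso", M = 20, K = 5,
                lambda_rule = "min", seed = 7)
print(res)
#> svrs_result (lasso, M = 20, lambda_min): 12 covariates selected of 100
#> selected: X1, X2, X3, X4, X5, X6, X8, X9, X10, X11, X12, X70

head(rank_table(res$ranks), 4)
#>   covariate index rank_score p_drop in_support
#> 1        X1     1      99.20      0       TRUE
#> 2        X2     2      99.15      0       TRUE
#> 3        X3     3      97.35      0       TRUE
#> 4        X5     5      96.85      0       TRUE

m <- selection_metrics(res$selection$selected, sim$truth)
sprintf("TPR = %.3f  FPR = %.3f  FDR = %.3f  AUC = %.3f", m$TPR, m$FPR, m$FDR, m$AUC)
#> "TPR = 0.917  FPR = 0.011  FDR = 0.083  AUC = 0.953"
```

The truth manifest says covariates 1–12 carry signal: at this small
`n_b = 1000` / M = 20 setting the pipeline recovered 11 of 12 signals with a
single false positive. At `n_b ≥ 3000` and M = 100 all 12 signals are
recovered (TPR = 1) with zero to two false positives; the weakest signal
(|β| = 0.4) is the one lost at small samples.

Rank scores near 100 (= p) mean a covariate outranked the others in nearly
every fit; `p_drop` is the fraction of fits in which the penalty removed it
entirely.

## Command line

```sh
Rscript inst/cli/svrs.R simulate --model COR-24 --imbalance 1000 --nb 5000 \
        --seed 7 --out data.csv --truth truth.json
Rscript inst/cli/svrs.R run --data data.csv --method lasso --M 100 \
        --lambda-rule min --seed 7 --out results/
Rscript inst/cli/svrs.R permute --data data.csv --columns 13-100 --seed 7 \
        --out permuted.csv
```

## Replicating the full experiment

`run_simulation_grid()` drives the full 4-model × {1:50, 1:100, 1:1000} ×
{1000..5000} grid; at M = 500 this is an overnight job and is not part of
the test suite:

```r
grid <- run_simulation_grid(
  models = c("UNCOR-12", "COR-12", "UNCOR-24", "COR-24"),
  I_values = c(50, 100, 1000), nb_values = c(1000, 2000, 3000, 4000, 5000),
  methods = c("lasso", "adalasso", "ridge"), M = 500,
  base_seed = 1, out_csv = "grid.csv")
```
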
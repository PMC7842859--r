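# fedcohort

Federated learning of clinical risk models across simulated hospital
cohorts — local vs pooled vs federated training, evaluated by bootstrap
AUROC.

## The problem

Mortality-prediction models improve with large, diverse training data, but
patient-level records are siloed in individual hospitals and usually cannot
be pooled. Federated learning trains a shared model by exchanging only
model parameters with a central aggregator. `fedcohort` implements and
stress-tests that workflow for 7-day in-hospital mortality prediction
across five hospitals with very different sizes (485–1644 patients) and
mortality prevalences (5.6%–24.2%), for researchers in clinical ML and
biostatistics who want a fully reproducible, data-free testbed of the
local / pooled / federated comparison.

The core procedure is **federated averaging (FedAvg)**. Each round, the
aggregator sends global parameters $w$ to every site $k$; the site trains
one epoch on its own data, returning $w_k$; the aggregator sets

$$w \leftarrow \sum_k \frac{n_k}{\sum_j n_j}\, w_k,$$

layer by layer, where $n_k$ is the site's training-sample count. Two model
families share one trainable-parameter container so both can be federated:
L1-penalized logistic regression ("LASSO", trained by proximal gradient
descent with soft-thresholding $S_{\eta\lambda}$ so coefficients reach
exact zeros) and a fixed-architecture multilayer perceptron (rectifier
hidden layer, sigmoid output), both minimizing binary cross-entropy.
Optionally each site perturbs outgoing parameters with Gaussian noise
$\mathcal N(0, \sigma^2)$ before transmission.

Because the real records are private, the package ships a synthetic
generator calibrated to the published five-site profiles: per-site case
mix (gender, age, ethnicity, race, 19 comorbidities, 8 vitals/labs) and a
shared sparse logistic outcome model whose per-site intercepts are solved
by bisection so each site hits its published mortality prevalence exactly.
Evaluation follows the published protocol: B independent stratified 70/30
train/test resplits, mean AUROC (rank-based Mann–Whitney) with percentile
95% CIs.

## Worked example

```r
library(fedcohort)

# the five simulated hospitals, calibrated to the published cohort profile
profiles <- default_mshs_profiles()
schema   <- default_schema()
model    <- default_outcome_model(schema)
cohorts  <- generate_system(profiles, schema, model, seed = 1)
sum(vapply(cohorts, nrow, integer(1)))
#> [1] 4029

# interhospital comparison table (chi-square / Kruskal-Wallis, suppression)
cmp <- build_comparison_table(cohorts)
head(render_comparison(cmp)[, c("characteristic", "MSB", "MSH", "MSW", "p")], 3)
#> # A tibble: 3 x 5
#>   characteristic MSB              MSH              MSW              p
#>   <chr>          <chr>            <chr>            <chr>            <chr>
#> 1 gender_male    339 (55.5)       951 (57.8)       244 (50.3)       <.001
#> 2 age            71.4 (61.5-81.5) 63.4 (52.0-73.8) 65.0 (51.7-77.5) <.001
#> 3 ethnicity      17 (2.8)         457 (27.8)       106 (21.9)       <.001

# local vs federated LASSO under the bootstrap protocol (B = 10 here)
boot <- bootstrap_config(n_iterations = 10, master_seed = 7)
loc <- run_bootstrap(cohorts, "lasso", "local", boot_cfg = boot)
fed <- run_bootstrap(cohorts, "lasso", "federated", boot_cfg = boot,
                     fed_cfg = federation_config(rounds = 50, seed = 7))
strategy_table(list(loc, fed))
#> # A tibble: 2 x 7
#>   family strategy  MSB                 MSH                 MSM
#>   <chr>  <chr>     <chr>               <chr>               <chr>
#> 1 lasso  local     0.677 (0.598-0.724) 0.799 (0.764-0.845) 0.751 (0.640-0.808)
#> 2 lasso  federated 0.704 (0.654-0.753) 0.810 (0.775-0.860) 0.780 (0.746-0.820)
#>   MSQ                 MSW
#> 1 0.749 (0.669-0.787) 0.704 (0.622-0.814)
#> 2 0.782 (0.734-0.851) 0.786 (0.703-0.878)
```

Each cell is the mean test-set AUROC over the bootstrap resplits with its
percentile 95% CI. The pattern mirrors the published finding: the
federated model clearly beats local training at MSW — the smallest site
(n = 485) with the lowest mortality prevalence (5.6%), where a local model
has barely two dozen positive cases to learn from — while larger sites
gain less. `autoplot()` on a federated round log draws the per-site
AUROC/loss learning curves, and `tidy()`/`glance()` extract coefficient
tables and summaries from fitted objects.

A config-driven driver covers the full grid: `cmd_simulate()`,
`cmd_cohort_table()` and `cmd_experiment()` consume a YAML config
(validated against the schema in `inst/extdata/config-schema.json`) and
write cohort CSVs, comparison tables, long-format results, strategy tables,
learning curves and a reproducibility manifest. A thin CLI wrapper lives at
`inst/cli/fedcohort.R`.

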
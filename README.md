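# graftann

Predicting five-year kidney graft survival from donor and recipient
covariates, with a swarm-optimized neural network.

Kidney transplantation outcomes depend on dozens of interacting donor and
recipient characteristics, and most of them carry little signal. `graftann`
implements an end-to-end pipeline for the binary question *will this graft
still function five years after transplantation?*:

1. **Preprocessing** — identifier and post-operative columns are removed
   (the model must predict *before* surgery), missing covariate values are
   imputed with the mean of their nearest observed neighbours in temporal
   order (records sorted by transplant date), and the outcome label is
   derived by censoring arithmetic: graft time is `dialysis start −
   transplant date` for failed grafts and `last follow-up − transplant
   date` otherwise, compared against a 1826-day horizon.
2. **Hybrid feature selection** — an information-gain filter (features with
   `IG = 0` bits about the label are rejected), a wrapper search over
   feature subsets driven by the African Buffalo Optimization (ABO)
   metaheuristic with classifier validation accuracy as fitness, and a
   one-by-one backward elimination pass that drops a feature only when its
   removal strictly improves validation accuracy.
3. **Prediction** — a single-hidden-layer perceptron,
   `t_n = f(m_n + Σ_p μ_np l_p)`, `s = g(a + Σ_n b_n t_n)`, whose weight
   vector is trained by the same ABO optimizer (no gradients), with
   tanh/logistic/linear activations.
4. **Evaluation** — confusion-matrix measures (accuracy, precision, recall,
   F-measure) plus RMSE and MAE of the predicted survival probabilities.

The ABO metaheuristic maintains a herd of candidate solutions, each with an
exploitation position `w` and exploration move `m`, updated by

```
m' = m + le1 (bg − w) + le2 (bp − w)      # herd best bg, personal best bp
w' = w + m' / λ*                          # then clamped to the search box
```

with learning factors `le1 = 0.6`, `le2 = 0.5` and `λ* = 1` by default, and
an elitist contracting restart when the herd best stagnates.

Because real transplant registries are private, the package ships a
synthetic cohort generator with planted ground truth (a known informative
subset acting through a logistic model, outcome-independent identifier and
post-operative columns, censoring-consistent date columns, and sparse
missingness that never defeats temporal imputation), so every stage is
testable against a known answer.

## Worked example

```r
library(graftann)

config <- pipeline_config(seed = 1)     # 2000 patients, 67 columns,
res <- run_pipeline(config, dir = "run1")  # 61 pre-op features, 10 informative
res$metrics
#> Graft-survival prediction performance
#>   confusion: tp=183 tn=177 fp=125 fn=115
#>   accuracy    60.00%
#>   precision   59.42%
#>   recall      61.41%
#>   f_measure   60.40%
#>   rmse       0.4876
#>   mae        0.4682

sum(res$mask$selected)                       # features kept by hybrid selection
#> [1] 39
mean(res$truth$informative_features %in% selected_features(res$mask))
#> [1] 0.9                                    # planted-informative recall
```

The selection stages recover 9 of the 10 planted informative features while
discarding a third of the candidates. Test-set accuracy of the end-to-end
default run is moderate: training several hundred network weights with a
derivative-free swarm is the method's bottleneck (see the methods vignette);
on small feature sets the same trainer is accurate — e.g. it reaches ≥ 95%
training accuracy on separable two-feature problems, and the optimizer
itself drives the 5-dimensional sphere benchmark below `1e-8`:

```r
abo_minimize(function(x) sum(x^2), dims = 5,
             abo_config(n_buffalo = 20, max_iterations = 200, seed = 1))$best_f
#> [1] 8.06e-09
```

Each result type has `tidy()`, `glance()` and `autoplot()` methods, and all
artifacts (cohort CSV with a schema sidecar, feature masks and rankings,
serialized network weights, predictions, metrics, a manifest) are plain
text and byte-identical across reruns with the same config and seed.

A thin command-line wrapper is installed at `inst/cli/graftann.R`:

```sh
Rscript inst/cli/graftann.R run --seed 1 --out run1
Rscript inst/cli/graftann.R simulate --config my_config.yaml --out cohort_dir
```

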
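# irnet

Comparing insulin-resistance surrogate markers — HOMA-IR, the
triglyceride-glucose (TyG) index, and the triglyceride to HDL cholesterol
ratio (TG/HDL) — against diabetes and dyslipidemia in complex-survey
cohorts, using discrete Bayesian networks.

Three questions drive the package:

1. **Discrimination** — which marker best separates cases from non-cases?
   Answered with survey-weighted AUC and weighted mutual information.
2. **Dependence structure** — which associations survive conditioning on
   everything else? Answered by learning a Bayesian network over the
   categorical analysis variables (AIC hill-climbing with bootstrap
   arc-strength model averaging) and reading off each marker's Markov
   blanket.
3. **Scenario probabilities** — e.g. P(diabetes | marker quartile),
   estimated on the fitted network by exact enumeration or likelihood
   weighting.

Everything needed to run the analysis end to end is included: the clinical
derivation layer (index formulas, guideline cut-offs, Friedewald LDL,
composite outcomes, exclusion cascade), hand-implemented survey statistics
(second-order Rao-Scott chi-square, weighted MI, weighted ROC/AUC), the
network machinery (scores, search, d-separation, bootstrap averaging,
inference), and a seeded synthetic cohort generator with a known 17-node
ground-truth network for validation. The API is tidyverse-native: tibbles
in and out, `tidy()`/`glance()` methods, and `autoplot()` for every result
type.

## Worked example

```r
library(irnet)

# a seeded synthetic survey cohort with known ground truth
spec <- ir_ground_truth()
cohort <- sample_cohort(spec, 2000, seed = 1)
cohort <- emit_continuous(cohort, spec, seed = 2)
cohort <- derive_indices(cohort)
dplyr::select(cohort, id, weight, fbg, tg, hdl, homa_ir, tyg, tg_hdl)
#> # A tibble: 2,000 × 8
#>      id weight   fbg    tg   hdl homa_ir   tyg tg_hdl
#>   <int>  <dbl> <dbl> <dbl> <dbl>   <dbl> <dbl>  <dbl>
#> 1     1  1.01   92.3 113.   55.1    1.44  8.56   2.06
#> 2     2  0.853 117.   90.5  40.6    2.63  8.58   2.23
#> 3     3  1.93  122.  149.   67.7    2.62  9.11   2.20
#> # ℹ 1,997 more rows

# marker discrimination against both outcomes
compare_markers(cohort)
#> # A tibble: 6 × 7
#>   marker  outcome      mi_nats mi_pct   auc rank_auc rank_mi
#>   <chr>   <chr>          <dbl>  <dbl> <dbl>    <int>   <int>
#> 1 homa_ir diabetes     0.147   24.7   0.809        1       1
#> 2 tyg     diabetes     0.104   17.5   0.739        2       2
#> 3 tg_hdl  diabetes     0.0527   8.85  0.548        3       3
#> 4 homa_ir dyslipidemia 0.00139  0.232 0.532        3       3
#> 5 tyg     dyslipidemia 0.00150  0.250 0.672        2       2
#> 6 tg_hdl  dyslipidemia 0.00221  0.369 0.736        1       1

# network over the categorical analysis variables
dag <- hill_climb(cohort[, bn_node_set(cohort)])
markov_blanket(dag, "homa_ir_q")
#> [1] "diabetes"     "fbg_cat"      "hdl_cat"      "obesity_bmi"  "obesity_wc"
#> [6] "obesity_whtr" "sex"          "tyg_q"
markov_blanket(dag, "tg_hdl_q")
#> [1] "tyg_q"
```

HOMA-IR ranks first for diabetes, TG/HDL first for dyslipidemia, and the
blankets show the qualitative pattern the network analysis is after: TyG
sits in the blanket of both other markers, while HOMA-IR and TG/HDL are
conditionally independent of each other given the rest.

The whole analysis — derivation, description, marker comparison,
bootstrap structure learning, model averaging, blankets, scenario
queries, text artifacts — is one call:

```r
report <- run_pipeline(pipeline_config(seed = 1, out_dir = "results"))
```

`autoplot()` works on bootstrap strengths, learned DAGs, ROC curves, and
scenario tables. A command-line interface with the same subcommands lives
at `system.file("cli", "irnet.R", package = "irnet")`.

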
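# odcea

Cost-effectiveness analysis of **six- versus four-implant bar-retained
maxillary overdentures**, as a probabilistic Markov cohort model.

An edentulous upper jaw can be restored with an implant-supported overdenture
on six or on four implants. Six implants cost more up front but each implant
carries less load, so per-year implant- and denture-failure probabilities are
lower; failures trigger repair costs and depress patient satisfaction. The
package answers the decision question: **at what willingness-to-pay λ, in euro
per year of denture satisfaction, does the six-implant strategy become the
preferable treatment?**

## The model in brief

* **State**: number of implants in function (0–6); implants are never
  replaced. Cohorts start at 6 or 4 (the two strategies) and run for 10 annual
  cycles (configurable).
* **Per cycle**, two independent events: *implant failure* (state decrements
  by one, repair-after-implant-loss billed) and *denture failure* (repair
  without implant loss). Failure probabilities are triangular distributions,
  anchored at the six- and four-implant evidence and linearly
  interpolated/extrapolated across counts.
* **Rewards**: cycle cost = expected repair costs (initial prosthesis cost at
  time 0); cycle effect = satisfaction score of the cycle-start state,
  multiplied once by a repair-adjustment factor in any failure cycle. No
  discounting, no half-cycle correction.
* **PSA**: 50,000 Monte Carlo draws through the triangular inverse CDFs,
  common random parameters for both strategies, fixed
  treatment-complexity cost factor per run (1.0 / 2.3 / 3.5 fee tiers).
* **Outputs**: cost-effectiveness plane, acceptability curves (net monetary
  benefit), and the λ at which the six-implant acceptability crosses 0.5 — the
  median per-draw ICER — with a bootstrap Monte Carlo standard error.

See the vignette (`vignettes/overdenture-cea.Rmd`) for the full model
description, conventions and design decisions.

## Worked example

```r
library(odcea)

model <- base_case_model()

# deterministic cohort at modal parameters, fee factor 2.3
params <- realize_parameters(model, cost_factor = 2.3)
run_cohort(params, "six")
#> six-implant strategy: total cost 8177.04 EUR, total effect 8.8602 satisfaction-years (10 cycles)

# probabilistic sensitivity analysis, 50,000 draws (~1 s)
psa <- simulate_psa(model, n_draws = 50000, cost_factor = 2.3, seed = 1)
glance(psa)
#> # A tibble: 1 × 9
#>   n_draws horizon mean_cost_six mean_cost_four mean_effect_six mean_effect_four
#>     <int>   <int>         <dbl>          <dbl>           <dbl>            <dbl>
#> 1   50000      10         8182.          6934.            8.86             8.78
#> # ℹ 3 more variables: mean_inc_cost <dbl>, mean_inc_effect <dbl>,
#> #   median_icer <dbl>

# willingness-to-pay threshold where six implants become preferable
find_threshold(psa)
#> # A tibble: 1 × 5
#>   scenario  cost_factor threshold mc_se n_draws
#> * <chr>           <dbl>     <dbl> <dbl>   <int>
#> 1 base_case         2.3    17081.  23.9   50000

# the acceptability curve crosses 0.5 at the same place
curve <- ceac(psa)
head(curve[curve$p_six >= 0.5, ], 3)
#> # A tibble: 3 × 3
#>   lambda p_six p_four
#>    <dbl> <dbl>  <dbl>
#> 1  17250 0.516  0.484
#> 2  17500 0.542  0.458
#> 3  17750 0.566  0.434
```

`autoplot(psa)`, `autoplot(curve)` and `autoplot(run_cohort(params, "six"))`
draw the cost-effectiveness plane, the acceptability curves and the cohort
occupancy trace. `tidy()` methods return long-format tibbles throughout.

One-way sensitivity analyses cross 12 reference scenarios (alternative
satisfaction declines, the no-implant denture-failure mode, fixed
repair-adjustment values) with the three fee tiers:

```r
one_way_sensitivity(n_draws = 5000)   # 36-row threshold table
```

End-to-end runs with CSV/JSON outputs and YAML model configs:

```r
run_analysis("results/base", n_draws = 50000, seed = 1)
run_scenario_suite("results/suite", n_draws = 50000, seed = 1)
read_model_config(packaged_config("satisfaction_A"))
```

A thin command-line wrapper lives at `inst/cli/odcea.R`
(`Rscript inst/cli/odcea.R run --out results/base --seed 1`).

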
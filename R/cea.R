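#' Incremental cost-effectiveness ratio
#'
#' The additional cost per additional satisfaction-year of strategy A over
#' strategy B, `(cost_a - cost_b) / (effect_a - effect_b)`. Vectorized over
#' draws.
#'
#' @param cost_a,effect_a Cost (euro) and effect (satisfaction-years) of the
#'   comparator of interest.
#' @param cost_b,effect_b Cost and effect of the baseline strategy.
#'
#' @return Euro per satisfaction-year. A zero incremental effect is an
#'   undefined-ICER condition and raises an error.
#' @export
icer <- function(cost_a, effect_a, cost_b, effect_b) {
  delta_e <- effect_a - effect_b
  if (any(delta_e == 0)) {
    rlang::abort("ICER undefined: zero incremental effect", class = "odcea_undefined_icer")
  }
  (cost_a - cost_b) / delta_e
}

#' Net monetary benefit
#'
#' `lambda * effect - cost`: the money-scale value of an outcome at
#' willingness-to-pay `lambda` euro per satisfaction-year. At a given `lambda`
#' the strategy with the higher net monetary benefit is preferred; the
#' difference in net monetary benefit between two strategies changes sign
#' exactly at their ICER whenever the incremental effect is positive.
#'
#' @param cost Cost in euro.
#' @param effect Effect in satisfaction-years.
#' @param lambda Willingness-to-pay in euro per satisfaction-year
#'   (non-negative).
#'
#' @return Net monetary benefit in euro.
#' @export
net_monetary_benefit <- function(cost, effect, lambda) {
  if (any(lambda < 0)) {
    rlang::abort("willingness-to-pay must be non-negative", class = "odcea_invalid_lambda")
  }
  lambda * effect - cost
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value on the grid, the acceptability of the
#' six-implant strategy is the fraction of Monte Carlo draws in which its net
#' monetary benefit strictly exceeds the four-implant strategy's; exact ties
#' (probability-zero events under continuous parameter draws) are split
#' equally. With only two strategies the two acceptabilities sum to one at
#' every grid point.
#'
#' @param psa An `"od_psa"` tibble from [simulate_psa()].
#' @param lambda_grid Willingness-to-pay grid in euro per satisfaction-year
#'   (default 0 to 50,000 in steps of 250).
#'
#' @return A tibble of class `"od_ceac"` with columns `lambda`, `p_six`,
#'   `p_four`.
#' @export
ceac <- function(psa, lambda_grid = seq(0, 50000, by = 250)) {
  stopifnot(nrow(psa) >= 1, length(lambda_grid) >= 1)
  delta_e <- psa$effect_six - psa$effect_four
  delta_c <- psa$cost_six - psa$cost_four
  p_six <- vapply(lambda_grid, function(lambda) {
    nmb_diff <- lambda * delta_e - delta_c
    mean(nmb_diff > 0) + 0.5 * mean(nmb_diff == 0)
  }, numeric(1))
  structure(
    tibble::tibble(lambda = lambda_grid, p_six = p_six, p_four = 1 - p_six),
    class = c("od_ceac", class(tibble::tibble()))
  )
}

#' Willingness-to-pay threshold where the six-implant strategy becomes preferable
#'
#' The threshold is the willingness-to-pay at which the six-implant
#' acceptability curve crosses 0.5. When every draw has a positive incremental
#' effect -- which holds throughout the base case, where the six-implant
#' strategy is more effective in every realizable draw -- that crossing equals
#' the median of the per-draw ICERs, which is how it is computed here: exactly,
#' without a grid. The Monte Carlo standard error of the median is estimated by
#' a nonparametric bootstrap over draws.
#'
#' @param psa An `"od_psa"` tibble from [simulate_psa()].
#' @param n_boot Bootstrap replicates for the standard error (default 200).
#' @param scenario,cost_factor Optional labels carried into the result; the
#'   cost factor defaults to the PSA's recorded setting.
#'
#' @return A one-row tibble of class `"od_threshold"` with columns `scenario`,
#'   `cost_factor`, `threshold` (euro per satisfaction-year), `mc_se` and
#'   `n_draws`.
#' @export
find_threshold <- function(psa, n_boot = 200, scenario = "base_case",
                           cost_factor = NULL) {
  delta_e <- psa$effect_six - psa$effect_four
  if (any(delta_e <= 0)) {
    rlang::abort(
      "median-ICER threshold extraction requires a positive incremental effect in every draw",
      class = "odcea_nonpositive_effect"
    )
  }
  icers <- (psa$cost_six - psa$cost_four) / delta_e
  n <- length(icers)
  boot_medians <- vapply(seq_len(n_boot), function(b) {
    stats::median(icers[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  if (is.null(cost_factor)) {
    cost_factor <- attr(psa, "cost_factor")
    if (is_tri(cost_factor)) cost_factor <- NA_real_
    if (is.null(cost_factor)) cost_factor <- NA_real_
  }
  structure(
    tibble::tibble(
      scenario = scenario,
      cost_factor = cost_factor,
      threshold = stats::median(icers),
      mc_se = stats::sd(boot_medians),
      n_draws = n
    ),
    class = c("od_threshold", class(tibble::tibble()))
  )
}

#' One-way sensitivity analysis over scenario and cost-factor grids
#'
#' Re-runs the full probabilistic sensitivity analysis and threshold extraction
#' for every combination of scenario and treatment-complexity cost factor. The
#' default grid covers the reference scenario set of [reference_scenarios()]:
#' the base case, two alternative satisfaction scenarios, a grid over the
#' no-implant denture-failure mode, and a grid of fixed repair-adjustment
#' values, each crossed with the three fee-multiplier tiers.
#'
#' @param model Baseline [od_model()] that scenarios modify (default
#'   [base_case_model()]).
#' @param scenarios List of scenarios from [reference_scenarios()] or
#'   [od_scenario()].
#' @param cost_factors Complexity factors to cross with (default 1.0, 2.3,
#'   3.5).
#' @param n_draws,seed Monte Carlo protocol per cell (defaults 50,000 draws,
#'   seed 1). The same seed is reused across cells (common random numbers), so
#'   cells differ only through the scenario, not through sampling noise.
#' @param n_boot Bootstrap replicates for each threshold's standard error.
#'
#' @return A tibble with one row per scenario and cost factor: `scenario`,
#'   `cost_factor`, `threshold`, `mc_se`, `n_draws`.
#' @export
one_way_sensitivity <- function(model = base_case_model(),
                                scenarios = reference_scenarios(),
                                cost_factors = c(1.0, 2.3, 3.5),
                                n_draws = 50000, seed = 1L, n_boot = 200) {
  if (inherits(scenarios, "od_scenario")) scenarios <- list(scenarios)
  purrr::map_dfr(scenarios, function(sc) {
    scenario_model <- apply_scenario(model, sc)
    purrr::map_dfr(cost_factors, function(f) {
      psa <- simulate_psa(scenario_model, n_draws = n_draws, cost_factor = f, seed = seed)
      find_threshold(psa, n_boot = n_boot, scenario = sc$label, cost_factor = f)
    })
  })
}
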
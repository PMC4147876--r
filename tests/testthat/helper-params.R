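# Build an od_parameters object from one row of a draw_parameters() tibble,
# so the scalar reference engine can be compared against the vectorized one.
params_from_draw <- function(draws, i, model) {
  structure(
    list(
      p_implant = c(0, as.numeric(draws[i, paste0("p_implant_", 1:6)])),
      p_denture = as.numeric(draws[i, paste0("p_denture_", 0:6)]),
      satisfaction = model$satisfaction$satisfaction,
      repair_adjustment = draws$repair_adjustment[i],
      cost_factor = draws$cost_factor[i],
      costs = list(
        new_six = draws$cost_new_six[i],
        new_four = draws$cost_new_four[i],
        repair_implant = draws$cost_repair_implant[i],
        repair_denture = draws$cost_repair_denture[i]
      ),
      horizon = model$horizon
    ),
    class = "od_parameters"
  )
}

# A base-case model whose every distribution is collapsed to its mode, so the
# PSA reduces to the deterministic cohort evaluation.
degenerate_base_case <- function(horizon = 10L) {
  model <- base_case_model(horizon = horizon)
  rates <- model$failure_rates
  rates$low <- rates$mode
  rates$high <- rates$mode
  od_model(rates, model$satisfaction, tri(0.9, 0.9, 0.9), model$costs,
           horizon = horizon)
}
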
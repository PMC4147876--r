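# Independent patient-level microsimulation oracle for the cohort recursion.
# Each simulated patient carries an implant count; every year the two failure
# events are sampled as independent Bernoulli trials, repairs are billed, and
# the year's satisfaction is scored at the count held during the year, scaled
# once by the repair adjustment if anything failed. Deliberately built on
# per-patient sampling, not on the expected-value recursion it validates.
microsim_outcomes <- function(params, strategy, n_patients) {
  stopifnot(inherits(params, "od_parameters"))
  count <- rep(if (strategy == "six") 6L else 4L, n_patients)
  cost <- rep(params$costs[[paste0("new_", strategy)]], n_patients)
  sat <- numeric(n_patients)
  for (cycle in seq_len(params$horizon)) {
    fail_implant <- stats::runif(n_patients) < params$p_implant[count + 1]
    fail_denture <- stats::runif(n_patients) < params$p_denture[count + 1]
    cost <- cost + fail_implant * params$costs$repair_implant +
      fail_denture * params$costs$repair_denture
    year_sat <- params$satisfaction[count + 1]
    hit <- fail_implant | fail_denture
    sat <- sat + ifelse(hit, year_sat * params$repair_adjustment, year_sat)
    count <- count - fail_implant
  }
  list(
    mean_cost = mean(cost), se_cost = stats::sd(cost) / sqrt(n_patients),
    mean_effect = mean(sat), se_effect = stats::sd(sat) / sqrt(n_patients)
  )
}
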
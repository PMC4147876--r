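base_params <- function(cost_factor = 2.3, horizon = 10L) {
  realize_parameters(base_case_model(horizon = horizon), cost_factor = cost_factor)
}

test_that("cycle events enumerate the independent 2x2 failure table", {
  params <- base_params()
  # published modal probabilities at four implants
  ev <- cycle_events(4, params)
  expect_equal(ev$probability[ev$event == "both"], 0.037 * 0.035)
  expect_equal(ev$probability[ev$event == "implant"], 0.037 * (1 - 0.035))
  expect_equal(ev$probability[ev$event == "denture"], (1 - 0.037) * 0.035)
  expect_equal(ev$probability[ev$event == "none"], (1 - 0.037) * (1 - 0.035))
  expect_equal(sum(ev$probability), 1, tolerance = 1e-12)

  # structural zero: no implant can fail at count 0
  ev0 <- cycle_events(0, params)
  expect_identical(ev0$probability[ev0$event %in% c("implant", "both")], c(0, 0))
  expect_equal(sum(ev0$probability), 1, tolerance = 1e-12)

  # no-failure limit
  p0 <- params
  p0$p_implant[] <- 0
  p0$p_denture[] <- 0
  ev_none <- cycle_events(5, p0)
  expect_identical(ev_none$probability[ev_none$event == "none"], 1)
})

test_that("cycle rewards price repairs and score the occupied state's satisfaction", {
  params <- base_params(cost_factor = 2.3)

  sound <- cycle_reward(6, "none", params)
  expect_identical(sound$cost, 0)
  expect_identical(sound$satisfaction, 0.89)
  expect_identical(sound$n_end, 6L)

  denture_only <- cycle_reward(4, "denture", params)
  expect_equal(denture_only$cost, 84.93 + 50.00)
  expect_equal(denture_only$satisfaction, 0.89 * 0.9)
  expect_identical(denture_only$n_end, 4L)

  params1 <- base_params(cost_factor = 1.0)
  both <- cycle_reward(4, "both", params1)
  expect_equal(both$cost, 206.68 + 160.00 + 65.19 + 50.00)
  # the adjustment applies once per failure cycle, to the satisfaction of the
  # state occupied during the cycle; the count drop takes effect next cycle
  expect_equal(both$satisfaction, 0.89 * 0.9)
  expect_identical(both$n_end, 3L)

  expect_error(cycle_reward(0, "implant", params), class = "odcea_invalid_event")
})

test_that("cohort without failures accrues only the initial cost and full satisfaction", {
  params <- base_params()
  params$p_implant[] <- 0
  params$p_denture[] <- 0
  res <- run_cohort(params, "six")
  expect_equal(res$total_cost, 2990.86 + 5070.30)
  expect_equal(res$total_effect, 10 * 0.89)
  expect_true(all(res$trace$p_count_6 == 1))
})

test_that("a one-cycle cohort equals the hand enumeration of the four events", {
  params <- base_params(cost_factor = 2.3, horizon = 1L)
  res <- run_cohort(params, "four")
  p_i <- 0.037
  p_d <- 0.035
  p_any <- p_i + p_d - p_i * p_d
  expect_equal(res$total_cost,
               (2199.98 + 4507.82) + p_i * (267.35 + 160) + p_d * (84.93 + 50))
  expect_equal(res$total_effect, 0.89 * ((1 - p_any) + 0.9 * p_any))
})

test_that("the cohort trace conserves probability and implants are never regained", {
  draws <- draw_parameters(base_case_model(), 8, seed = 202)
  model <- base_case_model()
  for (i in seq_len(nrow(draws))) {
    params <- params_from_draw(draws, i, model)
    for (strategy in c("six", "four")) {
      res <- run_cohort(params, strategy)
      occupancy <- as.matrix(res$trace[paste0("p_count_", 0:6)])
      expect_equal(unname(rowSums(occupancy)), rep(1, params$horizon),
                   tolerance = 1e-12)
      n0 <- if (strategy == "six") 6 else 4
      expect_true(all(occupancy[, (0:6) > n0] == 0))
      mean_count <- occupancy %*% (0:6)
      expect_true(all(diff(mean_count) <= 1e-12))
      expect_gte(res$total_cost, params$costs[[paste0("new_", strategy)]])
      expect_true(res$total_effect >= 0 &&
                    res$total_effect <= params$horizon * max(params$satisfaction))
    }
  }
})

test_that("the vectorized engine agrees exactly with the scalar reference", {
  model <- base_case_model()
  draws <- draw_parameters(model, 12, cost_factor = tri(1.0, 2.3, 3.5), seed = 77)
  for (strategy in c("six", "four")) {
    batch <- odcea:::cohort_batch(draws, model$satisfaction$satisfaction,
                                  model$horizon, strategy)
    for (i in seq_len(nrow(draws))) {
      ref <- run_cohort(params_from_draw(draws, i, model), strategy)
      expect_equal(batch$cost[i], ref$total_cost, tolerance = 1e-12)
      expect_equal(batch$effect[i], ref$total_effect, tolerance = 1e-12)
    }
  }
})

test_that("cohort expectations match the patient-level microsimulation", {
  params <- base_params()
  set.seed(11)
  for (strategy in c("six", "four")) {
    res <- run_cohort(params, strategy)
    sim <- microsim_outcomes(params, strategy, n_patients = 2e5)
    expect_lt(abs(res$total_cost - sim$mean_cost), 3 * sim$se_cost)
    expect_lt(abs(res$total_effect - sim$mean_effect), 3 * sim$se_effect)
  }
})

test_that("raising any single failure probability cannot help the patient", {
  params <- base_params()
  baseline <- run_cohort(params, "four")
  init_cost <- params$costs$new_four
  for (count in c(4, 3, 2)) {
    bumped <- params
    bumped$p_implant[count + 1] <- min(1, bumped$p_implant[count + 1] + 0.05)
    res <- run_cohort(bumped, "four")
    expect_lte(res$total_effect, baseline$total_effect)
    expect_gte(res$total_cost - init_cost, baseline$total_cost - init_cost)

    bumped_d <- params
    bumped_d$p_denture[count + 1] <- min(1, bumped_d$p_denture[count + 1] + 0.05)
    res_d <- run_cohort(bumped_d, "four")
    expect_lte(res_d$total_effect, baseline$total_effect)
    expect_gte(res_d$total_cost - init_cost, baseline$total_cost - init_cost)
  }
})

test_that("at modal parameters six implants are more effective and more costly", {
  for (horizon in c(1L, 3L, 10L)) {
    params <- base_params(horizon = horizon)
    six <- run_cohort(params, "six")
    four <- run_cohort(params, "four")
    expect_gte(six$total_effect, four$total_effect)
    expect_gte(six$total_cost, four$total_cost)
  }
})
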
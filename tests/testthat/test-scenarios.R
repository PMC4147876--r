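test_that("the reference suite contains the twelve documented scenarios", {
  scenarios <- reference_scenarios()
  expect_identical(length(scenarios), 12L)
  expect_identical(
    names(scenarios),
    c("base_case", "satisfaction_A", "satisfaction_B",
      "no_implant_failure_0.00", "no_implant_failure_0.06", "no_implant_failure_0.12",
      "repair_adjustment_0.0", "repair_adjustment_0.2", "repair_adjustment_0.4",
      "repair_adjustment_0.6", "repair_adjustment_0.8", "repair_adjustment_1.0")
  )
  expect_identical(scenarios$satisfaction_A$satisfaction[["4"]], 0.80)
  expect_identical(scenarios$satisfaction_B$satisfaction[["2"]], 0.77)
  expect_null(scenarios$base_case$satisfaction)
  expect_identical(scenarios$`repair_adjustment_0.4`$repair_adjustment, 0.4)
  expect_identical(scenarios$`no_implant_failure_0.06`$no_implant_mode, 0.06)
})

test_that("applying a scenario overrides exactly the targeted pieces", {
  model <- base_case_model()

  a <- apply_scenario(model, reference_scenarios()$satisfaction_A)
  expect_identical(a$satisfaction$satisfaction,
                   c(0.63, 0.67, 0.72, 0.76, 0.80, 0.85, 0.89))
  expect_identical(a$failure_rates, model$failure_rates)
  expect_identical(a$repair_adjustment, model$repair_adjustment)
  expect_identical(a$costs, model$costs)

  base_sat <- apply_scenario(model, reference_scenarios()$base_case)
  expect_identical(base_sat$satisfaction$satisfaction,
                   c(0.63, 0.735, 0.84, 0.865, 0.89, 0.89, 0.89))

  fixed <- apply_scenario(model, od_scenario("adj0", repair_adjustment = 0))
  expect_identical(fixed$repair_adjustment, tri(0, 0, 0))
  expect_identical(fixed$satisfaction, model$satisfaction)

  none <- apply_scenario(model, od_scenario("nf", no_implant_mode = 0.12))
  row <- dplyr::filter(none$failure_rates, .data$type == "denture", .data$count == 0)
  expect_identical(c(row$low, row$mode, row$high), c(0.024, 0.12, 0.24))
  other <- dplyr::filter(none$failure_rates, !(.data$type == "denture" & .data$count == 0))
  expect_identical(other,
                   dplyr::filter(model$failure_rates,
                                 !(.data$type == "denture" & .data$count == 0)))
})

test_that("invalid scenario overrides are rejected", {
  expect_error(od_scenario("bad", satisfaction = c("6" = 0.8, "4" = 0.9)),
               class = "odcea_invalid_scenario")
  expect_error(
    od_scenario("bad", satisfaction = c("6" = 0.8, "5" = 0.85, "4" = 0.9, "3" = 0.7,
                                        "2" = 0.6, "1" = 0.5, "0" = 0.4)),
    class = "odcea_invalid_satisfaction"
  )
  expect_error(od_scenario("bad", no_implant_mode = 0.6),
               class = "odcea_invalid_scenario")
  expect_error(od_scenario("bad", repair_adjustment = 1.2),
               class = "odcea_invalid_scenario")
})

test_that("alternative satisfaction scenarios lower the threshold, fixed adjustment orders it", {
  n <- 2000
  base <- find_threshold(simulate_psa(base_case_model(), n, cost_factor = 1.0, seed = 6),
                         n_boot = 10)
  model_a <- apply_scenario(base_case_model(), reference_scenarios()$satisfaction_A)
  a <- find_threshold(simulate_psa(model_a, n, cost_factor = 1.0, seed = 6), n_boot = 10)
  expect_lt(a$threshold, 0.25 * base$threshold)

  adj0 <- apply_scenario(base_case_model(),
                         reference_scenarios()$`repair_adjustment_0.0`)
  adj1 <- apply_scenario(base_case_model(),
                         reference_scenarios()$`repair_adjustment_1.0`)
  t0 <- find_threshold(simulate_psa(adj0, n, cost_factor = 1.0, seed = 6), n_boot = 10)
  t1 <- find_threshold(simulate_psa(adj1, n, cost_factor = 1.0, seed = 6), n_boot = 10)
  expect_lt(t0$threshold, base$threshold)
  expect_gt(t1$threshold, base$threshold)
})

test_that("random instances are valid models and reproducible from the seed", {
  for (seed in c(1, 7, 13, 101, 555, 2024)) {
    model <- random_instance(seed)
    expect_s3_class(model, "od_model")
    rates <- model$failure_rates
    expect_true(all(rates$low >= 0 & rates$high <= 1))
    for (tp in c("implant", "denture")) {
      modes <- dplyr::filter(rates, .data$type == tp, .data$count >= 1) |>
        dplyr::arrange(.data$count)
      expect_true(all(diff(modes$mode) < 0))
    }
    expect_true(all(diff(model$satisfaction$satisfaction) >= 0))
    # the whole pipeline runs on the instance
    psa <- simulate_psa(model, n_draws = 200, seed = seed)
    expect_true(all(is.finite(psa$cost_six)) && all(is.finite(psa$effect_four)))
  }
  expect_identical(random_instance(99), random_instance(99))
  expect_false(identical(random_instance(99), random_instance(100)))
})
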
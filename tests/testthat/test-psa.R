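test_that("with every distribution collapsed to its mode the PSA is deterministic", {
  model <- degenerate_base_case()
  psa <- simulate_psa(model, n_draws = 50, cost_factor = 2.3, seed = 5)
  params <- realize_parameters(base_case_model(), cost_factor = 2.3)
  six <- run_cohort(params, "six")
  four <- run_cohort(params, "four")
  expect_equal(psa$cost_six, rep(six$total_cost, 50), tolerance = 1e-12)
  expect_equal(psa$effect_six, rep(six$total_effect, 50), tolerance = 1e-12)
  expect_equal(psa$cost_four, rep(four$total_cost, 50), tolerance = 1e-12)
  expect_equal(psa$effect_four, rep(four$total_effect, 50), tolerance = 1e-12)
})

test_that("the same seed reproduces the run and different seeds differ", {
  model <- base_case_model()
  a <- simulate_psa(model, n_draws = 200, seed = 42)
  b <- simulate_psa(model, n_draws = 200, seed = 42)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- simulate_psa(model, n_draws = 200, seed = 43)
  expect_false(identical(a$cost_six, c$cost_six))
})

test_that("growing the number of draws keeps the initial draws bit-identical", {
  model <- base_case_model()
  small <- draw_parameters(model, 100, seed = 9)
  large <- draw_parameters(model, 250, seed = 9)
  expect_identical(small, large[1:100, ])
  # and also under a sampled cost factor, which consumes the same 15th column
  small_s <- draw_parameters(model, 100, cost_factor = tri(1.0, 2.3, 3.5), seed = 9)
  large_s <- draw_parameters(model, 250, cost_factor = tri(1.0, 2.3, 3.5), seed = 9)
  expect_identical(small_s, large_s[1:100, ])
  # fixed- and sampled-factor modes consume the identical uniform stream, so
  # the probability columns agree bit for bit across the two modes
  prob_cols <- c(paste0("p_implant_", 6:1), paste0("p_denture_", 6:0),
                 "repair_adjustment")
  expect_identical(small[prob_cols], small_s[prob_cols])
})

test_that("sampled parameters respect their triangular supports", {
  model <- base_case_model()
  draws <- draw_parameters(model, 2000, cost_factor = tri(1.0, 2.3, 3.5), seed = 31)
  rates <- model$failure_rates
  check_col <- function(col, tp, n) {
    row <- dplyr::filter(rates, .data$type == tp, .data$count == n)
    expect_true(all(draws[[col]] >= row$low & draws[[col]] <= row$high))
  }
  for (n in 1:6) {
    check_col(paste0("p_implant_", n), "implant", n)
    check_col(paste0("p_denture_", n), "denture", n)
  }
  check_col("p_denture_0", "denture", 0)
  expect_true(all(draws$repair_adjustment >= 0.8 & draws$repair_adjustment <= 0.99))
  expect_true(all(draws$cost_factor >= 1.0 & draws$cost_factor <= 3.5))

  # sample means sit within 3 Monte Carlo standard errors of the closed form
  d6 <- tri(0.014, 0.018, 0.023)
  sd6 <- sqrt((d6$low^2 + d6$mode^2 + d6$high^2 - d6$low * d6$mode -
                 d6$low * d6$high - d6$mode * d6$high) / 18)
  expect_lt(abs(mean(draws$p_implant_6) - tri_mean(d6)), 3 * sd6 / sqrt(2000))
})

test_that("a fixed cost factor fixes every realized cost across draws", {
  draws <- draw_parameters(base_case_model(), 50, cost_factor = 3.5, seed = 2)
  expect_identical(unique(draws$cost_factor), 3.5)
  expect_identical(unique(draws$cost_new_six), 4392.27 + 5070.30)
  expect_identical(unique(draws$cost_repair_denture), 103.16 + 50)
  expect_error(draw_parameters(base_case_model(), 5, cost_factor = 0.5),
               class = "odcea_invalid_cost")
  expect_error(draw_parameters(base_case_model(), 5, cost_factor = tri(0.5, 2, 3)),
               class = "odcea_invalid_cost")
})

test_that("tidy() and glance() reshape the PSA faithfully", {
  psa <- simulate_psa(base_case_model(), n_draws = 40, seed = 3)
  long <- tidy(psa)
  expect_identical(nrow(long), 80L)
  expect_setequal(names(long), c("draw", "strategy", "cost", "effect"))
  row <- dplyr::filter(long, .data$draw == 17, .data$strategy == "six")
  expect_identical(row$cost, psa$cost_six[17])
  expect_identical(row$effect, psa$effect_six[17])

  g <- glance(psa)
  expect_identical(g$n_draws, 40L)
  expect_equal(g$mean_inc_cost, mean(psa$cost_six - psa$cost_four))
  expect_equal(g$median_icer,
               stats::median((psa$cost_six - psa$cost_four) /
                               (psa$effect_six - psa$effect_four)))
})

test_that("every draw has the six-implant strategy costlier and more effective", {
  psa <- simulate_psa(base_case_model(), n_draws = 5000, seed = 8,
                      cost_factor = tri(1.0, 2.3, 3.5))
  expect_true(all(psa$cost_six > psa$cost_four))
  expect_true(all(psa$effect_six > psa$effect_four))
})
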
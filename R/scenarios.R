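#' The base-case overdenture decision model
#'
#' The default parameterization: annual implant- and denture-failure triangular
#' distributions anchored at the six- and four-implant evidence (intermediate
#' counts interpolated), satisfaction point estimates anchored at six/four
#' (0.89), two (0.84) and zero (0.63) implants, a `Triangular(0.8, 0.9, 0.99)`
#' repair-period adjustment, the German fee-schedule cost table at complexity
#' factors 1.0 / 2.3 / 3.5, and a ten-year horizon of annual cycles.
#'
#' @param horizon Number of annual cycles (default 10).
#' @return An [od_model()].
#' @examples
#' model <- base_case_model()
#' model$failure_rates
#' @export
base_case_model <- function(horizon = 10L) {
  od_model(
    failure_rates = interpolate_failure_rates(
      implant_six  = tri(0.014, 0.018, 0.023),
      implant_four = tri(0.030, 0.037, 0.046),
      denture_six  = tri(0.015, 0.026, 0.044),
      denture_four = tri(0.022, 0.035, 0.069),
      denture_none = tri(0.01, 0.05, 0.10)
    ),
    satisfaction = interpolate_satisfaction(
      c("6" = 0.89, "4" = 0.89, "2" = 0.84, "0" = 0.63)
    ),
    repair_adjustment = tri(0.8, 0.9, 0.99),
    costs = base_case_costs(),
    horizon = horizon
  )
}

base_case_costs <- function() {
  cost_schedule(
    labor = tibble::tribble(
      ~item,             ~factor, ~cost,
      "new_six",         1.0,     1472.67,
      "new_six",         2.3,     2990.86,
      "new_six",         3.5,     4392.27,
      "new_four",        1.0,     1130.07,
      "new_four",        2.3,     2199.98,
      "new_four",        3.5,     3190.67,
      "repair_implant",  1.0,     206.68,
      "repair_implant",  2.3,     267.35,
      "repair_implant",  3.5,     323.39,
      "repair_denture",  1.0,     65.19,
      "repair_denture",  2.3,     84.93,
      "repair_denture",  3.5,     103.16
    ),
    material = c(
      new_six = 5070.30,
      new_four = 4507.82,
      repair_implant = 160.00,
      repair_denture = 50.00
    )
  )
}

#' Define a sensitivity-analysis scenario
#'
#' A scenario is a labelled set of overrides on the base-case model: an
#' alternative full satisfaction table, a different mode for the no-implant
#' denture-failure distribution, and/or a fixed (degenerate) repair-period
#' adjustment. Overrides must satisfy the underlying invariants (bounded,
#' monotone).
#'
#' @param label Scenario name.
#' @param satisfaction Optional named numeric vector over counts `"0"` .. `"6"`
#'   replacing the satisfaction table.
#' @param no_implant_mode Optional mode for the no-implant denture-failure
#'   distribution; its minimum and maximum keep the base case's relative shape
#'   (0.2x and 2x the mode), and a mode of 0 collapses to a point mass at 0.
#' @param repair_adjustment Optional fixed repair-adjustment value in `[0, 1]`,
#'   replacing the triangular distribution by a point mass.
#'
#' @return An object of class `"od_scenario"`.
#' @export
od_scenario <- function(label, satisfaction = NULL, no_implant_mode = NULL,
                        repair_adjustment = NULL) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.null(satisfaction)) {
    if (!all(as.character(0:6) %in% names(satisfaction))) {
      rlang::abort("scenario satisfaction override must name counts '0' through '6'",
                   class = "odcea_invalid_scenario")
    }
    validate_satisfaction(tibble::tibble(
      count = 0:6, satisfaction = unname(satisfaction[as.character(0:6)])
    ))
  }
  if (!is.null(no_implant_mode)) {
    stopifnot(is.numeric(no_implant_mode), length(no_implant_mode) == 1L)
    if (no_implant_mode < 0 || 2 * no_implant_mode > 1) {
      rlang::abort("no-implant failure mode out of range", class = "odcea_invalid_scenario")
    }
  }
  if (!is.null(repair_adjustment)) {
    stopifnot(is.numeric(repair_adjustment), length(repair_adjustment) == 1L)
    if (repair_adjustment < 0 || repair_adjustment > 1) {
      rlang::abort("repair adjustment must lie in [0, 1]", class = "odcea_invalid_scenario")
    }
  }
  structure(
    list(label = label, satisfaction = satisfaction,
         no_implant_mode = no_implant_mode, repair_adjustment = repair_adjustment),
    class = "od_scenario"
  )
}

#' @export
print.od_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s'\n", x$label))
  if (!is.null(x$satisfaction)) {
    cat("  satisfaction override:",
        paste(x$satisfaction[as.character(6:0)], collapse = ", "),
        "(counts 6..0)\n")
  }
  if (!is.null(x$no_implant_mode)) {
    cat("  no-implant denture-failure mode:", x$no_implant_mode, "\n")
  }
  if (!is.null(x$repair_adjustment)) {
    cat("  repair adjustment fixed at:", x$repair_adjustment, "\n")
  }
  invisible(x)
}

#' Apply a scenario's overrides to a model
#'
#' @param model An [od_model()].
#' @param scenario An [od_scenario()].
#' @return A modified [od_model()].
#' @export
apply_scenario <- function(model, scenario) {
  stopifnot(inherits(model, "od_model"), inherits(scenario, "od_scenario"))
  satisfaction <- if (is.null(scenario$satisfaction)) {
    model$satisfaction
  } else {
    tibble::tibble(count = 0:6,
                   satisfaction = unname(scenario$satisfaction[as.character(0:6)]))
  }
  failure_rates <- model$failure_rates
  if (!is.null(scenario$no_implant_mode)) {
    m <- scenario$no_implant_mode
    idx <- failure_rates$type == "denture" & failure_rates$count == 0
    failure_rates$low[idx] <- 0.2 * m
    failure_rates$mode[idx] <- m
    failure_rates$high[idx] <- 2 * m
  }
  adjustment <- if (is.null(scenario$repair_adjustment)) {
    model$repair_adjustment
  } else {
    tri(scenario$repair_adjustment, scenario$repair_adjustment, scenario$repair_adjustment)
  }
  od_model(failure_rates, satisfaction, adjustment, model$costs, model$horizon)
}

#' Reference scenario suite for the one-way sensitivity analysis
#'
#' The scenarios explored in the sensitivity analysis: the base case;
#' alternative satisfaction scenario A, a constant satisfaction decline per
#' implant lost (0.89, 0.85, 0.80, 0.76, 0.72, 0.67, 0.63 for counts 6..0);
#' alternative satisfaction scenario B, a proportionally increasing decline
#' (0.89, 0.88, 0.85, 0.82, 0.77, 0.70, 0.63); the no-implant denture-failure
#' mode varied over 0.00, 0.06 and 0.12; and the repair-period adjustment fixed
#' at 0.0, 0.2, 0.4, 0.6, 0.8 and 1.0.
#'
#' @return A named list of [od_scenario()] objects (12 scenarios; crossing them
#'   with the three cost factors yields the 36-cell threshold table).
#' @export
reference_scenarios <- function() {
  sat_a <- c("6" = 0.89, "5" = 0.85, "4" = 0.80, "3" = 0.76,
             "2" = 0.72, "1" = 0.67, "0" = 0.63)
  sat_b <- c("6" = 0.89, "5" = 0.88, "4" = 0.85, "3" = 0.82,
             "2" = 0.77, "1" = 0.70, "0" = 0.63)
  scenarios <- c(
    list(od_scenario("base_case")),
    list(od_scenario("satisfaction_A", satisfaction = sat_a)),
    list(od_scenario("satisfaction_B", satisfaction = sat_b)),
    purrr::map(c(0.00, 0.06, 0.12), function(m) {
      od_scenario(sprintf("no_implant_failure_%.2f", m), no_implant_mode = m)
    }),
    purrr::map(seq(0, 1, by = 0.2), function(a) {
      od_scenario(sprintf("repair_adjustment_%.1f", a), repair_adjustment = a)
    })
  )
  stats::setNames(scenarios, purrr::map_chr(scenarios, "label"))
}

#' Generate a random, structurally valid model instance
#'
#' Draws a random parameterization that satisfies every structural assumption
#' of the analysis -- failure-rate modes decreasing in implant count within
#' `[0, 0.2]`, monotone satisfaction anchors in `[0.5, 1]`, six-implant costs
#' above four-implant costs, labor costs non-decreasing in the complexity
#' factor -- for use as a property-testing fixture across the whole pipeline.
#' Reproducible: the same seed yields the same instance.
#'
#' @param seed Integer seed.
#' @param horizon Number of annual cycles (default 10).
#' @return An [od_model()].
#' @export
random_instance <- function(seed, horizon = 10L) {
  set.seed(seed)
  # Anchored triangle pair for one failure type: the six-implant mode lies
  # below the four-implant mode, and the four-implant low/high gaps are at
  # least as wide as the six-implant ones, so linear extrapolation of the
  # (low, mode, high) components down to count 1 preserves their ordering.
  rand_tri_pair <- function() {
    m6 <- stats::runif(1, 0.005, 0.08)
    m4 <- m6 + stats::runif(1, 0.01, 0.045)
    gap_low6 <- stats::runif(1, 0.0005, 0.004)
    gap_low4 <- gap_low6 + stats::runif(1, 0, 0.003)
    gap_high6 <- stats::runif(1, 0.0005, 0.004)
    gap_high4 <- gap_high6 + stats::runif(1, 0, 0.003)
    list(six = tri(m6 - gap_low6, m6, m6 + gap_high6),
         four = tri(m4 - gap_low4, m4, m4 + gap_high4))
  }
  # keep the count-1 extrapolation (2.5 steps beyond four) inside [0, 0.2]
  implant <- rand_tri_pair()
  denture <- rand_tri_pair()
  dn_mode <- stats::runif(1, 0.01, 0.15)
  den0 <- tri(stats::runif(1, 0.2, 1) * dn_mode, dn_mode,
              dn_mode + stats::runif(1, 0.005, 0.05))

  anchors <- sort(stats::runif(4, 0.5, 1)) # counts 0, 2, 4, 6
  satisfaction <- interpolate_satisfaction(
    c("6" = anchors[4], "4" = anchors[3], "2" = anchors[2], "0" = anchors[1])
  )
  adjustment_mode <- stats::runif(1, 0.3, 0.95)
  adjustment <- tri(max(0, adjustment_mode - 0.1), adjustment_mode,
                    min(1, adjustment_mode + 0.1))

  base_labor <- c(new_four = stats::runif(1, 800, 1500),
                  repair_implant = stats::runif(1, 100, 300),
                  repair_denture = stats::runif(1, 30, 100))
  base_labor <- c(new_six = base_labor[["new_four"]] + stats::runif(1, 200, 600),
                  base_labor)
  growth <- sort(c(1, stats::runif(2, 1, 3.2)))
  labor <- purrr::map_dfr(COST_ITEMS, function(it) {
    tibble::tibble(item = it, factor = COST_FACTOR_ANCHORS,
                   cost = base_labor[[it]] * growth)
  })
  material <- c(new_six = stats::runif(1, 3000, 6000),
                new_four = 0, repair_implant = stats::runif(1, 80, 250),
                repair_denture = stats::runif(1, 20, 80))
  material[["new_four"]] <- material[["new_six"]] - stats::runif(1, 100, 500)

  od_model(
    failure_rates = interpolate_failure_rates(implant$six, implant$four,
                                              denture$six, denture$four, den0),
    satisfaction = satisfaction,
    repair_adjustment = adjustment,
    costs = cost_schedule(labor, material),
    horizon = horizon
  )
}
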
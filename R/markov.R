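#' Within-cycle failure-event distribution
#'
#' In every annual cycle a denture in the state with `n` remaining implants can
#' stay sound, suffer an implant failure, suffer a denture failure, or both.
#' Implant and denture failures are assumed independent, so the four disjoint
#' event probabilities are the products of the two marginal annual
#' probabilities. At `n = 0` no implant remains, so implant failure is
#' structurally impossible.
#'
#' @param n Implant count at cycle start (0-6).
#' @param params Realized parameters from [realize_parameters()].
#'
#' @return A tibble with columns `event` (`"none"`, `"implant"`, `"denture"`,
#'   `"both"`) and `probability`, summing to 1.
#' @export
cycle_events <- function(n, params) {
  stopifnot(inherits(params, "od_parameters"), n %in% 0:6)
  p_i <- params$p_implant[n + 1]
  p_d <- params$p_denture[n + 1]
  if (p_i < 0 || p_i > 1 || p_d < 0 || p_d > 1) {
    rlang::abort("failure probabilities must lie in [0, 1]",
                 class = "odcea_invalid_rate")
  }
  tibble::tibble(
    event = c("none", "implant", "denture", "both"),
    probability = c((1 - p_i) * (1 - p_d), p_i * (1 - p_d), (1 - p_i) * p_d, p_i * p_d)
  )
}

#' Cost and satisfaction accrued by one cycle event
#'
#' An implant failure (alone or together with a denture failure) incurs the
#' repair-after-implant-failure cost, a denture failure the
#' repair-without-implant-loss cost; when both occur in one cycle both repairs
#' are charged. The cycle's satisfaction is the satisfaction score of the state
#' occupied during the cycle -- the cycle-start implant count -- multiplied
#' once by the realized repair adjustment when at least one failure occurred
#' (one repair episode per cycle, however many repairs it bundles). An implant
#' lost this cycle lowers the satisfaction score from the next cycle onwards,
#' via the state transition.
#'
#' @param n_start Implant count at cycle start (0-6).
#' @param event One of `"none"`, `"implant"`, `"denture"`, `"both"`.
#' @param params Realized parameters from [realize_parameters()].
#'
#' @return A list with elements `cost` (euro) and `satisfaction`
#'   (satisfaction-year fraction) and `n_end` (implant count entering the next
#'   cycle).
#' @export
cycle_reward <- function(n_start, event, params) {
  stopifnot(inherits(params, "od_parameters"), n_start %in% 0:6)
  event <- match.arg(event, c("none", "implant", "denture", "both"))
  implant_failed <- event %in% c("implant", "both")
  denture_failed <- event %in% c("denture", "both")
  if (implant_failed && n_start == 0) {
    rlang::abort("no implant can fail when none remains", class = "odcea_invalid_event")
  }
  cost <- 0
  if (implant_failed) cost <- cost + params$costs$repair_implant
  if (denture_failed) cost <- cost + params$costs$repair_denture
  sat <- params$satisfaction[n_start + 1]
  if (implant_failed || denture_failed) sat <- sat * params$repair_adjustment
  list(
    cost = cost,
    satisfaction = sat,
    n_end = as.integer(n_start) - as.integer(implant_failed)
  )
}

#' Evaluate one treatment strategy over the model horizon
#'
#' Runs the Markov cohort recursion for a six- or four-implant bar-retained
#' overdenture under one fully realized parameter set. All probability mass
#' starts at the strategy's initial implant count and the new-denture cost
#' (labor at the realized complexity factor plus material/lab) is charged at
#' time zero. Each annual cycle then accrues the expected repair cost and the
#' expected satisfaction by enumerating the four within-cycle events via
#' [cycle_events()] and [cycle_reward()], and propagates the implant-count
#' distribution: an implant failure moves mass down by exactly one count, and
#' implants are never replaced, so the mean implant count can only decrease.
#' Neither costs nor effects are discounted and no half-cycle correction is
#' applied. The recursion is deterministic: identical inputs give bit-identical
#' outputs.
#'
#' @param params Realized parameters from [realize_parameters()].
#' @param strategy `"six"` or `"four"`, the initial implant count.
#'
#' @return A list of class `"od_cohort"` with elements `strategy`,
#'   `total_cost` (euro), `total_effect` (satisfaction-years) and `trace`, a
#'   tibble with one row per cycle: cycle index, cycle-start occupancy
#'   probabilities `p_count_0` .. `p_count_6`, `expected_cost` and
#'   `expected_satisfaction` for the cycle.
#' @examples
#' model <- base_case_model()
#' run_cohort(realize_parameters(model, cost_factor = 2.3), "six")
#' @export
run_cohort <- function(params, strategy = c("six", "four")) {
  stopifnot(inherits(params, "od_parameters"))
  strategy <- match.arg(strategy)
  n0 <- if (strategy == "six") 6L else 4L

  mass <- numeric(7)
  mass[n0 + 1] <- 1
  total_cost <- params$costs[[paste0("new_", strategy)]]
  total_effect <- 0
  trace <- vector("list", params$horizon)

  for (cycle in seq_len(params$horizon)) {
    cycle_cost <- 0
    cycle_sat <- 0
    next_mass <- numeric(7)
    for (n in 0:6) {
      if (mass[n + 1] == 0) next
      events <- cycle_events(n, params)
      for (k in seq_len(nrow(events))) {
        p <- events$probability[k]
        if (p == 0) next
        reward <- cycle_reward(n, events$event[k], params)
        cycle_cost <- cycle_cost + mass[n + 1] * p * reward$cost
        cycle_sat <- cycle_sat + mass[n + 1] * p * reward$satisfaction
        next_mass[reward$n_end + 1] <- next_mass[reward$n_end + 1] + mass[n + 1] * p
      }
    }
    trace[[cycle]] <- tibble::tibble(
      cycle = cycle,
      !!!stats::setNames(as.list(mass), paste0("p_count_", 0:6)),
      expected_cost = cycle_cost,
      expected_satisfaction = cycle_sat
    )
    total_cost <- total_cost + cycle_cost
    total_effect <- total_effect + cycle_sat
    mass <- next_mass
  }

  structure(
    list(
      strategy = strategy,
      total_cost = total_cost,
      total_effect = total_effect,
      trace = dplyr::bind_rows(trace)
    ),
    class = "od_cohort"
  )
}

#' @export
print.od_cohort <- function(x, ...) {
  cat(sprintf("%s-implant strategy: total cost %.2f EUR, total effect %.4f satisfaction-years (%d cycles)\n",
              x$strategy, x$total_cost, x$total_effect, nrow(x$trace)))
  invisible(x)
}

#' @rdname run_cohort
#' @param x An `od_cohort` object.
#' @param ... Unused.
#' @method tidy od_cohort
#' @export
tidy.od_cohort <- function(x, ...) {
  x$trace
}

#' @rdname run_cohort
#' @method glance od_cohort
#' @export
glance.od_cohort <- function(x, ...) {
  tibble::tibble(
    strategy = x$strategy,
    total_cost = x$total_cost,
    total_effect = x$total_effect,
    horizon = nrow(x$trace)
  )
}

# Vectorized cohort evaluation across PSA draws.
#
# `draws` is the tibble produced by draw_parameters(); columns p_implant_6..1,
# p_denture_6..1, p_denture_0, repair_adjustment plus realized costs. The
# algebra collapses the four-event enumeration of run_cohort(): expected cycle
# cost from state n is p_i * repair_implant + p_d * repair_denture (repairs are
# additive and independent), expected cycle satisfaction is
# s(n) * ((1 - p_any) + adjustment * p_any) with p_any = p_i + p_d - p_i p_d,
# and mass moves down one count with probability p_i. Returns cost/effect
# vectors; run_cohort() is the readable single-draw reference and the two are
# tested for exact agreement.
cohort_batch <- function(draws, satisfaction, horizon, strategy) {
  n_draws <- nrow(draws)
  n0 <- if (strategy == "six") 6L else 4L

  p_i <- cbind(0, as.matrix(draws[paste0("p_implant_", 1:6)]))
  p_d <- as.matrix(draws[paste0("p_denture_", 0:6)])
  adj <- draws$repair_adjustment
  c_ri <- draws$cost_repair_implant
  c_rd <- draws$cost_repair_denture

  mass <- matrix(0, n_draws, 7)
  mass[, n0 + 1] <- 1
  cost <- draws[[paste0("cost_new_", strategy)]]
  effect <- numeric(n_draws)
  s_row <- matrix(satisfaction, n_draws, 7, byrow = TRUE)

  for (cycle in seq_len(horizon)) {
    cost <- cost + rowSums(mass * (p_i * c_ri + p_d * c_rd))
    p_any <- p_i + p_d - p_i * p_d
    effect <- effect + rowSums(mass * s_row * ((1 - p_any) + adj * p_any))
    shifted <- mass * (1 - p_i)
    shifted[, 1:6] <- shifted[, 1:6] + mass[, 2:7] * p_i[, 2:7]
    mass <- shifted
  }
  tibble::tibble(cost = cost, effect = effect)
}
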
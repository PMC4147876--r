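N_UNIFORMS_PER_DRAW <- 15L

#' Sample realized parameter sets for probabilistic sensitivity analysis
#'
#' Each draw samples every failure-rate distribution (implant failure for
#' counts 6..1, denture failure for counts 6..1 and 0) and the repair
#' adjustment independently through their triangular inverse CDFs; satisfaction
#' scores are fixed point estimates and are never sampled. The
#' treatment-complexity cost factor is either held fixed (the acceptability-
#' curve analyses are run per complexity tier) or sampled from
#' `Triangular(1.0, 2.3, 3.5)` (the cost-effectiveness-plane scatter).
#'
#' Exactly 15 uniforms are consumed per draw, in a fixed documented order
#' (implant 6..1, denture 6..1, denture 0, adjustment, cost factor), draw by
#' draw. Consequently, for a given seed, increasing `n` leaves the initial
#' draws bit-identical.
#'
#' @param model An [od_model()].
#' @param n Number of draws.
#' @param cost_factor Either a fixed factor in `[1.0, 3.5]` or a [tri()]
#'   distribution over that range.
#' @param seed Optional integer; when supplied the session RNG is seeded before
#'   sampling.
#'
#' @return A tibble with one row per draw: realized probabilities
#'   `p_implant_6` .. `p_implant_1`, `p_denture_6` .. `p_denture_0`,
#'   `repair_adjustment`, `cost_factor`, and realized euro costs
#'   `cost_new_six`, `cost_new_four`, `cost_repair_implant`,
#'   `cost_repair_denture`.
#' @export
draw_parameters <- function(model, n, cost_factor = 2.3, seed = NULL) {
  stopifnot(inherits(model, "od_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  u <- matrix(stats::runif(n * N_UNIFORMS_PER_DRAW),
              ncol = N_UNIFORMS_PER_DRAW, byrow = TRUE)

  rate_tri <- function(type, count) {
    row <- dplyr::filter(model$failure_rates, .data$type == !!type, .data$count == !!count)
    tri(row$low, row$mode, row$high)
  }

  out <- tibble::tibble(draw = seq_len(n))
  for (k in 1:6) { # implant counts 6..1 consume columns 1..6
    count <- 7L - k
    out[[paste0("p_implant_", count)]] <- tri_quantile(rate_tri("implant", count), u[, k])
  }
  for (k in 1:6) { # denture counts 6..1 consume columns 7..12
    count <- 7L - k
    out[[paste0("p_denture_", count)]] <- tri_quantile(rate_tri("denture", count), u[, 6 + k])
  }
  out$p_denture_0 <- tri_quantile(rate_tri("denture", 0), u[, 13])
  out$repair_adjustment <- tri_quantile(model$repair_adjustment, u[, 14])
  out$cost_factor <- if (is_tri(cost_factor)) {
    if (cost_factor$low < 1.0 || cost_factor$high > 3.5) {
      rlang::abort("cost-factor distribution must lie within [1.0, 3.5]",
                   class = "odcea_invalid_cost")
    }
    tri_quantile(cost_factor, u[, 15])
  } else {
    stopifnot(is.numeric(cost_factor), length(cost_factor) == 1L)
    if (cost_factor < 1.0 || cost_factor > 3.5) {
      rlang::abort("cost factor must lie within [1.0, 3.5]", class = "odcea_invalid_cost")
    }
    rep(cost_factor, n) # column 15 is still consumed, keeping the stream layout fixed
  }

  mat <- model$costs$material
  out$cost_new_six <- labor_cost_at_factor(model$costs, "new_six", out$cost_factor) +
    mat[["new_six"]]
  out$cost_new_four <- labor_cost_at_factor(model$costs, "new_four", out$cost_factor) +
    mat[["new_four"]]
  out$cost_repair_implant <- labor_cost_at_factor(model$costs, "repair_implant", out$cost_factor) +
    mat[["repair_implant"]]
  out$cost_repair_denture <- labor_cost_at_factor(model$costs, "repair_denture", out$cost_factor) +
    mat[["repair_denture"]]
  out
}

#' Run the Monte Carlo probabilistic sensitivity analysis
#'
#' Draws `n_draws` parameter sets with [draw_parameters()] and evaluates both
#' the six- and the four-implant strategy on each draw with the Markov cohort
#' engine, using common realized parameters for the two strategies within a
#' draw (both arms face the same failure rates, adjustment and complexity
#' factor, which is what the shared decision-tree structure implies and which
#' also reduces Monte Carlo noise in their comparison). The default protocol is
#' 50,000 repetitions over a 10-cycle horizon.
#'
#' @param model An [od_model()].
#' @param n_draws Number of Monte Carlo repetitions (default 50,000).
#' @param cost_factor Fixed factor or [tri()] distribution; see
#'   [draw_parameters()].
#' @param seed Integer seed (default 1); the run is fully reproducible.
#'
#' @return A tibble of class `"od_psa"` with the realized parameter columns of
#'   [draw_parameters()] plus `cost_six`, `effect_six`, `cost_four`,
#'   `effect_four`. Attributes `horizon`, `n_draws`, `seed` and `cost_factor`
#'   record the protocol.
#' @examples
#' psa <- simulate_psa(base_case_model(), n_draws = 500, seed = 7)
#' glance(psa)
#' @export
simulate_psa <- function(model, n_draws = 50000, cost_factor = 2.3, seed = 1L) {
  stopifnot(inherits(model, "od_model"), n_draws >= 1)
  draws <- draw_parameters(model, n_draws, cost_factor = cost_factor, seed = seed)
  six <- cohort_batch(draws, model$satisfaction$satisfaction, model$horizon, "six")
  four <- cohort_batch(draws, model$satisfaction$satisfaction, model$horizon, "four")
  draws$cost_six <- six$cost
  draws$effect_six <- six$effect
  draws$cost_four <- four$cost
  draws$effect_four <- four$effect
  structure(
    draws,
    class = c("od_psa", class(draws)),
    horizon = model$horizon,
    n_draws = n_draws,
    seed = seed,
    cost_factor = cost_factor
  )
}

#' Tidy a probabilistic sensitivity analysis
#'
#' @param x An `"od_psa"` tibble from [simulate_psa()].
#' @param ... Unused.
#' @return One row per draw and strategy with columns `draw`, `strategy`,
#'   `cost` and `effect` -- the long form of the cost-effectiveness plane.
#' @method tidy od_psa
#' @export
tidy.od_psa <- function(x, ...) {
  tibble::as_tibble(x)[c("draw", "cost_six", "effect_six", "cost_four", "effect_four")] |>
    tidyr::pivot_longer(-"draw",
                        names_to = c(".value", "strategy"),
                        names_pattern = "(cost|effect)_(six|four)")
}

#' Summarize a probabilistic sensitivity analysis
#'
#' @param x An `"od_psa"` tibble from [simulate_psa()].
#' @param ... Unused.
#' @return A one-row tibble with the number of draws, mean costs and effects
#'   per strategy, mean incremental cost and effect, and the median per-draw
#'   incremental cost-effectiveness ratio.
#' @method glance od_psa
#' @export
glance.od_psa <- function(x, ...) {
  tibble::tibble(
    n_draws = nrow(x),
    horizon = attr(x, "horizon"),
    mean_cost_six = mean(x$cost_six),
    mean_cost_four = mean(x$cost_four),
    mean_effect_six = mean(x$effect_six),
    mean_effect_four = mean(x$effect_four),
    mean_inc_cost = mean(x$cost_six - x$cost_four),
    mean_inc_effect = mean(x$effect_six - x$effect_four),
    median_icer = stats::median(icer(x$cost_six, x$effect_six, x$cost_four, x$effect_four))
  )
}
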
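#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
NULL

COUNTS <- 0:6
COST_ITEMS <- c("new_six", "new_four", "repair_implant", "repair_denture")
COST_FACTOR_ANCHORS <- c(1.0, 2.3, 3.5)

#' Build the per-implant-count failure-rate table
#'
#' Clinical evidence reports annual failure probabilities only for six- and
#' four-implant bar-retained overdentures; states with other implant counts are
#' reached as implants are lost. Each of `low`, `mode` and `high` for counts
#' 5, 3, 2 and 1 is filled in on the straight line through the six- and
#' four-implant anchors (extrapolated below four). Implant failure at count 0
#' is a structural point mass at zero (nothing remains to fail); denture
#' failure at count 0 uses its own supplied distribution, since a denture
#' without implant support can still fail.
#'
#' @param implant_six,implant_four [tri()] annual implant-failure distributions
#'   for the six- and four-implant states. The six-implant mode must lie below
#'   the four-implant mode (fewer implants fail more often per denture).
#' @param denture_six,denture_four [tri()] annual denture-failure distributions
#'   for the six- and four-implant states.
#' @param denture_none [tri()] annual denture-failure distribution with no
#'   remaining implants.
#'
#' @return A tibble with columns `count` (0-6), `type` (`"implant"` or
#'   `"denture"`), `low`, `mode`, `high`; all values are probabilities.
#' @examples
#' interpolate_failure_rates(
#'   implant_six  = tri(0.014, 0.018, 0.023),
#'   implant_four = tri(0.030, 0.037, 0.046),
#'   denture_six  = tri(0.015, 0.026, 0.044),
#'   denture_four = tri(0.022, 0.035, 0.069),
#'   denture_none = tri(0.010, 0.050, 0.100)
#' )
#' @export
interpolate_failure_rates <- function(implant_six, implant_four,
                                      denture_six, denture_four,
                                      denture_none) {
  for (d in list(implant_six, implant_four, denture_six, denture_four, denture_none)) {
    stopifnot(is_tri(d))
    if (d$low < 0 || d$high > 1) {
      rlang::abort("failure-rate distributions must lie within [0, 1]",
                   class = "odcea_invalid_rate")
    }
  }
  if (implant_six$mode >= implant_four$mode) {
    rlang::abort("six-implant implant-failure mode must be below the four-implant mode",
                 class = "odcea_invalid_rate")
  }

  line_through <- function(six, four, count) {
    # straight line through the anchors at counts 6 and 4; rounding to 12
    # decimals keeps cells derived from decimal inputs exact decimals
    round(six + (four - six) * (6 - count) / 2, 12)
  }
  fill <- function(six, four) {
    purrr::map_dfr(1:6, function(n) {
      tibble::tibble(
        count = n,
        low  = line_through(six$low,  four$low,  n),
        mode = line_through(six$mode, four$mode, n),
        high = line_through(six$high, four$high, n)
      )
    })
  }
  implant <- fill(implant_six, implant_four)
  denture <- fill(denture_six, denture_four)
  if (any(implant$low < 0) || any(implant$high > 1) ||
      any(denture$low < 0) || any(denture$high > 1)) {
    rlang::abort("extrapolated failure rate left [0, 1]; check the anchor distributions",
                 class = "odcea_invalid_rate")
  }

  out <- dplyr::bind_rows(
    tibble::tibble(count = 0L, type = "implant", low = 0, mode = 0, high = 0),
    dplyr::mutate(implant, type = "implant"),
    tibble::tibble(count = 0L, type = "denture",
                   low = denture_none$low, mode = denture_none$mode,
                   high = denture_none$high),
    dplyr::mutate(denture, type = "denture")
  )
  out <- dplyr::arrange(dplyr::select(out, "count", "type", "low", "mode", "high"),
                        .data$type, .data$count)
  validate_failure_rates(out)
  out
}

validate_failure_rates <- function(rates) {
  stopifnot(is.data.frame(rates),
            all(c("count", "type", "low", "mode", "high") %in% names(rates)))
  if (!setequal(rates$count[rates$type == "implant"], COUNTS) ||
      !setequal(rates$count[rates$type == "denture"], COUNTS)) {
    rlang::abort("failure-rate table must cover implant counts 0-6 for both failure types",
                 class = "odcea_invalid_rate")
  }
  with_rows <- dplyr::filter(rates, !(.data$type == "implant" & .data$count == 0))
  if (any(with_rows$low > with_rows$mode) || any(with_rows$mode > with_rows$high)) {
    rlang::abort("failure-rate rows must satisfy low <= mode <= high",
                 class = "odcea_invalid_rate")
  }
  if (any(rates$low < 0) || any(rates$high > 1)) {
    rlang::abort("failure rates must lie within [0, 1]", class = "odcea_invalid_rate")
  }
  imp0 <- dplyr::filter(rates, .data$type == "implant", .data$count == 0)
  if (any(c(imp0$low, imp0$mode, imp0$high) != 0)) {
    rlang::abort("implant failure at count 0 must be the point mass at 0",
                 class = "odcea_invalid_rate")
  }
  for (tp in c("implant", "denture")) {
    modes <- dplyr::arrange(dplyr::filter(rates, .data$type == tp, .data$count >= 1),
                            .data$count)$mode
    if (any(diff(modes) >= 0)) {
      rlang::abort(sprintf("%s-failure modes must be strictly decreasing in implant count", tp),
                   class = "odcea_invalid_rate")
    }
  }
  invisible(rates)
}

#' Interpolate the satisfaction scale across implant counts
#'
#' Denture satisfaction (1 = full satisfaction, 0 = none) is observed at four
#' anchors: six, four, two and zero implants. Counts 5, 3 and 1 are filled in
#' piecewise-linearly, i.e. as the arithmetic means of their adjacent anchors.
#' Satisfaction values are fixed point estimates throughout; they carry no
#' uncertainty distribution in the sensitivity analysis.
#'
#' @param anchors Named numeric vector with names `"6"`, `"4"`, `"2"`, `"0"`,
#'   values in `[0, 1]`, non-decreasing in implant count.
#'
#' @return A tibble with columns `count` (0-6) and `satisfaction`.
#' @examples
#' interpolate_satisfaction(c("6" = 0.89, "4" = 0.89, "2" = 0.84, "0" = 0.63))
#' @export
interpolate_satisfaction <- function(anchors) {
  stopifnot(is.numeric(anchors))
  needed <- c("6", "4", "2", "0")
  if (!all(needed %in% names(anchors))) {
    rlang::abort("satisfaction anchors must be named '6', '4', '2', '0'",
                 class = "odcea_invalid_satisfaction")
  }
  a <- anchors[needed]
  if (any(a < 0) || any(a > 1)) {
    rlang::abort("satisfaction anchors must lie within [0, 1]",
                 class = "odcea_invalid_satisfaction")
  }
  if (any(diff(rev(a)) < 0)) { # rev(): increasing count order 0,2,4,6
    rlang::abort("satisfaction anchors must be non-decreasing in implant count",
                 class = "odcea_invalid_satisfaction")
  }
  values <- c(
    a[["0"]], round(mean(c(a[["0"]], a[["2"]])), 12),
    a[["2"]], round(mean(c(a[["2"]], a[["4"]])), 12),
    a[["4"]], round(mean(c(a[["4"]], a[["6"]])), 12),
    a[["6"]]
  )
  tibble::tibble(count = COUNTS, satisfaction = values)
}

validate_satisfaction <- function(satisfaction) {
  stopifnot(is.data.frame(satisfaction),
            all(c("count", "satisfaction") %in% names(satisfaction)))
  if (!setequal(satisfaction$count, COUNTS)) {
    rlang::abort("satisfaction table must cover implant counts 0-6",
                 class = "odcea_invalid_satisfaction")
  }
  s <- dplyr::arrange(satisfaction, .data$count)$satisfaction
  if (any(s < 0) || any(s > 1)) {
    rlang::abort("satisfaction must lie within [0, 1]",
                 class = "odcea_invalid_satisfaction")
  }
  if (any(diff(s) < 0)) {
    rlang::abort("satisfaction must be non-decreasing in implant count",
                 class = "odcea_invalid_satisfaction")
  }
  invisible(satisfaction)
}

#' Build a cost schedule
#'
#' Treatment costs split into dentist labor, which scales with the
#' treatment-complexity fee multiplier of the German dental fee schedule
#' (anchored at factors 1.0, 2.3 and 3.5), and material/laboratory costs,
#' which do not depend on the multiplier. Four items are priced: a new
#' six-implant overdenture, a new four-implant overdenture, denture repair
#' after an implant failure, and denture repair without implant loss.
#'
#' @param labor Data frame (or tibble) with columns `item`, `factor`, `cost`:
#'   labor cost in euro per item at each anchor factor.
#' @param material Named numeric vector of factor-independent material/lab
#'   costs in euro, one entry per item.
#'
#' @return A list of class `"od_cost_schedule"`.
#' @export
cost_schedule <- function(labor, material) {
  stopifnot(is.data.frame(labor), all(c("item", "factor", "cost") %in% names(labor)),
            is.numeric(material))
  labor <- tibble::as_tibble(labor)
  if (!setequal(labor$item, COST_ITEMS) || !all(COST_ITEMS %in% names(material))) {
    rlang::abort(sprintf("cost items must be exactly: %s",
                         paste(COST_ITEMS, collapse = ", ")),
                 class = "odcea_invalid_cost")
  }
  if (!all(sort(unique(labor$factor)) == COST_FACTOR_ANCHORS) ||
      nrow(labor) != length(COST_ITEMS) * length(COST_FACTOR_ANCHORS)) {
    rlang::abort("labor costs must be given at exactly the anchor factors 1.0, 2.3, 3.5",
                 class = "odcea_invalid_cost")
  }
  if (any(labor$cost < 0) || any(material < 0)) {
    rlang::abort("costs must be non-negative", class = "odcea_invalid_cost")
  }
  for (it in COST_ITEMS) {
    costs <- dplyr::arrange(dplyr::filter(labor, .data$item == it), .data$factor)$cost
    if (any(diff(costs) < 0)) {
      rlang::abort("labor cost must be non-decreasing in the cost factor",
                   class = "odcea_invalid_cost")
    }
  }
  for (f in COST_FACTOR_ANCHORS) {
    at <- dplyr::filter(labor, .data$factor == f)
    six <- at$cost[at$item == "new_six"] + material[["new_six"]]
    four <- at$cost[at$item == "new_four"] + material[["new_four"]]
    if (six <= four) {
      rlang::abort("a new six-implant denture must cost more than a four-implant one",
                   class = "odcea_invalid_cost")
    }
  }
  structure(list(labor = labor, material = material[COST_ITEMS]),
            class = "od_cost_schedule")
}

#' @export
print.od_cost_schedule <- function(x, ...) {
  cat("Cost schedule (EUR)\n")
  wide <- tidyr::pivot_wider(x$labor, names_from = "factor", values_from = "cost",
                             names_prefix = "labor_")
  wide$material <- x$material[wide$item]
  print(wide)
  invisible(x)
}

#' Dentist labor cost at an arbitrary complexity factor
#'
#' At an anchor factor (1.0, 2.3, 3.5) this returns the scheduled value
#' exactly; between anchors it interpolates piecewise-linearly between the two
#' nearest anchors. The printed anchor columns are not scalar multiples of the
#' factor-1.0 column, so scaling that column by the factor would misprice
#' intermediate complexities; piecewise-linear interpolation honors all three
#' anchors.
#'
#' @param schedule A [cost_schedule()].
#' @param item One of `"new_six"`, `"new_four"`, `"repair_implant"`,
#'   `"repair_denture"`.
#' @param factor Numeric vector of complexity factors in `[1.0, 3.5]`.
#'
#' @return Labor cost(s) in euro.
#' @export
labor_cost_at_factor <- function(schedule, item, factor) {
  stopifnot(inherits(schedule, "od_cost_schedule"))
  if (!item %in% COST_ITEMS) {
    rlang::abort(sprintf("unknown cost item '%s'", item), class = "odcea_invalid_cost")
  }
  if (any(factor < 1.0) || any(factor > 3.5)) {
    rlang::abort("cost factor must lie within [1.0, 3.5]", class = "odcea_invalid_cost")
  }
  rows <- dplyr::arrange(dplyr::filter(schedule$labor, .data$item == !!item), .data$factor)
  stats::approx(rows$factor, rows$cost, xout = factor, method = "linear")$y
}

#' Assemble an overdenture decision model
#'
#' Bundles the failure-rate table, the satisfaction scale, the repair-period
#' satisfaction adjustment, and the cost schedule into one model object; the
#' horizon is the number of annual Markov cycles evaluated.
#'
#' @param failure_rates Output of [interpolate_failure_rates()] (or any table
#'   passing the same invariants).
#' @param satisfaction Output of [interpolate_satisfaction()] or a full
#'   `count`/`satisfaction` table (e.g. an alternative scenario).
#' @param repair_adjustment [tri()] multiplicative satisfaction factor in
#'   `[0, 1]` applied once to any cycle in which a failure occurs.
#' @param costs A [cost_schedule()].
#' @param horizon Integer number of annual cycles (default 10).
#'
#' @return An object of class `"od_model"`.
#' @seealso [base_case_model()] for the default parameterization.
#' @export
od_model <- function(failure_rates, satisfaction, repair_adjustment, costs,
                     horizon = 10L) {
  validate_failure_rates(failure_rates)
  validate_satisfaction(satisfaction)
  stopifnot(is_tri(repair_adjustment), inherits(costs, "od_cost_schedule"))
  if (repair_adjustment$low < 0 || repair_adjustment$high > 1) {
    rlang::abort("repair adjustment must lie within [0, 1]",
                 class = "odcea_invalid_satisfaction")
  }
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1L) {
    rlang::abort("horizon must be a positive integer number of cycles",
                 class = "odcea_invalid_model")
  }
  structure(
    list(
      failure_rates = tibble::as_tibble(failure_rates),
      satisfaction = dplyr::arrange(tibble::as_tibble(satisfaction), .data$count),
      repair_adjustment = repair_adjustment,
      costs = costs,
      horizon = horizon
    ),
    class = "od_model"
  )
}

#' @export
print.od_model <- function(x, ...) {
  cat(sprintf("Overdenture Markov decision model (%d annual cycles)\n", x$horizon))
  cat(sprintf("  repair adjustment: %s\n", format(x$repair_adjustment)))
  cat(sprintf("  satisfaction by implant count 0-6: %s\n",
              paste(format(x$satisfaction$satisfaction), collapse = ", ")))
  invisible(x)
}

#' Resolve a model to point parameter values
#'
#' Produces one fully realized parameter set: a single annual failure
#' probability per implant count and failure type, a realized repair
#' adjustment, and costs evaluated at a realized complexity factor. With
#' `quantiles = NULL` every distribution is resolved at its mode (the
#' deterministic base case); otherwise each parameter is resolved through its
#' inverse CDF at the supplied uniform, which is the primitive the
#' probabilistic sensitivity analysis is built on.
#'
#' @param model An [od_model()].
#' @param cost_factor Treatment-complexity factor in `[1.0, 3.5]`.
#' @param quantiles Optional named list of uniforms in `[0, 1]` with elements
#'   `implant` (counts 1-6, in decreasing-count order 6..1), `denture`
#'   (counts 6..1 then 0) and `adjustment`.
#'
#' @return A list of class `"od_parameters"` with elements `p_implant`,
#'   `p_denture` (numeric, indexed by count 0-6), `satisfaction`,
#'   `repair_adjustment`, `cost_factor`, `costs` (realized euro amounts:
#'   `new_six`, `new_four`, `repair_implant`, `repair_denture`), `horizon`.
#' @export
realize_parameters <- function(model, cost_factor = 2.3, quantiles = NULL) {
  stopifnot(inherits(model, "od_model"))
  rate_at <- function(type, count) {
    row <- dplyr::filter(model$failure_rates, .data$type == !!type, .data$count == !!count)
    tri(row$low, row$mode, row$high)
  }
  resolve <- function(d, u) if (is.null(u)) d$mode else tri_quantile(d, u)

  p_implant <- numeric(7)
  p_denture <- numeric(7)
  for (n in 6:1) {
    ui <- if (is.null(quantiles)) NULL else quantiles$implant[7 - n]
    ud <- if (is.null(quantiles)) NULL else quantiles$denture[7 - n]
    p_implant[n + 1] <- resolve(rate_at("implant", n), ui)
    p_denture[n + 1] <- resolve(rate_at("denture", n), ud)
  }
  u0 <- if (is.null(quantiles)) NULL else quantiles$denture[7]
  p_denture[1] <- resolve(rate_at("denture", 0), u0)
  ua <- if (is.null(quantiles)) NULL else quantiles$adjustment
  adjustment <- resolve(model$repair_adjustment, ua)

  structure(
    list(
      p_implant = p_implant,
      p_denture = p_denture,
      satisfaction = model$satisfaction$satisfaction,
      repair_adjustment = adjustment,
      cost_factor = cost_factor,
      costs = realize_costs(model$costs, cost_factor),
      horizon = model$horizon
    ),
    class = "od_parameters"
  )
}

realize_costs <- function(schedule, factor) {
  total <- function(item) labor_cost_at_factor(schedule, item, factor) +
    schedule$material[[item]]
  list(
    new_six = total("new_six"),
    new_four = total("new_four"),
    repair_implant = total("repair_implant"),
    repair_denture = total("repair_denture")
  )
}
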
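#' Write a model configuration file
#'
#' Serializes a model to a nested YAML configuration: the full per-count
#' failure-rate table (`[low, mode, high]` triples), the satisfaction table,
#' the repair-adjustment triple, the cost schedule and the horizon. The format
#' is the same one [read_model_config()] consumes and the same one the packaged
#' scenario fixtures in `inst/extdata/` use, and numeric values round-trip as
#' decimal strings.
#'
#' @param model An [od_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "od_model"))
  triple <- function(type, count) {
    row <- dplyr::filter(model$failure_rates, .data$type == !!type, .data$count == !!count)
    c(row$low, row$mode, row$high)
  }
  config <- list(
    horizon = model$horizon,
    failure_rates = list(
      implant = stats::setNames(lapply(0:6, function(n) triple("implant", n)),
                                as.character(0:6)),
      denture = stats::setNames(lapply(0:6, function(n) triple("denture", n)),
                                as.character(0:6))
    ),
    satisfaction = stats::setNames(
      as.list(model$satisfaction$satisfaction), as.character(model$satisfaction$count)
    ),
    repair_adjustment = c(model$repair_adjustment$low, model$repair_adjustment$mode,
                          model$repair_adjustment$high),
    costs = list(
      labor = stats::setNames(lapply(COST_ITEMS, function(it) {
        rows <- dplyr::arrange(dplyr::filter(model$costs$labor, .data$item == !!it),
                               .data$factor)
        stats::setNames(as.list(rows$cost), format(rows$factor, nsmall = 1))
      }), COST_ITEMS),
      material = as.list(model$costs$material)
    )
  )
  writeLines(yaml::as.yaml(config, precision = 12), path)
  invisible(path)
}

#' Read a model configuration file
#'
#' @param path YAML configuration written by [write_model_config()] or by hand
#'   in the same shape.
#' @return An [od_model()]. Malformed configurations raise a validation error
#'   naming the offending field.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("configuration file not found: %s", path),
                 class = "odcea_config_error")
  }
  config <- yaml::read_yaml(path)
  need <- c("horizon", "failure_rates", "satisfaction", "repair_adjustment", "costs")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0) {
    rlang::abort(sprintf("configuration is missing field(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "odcea_config_error")
  }
  parse_rates <- function(type) {
    block <- config$failure_rates[[type]]
    if (is.null(block) || !all(as.character(0:6) %in% names(block))) {
      rlang::abort(sprintf("failure_rates.%s must name counts '0' through '6'", type),
                   class = "odcea_config_error")
    }
    purrr::map_dfr(0:6, function(n) {
      v <- as.numeric(block[[as.character(n)]])
      if (length(v) != 3) {
        rlang::abort(sprintf("failure_rates.%s.%d must be a [low, mode, high] triple",
                             type, n),
                     class = "odcea_config_error")
      }
      tibble::tibble(count = n, type = type, low = v[1], mode = v[2], high = v[3])
    })
  }
  failure_rates <- dplyr::bind_rows(parse_rates("implant"), parse_rates("denture"))
  if (!all(as.character(0:6) %in% names(config$satisfaction))) {
    rlang::abort("satisfaction must name counts '0' through '6'",
                 class = "odcea_config_error")
  }
  satisfaction <- tibble::tibble(
    count = 0:6,
    satisfaction = purrr::map_dbl(as.character(0:6),
                                  ~ as.numeric(config$satisfaction[[.x]]))
  )
  adj <- as.numeric(config$repair_adjustment)
  if (length(adj) != 3) {
    rlang::abort("repair_adjustment must be a [low, mode, high] triple",
                 class = "odcea_config_error")
  }
  labor <- purrr::map_dfr(names(config$costs$labor), function(it) {
    anchors <- config$costs$labor[[it]]
    tibble::tibble(item = it, factor = as.numeric(names(anchors)),
                   cost = as.numeric(unlist(anchors)))
  })
  costs <- cost_schedule(labor, unlist(config$costs$material))
  od_model(failure_rates, satisfaction, tri(adj[1], adj[2], adj[3]), costs,
           horizon = config$horizon)
}

#' Validate a model configuration file
#'
#' @param path YAML configuration path.
#' @return `TRUE` invisibly on success; otherwise an error of class
#'   `"odcea_config_error"` (or a table-invariant error) naming the problem.
#' @export
validate_model_config <- function(path) {
  read_model_config(path)
  invisible(TRUE)
}

#' Path to a packaged scenario configuration
#'
#' The package ships the base case and the two alternative satisfaction
#' scenarios as YAML fixtures.
#'
#' @param name One of `"base_case"`, `"satisfaction_A"`, `"satisfaction_B"`.
#' @return Path to the installed configuration file.
#' @export
packaged_config <- function(name = c("base_case", "satisfaction_A", "satisfaction_B")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".yaml"), package = "odcea", mustWork = TRUE)
}

log_msg <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
}

#' Run the end-to-end analysis for one scenario
#'
#' Runs the probabilistic sensitivity analysis at the requested complexity
#' factor, derives acceptability curves, extracts the willingness-to-pay
#' threshold at each complexity tier, evaluates the deterministic (modal)
#' cohort trace for both strategies, and writes everything to `out_dir`:
#'
#' * `psa_draws.csv` -- `draw, strategy, cost_eur, effect_satisfaction_years`
#'   (the cost-effectiveness plane),
#' * `ceac.csv` -- `lambda_eur, p_six, p_four`,
#' * `thresholds.csv` -- `scenario, cost_factor, threshold_eur, mc_se`,
#' * `trace.csv` -- per-cycle occupancy and expected rewards at modal
#'   parameters,
#' * `manifest.json` -- everything needed to reproduce the run bit-identically
#'   (scenario, cost factor, draws, seed, horizon, lambda grid, package
#'   version) plus a timestamp.
#'
#' All CSVs use a header row, decimal points, UTF-8, and plain numbers without
#' currency symbols or thousands separators.
#'
#' @param out_dir Output directory; created (recursively) if absent.
#' @param model Baseline [od_model()]; ignored when `config` is given.
#' @param config Optional YAML configuration path overriding `model`.
#' @param scenario An [od_scenario()], a label from [reference_scenarios()], or
#'   `NULL` for the base case.
#' @param cost_factor Complexity factor for the PSA scatter and acceptability
#'   curves; either a number or a [tri()] distribution (scatter mode).
#' @param threshold_factors Complexity tiers for `thresholds.csv`.
#' @param n_draws,seed Monte Carlo protocol (defaults 50,000 draws, seed 1).
#' @param horizon Optional override of the model's cycle count.
#' @param lambda_max,lambda_step Willingness-to-pay grid for `ceac.csv`.
#' @param verbose Log stage progress via [message()].
#'
#' @return Invisibly, a list with elements `psa`, `ceac`, `thresholds`,
#'   `trace`, `manifest`, `files`.
#' @export
run_analysis <- function(out_dir,
                         model = base_case_model(),
                         config = NULL,
                         scenario = NULL,
                         cost_factor = 2.3,
                         threshold_factors = c(1.0, 2.3, 3.5),
                         n_draws = 50000,
                         seed = 1L,
                         horizon = NULL,
                         lambda_max = 50000,
                         lambda_step = 250,
                         verbose = TRUE) {
  t0 <- Sys.time()
  if (!is.null(config)) model <- read_model_config(config)
  if (!is.null(horizon)) model$horizon <- as.integer(horizon)
  if (is.character(scenario)) scenario <- reference_scenarios()[[scenario]]
  if (is.null(scenario)) scenario <- od_scenario("base_case")
  model <- apply_scenario(model, scenario)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log_msg(verbose, "scenario '%s': %d draws, horizon %d, cost factor %s",
          scenario$label, n_draws, model$horizon,
          if (is_tri(cost_factor)) format(cost_factor) else format(cost_factor))
  psa <- simulate_psa(model, n_draws = n_draws, cost_factor = cost_factor, seed = seed)
  curve <- ceac(psa, lambda_grid = seq(0, lambda_max, by = lambda_step))
  thresholds <- purrr::map_dfr(threshold_factors, function(f) {
    psa_f <- simulate_psa(model, n_draws = n_draws, cost_factor = f, seed = seed)
    find_threshold(psa_f, scenario = scenario$label, cost_factor = f)
  })
  modal <- realize_parameters(
    model,
    cost_factor = if (is_tri(cost_factor)) cost_factor$mode else cost_factor
  )
  trace <- purrr::map_dfr(c("six", "four"), function(s) {
    dplyr::mutate(run_cohort(modal, s)$trace, strategy = s, .before = 1)
  })
  log_msg(verbose, "thresholds: %s EUR/satisfaction-year",
          paste(round(thresholds$threshold), collapse = ", "))

  files <- file.path(out_dir, c("psa_draws.csv", "ceac.csv", "thresholds.csv",
                                "trace.csv", "manifest.json"))
  names(files) <- c("psa_draws", "ceac", "thresholds", "trace", "manifest")
  scatter <- dplyr::rename(tidy.od_psa(psa),
                           cost_eur = "cost", effect_satisfaction_years = "effect")
  write_output_csv(scatter, files[["psa_draws"]])
  write_output_csv(dplyr::rename(curve, lambda_eur = "lambda"), files[["ceac"]])
  write_output_csv(
    dplyr::rename(thresholds, threshold_eur = "threshold")[
      c("scenario", "cost_factor", "threshold_eur", "mc_se")],
    files[["thresholds"]]
  )
  write_output_csv(trace, files[["trace"]])

  manifest <- list(
    scenario = scenario$label,
    cost_factor = if (is_tri(cost_factor)) {
      list(low = cost_factor$low, mode = cost_factor$mode, high = cost_factor$high)
    } else cost_factor,
    threshold_factors = threshold_factors,
    n_draws = n_draws,
    seed = seed,
    horizon = model$horizon,
    lambda_max = lambda_max,
    lambda_step = lambda_step,
    out_dir = normalizePath(out_dir),
    package_version = as.character(utils::packageVersion("odcea")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE, pretty = TRUE)
  log_msg(verbose, "wrote %d files to %s in %.1fs", length(files), out_dir,
          as.numeric(difftime(Sys.time(), t0, units = "secs")))

  invisible(list(psa = psa, ceac = curve, thresholds = thresholds, trace = trace,
                 manifest = manifest, files = files))
}

#' Run the full one-way scenario suite
#'
#' Crosses every scenario of [reference_scenarios()] with the complexity
#' factors 1.0, 2.3 and 3.5 (36 threshold cells) and writes `thresholds.csv`
#' and `manifest.json` to `out_dir`.
#'
#' @inheritParams run_analysis
#' @return Invisibly, the threshold tibble.
#' @export
run_scenario_suite <- function(out_dir, model = base_case_model(), config = NULL,
                               n_draws = 50000, seed = 1L, verbose = TRUE) {
  t0 <- Sys.time()
  if (!is.null(config)) model <- read_model_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scenarios <- reference_scenarios()
  thresholds <- purrr::imap_dfr(scenarios, function(sc, label) {
    log_msg(verbose, "scenario '%s' ...", label)
    one_way_sensitivity(model, scenarios = list(sc), n_draws = n_draws, seed = seed)
  })
  write_output_csv(
    dplyr::rename(thresholds, threshold_eur = "threshold")[
      c("scenario", "cost_factor", "threshold_eur", "mc_se")],
    file.path(out_dir, "thresholds.csv")
  )
  manifest <- list(
    scenarios = names(scenarios), threshold_factors = c(1.0, 2.3, 3.5),
    n_draws = n_draws, seed = seed, horizon = model$horizon,
    out_dir = normalizePath(out_dir),
    package_version = as.character(utils::packageVersion("odcea")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_msg(verbose, "suite of %d thresholds done in %.1fs", nrow(thresholds),
          as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(thresholds)
}

# CSV writer/reader pair; readr renders doubles with the shortest decimal
# string that parses back to the identical binary value, so files round-trip
write_output_csv <- function(df, path) {
  readr::write_csv(df, path)
  invisible(path)
}

#' Read back a CSV written by the analysis runners
#'
#' Parsing goes through the C library's correctly rounded `strtod`, so doubles
#' written by the runners are restored bit-identically.
#'
#' @param path CSV file path.
#' @return A tibble with numeric columns restored at full precision.
#' @export
read_output_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
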
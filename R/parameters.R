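#' @importFrom stats lm coef median quantile rbeta rgamma rnorm runif setNames
#' @importFrom utils write.csv read.csv
NULL

config_error <- function(key, msg) {
  stop(sprintf("invalid configuration [%s]: %s", key, msg), call. = FALSE)
}

check_money <- function(amount, key) {
  if (!is.numeric(amount) || length(amount) != 1L || is.na(amount))
    config_error(key, "amount must be a single number")
  if (amount < 0) config_error(key, "amount must be >= 0")
  # amounts are quoted to the cent; more decimals indicate a data-entry slip
  if (abs(amount * 100 - round(amount * 100)) > 1e-6)
    config_error(key, sprintf("amount %s is not quoted to 2 decimals", format(amount)))
  invisible(amount)
}

#' Create a cost item
#'
#' A single cost component of a treatment arm, in already-converted dollars.
#' Items recur every cycle (`per_cycle`) or are incurred a single time
#' (`once`, at the start of `applies_from_cycle`, by default model entry).
#' The applicability window makes time-limited costs (e.g. parenteral
#' nutrition given only during the 24-week intervention, cycles 0-3)
#' expressible without code changes.
#'
#' @param name Short unique identifier within an arm.
#' @param amount Cost in dollars, non-negative, quoted to the cent.
#' @param recurrence `"per_cycle"` or `"once"`.
#' @param applies_from_cycle First cycle (0-based) in which the item accrues.
#' @param applies_through_cycle Last cycle in which it accrues (`Inf` =
#'   unbounded, the default, matching a per-cycle label with no end date).
#' @return An object of class `cost_item`.
#' @export
cost_item <- function(name, amount, recurrence = c("per_cycle", "once"),
                      applies_from_cycle = 0L, applies_through_cycle = Inf) {
  recurrence <- match.arg(recurrence)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    config_error("cost.name", "name must be a non-empty string")
  check_money(amount, paste0("cost.", name, ".amount"))
  if (applies_from_cycle < 0)
    config_error(paste0("cost.", name, ".applies_from_cycle"), "must be >= 0")
  if (applies_from_cycle > applies_through_cycle)
    config_error(paste0("cost.", name),
                 "applies_from_cycle must be <= applies_through_cycle")
  structure(list(name = name, amount = amount, recurrence = recurrence,
                 applies_from_cycle = as.numeric(applies_from_cycle),
                 applies_through_cycle = as.numeric(applies_through_cycle)),
            class = "cost_item")
}

#' Create a visit-wise utility schedule
#'
#' Exactly five utilities in `[0, 1]`: baseline plus visits 2-5 (visits fall
#' every 6 weeks, at the end of each model cycle).  With `carry_forward`
#' (the default) the visit-5 utility applies to all later cycles.
#'
#' @param values Numeric vector of length 5 (baseline, visit 2, ..., visit 5).
#' @param carry_forward Carry the last utility beyond visit 5?
#' @return An object of class `utility_schedule`.
#' @export
utility_schedule <- function(values, carry_forward = TRUE) {
  if (length(values) != 5L || !is.numeric(values))
    config_error("utilities", "exactly 5 numeric utilities required (baseline, visits 2-5)")
  if (any(is.na(values)) || any(values < 0) || any(values > 1))
    config_error("utilities",
                 sprintf("utilities must lie in [0,1]; got %s",
                         paste(format(values), collapse = ", ")))
  structure(list(values = as.numeric(values),
                 carry_forward = isTRUE(carry_forward)),
            class = "utility_schedule")
}

#' Weibull survival model
#'
#' Parametric survival S(t) = exp(-scale * t^shape) with t in model time
#' units; `time_unit_days` converts model time to days (default one 6-week
#' cycle = 42 days per unit).
#'
#' @param shape Shape parameter (gamma), > 0; < 1 means decreasing hazard.
#' @param scale Scale parameter (lambda), > 0, per (model time unit)^shape.
#' @param time_unit_days Days per model time unit.
#' @return An object of class `weibull_survival`.
#' @export
weibull_survival <- function(shape, scale, time_unit_days = 42) {
  if (!is.numeric(shape) || length(shape) != 1L || is.na(shape) || shape <= 0)
    config_error("survival.shape", "shape must be a single number > 0")
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0)
    config_error("survival.scale", "scale must be a single number > 0")
  if (!is.numeric(time_unit_days) || time_unit_days <= 0)
    config_error("survival.time_unit_days", "must be > 0")
  structure(list(shape = shape, scale = scale,
                 time_unit_days = as.numeric(time_unit_days)),
            class = "weibull_survival")
}

#' Cycle and horizon specification
#'
#' @param cycle_length_days Cycle length in days (6 weeks = 42).
#' @param horizon_cycles Number of cycles; 43 = floor(5 x 365.25 / 42), a
#'   5-year horizon.
#' @param annual_discount_rate Annual discount rate applied identically to
#'   costs and QALYs, compounded pro-rata by exact day count.
#' @return An object of class `cycle_spec`.
#' @export
cycle_spec <- function(cycle_length_days = 42, horizon_cycles = 43,
                       annual_discount_rate = 0.03) {
  if (cycle_length_days <= 0) config_error("cycle.cycle_length_days", "must be > 0")
  if (horizon_cycles < 1) config_error("cycle.horizon_cycles", "must be >= 1")
  if (annual_discount_rate < 0 || annual_discount_rate >= 1)
    config_error("cycle.annual_discount_rate", "must be in [0, 1)")
  structure(list(cycle_length_days = as.numeric(cycle_length_days),
                 horizon_cycles = as.integer(horizon_cycles),
                 annual_discount_rate = as.numeric(annual_discount_rate)),
            class = "cycle_spec")
}

#' Cycle length expressed in the survival model's time units
#'
#' The `u` of the per-cycle transition-probability formula.
#' @param cycle A [cycle_spec()].
#' @param survival A [weibull_survival()].
#' @return Cycle length in model time units (> 0).
#' @export
cycle_u <- function(cycle, survival) {
  cycle$cycle_length_days / survival$time_unit_days
}

#' Treatment arm specification
#'
#' @param name Arm label.
#' @param survival A [weibull_survival()] driving the arm's transitions.
#' @param costs List of [cost_item()]s; names must be unique within the arm.
#' @param utilities A [utility_schedule()].
#' @return An object of class `arm_spec`.
#' @export
arm_spec <- function(name, survival, costs, utilities) {
  stopifnot(inherits(survival, "weibull_survival"),
            inherits(utilities, "utility_schedule"))
  if (!all(vapply(costs, inherits, logical(1), "cost_item")))
    config_error(paste0("arm.", name, ".costs"), "costs must be cost_item objects")
  nm <- vapply(costs, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    config_error(paste0("arm.", name, ".costs"),
                 paste("duplicate cost item name:", nm[duplicated(nm)][1]))
  structure(list(name = name, survival = survival,
                 costs = setNames(costs, nm), utilities = utilities),
            class = "arm_spec")
}

#' Probabilistic sensitivity analysis configuration
#'
#' @param n_iterations Monte Carlo iterations (default 1,000).
#' @param seed Master seed for the per-iteration substreams.
#' @param interval_interpretation How the deterministic fluctuation band
#'   `m (1 +/- f)` maps to a sampling sd: `"ci95"` reads it as a central 95%
#'   interval (sd = m f / 1.96, the default); `"two_sd"` uses sd = m f / 2.
#' @return An object of class `psa_config`.
#' @export
psa_config <- function(n_iterations = 1000L, seed = 20220518L,
                       interval_interpretation = c("ci95", "two_sd")) {
  if (n_iterations < 1) config_error("psa.n_iterations", "must be >= 1")
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 interval_interpretation = match.arg(interval_interpretation)),
            class = "psa_config")
}

#' Full model configuration
#'
#' Exactly two arms: intervention first, comparator second.
#'
#' @param intervention,comparator [arm_spec()] objects.
#' @param cycle A [cycle_spec()].
#' @param wtp Willingness-to-pay threshold in $/QALY (default $29,307, three
#'   times Chinese per-capita GDP).
#' @param psa A [psa_config()].
#' @param dsa Named list of one-way fluctuation fractions by parameter
#'   family: `cost` (0.50), `utility` (0.30), `transition` (0.30).
#' @param utility_mapping `"visit_k2"` (default): cycle k accrues the visit
#'   k+2 utility (visits mark cycle ends, utilities reflect on-treatment
#'   states); `"visit_k1"`: cycle k accrues the visit k+1 utility, i.e.
#'   baseline utility is accrued in cycle 0.
#' @return An object of class `model_config`.
#' @export
model_config <- function(intervention, comparator, cycle = cycle_spec(),
                         wtp = 29307, psa = psa_config(),
                         dsa = list(cost = 0.50, utility = 0.30, transition = 0.30),
                         utility_mapping = c("visit_k2", "visit_k1")) {
  stopifnot(inherits(intervention, "arm_spec"), inherits(comparator, "arm_spec"),
            inherits(cycle, "cycle_spec"), inherits(psa, "psa_config"))
  if (!is.numeric(wtp) || wtp <= 0) config_error("wtp", "must be > 0")
  for (f in c("cost", "utility", "transition"))
    if (is.null(dsa[[f]]) || dsa[[f]] < 0)
      config_error(paste0("dsa.", f), "fluctuation fraction must be >= 0")
  structure(list(arms = list(intervention = intervention, comparator = comparator),
                 cycle = cycle, wtp = as.numeric(wtp), psa = psa,
                 dsa = dsa[c("cost", "utility", "transition")],
                 utility_mapping = match.arg(utility_mapping)),
            class = "model_config")
}

## ---- configuration file (YAML) --------------------------------------------

arm_from_list <- function(x, key) {
  if (is.null(x$name)) config_error(paste0(key, ".name"), "missing arm name")
  if (is.null(x$survival))
    config_error(paste0(key, ".survival"), "missing survival parameters")
  sv <- x$survival
  w <- weibull_survival(shape = sv$shape %||% config_error(paste0(key, ".survival.shape"), "missing"),
                        scale = sv$scale %||% config_error(paste0(key, ".survival.scale"), "missing"),
                        time_unit_days = sv$time_unit_days %||% 42)
  if (is.null(x$utilities)) config_error(paste0(key, ".utilities"), "missing")
  us <- utility_schedule(unlist(x$utilities))
  costs <- lapply(x$costs, function(ci) {
    if (is.null(ci$amount) || !is.numeric(ci$amount))
      config_error(paste0(key, ".costs.", ci$name %||% "?", ".amount"),
                   "missing or non-numeric amount")
    cost_item(name = ci$name, amount = ci$amount,
              recurrence = ci$recurrence %||% "per_cycle",
              applies_from_cycle = ci$applies_from_cycle %||% 0L,
              applies_through_cycle = ci$applies_through_cycle %||% Inf)
  })
  arm_spec(x$name, w, costs, us)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a model configuration from YAML
#'
#' The schema mirrors the parameter table of the analysis: a `cycle` block,
#' `wtp`, `dsa` fluctuation fractions, a `psa` block, optional `currency`
#' metadata (the CNY/USD exchange rate is metadata only -- amounts are stored
#' already converted and the engine never applies it), and an `arms` list of
#' exactly two entries whose `role` fields mark the intervention and the
#' comparator.  Omitted fields take the documented defaults (e.g. a 3%
#' annual discount rate).  Violated invariants raise an error naming the
#' offending key.
#'
#' @param path Path to a YAML configuration file.
#' @return A [model_config()].
#' @seealso [hpncea_example_config()] for the packaged parameter fixture.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$arms) || length(raw$arms) != 2L)
    config_error("arms", "exactly two arms (intervention, comparator) required")
  roles <- vapply(raw$arms, function(a) a$role %||% "", character(1))
  ii <- match("intervention", roles); ci <- match("comparator", roles)
  if (is.na(ii) || is.na(ci))
    config_error("arms.role", "one arm must have role 'intervention' and one 'comparator'")
  cyc <- raw$cycle %||% list()
  dsa_default <- list(cost = 0.50, utility = 0.30, transition = 0.30)
  dsa <- utils::modifyList(dsa_default, raw$dsa %||% list())
  psa_raw <- raw$psa %||% list()
  model_config(
    intervention = arm_from_list(raw$arms[[ii]], paste0("arms.", raw$arms[[ii]]$name %||% ii)),
    comparator   = arm_from_list(raw$arms[[ci]], paste0("arms.", raw$arms[[ci]]$name %||% ci)),
    cycle = cycle_spec(cycle_length_days = cyc$cycle_length_days %||% 42,
                       horizon_cycles = cyc$horizon_cycles %||% 43,
                       annual_discount_rate = cyc$annual_discount_rate %||% 0.03),
    wtp = raw$wtp %||% 29307,
    psa = psa_config(n_iterations = psa_raw$n_iterations %||% 1000L,
                     seed = psa_raw$seed %||% 20220518L,
                     interval_interpretation = psa_raw$interval_interpretation %||% "ci95"),
    dsa = dsa,
    utility_mapping = raw$utility_mapping %||% "visit_k2")
}

arm_to_list <- function(arm, role) {
  list(name = arm$name, role = role,
       survival = list(shape = arm$survival$shape, scale = arm$survival$scale,
                       time_unit_days = arm$survival$time_unit_days),
       utilities = arm$utilities$values,
       costs = lapply(unname(arm$costs), function(ci) {
         out <- list(name = ci$name, amount = ci$amount, recurrence = ci$recurrence)
         if (ci$applies_from_cycle != 0) out$applies_from_cycle <- ci$applies_from_cycle
         if (is.finite(ci$applies_through_cycle))
           out$applies_through_cycle <- ci$applies_through_cycle
         out
       }))
}

#' Write a model configuration to YAML
#'
#' Inverse of [read_config()]: `read_config(write_config(cfg, path))`
#' reproduces the configuration value for value.
#'
#' @param config A [model_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- list(
    wtp = config$wtp,
    cycle = unclass(config$cycle),
    dsa = config$dsa,
    psa = unclass(config$psa),
    utility_mapping = config$utility_mapping,
    arms = list(arm_to_list(config$arms$intervention, "intervention"),
                arm_to_list(config$arms$comparator, "comparator")))
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Packaged parameter fixture
#'
#' Path to (or the parsed form of) the YAML file carrying the published
#' model parameters: per-arm cost items in dollars with their once/per-cycle
#' recurrence, visit-wise utilities, Weibull shape and scale per arm, the
#' 6-week cycle, 5-year horizon, 3% discount rate and the $29,307/QALY
#' willingness-to-pay threshold.
#'
#' @param parsed If `TRUE` return the [model_config()], otherwise the path.
#' @return A path or a `model_config`.
#' @export
hpncea_example_config <- function(parsed = TRUE) {
  p <- system.file("extdata", "table1.yaml", package = "hpncea", mustWork = TRUE)
  if (parsed) read_config(p) else p
}

## ---- result writers -------------------------------------------------------

#' Write an analysis result to CSV
#'
#' Column orders are fixed and documented per class: CEA summaries write
#' `(arm, cost, qaly, d_cost, d_qaly, icer, dominance)`; Markov traces write
#' `(cycle, alive, p_death, cost_inc, qaly_inc, cum_cost, cum_qaly)`; tornado
#' tables write entries sorted by spread descending; PSA results write
#' `(iter, d_cost, d_qaly)`; CEAC curves write `(wtp, probability)`.
#' Numbers round-trip at full double precision.
#'
#' @param x A result object (`cea_result`, `markov_trace`, `tornado`,
#'   `psa_result`, or `ceac` data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) UseMethod("write_results")

write_csv_precise <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.15g", v))
  ok <- tryCatch({ write.csv(df, path, row.names = FALSE, quote = FALSE); TRUE },
                 error = function(e) stop("cannot write results to ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' @export
write_results.cea_result <- function(x, path) {
  df <- data.frame(arm = x$arms$arm, cost = x$arms$cost, qaly = x$arms$effect,
                   d_cost = c(x$d_cost, NA), d_qaly = c(x$d_effect, NA),
                   icer = c(x$icer, NA), dominance = c(x$dominance, NA))
  write_csv_precise(df, path)
}

#' @export
write_results.markov_trace <- function(x, path) {
  write_csv_precise(as.data.frame(x)[, c("cycle", "alive", "p_death", "cost_inc",
                                         "qaly_inc", "cum_cost", "cum_qaly")], path)
}

#' @export
write_results.tornado <- function(x, path) {
  df <- as.data.frame(x)
  df <- df[order(-df$spread), , drop = FALSE]
  write_csv_precise(df, path)
}

#' @export
write_results.psa_result <- function(x, path) {
  write_csv_precise(x$iterations[, c("iter", "d_cost", "d_qaly")], path)
}

#' @export
write_results.ceac <- function(x, path) {
  write_csv_precise(as.data.frame(x)[, c("wtp", "probability")], path)
}

#' @export
write_results.data.frame <- function(x, path) write_csv_precise(x, path)

#' Write a base-case JSON summary
#'
#' @param x A `cea_result`.
#' @param path Output JSON path.
#' @param wtp Willingness-to-pay used for the net-monetary-benefit line.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path, wtp = 29307) {
  stopifnot(inherits(x, "cea_result"))
  out <- list(arms = x$arms, d_cost = x$d_cost, d_effect = x$d_effect,
              icer = x$icer, dominance = x$dominance,
              effect_unit = x$effect_unit, wtp = wtp,
              nmb = nmb(wtp, x$d_effect, x$d_cost))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
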
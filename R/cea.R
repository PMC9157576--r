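## Incremental cost-effectiveness outcomes.

#' Incremental cost-effectiveness ratio and dominance class
#'
#' Increments are intervention minus comparator.  Dominance follows the
#' cost-effectiveness plane: cheaper and more effective is `dominant`,
#' costlier and less effective is `dominated`; both-positive increments are
#' `tradeoff_NE` and both-negative `tradeoff_SW`, the two quadrants where an
#' ICER is meaningful.  A zero effect increment yields an undefined ICER
#' (`NA`) with the increments still reported.
#'
#' @param c1,c0 Total cost, intervention and comparator ($).
#' @param e1,e0 Total effect, intervention and comparator.
#' @param arm_names Labels, intervention first.
#' @param effect_unit Unit label carried on the result (e.g. `"QALY"`,
#'   `"kg"`), so ratios in different units can never be compared silently.
#' @return An object of class `cea_result`: per-arm totals, `d_cost`,
#'   `d_effect`, `icer`, `icer_defined`, `dominance`, `effect_unit`.
#' @export
compute_icer <- function(c1, c0, e1, e0,
                         arm_names = c("intervention", "comparator"),
                         effect_unit = "QALY") {
  stopifnot(is.finite(c1), is.finite(c0), is.finite(e1), is.finite(e0))
  d_cost <- c1 - c0
  d_effect <- e1 - e0
  dominance <-
    if (d_cost < 0 && d_effect > 0) "dominant"
    else if (d_cost > 0 && d_effect < 0) "dominated"
    else if (d_effect >= 0) "tradeoff_NE"
    else "tradeoff_SW"
  icer_defined <- d_effect != 0
  icer <- if (icer_defined) d_cost / d_effect else NA_real_
  structure(list(
    arms = data.frame(arm = arm_names, cost = c(c1, c0), effect = c(e1, e0)),
    d_cost = d_cost, d_effect = d_effect,
    icer = icer, icer_defined = icer_defined,
    dominance = dominance, effect_unit = effect_unit),
    class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("Cost-effectiveness result (%s)\n", x$effect_unit))
  print(x$arms, row.names = FALSE)
  cat(sprintf("  d_cost = %.2f, d_effect = %.4f, dominance = %s\n",
              x$d_cost, x$d_effect, x$dominance))
  if (x$icer_defined)
    cat(sprintf("  ICER = %.2f $/%s\n", x$icer, x$effect_unit))
  else cat("  ICER undefined (zero effect increment)\n")
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp * d_effect - d_cost`; positive exactly when the intervention is
#' cost-effective at that willingness-to-pay (for `d_effect > 0`, NMB > 0
#' iff ICER < wtp).
#'
#' @param wtp Willingness-to-pay in $ per effect unit.
#' @param delta_e Effect increment.
#' @param delta_c Cost increment ($).
#' @return Net monetary benefit in dollars.
#' @export
nmb <- function(wtp, delta_e, delta_c) wtp * delta_e - delta_c

#' Willingness-to-pay headroom
#'
#' The largest additional one-time intervention-arm cost (e.g. a training
#' fee for home-catheter care) that keeps the ICER at or below the
#' willingness-to-pay threshold: `wtp * delta_e - delta_c`.  Defined only
#' for a positive effect increment.
#'
#' @inheritParams nmb
#' @return Headroom in dollars.
#' @export
headroom <- function(wtp, delta_e, delta_c) {
  if (!is.finite(delta_e) || delta_e <= 0)
    stop("headroom is defined only for a positive effect increment", call. = FALSE)
  wtp * delta_e - delta_c
}

## ---- secondary (per-visit, multi-metric) ICERs ----------------------------

effect_units <- c(Qol = "utility", BMI = "kg h-2", FFM = "kg",
                  FFMI = "kg h-2", handgrip = "kg", `6MWT` = "m")

#' Cumulative per-patient discounted cost through a visit
#'
#' Costs accumulated from model entry through the cycle ending at visit `v`
#' (visit v falls at the end of cycle v-2, so v-1 cycles have elapsed), at
#' full cohort weight: the secondary effect metrics are measured on patients
#' alive at the visit, so the matching cost is the cost a surviving patient
#' has accumulated, discounted with the same convention as the primary
#' analysis.
#'
#' @param arm An [arm_spec()].
#' @param cycle A [cycle_spec()].
#' @param visit Visit number in 2..5.
#' @return Discounted cost in dollars.
#' @export
cost_through_visit <- function(arm, cycle, visit) {
  stopifnot(visit %in% 2:5)
  n_cycles <- visit - 1L                       # cycles 0 .. visit-2
  k <- seq_len(n_cycles) - 1L
  disc <- (1 + cycle$annual_discount_rate)^(-k * cycle$cycle_length_days / 365.25)
  total <- 0
  for (ci in arm$costs) {
    if (ci$recurrence == "once") {
      if (ci$applies_from_cycle <= n_cycles - 1L)
        total <- total + ci$amount *
          (if (ci$applies_from_cycle == 0) 1 else disc[ci$applies_from_cycle + 1L])
    } else {
      on <- k >= ci$applies_from_cycle & k <= ci$applies_through_cycle
      total <- total + ci$amount * sum(disc[on])
    }
  }
  total
}

#' Effect-change table for quality of life implied by the utility schedules
#'
#' Builds the `(metric, unit, arm, visit, change_from_baseline)` table for
#' the Qol metric directly from a model's utility schedules (visit utility
#' minus baseline utility per arm), in the schema consumed by
#' [secondary_icer()].
#'
#' @param model A [model_config()].
#' @return A data frame in the effect-delta schema.
#' @export
qol_effects_from_config <- function(model) {
  rows <- lapply(model$arms, function(arm) {
    v <- arm$utilities$values
    data.frame(metric = "Qol", unit = "utility", arm = arm$name,
               visit = 2:5, change_from_baseline = v[2:5] - v[1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Secondary ICER for one effect metric at one visit
#'
#' The effect increment is the between-arm difference in change from
#' baseline at the visit; the cost increment is the between-arm difference
#' in per-patient discounted cost through that visit
#' ([cost_through_visit()]).  Negative ratios are passed through numerically
#' but flagged by their dominance class, since a bare negative ICER is
#' ambiguous.
#'
#' @param effects Data frame `(metric, unit, arm, visit,
#'   change_from_baseline)` covering both arms.
#' @param metric Metric name, e.g. `"Qol"`, `"BMI"`, `"handgrip"`.
#' @param visit Visit in 2..5.
#' @param model A [model_config()] supplying costs, cycle and arm names.
#' @return A `cea_result` with the metric's unit as effect unit; costs are
#'   per-visit cumulative, effects are changes from baseline.
#' @export
secondary_icer <- function(effects, metric, visit, model) {
  stopifnot(visit %in% 2:5)
  int <- model$arms$intervention; comp <- model$arms$comparator
  pick <- function(arm_name) {
    r <- effects[effects$metric == metric & effects$visit == visit &
                   effects$arm == arm_name, , drop = FALSE]
    if (nrow(r) != 1L)
      stop(sprintf("need exactly one %s change for arm '%s' at visit %d",
                   metric, arm_name, visit), call. = FALSE)
    r
  }
  r1 <- pick(int$name); r0 <- pick(comp$name)
  unit <- unique(c(r1$unit, r0$unit))
  if (length(unit) != 1L)
    stop("inconsistent units for metric ", metric, call. = FALSE)
  compute_icer(cost_through_visit(int, model$cycle, visit),
               cost_through_visit(comp, model$cycle, visit),
               r1$change_from_baseline, r0$change_from_baseline,
               arm_names = c(int$name, comp$name), effect_unit = unit)
}

#' Visit-by-metric secondary ICER table
#'
#' @param effects Effect-delta table (see [secondary_icer()]).
#' @param model A [model_config()].
#' @param visits Visits to tabulate (default 2:5).
#' @return Data frame with one row per visit and one column per metric
#'   (ICER in $ per metric unit; `NA` where undefined).
#' @export
secondary_icer_table <- function(effects, model, visits = 2:5) {
  metrics <- unique(effects$metric)
  out <- data.frame(visit = visits)
  for (m in metrics)
    out[[m]] <- vapply(visits, function(v)
      secondary_icer(effects, m, v, model)$icer, numeric(1))
  out
}
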
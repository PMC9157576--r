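## Synthetic-trial generator: survival data, digitized Kaplan-Meier point
## clouds and per-visit effect trajectories with known ground truth.

default_effect_means <- function() {
  # change from baseline at visits 2-5; Qol rows reproduce the packaged
  # utility schedules, the remaining metrics are plausible trajectories for
  # a supplemental-nutrition trial (improving muscle metrics under sHPN,
  # slow decline under usual care) -- the trial itself reports no dispersions
  list(
    Qol      = list(unit = "utility", sd = 0.05,
                    intervention = c(0.07, 0.09, 0.18, 0.09),
                    comparator   = c(0.01, -0.11, -0.04, -0.08)),
    BMI      = list(unit = "kg h-2", sd = 0.4,
                    intervention = c(0.3, 0.6, 0.4, 0.3),
                    comparator   = c(-0.4, -0.5, -0.3, -0.2)),
    FFM      = list(unit = "kg", sd = 0.8,
                    intervention = c(1.2, 1.8, 1.5, 1.4),
                    comparator   = c(-0.8, -1.0, -0.7, -0.6)),
    FFMI     = list(unit = "kg h-2", sd = 0.3,
                    intervention = c(0.5, 0.7, 0.6, 0.5),
                    comparator   = c(-0.3, -0.4, -0.3, -0.2)),
    handgrip = list(unit = "kg", sd = 1.5,
                    intervention = c(-0.5, 1.0, 1.2, 2.5),
                    comparator   = c(0.6, 0.1, 0.2, -0.4)),
    `6MWT`   = list(unit = "m", sd = 15,
                    intervention = c(25, 20, 18, 15),
                    comparator   = c(-5, -8, -10, -12)))
}

#' Specification of a synthetic two-arm nutrition trial
#'
#' Defaults emulate the source trial's design: 24 + 23 patients, two-arm
#' Weibull survival with medians near 168/169 days (the packaged shape
#' parameters, scale calibrated to those medians), administrative censoring
#' at the 24-week treatment window, and per-visit effect-metric trajectories
#' (Qol, BMI, FFM, FFMI, handgrip, 6MWT) as mean change from baseline plus
#' additive Gaussian noise.
#'
#' @param n Per-arm sample sizes, intervention first (default `c(24, 23)`).
#' @param survival List of two [weibull_survival()] models (intervention,
#'   comparator).
#' @param censor_days Administrative censoring time in days; default 168
#'   (24 weeks).  Use ~1826 for a 5-year follow-up when studying the
#'   survival tail.
#' @param effect_means Per-metric list with elements `unit`, `sd`,
#'   `intervention`, `comparator` (mean changes at visits 2-5).
#' @param arm_names Labels.
#' @return An object of class `synthetic_trial_spec`.
#' @export
synthetic_trial_spec <- function(n = c(24L, 23L),
                                 survival = list(
                                   calibrate_median(weibull_survival(0.89735193, 0.05464799, 42), 168),
                                   calibrate_median(weibull_survival(0.95341849, 0.04435547, 42), 169)),
                                 censor_days = 168,
                                 effect_means = default_effect_means(),
                                 arm_names = c("sHPN", "Non-sHPN")) {
  stopifnot(length(n) == 2L, all(n >= 2L), censor_days > 0,
            length(survival) == 2L,
            all(vapply(survival, inherits, logical(1), "weibull_survival")))
  structure(list(n = as.integer(n), survival = survival,
                 censor_days = as.numeric(censor_days),
                 effect_means = effect_means, arm_names = arm_names),
            class = "synthetic_trial_spec")
}

#' Simulate per-patient survival data
#'
#' Inverse-transform sampling, `T = time_unit_days * (-log(U)/lambda)^(1/gamma)`,
#' with administrative censoring at `censor_days`.
#'
#' @param spec A [synthetic_trial_spec()].
#' @param seed Integer seed; all generators take explicit seeds.
#' @return Data frame `(arm, time_days, event)` with `event = TRUE` for an
#'   observed death.
#' @export
simulate_survival <- function(spec, seed) {
  stopifnot(inherits(spec, "synthetic_trial_spec"))
  set.seed(seed)
  rows <- lapply(1:2, function(a) {
    w <- spec$survival[[a]]
    u <- runif(spec$n[a])
    t <- w$time_unit_days * (-log(u) / w$scale)^(1 / w$shape)
    event <- t <= spec$censor_days
    data.frame(arm = spec$arm_names[a],
               time_days = pmin(t, spec$censor_days), event = event)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' At each distinct event time the survival estimate multiplies by
#' `1 - d/n_at_risk`.  Censored observations leave the estimate unchanged
#' but reduce the risk set.
#'
#' @param time_days Observation times in days.
#' @param event Logical event indicators (`TRUE` = death observed).
#' @param arm Arm label for the returned points.
#' @return A [km_points()] object with one point per distinct event time
#'   (points with zero estimated survival are retained only while positive,
#'   since downstream curve fitting works on (0, 1]).
#' @export
km_estimate <- function(time_days, event, arm = "") {
  stopifnot(length(time_days) == length(event))
  if (!any(event)) stop("Kaplan-Meier estimate requires at least one event", call. = FALSE)
  o <- order(time_days)
  time_days <- time_days[o]; event <- as.logical(event[o])
  ev_times <- unique(time_days[event])
  s <- 1
  out_t <- out_s <- numeric(0)
  for (te in ev_times) {
    n_risk <- sum(time_days >= te)
    d <- sum(time_days == te & event)
    s <- s * (1 - d / n_risk)
    out_t <- c(out_t, te); out_s <- c(out_s, s)
  }
  keep <- out_s > 0
  if (!all(keep)) {
    # keep the terminal drop-to-zero point out of the (0,1]-constrained
    # container; record it as an attribute for completeness
    zero_at <- out_t[!keep][1]
    pts <- km_points(out_t[keep], out_s[keep], arm)
    attr(pts, "zero_at") <- zero_at
    return(pts)
  }
  km_points(out_t, out_s, arm)
}

#' Emulate digitizing a published survival curve
#'
#' Samples `n_points` time positions uniformly over the curve's support,
#' reads the step function there, and adds Gaussian jitter on the survival
#' axis only (time positions exact), mimicking the dominant pixel-reading
#' error of graph-digitizer software.  Jittered values are clipped to
#' (0, 1].
#'
#' @param km A [km_points()] step function.
#' @param n_points Number of digitized points (>= 3).
#' @param jitter_sd Gaussian sd of the survival-axis jitter.
#' @param seed Integer seed.
#' @return A [km_points()]-shaped data frame of digitized coordinates (the
#'   jitter can make it locally non-monotone, as real digitized data are).
#' @export
digitize_curve <- function(km, n_points = 30L, jitter_sd = 0.02, seed = 1L) {
  stopifnot(inherits(km, "km_points"), n_points >= 3L)
  set.seed(seed)
  tmax <- max(km$time_days)
  t <- sort(runif(n_points, min = 0, max = tmax))
  s <- vapply(t, function(ti) {
    below <- km$time_days <= ti
    if (any(below)) km$survival[max(which(below))] else 1
  }, numeric(1))
  s <- s + rnorm(n_points, sd = jitter_sd)
  s <- pmin(1, pmax(1e-6, s))
  structure(data.frame(time_days = t, survival = s),
            arm = attr(km, "arm"), class = c("km_points", "data.frame"))
}

#' Generate noisy per-visit effect trajectories
#'
#' Per metric, arm and visit: change from baseline = specified mean +
#' Gaussian noise.  Qol changes are additionally clipped so that baseline +
#' change stays a valid utility in `[0, 1]`.
#'
#' @param spec A [synthetic_trial_spec()].
#' @param seed Integer seed.
#' @param noise_sd `NULL` to use each metric's own sd, or a single override
#'   (0 gives the means exactly).
#' @param qol_baseline Baseline utilities (intervention, comparator) used
#'   for the Qol clipping.
#' @return Data frame `(metric, unit, arm, visit, change_from_baseline)` in
#'   the schema consumed by [secondary_icer()].
#' @export
generate_effect_trajectories <- function(spec, seed, noise_sd = NULL,
                                         qol_baseline = c(0.60, 0.64)) {
  stopifnot(inherits(spec, "synthetic_trial_spec"))
  set.seed(seed)
  rows <- list()
  for (m in names(spec$effect_means)) {
    em <- spec$effect_means[[m]]
    sd_m <- if (is.null(noise_sd)) em$sd else noise_sd
    for (a in 1:2) {
      mu <- em[[c("intervention", "comparator")[a]]]
      ch <- mu + rnorm(4, sd = sd_m)
      if (m == "Qol")
        ch <- pmin(1 - qol_baseline[a], pmax(-qol_baseline[a], ch))
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, unit = em$unit, arm = spec$arm_names[a],
        visit = 2:5, change_from_baseline = ch)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
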
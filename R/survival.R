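#' Kaplan-Meier curve points
#'
#' A digitized (or estimated) survival curve: strictly increasing times in
#' days with non-increasing survival fractions in (0, 1].
#'
#' @param time_days Numeric vector of times in days, strictly increasing.
#' @param survival Survival fractions in (0, 1], non-increasing.
#' @param arm Arm label.
#' @return A data frame of class `km_points` with columns `time_days`,
#'   `survival` and an `arm` attribute.
#' @export
km_points <- function(time_days, survival, arm = "") {
  if (length(time_days) != length(survival))
    stop("time_days and survival must have equal length", call. = FALSE)
  if (any(diff(time_days) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(diff(survival) > 1e-12))
    stop("survival must be non-increasing", call. = FALSE)
  if (length(survival) && (survival[1] > 1 || any(survival <= 0)))
    stop("survival fractions must lie in (0, 1]", call. = FALSE)
  structure(data.frame(time_days = time_days, survival = survival),
            arm = arm, class = c("km_points", "data.frame"))
}

#' Evaluate Weibull survival
#'
#' S(t) = exp(-lambda t^gamma) with t in model time units.
#'
#' @param w A [weibull_survival()].
#' @param t Time(s) in model units, >= 0.
#' @return Survival fraction(s) in (0, 1]; S(0) = 1.
#' @export
survival_at <- function(w, t) {
  stopifnot(inherits(w, "weibull_survival"))
  if (any(t < 0)) stop("survival time must be >= 0", call. = FALSE)
  exp(-w$scale * t^w$shape)
}

#' Per-cycle death probability
#'
#' Probability of dying during the cycle ending at time `t`, given alive at
#' its start: `Pt = 1 - exp(lambda (t-u)^gamma - lambda t^gamma)`, i.e.
#' `1 - S(t)/S(t-u)`.  With `gamma = 1` (exponential survival) the value is
#' `1 - exp(-lambda u)` for every cycle.
#'
#' @param w A [weibull_survival()].
#' @param t End-of-cycle time in model units, `t >= u`.
#' @param u Cycle length in model units, > 0.
#' @return Death probability in `[0, 1)`.
#' @export
transition_probability <- function(w, t, u) {
  stopifnot(inherits(w, "weibull_survival"))
  if (any(u <= 0)) stop("cycle length u must be > 0", call. = FALSE)
  if (any(t < u)) stop("end-of-cycle time t must be >= u", call. = FALSE)
  1 - exp(w$scale * (t - u)^w$shape - w$scale * t^w$shape)
}

#' Fit a Weibull survival model to digitized curve points
#'
#' Complementary-log-log linearization: ordinary least squares of
#' `log(-log S)` on `log t` gives the shape as the slope and `log(scale)` as
#' the intercept.  The linearization is exact on noiseless Weibull points,
#' which is the appropriate estimator when the input is curve coordinates
#' read off a published figure rather than individual event times (an
#' interval-censored likelihood has no data to work with here).  Points with
#' survival outside the open interval (0, 1) -- including the t = 0, S = 1
#' anchor -- are excluded from the regression and reported via a message.
#'
#' @param points A [km_points()] object, or any data frame with columns
#'   `time_days` and `survival` (digitized coordinates may be locally
#'   non-monotone and need not satisfy the `km_points` invariants).
#' @param time_unit_days Days per model time unit of the returned model.
#' @return A [weibull_survival()].
#' @export
fit_weibull <- function(points, time_unit_days = 42) {
  stopifnot(is.data.frame(points),
            all(c("time_days", "survival") %in% names(points)))
  s <- points$survival
  t <- points$time_days / time_unit_days
  usable <- is.finite(s) & is.finite(t) & s > 0 & s < 1 & t > 0
  if (any(!usable))
    message(sprintf("fit_weibull: excluding %d point(s) with S outside (0,1) or t <= 0 (t_days = %s)",
                    sum(!usable),
                    paste(format(points$time_days[!usable]), collapse = ", ")))
  if (sum(usable) < 3L)
    stop(sprintf("fit_weibull: need >= 3 usable points with S in (0,1); have %d after dropping %d (dropped t_days = %s)",
                 sum(usable), sum(!usable),
                 paste(format(points$time_days[!usable]), collapse = ", ")),
         call. = FALSE)
  y <- log(-log(s[usable]))
  x <- log(t[usable])
  co <- coef(lm(y ~ x))
  shape <- unname(co[2]); scale <- exp(unname(co[1]))
  if (!is.finite(shape) || shape <= 0 || !is.finite(scale) || scale <= 0)
    stop("fit_weibull: degenerate fit (non-positive shape or scale)", call. = FALSE)
  weibull_survival(shape = shape, scale = scale, time_unit_days = time_unit_days)
}

#' Median survival time in days
#'
#' `time_unit_days * (log(2)/scale)^(1/shape)`.
#'
#' @param w A [weibull_survival()].
#' @return Median survival in days.
#' @export
median_survival <- function(w) {
  stopifnot(inherits(w, "weibull_survival"))
  w$time_unit_days * (log(2) / w$scale)^(1 / w$shape)
}

#' Rescale a Weibull model to a target median survival
#'
#' Adjusts the scale parameter (shape unchanged) so that
#' [median_survival()] equals `median_days`.  Useful when published shape
#' and scale are expressed in an unstated time unit but the median survival
#' in days is reported.
#'
#' @param w A [weibull_survival()].
#' @param median_days Target median survival in days.
#' @return A [weibull_survival()] with the same shape and time unit.
#' @export
calibrate_median <- function(w, median_days) {
  stopifnot(inherits(w, "weibull_survival"), median_days > 0)
  m_units <- median_days / w$time_unit_days
  weibull_survival(shape = w$shape, scale = log(2) / m_units^w$shape,
                   time_unit_days = w$time_unit_days)
}

#' Per-cycle transition probability table
#'
#' @param w A [weibull_survival()].
#' @param cycle A [cycle_spec()].
#' @return Data frame `(cycle, t_end, p_death)` for cycles 0..H-1.
#' @export
transition_table <- function(w, cycle = cycle_spec()) {
  u <- cycle_u(cycle, w)
  k <- seq_len(cycle$horizon_cycles) - 1L
  data.frame(cycle = k, t_end = (k + 1) * u,
             p_death = transition_probability(w, (k + 1) * u, u))
}
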
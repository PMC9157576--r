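## One-way deterministic (tornado) and probabilistic sensitivity analyses.

#' Parameter ranges for one-way sensitivity analysis
#'
#' One row per varied parameter (or grouped parameter multiplier):
#' every cost item (fluctuation `dsa$cost`, default 50%), each arm's utility
#' schedule as one grouped multiplier (`dsa$utility`, 30%), and each arm's
#' Weibull (shape, scale) pair as one grouped multiplier (`dsa$transition`,
#' 30%).  A cost item appearing in both arms with the same amount is a
#' single shared parameter varied jointly (so it influences the increments
#' only through the arms' differing survival weighting).  For cost items
#' the range is on the amount; for grouped entries it is a multiplier
#' around 1.
#'
#' @param model A [model_config()].
#' @return Data frame `(parameter, arm, family, name, base, low, high)`;
#'   `arm` is `"shared"` for jointly varied items.
#' @export
param_ranges <- function(model) {
  rows <- list()
  int <- model$arms$intervention; comp <- model$arms$comparator
  f <- model$dsa$cost
  shared <- intersect(names(int$costs), names(comp$costs))
  shared <- shared[vapply(shared, function(nm)
    int$costs[[nm]]$amount == comp$costs[[nm]]$amount, logical(1))]
  for (nm in shared)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = paste("shared", "cost", nm, sep = "/"),
      arm = "shared", family = "cost", name = nm,
      base = int$costs[[nm]]$amount,
      low = int$costs[[nm]]$amount * (1 - f),
      high = int$costs[[nm]]$amount * (1 + f))
  for (arm in model$arms) {
    for (ci in arm$costs) {
      if (ci$name %in% shared) next
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = paste(arm$name, "cost", ci$name, sep = "/"),
        arm = arm$name, family = "cost", name = ci$name,
        base = ci$amount, low = ci$amount * (1 - f), high = ci$amount * (1 + f))
    }
    fu <- model$dsa$utility
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = paste(arm$name, "utility", sep = "/"),
      arm = arm$name, family = "utility", name = "utility",
      base = 1, low = 1 - fu, high = 1 + fu)
    ft <- model$dsa$transition
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = paste(arm$name, "transition", sep = "/"),
      arm = arm$name, family = "transition", name = "transition",
      base = 1, low = 1 - ft, high = 1 + ft)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

set_arm <- function(model, arm_name, new_arm) {
  role <- if (model$arms$intervention$name == arm_name) "intervention" else "comparator"
  model$arms[[role]] <- new_arm
  model
}

perturb_model <- function(model, row, value) {
  roles <- if (row$arm == "shared") c("intervention", "comparator")
           else if (model$arms$intervention$name == row$arm) "intervention"
           else "comparator"
  for (role in roles) {
    arm <- model$arms[[role]]
    if (row$family == "cost") {
      ci <- arm$costs[[row$name]]
      ci$amount <- value
      arm$costs[[row$name]] <- ci
    } else if (row$family == "utility") {
      # grouped multiplier; schedule invariant keeps utilities within [0,1]
      arm$utilities$values <- pmin(1, pmax(0, arm$utilities$values * value))
    } else {
      arm$survival$shape <- arm$survival$shape * value
      arm$survival$scale <- arm$survival$scale * value
    }
    model$arms[[role]] <- arm
  }
  model
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full base-case analysis at each parameter's low and high
#' value with everything else held at base.  Entries carry the ICER at both
#' ends but are ranked by the spread in net monetary benefit at the model's
#' willingness-to-pay: over a range in which the effect increment changes
#' sign the ICER passes through a pole and its spread is not a usable
#' influence measure, whereas NMB is linear in the increments and ranks
#' parameters the way the underlying decision changes.
#'
#' @param model A [model_config()].
#' @param wtp Willingness-to-pay for the NMB ranking (default the model's).
#' @return Data frame of class `tornado`, sorted by `spread` (NMB range, $)
#'   descending: `(parameter, arm, family, low, high, icer_low, icer_high,
#'   nmb_low, nmb_high, spread)`.
#' @export
one_way_dsa <- function(model, wtp = model$wtp) {
  ranges <- param_ranges(model)
  base <- run_cea(model)
  eval_at <- function(row, value) {
    res <- run_cea(perturb_model(model, row, value))
    c(icer = res$icer, nmb = nmb(wtp, res$d_effect, res$d_cost))
  }
  ent <- lapply(seq_len(nrow(ranges)), function(i) {
    row <- ranges[i, ]
    lo <- eval_at(row, row$low); hi <- eval_at(row, row$high)
    data.frame(parameter = row$parameter, arm = row$arm, family = row$family,
               low = row$low, high = row$high,
               icer_low = lo[["icer"]], icer_high = hi[["icer"]],
               nmb_low = lo[["nmb"]], nmb_high = hi[["nmb"]],
               spread = abs(hi[["nmb"]] - lo[["nmb"]]))
  })
  out <- do.call(rbind, ent)
  out <- out[order(-out$spread), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base$icer
  attr(out, "wtp") <- wtp
  class(out) <- c("tornado", "data.frame")
  out
}

## ---- probabilistic sensitivity analysis -----------------------------------

beta_from_moments <- function(m, s, key) {
  if (m <= 0 || m >= 1)
    stop(sprintf("beta distribution requested for '%s' with mean %g outside (0,1)",
                 key, m), call. = FALSE)
  if (s <= 0) return(c(shape1 = Inf, shape2 = Inf))  # degenerate, handled upstream
  v <- s^2
  if (v >= m * (1 - m))
    stop(sprintf("beta moment matching impossible for '%s': sd %g too large for mean %g",
                 key, s, m), call. = FALSE)
  nu <- m * (1 - m) / v - 1
  c(shape1 = m * nu, shape2 = (1 - m) * nu)
}

sd_divisor <- function(interval_interpretation) {
  switch(interval_interpretation, ci95 = 1.96, two_sd = 2,
         stop("unknown interval interpretation", call. = FALSE))
}

draw_beta <- function(m, f, div, key) {
  if (f == 0 || m == 0) return(m)
  ab <- beta_from_moments(m, m * f / div, key)
  rbeta(1, ab[["shape1"]], ab[["shape2"]])
}

draw_gamma <- function(m, f, div, key) {
  if (f == 0 || m == 0) return(m)
  if (m < 0) stop(sprintf("gamma distribution requested for '%s' with negative mean", key),
                  call. = FALSE)
  k <- (div / f)^2                      # cv = f/div => shape = 1/cv^2
  rgamma(1, shape = k, scale = m / k)
}

#' Draw one perturbed model for probabilistic sensitivity analysis
#'
#' Utilities and the Weibull shape/scale (all in (0,1) here) are drawn from
#' beta distributions, costs from gamma distributions, each moment-matched
#' to mean `m` and sd `m*f/1.96` where `f` is the family's fluctuation
#' fraction (the deterministic band read as a central 95% interval; see
#' [psa_config()]).  A mean outside a beta's support raises an error rather
#' than silently switching family.  All draws are independent.
#'
#' @param model A [model_config()].
#' @return A perturbed `model_config` (uses the current RNG stream).
#' @export
sample_parameters <- function(model) {
  div <- sd_divisor(model$psa$interval_interpretation)
  for (role in c("intervention", "comparator")) {
    arm <- model$arms[[role]]
    fu <- model$dsa$utility
    arm$utilities$values <- vapply(seq_along(arm$utilities$values), function(i)
      draw_beta(arm$utilities$values[i], fu, div,
                paste0(arm$name, ".utilities[", i, "]")), numeric(1))
    ft <- model$dsa$transition
    arm$survival$shape <- draw_beta(arm$survival$shape, ft, div,
                                    paste0(arm$name, ".survival.shape"))
    arm$survival$scale <- draw_beta(arm$survival$scale, ft, div,
                                    paste0(arm$name, ".survival.scale"))
    fc <- model$dsa$cost
    for (nm in names(arm$costs))
      arm$costs[[nm]]$amount <- draw_gamma(arm$costs[[nm]]$amount, fc, div,
                                           paste0(arm$name, ".cost.", nm))
    model$arms[[role]] <- arm
  }
  model
}

#' Monte Carlo probabilistic sensitivity analysis
#'
#' Runs `n_iterations` full model evaluations on independently sampled
#' parameter sets.  One master seed spawns a fixed vector of per-iteration
#' substream seeds, so results are bitwise reproducible and invariant to
#' evaluation order.
#'
#' @param model A [model_config()].
#' @param psa A [psa_config()] (default the model's own).
#' @return An object of class `psa_result`: `$iterations` data frame
#'   `(iter, d_cost, d_qaly, cost_1, cost_0, qaly_1, qaly_0)`, `$base` the
#'   unperturbed `cea_result`, and `$means`.
#' @export
run_psa <- function(model, psa = model$psa) {
  stopifnot(inherits(model, "model_config"), inherits(psa, "psa_config"))
  n <- psa$n_iterations
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(psa$seed)
  substreams <- sample.int(.Machine$integer.max - 1L, n)
  res <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("d_cost", "d_qaly", "cost_1", "cost_0",
                                        "qaly_1", "qaly_0")))
  for (i in seq_len(n)) {
    set.seed(substreams[i])
    r <- run_cea(sample_parameters(model))
    res[i, ] <- c(r$d_cost, r$d_effect, r$arms$cost[1], r$arms$cost[2],
                  r$arms$effect[1], r$arms$effect[2])
  }
  iterations <- data.frame(iter = seq_len(n), res)
  structure(list(iterations = iterations, base = run_cea(model),
                 means = colMeans(res), n_iterations = n, seed = psa$seed),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (seed %d)\n", x$n_iterations, x$seed))
  cat(sprintf("  mean d_cost = %.2f, mean d_qaly = %.4f (base: %.2f, %.4f)\n",
              x$means[["d_cost"]], x$means[["d_qaly"]],
              x$base$d_cost, x$base$d_effect))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Probability that the intervention is cost-effective at each
#' willingness-to-pay: the fraction of PSA iterations with positive net
#' monetary benefit, `wtp * d_qaly - d_cost > 0`.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Willingness-to-pay grid in $/QALY; the default 0 to
#'   60,000 by 500 brackets both the $2,500 and the $29,307 thresholds of
#'   interest.
#' @return Data frame of class `ceac`: `(wtp, probability)`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 60000, by = 500)) {
  stopifnot(inherits(psa, "psa_result"))
  it <- psa$iterations
  prob <- vapply(wtp_grid, function(w) mean(w * it$d_qaly - it$d_cost > 0),
                 numeric(1))
  structure(data.frame(wtp = wtp_grid, probability = prob),
            class = c("ceac", "data.frame"))
}
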
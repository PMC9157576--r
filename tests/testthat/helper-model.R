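# Shared builders for the test suite.

fixture_model <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- hpncea_example_config()
    cached
  }
})

# published reference totals used by the convention search
table2_reference <- c(cost_1 = 10693.40, qaly_1 = 0.6081,
                      cost_0 = 8642.22, qaly_0 = 0.5237, icer = 24289.17)

# a minimal two-arm model: near-immortal cohort, flat costs/utilities
flat_arm <- function(name, per_cycle = 100, once = 0, utility = 1,
                     shape = 1, scale = 1e-12, time_unit_days = 42) {
  costs <- list(cost_item("recurring", per_cycle, "per_cycle"))
  if (once > 0) costs <- c(costs, list(cost_item("entry", once, "once")))
  arm_spec(name, weibull_survival(shape, scale, time_unit_days),
           costs, utility_schedule(rep(utility, 5)))
}

tiny_model <- function(r = 0, H = 10, ...) {
  model_config(flat_arm("A", ...), flat_arm("B", per_cycle = 50),
               cycle = cycle_spec(horizon_cycles = H, annual_discount_rate = r))
}

write_temp_yaml <- function(lines) {
  p <- withr::local_tempfile(fileext = ".yaml", .local_envir = parent.frame())
  writeLines(lines, p)
  p
}
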
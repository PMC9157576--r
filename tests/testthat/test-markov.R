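test_that("trace conserves the cohort and telescopes to the survival curve", {
  m <- fixture_model()
  for (arm in m$arms) {
    tr <- run_trace(arm, m$cycle)
    expect_equal(tr$alive[1], 1)
    expect_equal(tr$alive + tr$dead, rep(1, nrow(tr)), tolerance = 1e-12)
    expect_true(all(diff(tr$alive) <= 0))
    u <- cycle_u(m$cycle, arm$survival)
    expect_equal(tr$alive, survival_at(arm$survival, tr$cycle * u),
                 tolerance = 1e-12)
  }
})

test_that("no-death limit keeps the whole cohort alive", {
  arm <- flat_arm("A", shape = 1, scale = 1e-14)
  tr <- run_trace(arm, cycle_spec(horizon_cycles = 43))
  expect_equal(tr$alive, rep(1, 43), tolerance = 1e-10)
})

test_that("first-cycle survivors equal 1 - Pt(u, u) on the fixture", {
  m <- fixture_model()
  arm <- m$arms$intervention
  u <- cycle_u(m$cycle, arm$survival)
  tr <- run_trace(arm, m$cycle)
  expect_equal(tr$alive[2], 1 - transition_probability(arm$survival, u, u),
               tolerance = 1e-15)
})

test_that("cost accrual: per-cycle sums, once-item timing, fixture hand sum", {
  cyc <- cycle_spec(horizon_cycles = 10, annual_discount_rate = 0)
  no_death <- flat_arm("A", per_cycle = 100, shape = 1, scale = 1e-14)
  tr <- run_trace(no_death, cyc)
  expect_equal(accrue_costs(tr, no_death, cyc), 1000, tolerance = 1e-9)

  # a once item at model entry contributes its face value regardless of
  # horizon and discounting
  once_only <- arm_spec("A", weibull_survival(1, 1e-14),
                        list(cost_item("entry", 50, "once")),
                        utility_schedule(rep(1, 5)))
  for (cyc2 in list(cycle_spec(horizon_cycles = 1),
                    cycle_spec(horizon_cycles = 43, annual_discount_rate = 0.1))) {
    tr2 <- run_trace(once_only, cyc2)
    expect_equal(accrue_costs(tr2, once_only, cyc2), 50, tolerance = 1e-12)
  }

  # fixture sHPN arm over a single undiscounted cycle: hand sum of the
  # published items, 798.12 once + 1,470.64 recurring
  m <- fixture_model()
  cyc1 <- cycle_spec(horizon_cycles = 1, annual_discount_rate = 0)
  tr1 <- run_trace(m$arms$intervention, cyc1)
  expect_equal(accrue_costs(tr1, m$arms$intervention, cyc1), 2268.76,
               tolerance = 1e-9)
})

test_that("applicability windows bound per-cycle accrual", {
  cyc <- cycle_spec(horizon_cycles = 10, annual_discount_rate = 0)
  arm <- arm_spec("A", weibull_survival(1, 1e-14),
                  list(cost_item("drug", 100, "per_cycle",
                                 applies_from_cycle = 0,
                                 applies_through_cycle = 3)),
                  utility_schedule(rep(1, 5)))
  tr <- run_trace(arm, cyc)
  expect_equal(accrue_costs(tr, arm, cyc), 400, tolerance = 1e-9)
})

test_that("QALY accrual: full-health identity, zero utility, fixture visit-2", {
  cyc <- cycle_spec(horizon_cycles = 43, annual_discount_rate = 0)
  healthy <- flat_arm("A", utility = 1, shape = 1, scale = 1e-14)
  tr <- run_trace(healthy, cyc)
  expect_equal(accrue_qalys(tr, healthy, cyc), 43 * 42 / 365.25, tolerance = 1e-9)

  dead_inside <- flat_arm("A", utility = 0, shape = 1, scale = 1e-14)
  expect_equal(accrue_qalys(run_trace(dead_inside, cyc), dead_inside, cyc), 0)

  # single undiscounted cycle of the fixture sHPN arm accrues the visit-2
  # utility 0.67 for one 6-week cycle
  m <- fixture_model()
  cyc1 <- cycle_spec(horizon_cycles = 1, annual_discount_rate = 0)
  tr1 <- run_trace(m$arms$intervention, cyc1)
  expect_equal(accrue_qalys(tr1, m$arms$intervention, cyc1),
               0.67 * 42 / 365.25, tolerance = 1e-12)
})

test_that("utility-to-cycle mapping follows visits and carries forward", {
  us <- utility_schedule(c(0.60, 0.67, 0.69, 0.78, 0.69))
  expect_equal(utility_at_cycle(us, 0:5),
               c(0.67, 0.69, 0.78, 0.69, 0.69, 0.69))
  expect_equal(utility_at_cycle(us, 0:5, mapping = "visit_k1"),
               c(0.60, 0.67, 0.69, 0.78, 0.69, 0.69))
  no_carry <- utility_schedule(c(0.60, 0.67, 0.69, 0.78, 0.69),
                               carry_forward = FALSE)
  expect_equal(utility_at_cycle(no_carry, 0:5),
               c(0.67, 0.69, 0.78, 0.69, 0, 0))
})

test_that("discounting strictly reduces totals accrued after cycle 0", {
  m <- fixture_model()
  cyc0 <- cycle_spec(horizon_cycles = 43, annual_discount_rate = 0)
  arm <- m$arms$intervention
  t_disc <- run_trace(arm, m$cycle); t_flat <- run_trace(arm, cyc0)
  expect_lt(accrue_costs(t_disc, arm, m$cycle), accrue_costs(t_flat, arm, cyc0))
  expect_lt(accrue_qalys(t_disc, arm, m$cycle), accrue_qalys(t_flat, arm, cyc0))
})

test_that("engine is linear in cost amounts", {
  m <- fixture_model()
  arm <- m$arms$intervention
  doubled <- arm
  for (nm in names(doubled$costs))
    doubled$costs[[nm]]$amount <- doubled$costs[[nm]]$amount * 2
  tr <- run_trace(arm, m$cycle)
  expect_equal(accrue_costs(tr, doubled, m$cycle),
               2 * accrue_costs(tr, arm, m$cycle), tolerance = 1e-12)
})

test_that("undiscounted QALYs factor into life expectancy times utility", {
  cyc <- cycle_spec(horizon_cycles = 43, annual_discount_rate = 0)
  w <- weibull_survival(0.9, 0.08)
  base <- arm_spec("A", w, list(cost_item("c", 1)), utility_schedule(rep(1, 5)))
  third <- arm_spec("A", w, list(cost_item("c", 1)), utility_schedule(rep(0.37, 5)))
  tr <- run_trace(base, cyc)
  ly <- accrue_qalys(tr, base, cyc)          # life-years at utility 1
  expect_equal(accrue_qalys(tr, third, cyc), 0.37 * ly, tolerance = 1e-12)

  # the discrete life expectancy brackets the continuous restricted mean:
  # alive-at-start accrual is a left Riemann sum of a decreasing S(t)
  u <- cycle_u(cyc, w)
  rmst <- stats::integrate(function(t) survival_at(w, t), 0, 43 * u,
                           rel.tol = 1e-10)$value * 42 / 365.25
  cycle_years <- 42 / 365.25
  expect_gte(ly, rmst)
  expect_lte(ly, rmst + cycle_years)
})

test_that("half-cycle correction lowers recurring accrual for a dying cohort", {
  m <- fixture_model()
  arm <- m$arms$intervention
  full <- run_arm(arm, m$cycle)
  half <- run_arm(arm, m$cycle, half_cycle = TRUE)
  expect_lt(attr(half, "total_qaly"), attr(full, "total_qaly"))
  expect_lt(attr(half, "total_cost"), attr(full, "total_cost"))
  # a once item at model entry is unaffected by the correction
  once_only <- arm_spec("A", arm$survival, list(cost_item("entry", 50, "once")),
                        arm$utilities)
  tr <- run_trace(once_only, m$cycle)
  expect_equal(accrue_costs(tr, once_only, m$cycle, half_cycle = TRUE), 50,
               tolerance = 1e-12)
})
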
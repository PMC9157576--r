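test_that("packaged fixture carries every published parameter exactly", {
  m <- fixture_model()
  shpn <- m$arms$intervention
  ctrl <- m$arms$comparator
  expect_equal(shpn$name, "sHPN")

  expect_equal(shpn$costs[["PN"]]$amount, 421.58)
  expect_equal(shpn$costs[["PN"]]$recurrence, "per_cycle")
  expect_equal(shpn$costs[["CVC"]]$amount, 64.48)
  expect_equal(shpn$costs[["CVC"]]$recurrence, "once")
  expect_equal(shpn$costs[["CVC care"]]$amount, 221.79)
  expect_equal(shpn$costs[["PICC"]]$amount, 359.38)
  expect_equal(shpn$costs[["Homecare nurse"]]$amount, 41.07)
  expect_equal(shpn$costs[["Ward"]]$amount, 8.56)
  expect_equal(shpn$costs[["Readmission"]]$amount, 365.70)
  expect_equal(shpn$costs[["Supportive care"]]$amount, 675.00)
  expect_equal(shpn$costs[["Follow-up"]]$amount, 111.20)
  expect_equal(ctrl$costs[["EN"]]$amount, 3.54)
  expect_equal(ctrl$costs[["EN"]]$recurrence, "once")
  expect_setequal(names(ctrl$costs),
                  c("Readmission", "EN", "Supportive care", "Follow-up"))

  expect_equal(shpn$utilities$values, c(0.60, 0.67, 0.69, 0.78, 0.69))
  expect_equal(ctrl$utilities$values, c(0.64, 0.65, 0.53, 0.60, 0.56))

  expect_equal(shpn$survival$shape, 0.89735193)
  expect_equal(shpn$survival$scale, 0.05464799)
  expect_equal(ctrl$survival$shape, 0.95341849)
  expect_equal(ctrl$survival$scale, 0.04435547)

  expect_equal(m$cycle$cycle_length_days, 42)
  expect_equal(m$cycle$horizon_cycles, 43L)
  expect_equal(m$cycle$annual_discount_rate, 0.03)
  expect_equal(m$wtp, 29307)
  expect_equal(m$psa$n_iterations, 1000L)
  expect_equal(m$dsa, list(cost = 0.50, utility = 0.30, transition = 0.30))
})

test_that("validation errors name the offending key", {
  expect_error(utility_schedule(c(0.6, 0.67, 1.2, 0.78, 0.69)), "utilities")
  expect_error(utility_schedule(c(0.6, 0.67, 0.78, 0.69)), "exactly 5")
  expect_error(cost_item("PN", -1), "amount")
  expect_error(cost_item("PN", 421.583), "2 decimals")
  expect_error(cost_item("PN", 100, applies_from_cycle = 5,
                         applies_through_cycle = 3), "applies_from_cycle")
  expect_error(weibull_survival(-1, 0.05), "shape")
  expect_error(cycle_spec(annual_discount_rate = 1.5), "discount")

  # duplicate cost names within an arm
  w <- weibull_survival(1, 0.1)
  us <- utility_schedule(rep(0.5, 5))
  expect_error(arm_spec("A", w, list(cost_item("PN", 1), cost_item("PN", 2)), us),
               "duplicate")
})

test_that("config file errors: missing arm, bad utility, non-numeric amount", {
  one_arm <- write_temp_yaml(c(
    "arms:",
    "  - name: only",
    "    role: intervention",
    "    survival: {shape: 1, scale: 0.1}",
    "    utilities: [0.5, 0.5, 0.5, 0.5, 0.5]",
    "    costs: []"))
  expect_error(read_config(one_arm), "arms")

  bad_utility <- write_temp_yaml(c(
    "arms:",
    "  - name: a",
    "    role: intervention",
    "    survival: {shape: 1, scale: 0.1}",
    "    utilities: [0.5, 0.5, 1.2, 0.5, 0.5]",
    "    costs: []",
    "  - name: b",
    "    role: comparator",
    "    survival: {shape: 1, scale: 0.1}",
    "    utilities: [0.5, 0.5, 0.5, 0.5, 0.5]",
    "    costs: []"))
  expect_error(read_config(bad_utility), "utilities")

  bad_amount <- write_temp_yaml(c(
    "arms:",
    "  - name: a",
    "    role: intervention",
    "    survival: {shape: 1, scale: 0.1}",
    "    utilities: [0.5, 0.5, 0.5, 0.5, 0.5]",
    "    costs: [{name: PN, amount: lots}]",
    "  - name: b",
    "    role: comparator",
    "    survival: {shape: 1, scale: 0.1}",
    "    utilities: [0.5, 0.5, 0.5, 0.5, 0.5]",
    "    costs: []"))
  expect_error(read_config(bad_amount), "amount")

  expect_error(read_config("no/such/file.yaml"), "not found")
})

test_that("omitted fields take the documented defaults", {
  minimal <- write_temp_yaml(c(
    "arms:",
    "  - name: a",
    "    role: intervention",
    "    survival: {shape: 1, scale: 0.1}",
    "    utilities: [0.5, 0.5, 0.5, 0.5, 0.5]",
    "    costs: [{name: PN, amount: 10}]",
    "  - name: b",
    "    role: comparator",
    "    survival: {shape: 1, scale: 0.1}",
    "    utilities: [0.5, 0.5, 0.5, 0.5, 0.5]",
    "    costs: []"))
  m <- read_config(minimal)
  expect_equal(m$cycle$annual_discount_rate, 0.03)
  expect_equal(m$cycle$cycle_length_days, 42)
  expect_equal(m$cycle$horizon_cycles, 43L)
  expect_equal(m$wtp, 29307)
  expect_equal(m$arms$intervention$survival$time_unit_days, 42)
  expect_equal(m$arms$intervention$costs[["PN"]]$recurrence, "per_cycle")
  expect_equal(m$arms$intervention$costs[["PN"]]$applies_through_cycle, Inf)
})

test_that("write_config / read_config round-trips value for value", {
  m <- fixture_model()
  p <- withr::local_tempfile(fileext = ".yaml")
  write_config(m, p)
  m2 <- read_config(p)
  expect_equal(m2, m)

  # also with a bounded applicability window and non-default settings
  m3 <- with_treatment_window(with_time_unit(m, 14), 4)
  m3$cycle$annual_discount_rate <- 0.05
  write_config(m3, p)
  expect_equal(read_config(p), m3)
})

test_that("result writers have stable schemas and round-trip numerically", {
  m <- fixture_model()
  res <- run_cea(m)
  p <- withr::local_tempfile(fileext = ".csv")
  write_results(res, p)
  back <- read.csv(p)
  expect_identical(names(back),
                   c("arm", "cost", "qaly", "d_cost", "d_qaly", "icer", "dominance"))
  expect_equal(back$cost, res$arms$cost, tolerance = 1e-12)
  expect_equal(back$icer[1], res$icer, tolerance = 1e-12)

  tr <- attr(res, "traces")$intervention
  write_results(tr, p)
  back <- read.csv(p)
  expect_identical(names(back), c("cycle", "alive", "p_death", "cost_inc",
                                  "qaly_inc", "cum_cost", "cum_qaly"))
  expect_equal(back$cum_cost[nrow(back)], attr(tr, "total_cost"), tolerance = 1e-12)

  # an empty PSA result writes a header-only file
  empty <- structure(list(iterations = data.frame(iter = integer(),
                                                  d_cost = numeric(),
                                                  d_qaly = numeric())),
                     class = "psa_result")
  write_results(empty, p)
  expect_identical(readLines(p), "iter,d_cost,d_qaly")
})

test_that("tornado rows are written sorted by spread descending", {
  tor <- one_way_dsa(tiny_model(H = 5))
  # shuffle, write, and check the file is re-sorted
  shuffled <- tor[rev(seq_len(nrow(tor))), ]
  class(shuffled) <- class(tor)
  p <- withr::local_tempfile(fileext = ".csv")
  write_results(shuffled, p)
  back <- read.csv(p)
  expect_equal(back$spread, sort(back$spread, decreasing = TRUE))
})
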
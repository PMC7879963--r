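test_that("a zero-flow step returns the state unchanged", {
  spec <- sf_spec(
    stocks = data.frame(name = c("a", "b"), initial = c(10, 20), units = "persons"),
    flows = data.frame(name = "t", source = "a", target = "b", rate = "0 * a"))
  st <- c(a = 123.4, b = 56.7)
  expect_identical(sf_step(st, spec, 2010)$state, st)
})

test_that("one-year update matches hand arithmetic", {
  # level 100, constant inflow 5/yr, outflow 0.1 * level -> 100 + 5 - 10 = 95
  spec <- one_stock_spec(x0 = 100, b = 5, m = 0.1)
  res <- sf_step(c(x = 100), spec, 2010)
  expect_equal(res$state[["x"]], 95)
  expect_equal(unname(res$flows), c(5, 10))
})

test_that("an outflow exceeding the level clamps at zero and logs the deficit", {
  spec <- sf_spec(
    stocks = data.frame(name = "x", initial = 10, units = "persons"),
    flows = data.frame(name = "drain", source = "x", target = "external",
                       rate = "50"))
  res <- sf_step(c(x = 10), spec, 2010)
  expect_equal(res$state[["x"]], 0)
  expect_equal(res$clamp$deficit, 40)
  expect_equal(res$clamp$stock, "x")
  traj <- sf_simulate(spec, sf_clock(2010, 2012))
  expect_equal(traj$clamp_total, 40 + 50)  # year 2 drains an empty stock fully
})

test_that("closed systems conserve total persons every year", {
  spec <- closed_two_stock_spec()
  traj <- sf_simulate(spec, sf_clock(2010, 2060))
  totals <- rowSums(traj$stocks)
  expect_equal(totals, rep(1000, 51), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the engine reproduces the linear one-stock recurrence closed form", {
  x0 <- 250; b <- 12; m <- 0.07
  traj <- sf_simulate(one_stock_spec(x0, b, m), sf_clock(2010, 2060))
  expected <- linear_recurrence(x0, b, m, 0:50)
  expect_equal(unname(traj$stocks[, "x"]), expected, tolerance = 1e-12)
})

test_that("a 2010-2060 clock records exactly 51 annual states", {
  clock <- sf_clock(2010, 2060)
  expect_length(clock_years(clock), 51)
  traj <- sf_simulate(one_stock_spec(), clock)
  expect_identical(nrow(traj$stocks), 51L)
  expect_identical(traj$years, 2010:2060)
})

test_that("simulate is a pure function: equal inputs, identical trajectories", {
  spec <- closed_two_stock_spec()
  t1 <- sf_simulate(spec, sf_clock(2010, 2040))
  t2 <- sf_simulate(spec, sf_clock(2010, 2040))
  expect_identical(t1, t2)
})

test_that("validate_spec reports findings instead of raising", {
  # flow referencing a missing stock, named in the finding
  bad <- sf_spec(
    stocks = data.frame(name = "smokers", initial = 10, units = "persons"),
    flows = data.frame(name = "quit", source = "smokerz", target = "external",
                       rate = "1"),
    check = FALSE)
  f <- validate_spec(bad)
  expect_identical(nrow(f), 1L)
  expect_match(f$message, "smokerz")
  expect_identical(f$severity, "error")

  # well-formed spec: empty findings
  expect_identical(nrow(validate_spec(closed_two_stock_spec())), 0L)

  # duplicate parameter definition
  dup <- sf_spec(
    stocks = data.frame(name = "x", initial = 1, units = "persons"),
    flows = data.frame(name = "f", source = "x", target = "external", rate = "k * x"),
    parameters = c(list(k = 1), list(k = 2)),
    check = FALSE)
  f <- validate_spec(dup)
  expect_true(any(grepl("defined more than once", f$message)))

  # grammar violations and unresolved symbols are findings too
  ugly <- sf_spec(
    stocks = data.frame(name = "x", initial = 1, units = "persons"),
    flows = data.frame(name = c("f", "g"), source = "x", target = "external",
                       rate = c("exp(x)", "x * missing_param")),
    check = FALSE)
  f <- validate_spec(ugly)
  expect_true(any(grepl("operator 'exp'", f$message)))
  expect_true(any(grepl("unresolved symbol 'missing_param'", f$message)))
  expect_error(sf_simulate(ugly, sf_clock(2010, 2012)), "invalid spec")
})

test_that("non-finite rates fail loudly, naming flow and year", {
  spec <- sf_spec(
    stocks = data.frame(name = "x", initial = 1, units = "persons"),
    flows = data.frame(name = "bad", source = "x", target = "external",
                       rate = "x / k"),
    parameters = list(k = 0))
  expect_error(sf_step(c(x = 1), spec, 2013), "non-finite rate.*'bad'.*2013")
})

test_that("per-year trend multipliers scale parameter values", {
  years <- 2010:2020
  spec <- sf_spec(
    stocks = data.frame(name = "x", initial = 0, units = "persons"),
    flows = data.frame(name = "inflow", source = "external", target = "x",
                       rate = "b"),
    parameters = list(b = list(value = 10,
                               trend = stats::setNames(1.1^(0:10), years))),
    outputs = c(b_now = "b"))
  traj <- sf_simulate(spec, sf_clock(2010, 2020))
  expect_equal(unname(traj$outputs[, "b_now"]), 10 * 1.1^(0:10))
})

test_that("outputs can reference auxiliaries, flow rates and earlier outputs", {
  spec <- sf_spec(
    stocks = data.frame(name = "x", initial = 100, units = "persons"),
    flows = data.frame(name = "out_", source = "x", target = "external",
                       rate = "haz * x"),
    parameters = list(k = 0.02),
    aux = c(haz = "k * 2"),
    outputs = c(deaths = "out_", doubled = "deaths * 2"))
  ev <- sf_step(c(x = 100), spec, 2010)
  expect_equal(ev$outputs[["deaths"]], 4)
  expect_equal(ev$outputs[["doubled"]], 8)
})

test_that("trajectories export tidily and series lookup covers all slots", {
  traj <- sf_simulate(one_stock_spec(), sf_clock(2010, 2012))
  df <- as.data.frame(traj)
  expect_named(df, c("measure", "year", "value"))
  expect_setequal(unique(df$measure), c("x", "in_", "out_"))
  expect_identical(unname(traj_series(traj, "x")[1]), 100)
  expect_error(traj_series(traj, "nope"), "no measure 'nope'")
})
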
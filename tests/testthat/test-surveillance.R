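flat_spec <- function(level = 100, growth = 0.02) {
  sf_spec(
    stocks = data.frame(name = "x", initial = level, units = "persons"),
    flows = data.frame(name = "grow", source = "external", target = "x",
                       rate = sprintf("%.17g * x", growth)),
    outputs = c(series = "x * mult", flat = "7 * mult_flat"),
    parameters = list(mult = 1, mult_flat = 1))
}

panel_from <- function(traj, measure, years, f = identity, kind = "count") {
  v <- as.numeric(traj_series(traj, measure)[as.character(years)])
  surveillance_panel(data.frame(measure = measure, year = years, value = f(v),
                                kind = kind, source = "synthetic"))
}

test_that("a model series copied as observations is a perfect, aligned fit", {
  traj <- sf_simulate(flat_spec(), sf_clock(2010, 2030))
  p <- panel_from(traj, "series", 2012:2018)
  d <- compare_series(traj, p, "series")
  expect_identical(d$mape, 0)
  expect_identical(d$verdict, "aligned")
  expect_equal(d$slope_diff, 0, tolerance = 1e-9)
})

test_that("a constant 1.5x offset gives 50% relative MAPE and deviates", {
  traj <- sf_simulate(flat_spec(), sf_clock(2010, 2030))
  p <- panel_from(traj, "series", 2012:2018, f = function(v) v * 1.5)
  d <- compare_series(traj, p, "series")
  # MAPE of model against obs = |m - 1.5 m| / 1.5 m = 1/3
  expect_equal(d$mape, 1 / 3, tolerance = 1e-12)
  expect_identical(d$verdict, "deviating")
})

test_that("fewer than three overlapping years is an explicit error", {
  traj <- sf_simulate(flat_spec(), sf_clock(2010, 2030))
  p <- panel_from(traj, "series", 2012:2013)
  expect_error(compare_series(traj, p, "series"), "insufficient overlapping")
  expect_error(compare_series(traj, p, "ghost"), "no surveillance observations")
})

test_that("MAPE is scale-invariant, treating counts and percents uniformly", {
  traj <- sf_simulate(flat_spec(), sf_clock(2010, 2030))
  p1 <- panel_from(traj, "series", 2012:2018, f = function(v) v * 1.08)
  d1 <- compare_series(traj, p1, "series")
  scaled <- flat_spec(); scaled$parameters$mult$value <- 1e-3
  traj2 <- sf_simulate(scaled, sf_clock(2010, 2030))
  p2 <- panel_from(traj2, "series", 2012:2018, f = function(v) v * 1.08)
  d2 <- compare_series(traj2, p2, "series")
  expect_equal(d1$mape, d2$mape, tolerance = 1e-12)
})

test_that("surveillance panel invariants are enforced on load", {
  expect_error(surveillance_panel(
    data.frame(measure = "m", year = c(2010, 2010), value = 1,
               kind = "count", source = "s")),
    "strictly increasing")
  expect_error(surveillance_panel(
    data.frame(measure = "m", year = 2010, value = 120,
               kind = "percent", source = "s")),
    "\\[0, 100\\]")
  expect_error(surveillance_panel(
    data.frame(measure = "m", year = 2010, value = -1,
               kind = "count", source = "s")),
    "non-negative")
})

test_that("recalibration review keeps persistent deviators and drops oscillators", {
  mk_diag <- function(measure, verdict, residuals) {
    structure(list(measure = measure, verdict = verdict,
                   residuals = data.frame(year = seq_along(residuals),
                                          residual = residuals)),
              class = "fit_diagnostic")
  }
  diags <- structure(list(
    osc = mk_diag("osc", "deviating", c(1, -1, 1, -1, 1)),
    persistent = mk_diag("persistent", "deviating", c(2, 3, 1, 4, 2)),
    aligned_persistent = mk_diag("aligned_persistent", "aligned", c(1, 1, 1, 1))),
    class = "fit_diagnostics")
  names(diags) <- c("osc", "persistent", "aligned_persistent")
  expect_identical(recalibration_review(diags, persistence_years = 3),
                   "persistent")
})

test_that("a planted constant multiplier is recovered exactly without noise", {
  nation <- make_toy_nation(fixture_config(noise = 0))
  panel <- make_surveillance_panel(nation)
  res <- recalibrate_measure(nation, "adult_obesity_pct", panel, "constant")
  expect_equal(res$multiplier_path$multiplier[1], 1.30, tolerance = 1e-6)
  expect_true(all(res$multiplier_path$multiplier > 0))
  # planted log-linear drift recovered by the trend mode
  res2 <- recalibrate_measure(nation, "cvd_deaths", panel, "linear-trend")
  planted <- exp(0.06 * (res2$multiplier_path$year - 2010))
  expect_equal(res2$multiplier_path$multiplier, planted, tolerance = 1e-6)
})

test_that("observations equal to the model imply a unit multiplier", {
  cfg <- fixture_config(noise = 0,
                        deviators = data.frame(measure = character(),
                                               type = character(),
                                               value = numeric()))
  nation <- make_toy_nation(cfg)
  panel <- make_surveillance_panel(nation)
  res <- recalibrate_measure(nation, "diabetes_pct", panel, "constant")
  expect_equal(res$multiplier_path$multiplier, rep(1, 51), tolerance = 1e-12)
})

test_that("planted multipliers are recovered within 5% under 2% noise", {
  nation <- make_toy_nation(fixture_config(seed = 7, noise = 0.02))
  panel <- make_surveillance_panel(nation)
  res <- recalibrate_measure(nation, "diabetes_noncvd_deaths", panel, "constant")
  expect_equal(res$multiplier_path$multiplier[1], 1.25, tolerance = 0.05)
  res2 <- recalibrate_measure(nation, "distress_noncvd_deaths", panel, "constant")
  expect_equal(res2$multiplier_path$multiplier[1], 0.80, tolerance = 0.05)
})

test_that("recalibrating one measure leaves every other series bit-identical", {
  nation <- make_toy_nation(fixture_config(noise = 0))
  panel <- make_surveillance_panel(nation)
  res <- recalibrate_measure(nation, "adult_obesity_pct", panel, "constant")
  expect_identical(nrow(res$cross_effects), 24L)
  expect_true(all(res$cross_effects$series_identical))
  expect_identical(res$cross_effects$verdict_before,
                   res$cross_effects$verdict_after)
})

test_that("every panel measure gets exactly one diagnostic", {
  nation <- toy_nation_cached()
  panel <- make_surveillance_panel(nation)
  traj <- sf_simulate(nation$spec, nation$clock)
  diags <- compare_panel(traj, panel)
  expect_length(diags, 25L)
  expect_identical(sort(names(diags)), sort(unique(panel$measure)))
  s <- summary(diags)
  expect_identical(nrow(s), 25L)
  expect_true(all(s$verdict %in% c("aligned", "deviating")))
})
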
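# Deterministic desk-scale "toy nation": a complete, validating model spec
# covering risk-factor prevalences, CVD events and deaths in the non-CVD /
# post-CVD split, attributed non-CVD outcomes, levers, parameter bounds,
# cost tables and synthetic surveillance panels.  All numeric values are
# openly fictitious fixture choices except the quality acute/rehabilitation
# care bound pair (0.43, 0.90), the 3% discount rate, the 0.5% influence
# threshold and the 2018-2040 outcome window.

#' Fixture configuration
#'
#' @param population Adult population size (default 1,000,000).
#' @param start_year,end_year Simulation horizon (default 2010-2060).
#' @param seed Integer seed for surveillance noise; a fixed seed gives
#'   byte-identical fixtures.
#' @param noise Relative standard deviation of the lognormal surveillance
#'   noise (default 0.02).
#' @param deviators Deviator plan: data frame `(measure, type, value)` naming
#'   the measures whose surveillance series get a planted multiplier
#'   (`type = "constant"`, multiplier `value`) or a log-linear drift
#'   (`type = "drift"`, annual log-slope `value`). See [default_deviators()].
#' @export
fixture_config <- function(population = 1e6, start_year = 2010, end_year = 2060,
                           seed = 1L, noise = 0.02,
                           deviators = default_deviators()) {
  if (!is.finite(population) || population <= 0)
    stop("`population` must be positive", call. = FALSE)
  if (!is.finite(noise) || noise < 0)
    stop("`noise` must be >= 0", call. = FALSE)
  structure(list(population = population,
                 start_year = as.integer(start_year),
                 end_year = as.integer(end_year),
                 seed = as.integer(seed), noise = noise,
                 deviators = as.data.frame(deviators, stringsAsFactors = FALSE)),
            class = "fixture_config")
}

#' Default deviator plan: four persistently deviating measures
#'
#' Mirrors an external-validation outcome in which adult obesity prevalence,
#' CVD deaths, diabetes-related and distress-related non-CVD deaths drift
#' away from the model while the other measures track it.
#'
#' @export
default_deviators <- function() {
  data.frame(
    measure = c("adult_obesity_pct", "cvd_deaths",
                "diabetes_noncvd_deaths", "distress_noncvd_deaths"),
    type = c("constant", "drift", "constant", "constant"),
    value = c(1.30, 0.06, 1.25, 0.80),
    stringsAsFactors = FALSE)
}

# exogenous risk-factor metadata: 2010 prevalence, annual relative drift,
# relative risk for a first CVD event (NA = not in the event-rate product).
# Drifts are either flat or steep relative to survey noise so that trend
# direction is identifiable from the sampling windows.
toy_factor_meta <- function() {
  data.frame(
    factor = c("youth_obesity", "smoker_current", "smoker_former",
               "shs_exposure", "high_bp", "borderline_bp", "high_chol",
               "borderline_chol", "diabetes", "prediabetes", "distress"),
    p0 = c(0.17, 0.19, 0.22, 0.25, 0.30, 0.25, 0.12, 0.28, 0.10, 0.33, 0.04),
    drift = c(0.015, -0.020, 0, -0.040, 0, 0, -0.020, 0, 0.020, 0, 0.020),
    rr_event = c(NA, 2.5, 1.2, 1.25, 2.0, 1.2, 1.4, 1.1, 2.0, 1.15, 1.3),
    stringsAsFactors = FALSE)
}

# measure catalogue: the 25 surveillance-comparable outputs with their kind
# and synthetic sampling years (survey-style windows clipped to the clock)
toy_measure_meta <- function() {
  biennial <- "2011;2013;2015"
  m <- rbind(
    data.frame(measure = c("youth_obesity_pct", "adult_obesity_pct",
                           "current_smoker_pct", "former_smoker_pct",
                           "shs_exposure_pct", "high_bp_pct", "borderline_bp_pct",
                           "high_chol_pct", "borderline_chol_pct",
                           "diabetes_pct", "prediabetes_pct"),
               kind = "percent", years = biennial,
               source = "synthetic-exam-survey"),
    data.frame(measure = "distress_pct", kind = "percent",
               years = "2010;2012;2014;2016", source = "synthetic-interview-survey"),
    data.frame(measure = "cvd_deaths", kind = "count",
               years = paste(2010:2016, collapse = ";"),
               source = "synthetic-vital-statistics"),
    data.frame(measure = "post_cvd_prevalence_pct", kind = "percent",
               years = paste(2010:2016, collapse = ";"),
               source = "synthetic-interview-survey"),
    data.frame(measure = "post_cvd_disability_pct", kind = "percent",
               years = paste(2010:2015, collapse = ";"),
               source = "synthetic-interview-survey"),
    data.frame(measure = c("smoking_noncvd_deaths", "diabetes_noncvd_deaths",
                           "distress_noncvd_deaths"),
               kind = "count", years = paste(2010:2016, collapse = ";"),
               source = "synthetic-vital-statistics"),
    data.frame(measure = c("smoking_noncvd_hosp", "diabetes_noncvd_hosp",
                           "distress_noncvd_hosp"),
               kind = "count", years = paste(2010:2015, collapse = ";"),
               source = "synthetic-hospital-discharge"),
    data.frame(measure = c("hypertension_disability_pct", "smoking_disability_pct",
                           "diabetes_disability_pct", "obesity_disability_pct"),
               kind = "percent", years = paste(2010:2015, collapse = ";"),
               source = "synthetic-expenditure-panel"))
  m$measure <- as.character(m$measure)
  m
}

measure_years <- function(measures, measure) {
  as.integer(strsplit(measures$years[measures$measure == measure], ";")[[1L]])
}

#' Build the desk-scale toy nation
#'
#' Emits a complete, validating model covering every surveillance measure
#' class: 12 risk-factor prevalences (adult obesity endogenous, fed by a
#' youth-obesity aging transfer), first and recurrent CVD events with
#' quality-of-care-modified case fatality in the non-CVD / post-CVD split,
#' attributed non-CVD deaths, hospitalizations and disability, six
#' intervention levers obeying the "no change or better" guard, the
#' sensitivity bounds table (including the printed quality acute/
#' rehabilitation care pair 0.43/0.90), and the cost ledger.
#'
#' @param config A [fixture_config()].
#' @return An `sd_nation` list: `spec`, `clock`, `levers`, `bounds`, `costs`,
#'   `measures`, `factors` (a [risk_factor_table()] of the exogenous factor
#'   paths for the standalone epidemiological operations) and `config`.
#' @export
make_toy_nation <- function(config = fixture_config()) {
  clock <- sf_clock(config$start_year, config$end_year)
  years <- clock_years(clock)
  yr_chr <- as.character(years)
  scale <- config$population / 1e6
  meta <- toy_factor_meta()

  params <- list()
  trend_path <- function(drift) stats::setNames((1 + drift)^(years - years[1]), yr_chr)
  for (i in seq_len(nrow(meta))) {
    f <- meta$factor[i]
    params[[paste0("p_", f)]] <- list(value = meta$p0[i],
                                      trend = trend_path(meta$drift[i]))
    params[[paste0("pref_", f)]] <- meta$p0[i]
    if (!is.na(meta$rr_event[i]))
      params[[paste0("rr_ev_", f)]] <- meta$rr_event[i]
  }
  params$pref_adult_obesity <- 0.35
  params$rr_ev_adult_obesity <- 1.6

  params$base_event_rate <- 0.006
  params$case_fatality <- 0.30
  params$post_rate_ratio <- 3.0
  params$quality_q <- 0.60       # event-fatality ratio under full quality care
  params$quality_reach <- 0.05   # slice of events receiving upgraded care at movement 1
  params$lv_quality <- 0
  params$bg_mort_non <- 0.007
  params$bg_mort_post <- 0.020
  params$inflow <- 14000 * scale
  params$aging_frac <- 0.025
  params$ob_drift <- 0.009
  params$hosp_rate <- 0.08
  params$rr_mort_smoking <- 2.2
  params$rr_mort_diabetes <- 1.7
  params$rr_mort_distress <- 1.4
  params$rr_hosp_smoking <- 1.8
  params$rr_hosp_diabetes <- 1.6
  params$rr_hosp_distress <- 1.3
  params$disab_post_cvd <- 0.35
  params$disab_highbp <- 0.10
  params$disab_smoking <- 0.12
  params$disab_diabetes <- 0.25
  params$disab_obesity <- 0.15

  measures <- toy_measure_meta()
  for (m in measures$measure) params[[paste0("mult_", m)]] <- 1

  rr_term <- function(sym, pref, rr)
    sprintf("(1 + %s * (%s - 1)) / (1 + %s * (%s - 1))", sym, rr, pref, rr)
  prod_factors <- meta$factor[!is.na(meta$rr_event)]
  terms <- c(
    vapply(prod_factors, function(f)
      rr_term(paste0("p_", f), paste0("pref_", f), paste0("rr_ev_", f)),
      character(1)),
    rr_term("adult_obesity", "pref_adult_obesity", "rr_ev_adult_obesity"))
  aux <- c(
    risk_mult = paste(terms, collapse = " * "),
    event_rate_t = "base_event_rate * risk_mult",
    cf_eff = "case_fatality * (1 - lv_quality * quality_reach * (1 - quality_q))")

  stocks <- data.frame(
    name = c("non_cvd", "post_cvd", "adult_obesity"),
    initial = c(0.95 * config$population, 0.05 * config$population, 0.35),
    units = c("persons", "persons", "fraction"),
    stringsAsFactors = FALSE)

  flows <- data.frame(
    name = c("cvd_death_first", "cvd_survive_first", "cvd_death_post",
             "bg_death_non", "bg_death_post", "aging_in", "obesity_net"),
    source = c("non_cvd", "non_cvd", "post_cvd", "non_cvd", "post_cvd",
               "external", "external"),
    target = c("external", "post_cvd", "external", "external", "external",
               "non_cvd", "adult_obesity"),
    rate = c("non_cvd * event_rate_t * cf_eff",
             "non_cvd * event_rate_t * (1 - cf_eff)",
             "post_cvd * event_rate_t * post_rate_ratio * cf_eff",
             "non_cvd * bg_mort_non",
             "post_cvd * bg_mort_post",
             "inflow",
             "aging_frac * (p_youth_obesity - adult_obesity) + ob_drift"),
    stringsAsFactors = FALSE)

  paf <- function(p, rr) sprintf("(%s * (%s - 1)) / (1 + %s * (%s - 1))", p, rr, p, rr)
  pct <- function(expr, m) sprintf("100 * %s * mult_%s", expr, m)
  outputs <- c(
    noncvd_deaths_total = "bg_death_non + bg_death_post",
    noncvd_hosp_total = "(non_cvd + post_cvd) * hosp_rate",
    cvd_events = "non_cvd * event_rate_t + post_cvd * event_rate_t * post_rate_ratio",
    total_deaths = "cvd_death_first + cvd_death_post + bg_death_non + bg_death_post",
    population = "non_cvd + post_cvd",
    youth_obesity_pct = pct("p_youth_obesity", "youth_obesity_pct"),
    adult_obesity_pct = pct("adult_obesity", "adult_obesity_pct"),
    current_smoker_pct = pct("p_smoker_current", "current_smoker_pct"),
    former_smoker_pct = pct("p_smoker_former", "former_smoker_pct"),
    shs_exposure_pct = pct("p_shs_exposure", "shs_exposure_pct"),
    high_bp_pct = pct("p_high_bp", "high_bp_pct"),
    borderline_bp_pct = pct("p_borderline_bp", "borderline_bp_pct"),
    high_chol_pct = pct("p_high_chol", "high_chol_pct"),
    borderline_chol_pct = pct("p_borderline_chol", "borderline_chol_pct"),
    diabetes_pct = pct("p_diabetes", "diabetes_pct"),
    prediabetes_pct = pct("p_prediabetes", "prediabetes_pct"),
    distress_pct = pct("p_distress", "distress_pct"),
    cvd_deaths = "(cvd_death_first + cvd_death_post) * mult_cvd_deaths",
    post_cvd_prevalence_pct =
      "100 * post_cvd / (non_cvd + post_cvd) * mult_post_cvd_prevalence_pct",
    post_cvd_disability_pct = pct("disab_post_cvd", "post_cvd_disability_pct"),
    smoking_noncvd_deaths = sprintf(
      "noncvd_deaths_total * %s * mult_smoking_noncvd_deaths",
      paf("p_smoker_current", "rr_mort_smoking")),
    diabetes_noncvd_deaths = sprintf(
      "noncvd_deaths_total * %s * mult_diabetes_noncvd_deaths",
      paf("p_diabetes", "rr_mort_diabetes")),
    distress_noncvd_deaths = sprintf(
      "noncvd_deaths_total * %s * mult_distress_noncvd_deaths",
      paf("p_distress", "rr_mort_distress")),
    smoking_noncvd_hosp = sprintf(
      "noncvd_hosp_total * %s * mult_smoking_noncvd_hosp",
      paf("p_smoker_current", "rr_hosp_smoking")),
    diabetes_noncvd_hosp = sprintf(
      "noncvd_hosp_total * %s * mult_diabetes_noncvd_hosp",
      paf("p_diabetes", "rr_hosp_diabetes")),
    distress_noncvd_hosp = sprintf(
      "noncvd_hosp_total * %s * mult_distress_noncvd_hosp",
      paf("p_distress", "rr_hosp_distress")),
    hypertension_disability_pct =
      "100 * p_high_bp * disab_highbp * mult_hypertension_disability_pct",
    smoking_disability_pct =
      "100 * p_smoker_current * disab_smoking * mult_smoking_disability_pct",
    diabetes_disability_pct =
      "100 * p_diabetes * disab_diabetes * mult_diabetes_disability_pct",
    obesity_disability_pct =
      "100 * adult_obesity * disab_obesity * mult_obesity_disability_pct")

  spec <- sf_spec(stocks, flows, params, aux, outputs)

  levers <- lever_set(data.frame(
    lever = c("smoking_quit_services", "smoking_quit_services",
              "energy_dense_food_pricing", "energy_dense_food_pricing",
              "physical_activity_schools", "physical_activity_childcare",
              "bp_control", "quality_acute_rehab_care"),
    parameter = c("p_smoker_current", "p_smoker_former",
                  "ob_drift", "p_diabetes",
                  "p_youth_obesity", "p_youth_obesity",
                  "p_high_bp", "lv_quality"),
    max_effect = c(-0.14, 0.14, -0.004, -0.04, -0.05, -0.03, -0.15, 1),
    stringsAsFactors = FALSE))

  bounds <- parameter_bounds(data.frame(
    parameter = c("quality_q", "base_event_rate", "case_fatality",
                  "rr_ev_smoker_current", "rr_ev_high_bp", "rr_ev_diabetes",
                  "rr_ev_adult_obesity", "post_rate_ratio", "bg_mort_non",
                  "inflow", "aging_frac", "ob_drift"),
    default = c(0.60, 0.006, 0.30, 2.5, 2.0, 2.0, 1.6, 3.0, 0.007,
                14000 * scale, 0.025, 0.009),
    low = c(0.43, 0.00582, 0.291, 2.375, 1.9, 1.9, 1.52, 2.7, 0.0063,
            12600 * scale, 0.0225, 0.0081),
    high = c(0.90, 0.00618, 0.309, 2.625, 2.1, 2.1, 1.68, 3.3, 0.0077,
             15400 * scale, 0.0275, 0.0099),
    note = c("printed plausible range for quality acute/rehabilitation care effect",
             "event incidence tightly pinned by surveillance (+/-3%)",
             "case fatality tightly pinned by surveillance (+/-3%)",
             "meta-analytic RR (+/-5%)", "meta-analytic RR (+/-5%)",
             "meta-analytic RR (+/-5%)", "meta-analytic RR (+/-5%)",
             "post-CVD excess rate ratio (+/-10%)",
             "background mortality (+/-10%)", "net adult inflow (+/-10%)",
             "youth-to-adult aging fraction (+/-10%)",
             "adult-onset obesity drift (+/-10%)"),
    stringsAsFactors = FALSE))

  costs <- cost_ledger(
    implementation = data.frame(
      lever = c("smoking_quit_services", "energy_dense_food_pricing",
                "physical_activity_schools", "physical_activity_childcare",
                "bp_control", "quality_acute_rehab_care"),
      annual_cost = c(30e6, 5e6, 12e6, 8e6, 25e6, 20e6) * scale,
      stringsAsFactors = FALSE),
    unit_costs = data.frame(
      class = c("cvd_events", "smoking_noncvd_hosp", "diabetes_noncvd_hosp",
                "distress_noncvd_hosp"),
      unit_cost = c(60000, 15000, 15000, 15000),
      stringsAsFactors = FALSE),
    cost_year = 2012, discount_rate = 0.03)

  prev <- do.call(rbind, lapply(seq_len(nrow(meta)), function(i) {
    data.frame(factor = meta$factor[i], year = years,
               prevalence = meta$p0[i] * (1 + meta$drift[i])^(years - years[1]),
               stringsAsFactors = FALSE)
  }))
  rr <- rbind(
    data.frame(factor = prod_factors, outcome = "cvd_event",
               rr = meta$rr_event[!is.na(meta$rr_event)]),
    data.frame(factor = c("smoker_current", "diabetes", "distress"),
               outcome = "noncvd_death", rr = c(2.2, 1.7, 1.4)),
    data.frame(factor = c("smoker_current", "diabetes", "distress"),
               outcome = "noncvd_hosp", rr = c(1.8, 1.6, 1.3)))
  factors <- risk_factor_table(
    prev, rr,
    groups = list(smoking = c("smoker_current", "smoker_former")))

  structure(list(spec = spec, clock = clock, levers = levers, bounds = bounds,
                 costs = costs, measures = measures, factors = factors,
                 config = config),
            class = "sd_nation")
}

#' @export
print.sd_nation <- function(x, ...) {
  cat(sprintf("<sd_nation> population %s, %d-%d, %d measures, %d levers, %d bounds\n",
              format(x$config$population, big.mark = ","),
              x$clock$start_year, x$clock$end_year,
              nrow(x$measures), length(unique(x$levers$lever)), nrow(x$bounds)))
  invisible(x)
}

planted_multiplier <- function(config, measure, years) {
  dev <- config$deviators
  hit <- which(dev$measure == measure)
  if (!length(hit)) return(rep(1, length(years)))
  if (dev$type[hit] == "constant") return(rep(dev$value[hit], length(years)))
  exp(dev$value[hit] * (years - config$start_year))
}

#' Generate the synthetic surveillance panel
#'
#' For each measure, observations are the model output at the measure's
#' sampling years times the planted multiplier path (1 except for deviator
#' measures) times lognormal noise at the configured relative standard
#' deviation. The seed fixes the noise; the planted multipliers are part of
#' the plan, not the randomness, so different seeds change only the noise.
#'
#' @param nation An `sd_nation` from [make_toy_nation()].
#' @param config A [fixture_config()]; defaults to the nation's own.
#' @param traj Optional precomputed base trajectory.
#' @return A [surveillance_panel()].
#' @export
make_surveillance_panel <- function(nation, config = nation$config, traj = NULL) {
  if (is.null(traj)) traj <- sf_simulate(nation$spec, nation$clock)
  set.seed(config$seed)
  rows <- lapply(nation$measures$measure, function(m) {
    yrs <- measure_years(nation$measures, m)
    model <- as.numeric(traj_series(traj, m)[as.character(yrs)])
    plant <- planted_multiplier(config, m, yrs)
    noise <- exp(stats::rnorm(length(yrs), mean = 0, sd = config$noise))
    data.frame(measure = m, year = yrs, value = model * plant * noise,
               kind = nation$measures$kind[nation$measures$measure == m],
               source = nation$measures$source[nation$measures$measure == m],
               stringsAsFactors = FALSE)
  })
  surveillance_panel(do.call(rbind, rows))
}

#' Write a self-contained fixture directory
#'
#' Emits the model spec (YAML), lever, bound, cost and measure tables (CSV),
#' the synthetic surveillance panel (CSV) and the fixture configuration
#' (JSON). [read_fixture_dir()] reconstitutes the nation and panel.
#'
#' @param nation An `sd_nation`.
#' @param dir Target directory (created if needed).
#' @param panel Optional pre-built [surveillance_panel()]; generated from the
#'   nation's config when `NULL`.
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(nation, dir, panel = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_model_spec(nation$spec, file.path(dir, "model.yaml"))
  write_table(as.data.frame(nation$levers), file.path(dir, "levers.csv"))
  write_table(as.data.frame(nation$bounds), file.path(dir, "bounds.csv"))
  write_table(nation$costs$implementation, file.path(dir, "costs_implementation.csv"))
  write_table(nation$costs$unit_costs, file.path(dir, "costs_unit.csv"))
  write_table(nation$measures, file.path(dir, "measures.csv"))
  if (is.null(panel)) panel <- make_surveillance_panel(nation)
  write_table(as.data.frame(panel), file.path(dir, "surveillance.csv"))
  cfg <- nation$config
  jsonlite::write_json(
    list(population = cfg$population, start_year = cfg$start_year,
         end_year = cfg$end_year, seed = cfg$seed, noise = cfg$noise,
         deviators = cfg$deviators,
         cost_year = nation$costs$cost_year,
         discount_rate = nation$costs$discount_rate),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_fixture_dir
#' @export
read_fixture_dir <- function(dir) {
  if (!dir.exists(dir))
    stop("no such fixture directory: ", dir, call. = FALSE)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- fixture_config(population = cfg$population,
                           start_year = cfg$start_year, end_year = cfg$end_year,
                           seed = cfg$seed, noise = cfg$noise,
                           deviators = cfg$deviators)
  spec <- read_model_spec(file.path(dir, "model.yaml"))
  levers <- lever_set(read_table(file.path(dir, "levers.csv"),
                                 c("lever", "parameter", "max_effect")))
  bounds <- read_bounds(file.path(dir, "bounds.csv"))
  costs <- cost_ledger(
    read_table(file.path(dir, "costs_implementation.csv"), c("lever", "annual_cost")),
    read_table(file.path(dir, "costs_unit.csv"), c("class", "unit_cost")),
    cost_year = cfg$cost_year, discount_rate = cfg$discount_rate)
  measures <- read_table(file.path(dir, "measures.csv"),
                         c("measure", "kind", "years", "source"))
  panel <- read_surveillance(file.path(dir, "surveillance.csv"))
  nation <- structure(list(spec = spec,
                           clock = sf_clock(cfg$start_year, cfg$end_year),
                           levers = levers, bounds = bounds, costs = costs,
                           measures = measures,
                           factors = make_toy_nation(config)$factors,
                           config = config),
                      class = "sd_nation")
  list(nation = nation, panel = panel)
}
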
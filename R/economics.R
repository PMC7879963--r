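# Health-economic layer: implementation and medical cost streams, 3% annual
# discounting, and the derived net-cost / cost-per-death-averted outcomes.

#' Cost ledger
#'
#' @param implementation Data frame `(lever, annual_cost)`: implementation
#'   spend per year at full lever movement; scales linearly with movement.
#' @param unit_costs Data frame `(class, unit_cost)`: medical cost per
#'   outcome event for each costed outcome class.
#' @param cost_year Currency base year (e.g. 2012 for "2012 dollars"). Ledgers
#'   combined in [net_cost()] must share it; no silent conversion is done.
#' @param discount_rate Annual discount rate (default 0.03).
#' @export
cost_ledger <- function(implementation, unit_costs, cost_year,
                        discount_rate = 0.03) {
  implementation <- as.data.frame(implementation, stringsAsFactors = FALSE)
  unit_costs <- as.data.frame(unit_costs, stringsAsFactors = FALSE)
  miss <- setdiff(c("lever", "annual_cost"), names(implementation))
  if (length(miss))
    stop("`implementation` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(c("class", "unit_cost"), names(unit_costs))
  if (length(miss))
    stop("`unit_costs` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.finite(discount_rate) || discount_rate < 0)
    stop("`discount_rate` must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(implementation$annual_cost)) ||
      any(!is.finite(unit_costs$unit_cost)) || any(unit_costs$unit_cost < 0))
    stop("costs must be finite (unit costs non-negative)", call. = FALSE)
  structure(list(implementation = implementation, unit_costs = unit_costs,
                 cost_year = as.integer(cost_year),
                 discount_rate = discount_rate),
            class = "cost_ledger")
}

as_cost_series <- function(series) {
  if (is.data.frame(series)) {
    miss <- setdiff(c("year", "value"), names(series))
    if (length(miss))
      stop("cost series is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    return(series[, c("year", "value")])
  }
  if (is.null(names(series)))
    stop("a cost series must be a (year, value) data frame or a year-named vector",
         call. = FALSE)
  data.frame(year = as.numeric(names(series)), value = as.numeric(series))
}

#' Present value of an annual cost stream
#'
#' End-of-year convention counted from the base year: a payment in the base
#' year itself is undiscounted (exponent 0), and a payment t years later is
#' divided by `(1 + rate)^t`. At rate 0 this is the plain sum.
#'
#' @param series Annual stream: a data frame `(year, value)` or a numeric
#'   vector named by year.
#' @param rate Annual discount rate (>= 0).
#' @param base_year Discounting base year; must not exceed the first year of
#'   the series.
#' @return Present value (same currency as `series`).
#' @examples
#' present_value(c(`2019` = 103), rate = 0.03, base_year = 2018)  # 100
#' @export
present_value <- function(series, rate, base_year) {
  s <- as_cost_series(series)
  if (!is.finite(rate) || rate < 0)
    stop("`rate` must be finite and >= 0", call. = FALSE)
  if (nrow(s) && base_year > min(s$year))
    stop("`base_year` must not exceed the first year of the series", call. = FALSE)
  if (any(!is.finite(s$value)))
    stop("cost series contains non-finite values", call. = FALSE)
  sum(s$value / (1 + rate)^(s$year - base_year))
}

#' Annual medical cost change of a scenario versus its base run
#'
#' Attributable-fraction costing: only costed outcome classes contribute,
#' each at its unit cost times the scenario-minus-base difference in annual
#' counts. Negative values are savings.
#'
#' @param scenario_counts,base_counts Data frames `(class, year, count)` of
#'   annual outcome counts.
#' @param unit_costs Data frame `(class, unit_cost)`; every class appearing in
#'   the counts must have a unit cost.
#' @return Data frame `(year, value)` of annual cost changes.
#' @export
medical_cost_change <- function(scenario_counts, base_counts, unit_costs) {
  scenario_counts <- as.data.frame(scenario_counts, stringsAsFactors = FALSE)
  base_counts <- as.data.frame(base_counts, stringsAsFactors = FALSE)
  for (d in list(scenario_counts, base_counts)) {
    miss <- setdiff(c("class", "year", "count"), names(d))
    if (length(miss))
      stop("count table is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  classes <- union(unique(scenario_counts$class), unique(base_counts$class))
  unknown <- setdiff(classes, unit_costs$class)
  if (length(unknown))
    stop("no unit cost for outcome class(es): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  key <- function(d) paste(d$class, d$year)
  merged <- merge(scenario_counts, base_counts, by = c("class", "year"),
                  suffixes = c("_scenario", "_base"))
  uc <- stats::setNames(unit_costs$unit_cost, unit_costs$class)
  merged$change <- uc[merged$class] * (merged$count_scenario - merged$count_base)
  agg <- stats::aggregate(change ~ year, data = merged, FUN = sum)
  data.frame(year = agg$year, value = agg$change)
}

#' Net cost of an intervention
#'
#' Implementation present value plus medical-change present value (medical
#' savings enter negative). Both components must share a currency base year;
#' if year tags are supplied and differ, this is an error, never a silent
#' conversion.
#'
#' @param implementation_pv,medical_change_pv Present values in a common
#'   cost base year.
#' @param implementation_cost_year,medical_cost_year Optional currency-year
#'   tags, checked for equality when both are given.
#' @return Net cost.
#' @examples
#' net_cost(874, -166)  # 708
#' @export
net_cost <- function(implementation_pv, medical_change_pv,
                     implementation_cost_year = NULL, medical_cost_year = NULL) {
  if (!is.null(implementation_cost_year) && !is.null(medical_cost_year) &&
      implementation_cost_year != medical_cost_year)
    stop(sprintf("cost base years differ (%s vs %s); convert before combining",
                 implementation_cost_year, medical_cost_year), call. = FALSE)
  implementation_pv + medical_change_pv
}

#' Cost per death averted
#'
#' Undefined when no deaths are averted: returns an `NA` sentinel flagged
#' with attribute `undefined = TRUE` rather than dividing.
#'
#' @param net_cost Net cost (currency).
#' @param deaths_averted Cumulative deaths averted (> 0 for a defined ratio).
#' @return Currency per death averted, or a flagged `NA`.
#' @export
cost_per_death_averted <- function(net_cost, deaths_averted) {
  if (!is.finite(deaths_averted) || deaths_averted <= 0)
    return(structure(NA_real_, undefined = TRUE))
  net_cost / deaths_averted
}

#' Round a cost-per-death figure to the nearest $10,000 for reporting
#'
#' Commercial rounding (half away from zero), so a value already at the
#' reporting precision is returned unchanged.
#'
#' @param x Cost per death averted.
#' @export
report_cost_per_death <- function(x) {
  x <- as.numeric(x)
  ifelse(is.na(x), x, sign(x) * floor(abs(x) / 1e4 + 0.5) * 1e4)
}
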
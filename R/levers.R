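# Intervention levers and scenario construction: a lever is a 0-1 control
# whose movement shifts one or more model parameters linearly away from the
# status quo; scenarios difference an intervention run against the base run
# over an outcome window.

#' Lever set
#'
#' @param levers Data frame `(lever, parameter, max_effect)`: each row maps a
#'   lever to a target parameter and the additive parameter change at
#'   movement 1. A lever may target several parameters (one row each). The
#'   effect at movement 0 is exactly zero.
#' @export
lever_set <- function(levers) {
  levers <- as.data.frame(levers, stringsAsFactors = FALSE)
  miss <- setdiff(c("lever", "parameter", "max_effect"), names(levers))
  if (length(miss))
    stop("`levers` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(levers$max_effect)))
    stop("`max_effect` must be finite", call. = FALSE)
  structure(levers, class = c("lever_set", "data.frame"))
}

#' Apply lever movements to model parameters
#'
#' Linear interpolation: `parameter' = parameter + movement * max_effect`.
#' Untouched parameters are returned identical; movement 0 is the exact
#' status-quo identity.
#'
#' @param parameters Named parameter list as held by an [sf_spec()] (entries
#'   with a `value` element) or a plain named numeric list.
#' @param levers A [lever_set()].
#' @param movements Named numeric vector/list of movements in \[0, 1\], keyed
#'   by lever name.
#' @return The updated parameter list.
#' @export
apply_levers <- function(parameters, levers, movements) {
  movements <- unlist(movements)
  unknown <- setdiff(names(movements), levers$lever)
  if (length(unknown))
    stop("unknown lever(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  bad <- names(movements)[!is.finite(movements) | movements < 0 | movements > 1]
  if (length(bad))
    stop(sprintf("movement for lever '%s' must lie in [0, 1]", bad[1]),
         call. = FALSE)
  for (i in seq_len(nrow(levers))) {
    lv <- levers$lever[i]
    if (!lv %in% names(movements)) next
    p <- levers$parameter[i]
    if (!p %in% names(parameters))
      stop(sprintf("lever '%s' targets unknown parameter '%s'", lv, p),
           call. = FALSE)
    shift <- movements[[lv]] * levers$max_effect[i]
    if (is.list(parameters[[p]]) && "value" %in% names(parameters[[p]])) {
      parameters[[p]]$value <- parameters[[p]]$value + shift
    } else {
      parameters[[p]] <- parameters[[p]] + shift
    }
  }
  parameters
}

#' Translate a price policy into a pricing-lever movement
#'
#' A tax that changes prices by `price_change` acts on an energy-dense food
#' pricing lever only through the share of energy-dense consumption the taxed
#' goods represent: `movement = price_change * consumption_share`.
#'
#' @param price_change Fractional price change from the policy, in \[0, 1\].
#' @param consumption_share Taxed goods' share of energy-dense consumption,
#'   in \[0, 1\].
#' @return Lever movement in \[0, 1\], with a one-decimal percent label
#'   attached as attribute `"label"`.
#' @examples
#' translate_price_policy(0.078, 0.245)  # 0.0191, "1.9%"
#' @export
translate_price_policy <- function(price_change, consumption_share) {
  for (v in c(price_change, consumption_share))
    if (!is.finite(v) || v < 0 || v > 1)
      stop("`price_change` and `consumption_share` must lie in [0, 1]",
           call. = FALSE)
  movement <- price_change * consumption_share
  structure(movement, label = percent_label(movement))
}

#' Format a lever movement as a percent string
#'
#' @param movement Movement in \[0, 1\].
#' @param digits Decimal places (default 1, the reporting convention).
#' @export
percent_label <- function(movement, digits = 1) {
  sprintf("%.*f%%", digits, 100 * as.numeric(movement))
}

#' All-zero / all-maximum movement helpers
#'
#' @param nation A toy-nation object from [make_toy_nation()].
#' @param value Movement applied to every lever.
#' @export
lever_movements <- function(nation, value = 0) {
  stats::setNames(rep(value, length(unique(nation$levers$lever))),
                  unique(nation$levers$lever))
}

#' Run an intervention scenario against the base run
#'
#' Simulates the base trajectory (all levers at zero) and the intervention
#' trajectory (the supplied movements applied), then differences cumulative
#' outcomes over the closed outcome window: deaths and events averted are
#' base minus intervention; annual implementation and medical cost-change
#' streams are intervention minus base. Both runs share the spec and clock
#' and are fully deterministic.
#'
#' @param nation A toy-nation object from [make_toy_nation()] (or any object
#'   with `spec`, `clock`, `levers`, `costs` and a `cost_classes` map).
#' @param movements Named lever movements in \[0, 1\]; levers not named are
#'   left at zero.
#' @param window Outcome window `c(first, last)`, default 2018-2040, closed
#'   on both ends; must lie inside the clock.
#' @return A `scenario_result` with both trajectories, the cumulative deltas
#'   and the annual cost streams.
#' @export
run_scenario <- function(nation, movements = lever_movements(nation),
                         window = c(2018, 2040)) {
  clock <- nation$clock
  window <- as.integer(window)
  if (length(window) != 2L || window[1] > window[2] ||
      window[1] < clock$start_year || window[2] > clock$end_year)
    stop("outcome window must lie inside the simulation clock", call. = FALSE)
  base_traj <- sf_simulate(nation$spec, clock)
  ispec <- nation$spec
  ispec$parameters <- apply_levers(ispec$parameters, nation$levers, movements)
  int_traj <- sf_simulate(ispec, clock)
  wyears <- as.character(seq.int(window[1], window[2]))
  cum <- function(traj, m) sum(traj_series(traj, m)[wyears])

  deaths_averted <- cum(base_traj, "total_deaths") - cum(int_traj, "total_deaths")
  cvd_deaths_averted <- cum(base_traj, "cvd_deaths") - cum(int_traj, "cvd_deaths")
  events_averted <- cum(base_traj, "cvd_events") - cum(int_traj, "cvd_events")

  impl <- nation$costs$implementation
  mv <- stats::setNames(rep(0, nrow(impl)), impl$lever)
  mv[names(movements)[names(movements) %in% impl$lever]] <-
    unlist(movements)[names(movements) %in% impl$lever]
  annual_impl <- sum(mv * impl$annual_cost)
  implementation_costs <- data.frame(year = seq.int(window[1], window[2]),
                                     value = annual_impl)

  counts_of <- function(traj) {
    do.call(rbind, lapply(nation$costs$unit_costs$class, function(cl) {
      data.frame(class = cl, year = as.integer(wyears),
                 count = as.numeric(traj_series(traj, cl)[wyears]),
                 stringsAsFactors = FALSE)
    }))
  }
  medical_change <- medical_cost_change(counts_of(int_traj), counts_of(base_traj),
                                        nation$costs$unit_costs)

  structure(list(base = base_traj, intervention = int_traj,
                 movements = movements, window = window,
                 deaths_averted = deaths_averted,
                 cvd_deaths_averted = cvd_deaths_averted,
                 events_averted = events_averted,
                 implementation_costs = implementation_costs,
                 medical_change = medical_change,
                 ledger = nation$costs),
            class = "scenario_result")
}

#' Scenario comparison record
#'
#' Discounts the scenario's annual cost streams to present value at the
#' ledger's rate (base year = first window year, end-of-year convention) and
#' derives net cost and cost per death averted.
#'
#' @param result A `scenario_result` from [run_scenario()].
#' @param base_year Discounting base year (default: first window year).
#' @return A `scenario_report` list with implementation PV, medical change
#'   PV, net cost, deaths/events averted and cost per death averted (`NA`
#'   and `cost_per_death_defined = FALSE` for a null scenario).
#' @export
scenario_report <- function(result, base_year = result$window[1]) {
  rate <- result$ledger$discount_rate
  impl_pv <- present_value(result$implementation_costs, rate, base_year)
  med_pv <- present_value(result$medical_change, rate, base_year)
  net <- net_cost(impl_pv, med_pv,
                  implementation_cost_year = result$ledger$cost_year,
                  medical_cost_year = result$ledger$cost_year)
  cpd <- cost_per_death_averted(net, result$deaths_averted)
  structure(list(
    window = result$window,
    cost_year = result$ledger$cost_year,
    discount_rate = rate,
    movements = result$movements,
    implementation_pv = impl_pv,
    medical_change_pv = med_pv,
    net_cost = net,
    deaths_averted = result$deaths_averted,
    cvd_deaths_averted = result$cvd_deaths_averted,
    events_averted = result$events_averted,
    cost_per_death_averted = as.numeric(cpd),
    cost_per_death_averted_reported = report_cost_per_death(cpd),
    cost_per_death_defined = !isTRUE(attr(cpd, "undefined"))),
    class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("<scenario_report> window %d-%d (%d dollars, %.0f%% discount)\n",
              x$window[1], x$window[2], x$cost_year, 100 * x$discount_rate))
  cat(sprintf("  deaths averted        %12.1f\n", x$deaths_averted))
  cat(sprintf("  CVD deaths averted    %12.1f\n", x$cvd_deaths_averted))
  cat(sprintf("  events averted        %12.1f\n", x$events_averted))
  cat(sprintf("  implementation PV     %12.0f\n", x$implementation_pv))
  cat(sprintf("  medical change PV     %12.0f\n", x$medical_change_pv))
  cat(sprintf("  net cost              %12.0f\n", x$net_cost))
  if (x$cost_per_death_defined)
    cat(sprintf("  cost per death averted %11.0f (reported %s)\n",
                x$cost_per_death_averted,
                format(x$cost_per_death_averted_reported, big.mark = ",")))
  else cat("  cost per death averted: undefined (no deaths averted)\n")
  invisible(x)
}
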
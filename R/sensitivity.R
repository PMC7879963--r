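# One-way sensitivity harness: vary one parameter at a time between its
# plausible low and high bounds (all others at defaults), record the percent
# change in a focal outcome against a shared base run, filter by influence
# and order for a tornado display.

#' Parameter bounds table
#'
#' @param bounds Data frame `(parameter, default, low, high)` with an optional
#'   `note` provenance column; requires `low <= default <= high`, all finite.
#' @export
parameter_bounds <- function(bounds) {
  bounds <- as.data.frame(bounds, stringsAsFactors = FALSE)
  miss <- setdiff(c("parameter", "default", "low", "high"), names(bounds))
  if (length(miss))
    stop("`bounds` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"note" %in% names(bounds)) bounds$note <- ""
  v <- c(bounds$default, bounds$low, bounds$high)
  if (any(!is.finite(v)))
    stop("bounds must be finite", call. = FALSE)
  bad <- bounds$parameter[bounds$low > bounds$default | bounds$default > bounds$high]
  if (length(bad))
    stop("low <= default <= high violated for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(bounds, class = c("parameter_bounds", "data.frame"))
}

#' One-way sensitivity analysis
#'
#' For each bound independently, the model is re-run with the parameter at
#' its low and at its high value while every other input stays at its
#' default; the shared base run is computed exactly once. Percent changes are
#' expressed against the base-run outcome. A failed run produces a flagged
#' record rather than aborting the sweep.
#'
#' @param runner Function taking a named list of parameter overrides and
#'   returning the scalar focal outcome; `runner(list())` is the base run.
#' @param bounds A [parameter_bounds()] table.
#' @param outcome Outcome label carried into the records.
#' @return A `sensitivity_records` data frame, one row per bound in input
#'   order, with fractional changes (`change_low`, `change_high`),
#'   `influence = max(|low|, |high|)` and a `failed` flag; the base outcome is
#'   attached as attribute `"base_value"`.
#' @export
one_way <- function(runner, bounds, outcome = "outcome") {
  if (!inherits(bounds, "parameter_bounds")) bounds <- parameter_bounds(bounds)
  base <- runner(list())
  if (!is.finite(base) || base == 0)
    stop("base-run outcome must be finite and nonzero to express percent changes",
         call. = FALSE)
  try_run <- function(param, value) {
    tryCatch(runner(stats::setNames(list(value), param)),
             error = function(e) NA_real_)
  }
  rows <- lapply(seq_len(nrow(bounds)), function(i) {
    p <- bounds$parameter[i]
    v_low <- try_run(p, bounds$low[i])
    v_high <- try_run(p, bounds$high[i])
    failed <- !is.finite(v_low) || !is.finite(v_high)
    ch_low <- (v_low - base) / base
    ch_high <- (v_high - base) / base
    data.frame(parameter = p, outcome = outcome, base = base,
               value_low = v_low, value_high = v_high,
               change_low = ch_low, change_high = ch_high,
               influence = if (failed) NA_real_ else max(abs(ch_low), abs(ch_high)),
               failed = failed, stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  rownames(rec) <- NULL
  attr(rec, "base_value") <- base
  class(rec) <- c("sensitivity_records", "data.frame")
  rec
}

#' Influential parameters at a threshold
#'
#' Records whose influence is at or above the threshold ("0.5% or more" is
#' the default), sorted descending by influence with alphabetical
#' tie-breaking (tornado order). Flagged/failed records are never selected.
#'
#' @param records A `sensitivity_records` data frame from [one_way()].
#' @param threshold Influence threshold as a fraction (default 0.005 = 0.5%).
#' @return The selected subset in tornado order.
#' @export
influential <- function(records, threshold = 0.005) {
  keep <- !records$failed & is.finite(records$influence) &
    records$influence >= threshold
  sub <- records[keep, , drop = FALSE]
  sub <- sub[order(-sub$influence, sub$parameter), , drop = FALSE]
  rownames(sub) <- NULL
  attr(sub, "base_value") <- attr(records, "base_value")
  class(sub) <- c("sensitivity_records", "data.frame")
  sub
}

#' Tornado export table
#'
#' Per-parameter low/high percent changes in descending-influence order,
#' suitable for a horizontal bar chart; the base-run outcome used as the
#' percent denominator travels in attribute `"base_outcome"`.
#'
#' @param records A non-empty `sensitivity_records` data frame.
#' @export
tornado_table <- function(records) {
  if (!nrow(records)) stop("no sensitivity records to tabulate", call. = FALSE)
  ord <- records[order(-records$influence, records$parameter), , drop = FALSE]
  tab <- data.frame(parameter = ord$parameter,
                    pct_change_low = 100 * ord$change_low,
                    pct_change_high = 100 * ord$change_high,
                    influence_pct = 100 * ord$influence,
                    failed = ord$failed,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  attr(tab, "base_outcome") <- attr(records, "base_value")
  tab
}

#' Build a scenario-outcome runner for the sensitivity harness
#'
#' Returns a closure mapping parameter overrides (values replacing the spec
#' defaults) to a cumulative averted outcome of [run_scenario()]; the
#' internal-validation convention is all levers at their maximum.
#'
#' @param nation A toy nation from [make_toy_nation()].
#' @param movements Lever movements for the scenario (default: all at 1).
#' @param window Outcome window (default 2018-2040).
#' @param outcome One of `"cvd_deaths_averted"`, `"deaths_averted"`,
#'   `"events_averted"`.
#' @export
nation_runner <- function(nation, movements = lever_movements(nation, 1),
                          window = c(2018, 2040),
                          outcome = c("cvd_deaths_averted", "deaths_averted",
                                      "events_averted")) {
  outcome <- match.arg(outcome)
  force(movements); force(window)
  function(overrides = list()) {
    n2 <- nation
    for (p in names(overrides)) {
      if (!p %in% names(n2$spec$parameters))
        stop(sprintf("unknown parameter '%s'", p), call. = FALSE)
      n2$spec$parameters[[p]]$value <- as.numeric(overrides[[p]])
    }
    run_scenario(n2, movements, window)[[outcome]]
  }
}
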
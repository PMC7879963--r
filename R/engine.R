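# Annual-step stock-and-flow simulation core.
#
# A model is declared as stocks (compartments measured at January 1 of each
# year), flows (annual transfers between compartments or across the system
# boundary, acting over the following year), scalar parameters with optional
# per-year trend multipliers, auxiliary expressions, and named output
# expressions.  Rate expressions use a deliberately small arithmetic grammar
# (+, -, *, /, parentheses, numbers, named symbols) so a model file stays
# declarative and auditable: no arbitrary code is ever executed from a spec.

#' Simulation clock
#'
#' Defines the annual simulation horizon. Stocks are measured at January 1 of
#' each recorded year and flows act over the following year, so a clock from
#' 2010 to 2060 records exactly 51 annual states.
#'
#' @param start_year First calendar year recorded (default 2010).
#' @param end_year Last calendar year recorded (default 2060).
#' @return An object of class `sf_clock`.
#' @examples
#' length(clock_years(sf_clock(2010, 2060)))
#' @export
sf_clock <- function(start_year = 2010, end_year = 2060) {
  start_year <- as.integer(start_year)
  end_year <- as.integer(end_year)
  if (is.na(start_year) || is.na(end_year) || start_year >= end_year)
    stop("`start_year` must be an integer year strictly before `end_year`",
         call. = FALSE)
  structure(list(start_year = start_year, end_year = end_year, step = 1L),
            class = "sf_clock")
}

#' @rdname sf_clock
#' @param clock An `sf_clock`.
#' @export
clock_years <- function(clock) seq.int(clock$start_year, clock$end_year)

# -- rate expression grammar -------------------------------------------------

ALLOWED_OPS <- c("+", "-", "*", "/", "(")

check_grammar <- function(e) {
  if (is.numeric(e) || is.integer(e)) return(TRUE)
  if (is.name(e)) return(TRUE)
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (!op %in% ALLOWED_OPS)
      return(sprintf("operator '%s' is outside the rate grammar (+, -, *, /, parentheses)", op))
    for (i in seq_along(e)[-1L]) {
      ok <- check_grammar(e[[i]])
      if (!isTRUE(ok)) return(ok)
    }
    return(TRUE)
  }
  "only numbers, names and arithmetic are allowed in rate expressions"
}

compile_expr <- function(text, where) {
  parsed <- tryCatch(parse(text = text, keep.source = FALSE),
                     error = function(e) e)
  if (inherits(parsed, "error") || length(parsed) != 1L)
    return(structure(
      list(message = sprintf("cannot parse expression in %s: '%s'", where, text)),
      class = "prevsim_expr_error"))
  ok <- check_grammar(parsed[[1L]])
  if (!isTRUE(ok))
    return(structure(list(message = sprintf("%s (in %s)", ok, where)),
                     class = "prevsim_expr_error"))
  parsed[[1L]]
}

is_expr_error <- function(x) inherits(x, "prevsim_expr_error")

compile_spec_exprs <- function(spec) {
  list(
    aux = lapply(seq_along(spec$aux), function(i)
      compile_expr(spec$aux[[i]], sprintf("auxiliary '%s'", names(spec$aux)[i]))),
    flows = lapply(seq_len(nrow(spec$flows)), function(i)
      compile_expr(spec$flows$rate[i], sprintf("flow '%s'", spec$flows$name[i]))),
    outputs = lapply(seq_along(spec$outputs), function(i)
      compile_expr(spec$outputs[[i]], sprintf("output '%s'", names(spec$outputs)[i])))
  )
}

# -- spec construction -------------------------------------------------------

normalize_params <- function(parameters) {
  lapply(parameters, function(p) {
    if (is.list(p)) {
      trend <- p$trend
      if (!is.null(trend)) {
        trend <- unlist(trend)
        storage.mode(trend) <- "double"
      }
      list(value = as.numeric(p$value), trend = trend)
    } else {
      list(value = as.numeric(p), trend = NULL)
    }
  })
}

#' Declare a stock-and-flow model
#'
#' @param stocks Data frame with columns `name`, `initial` (level at the clock
#'   start, non-negative) and `units` (`"persons"` or `"fraction"`).
#' @param flows Data frame with columns `name`, `source`, `target` (stock
#'   names or `"external"` for the system boundary) and `rate`, an arithmetic
#'   expression over parameters, stocks and auxiliaries.
#' @param parameters Named list. Each entry is either a scalar or a
#'   `list(value =, trend =)` where `trend` is a named numeric vector of
#'   per-year multipliers (names are calendar years); the parameter's value in
#'   year y is `value * trend[y]` (multiplier 1 for years absent from the
#'   trend).
#' @param aux Named character vector of auxiliary expressions, evaluated in
#'   order each year before flows; later auxiliaries may reference earlier
#'   ones.
#' @param outputs Named character vector of derived output expressions,
#'   evaluated in order each year after flows; they may reference stocks,
#'   parameters, auxiliaries, flow rates and earlier outputs.
#' @param check If `TRUE` (default), stop on any error-level finding from
#'   [validate_spec()].
#' @return An object of class `sf_spec`.
#' @seealso [validate_spec()], [sf_simulate()]
#' @export
sf_spec <- function(stocks, flows, parameters = list(),
                    aux = character(), outputs = character(),
                    check = TRUE) {
  stocks <- as.data.frame(stocks, stringsAsFactors = FALSE)
  flows <- as.data.frame(flows, stringsAsFactors = FALSE)
  miss <- setdiff(c("name", "initial", "units"), names(stocks))
  if (length(miss))
    stop("`stocks` is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(c("name", "source", "target", "rate"), names(flows))
  if (length(miss))
    stop("`flows` is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  aux <- vapply(aux, as.character, character(1))
  outputs <- vapply(outputs, as.character, character(1))
  spec <- structure(
    list(stocks = stocks, flows = flows,
         parameters = normalize_params(parameters),
         aux = aux, outputs = outputs),
    class = "sf_spec")
  spec$compiled <- compile_spec_exprs(spec)
  if (check) {
    findings <- validate_spec(spec)
    bad <- findings[findings$severity == "error", , drop = FALSE]
    if (nrow(bad))
      stop("invalid model spec:\n",
           paste0("  - [", bad$location, "] ", bad$message, collapse = "\n"),
           call. = FALSE)
  }
  spec
}

#' Validate a model spec
#'
#' Checks every structural invariant of an [sf_spec()] and returns findings
#' rather than raising errors, so a malformed spec can be audited in full.
#'
#' @param spec An `sf_spec` (possibly built with `check = FALSE`).
#' @return A data frame with columns `severity` (`"error"` or `"warning"`),
#'   `location` and `message`; zero rows iff the spec is well formed.
#' @export
validate_spec <- function(spec) {
  f <- list()
  add <- function(severity, location, message)
    f[[length(f) + 1L]] <<- data.frame(severity = severity, location = location,
                                       message = message, stringsAsFactors = FALSE)

  stocks <- spec$stocks
  dup <- unique(stocks$name[duplicated(stocks$name)])
  for (d in dup) add("error", "stocks", sprintf("stock '%s' defined more than once", d))
  for (i in seq_len(nrow(stocks))) {
    if (!is.finite(stocks$initial[i]) || stocks$initial[i] < 0)
      add("error", sprintf("stock '%s'", stocks$name[i]),
          "initial value must be finite and non-negative")
    if (!stocks$units[i] %in% c("persons", "fraction"))
      add("error", sprintf("stock '%s'", stocks$name[i]),
          sprintf("units must be 'persons' or 'fraction', not '%s'", stocks$units[i]))
  }

  pn <- names(spec$parameters)
  if (length(spec$parameters) && (is.null(pn) || any(!nzchar(pn))))
    add("error", "parameters", "every parameter must be named")
  dup <- unique(pn[duplicated(pn)])
  for (d in dup) add("error", "parameters", sprintf("parameter '%s' defined more than once", d))
  for (nm in unique(pn)) {
    p <- spec$parameters[[nm]]
    if (!is.finite(p$value))
      add("error", sprintf("parameter '%s'", nm), "value must be finite")
    if (!is.null(p$trend) && (any(!is.finite(p$trend)) || is.null(names(p$trend))))
      add("error", sprintf("parameter '%s'", nm),
          "trend must be a named (by year) vector of finite multipliers")
  }

  dup <- unique(spec$flows$name[duplicated(spec$flows$name)])
  for (d in dup) add("error", "flows", sprintf("flow '%s' defined more than once", d))
  for (i in seq_len(nrow(spec$flows))) {
    for (side in c("source", "target")) {
      ref <- spec$flows[[side]][i]
      if (!ref %in% c(stocks$name, "external"))
        add("error", sprintf("flow '%s'", spec$flows$name[i]),
            sprintf("%s references unknown stock '%s'", side, ref))
    }
    if (spec$flows$source[i] == "external" && spec$flows$target[i] == "external")
      add("warning", sprintf("flow '%s'", spec$flows$name[i]),
          "connects external to external and moves nothing")
  }

  # symbol resolution, honouring sequential visibility
  base_syms <- c(stocks$name, pn)
  check_syms <- function(expr, where, allowed) {
    if (is_expr_error(expr)) {
      add("error", where, expr$message)
      return(invisible())
    }
    unknown <- setdiff(all.vars(expr), allowed)
    for (u in unknown)
      add("error", where, sprintf("unresolved symbol '%s'", u))
  }
  aux_names <- names(spec$aux)
  for (i in seq_along(spec$aux))
    check_syms(spec$compiled$aux[[i]], sprintf("auxiliary '%s'", aux_names[i]),
               c(base_syms, aux_names[seq_len(i - 1L)]))
  for (i in seq_len(nrow(spec$flows)))
    check_syms(spec$compiled$flows[[i]], sprintf("flow '%s'", spec$flows$name[i]),
               c(base_syms, aux_names))
  out_names <- names(spec$outputs)
  for (i in seq_along(spec$outputs))
    check_syms(spec$compiled$outputs[[i]], sprintf("output '%s'", out_names[i]),
               c(base_syms, aux_names, spec$flows$name, out_names[seq_len(i - 1L)]))

  if (!length(f))
    return(data.frame(severity = character(), location = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, f)
}

# -- evaluation --------------------------------------------------------------

param_values_at <- function(spec, year) {
  ykey <- as.character(year)
  vapply(spec$parameters, function(p) {
    v <- p$value
    if (!is.null(p$trend)) {
      m <- p$trend[ykey]
      if (!is.na(m)) v <- v * as.numeric(m)
    }
    v
  }, numeric(1))
}

eval_checked <- function(expr, env, what, year) {
  tryCatch(eval(expr, envir = env),
           error = function(e)
             stop(sprintf("cannot evaluate %s at year %s: %s",
                          what, year, conditionMessage(e)), call. = FALSE))
}

sf_eval_year <- function(spec, state, year) {
  env <- as.list(c(state, param_values_at(spec, year)))
  aux_names <- names(spec$aux)
  for (i in seq_along(spec$aux))
    env[[aux_names[i]]] <- eval_checked(spec$compiled$aux[[i]], env,
                                        sprintf("auxiliary '%s'", aux_names[i]), year)
  nf <- nrow(spec$flows)
  rates <- numeric(nf)
  names(rates) <- spec$flows$name
  for (i in seq_len(nf)) {
    r <- eval_checked(spec$compiled$flows[[i]], env,
                      sprintf("flow '%s'", spec$flows$name[i]), year)
    if (!is.finite(r))
      stop(sprintf("non-finite rate in flow '%s' at year %s", spec$flows$name[i], year),
           call. = FALSE)
    rates[i] <- r
    env[[spec$flows$name[i]]] <- r
  }
  outs <- numeric(length(spec$outputs))
  names(outs) <- names(spec$outputs)
  for (i in seq_along(spec$outputs)) {
    v <- eval_checked(spec$compiled$outputs[[i]], env,
                      sprintf("output '%s'", names(spec$outputs)[i]), year)
    outs[i] <- v
    env[[names(outs)[i]]] <- v
  }
  list(rates = rates, outputs = outs)
}

apply_flows <- function(spec, state, rates, year) {
  delta <- stats::setNames(numeric(nrow(spec$stocks)), spec$stocks$name)
  for (i in seq_len(nrow(spec$flows))) {
    src <- spec$flows$source[i]
    tgt <- spec$flows$target[i]
    if (src != "external") delta[src] <- delta[src] - rates[i]
    if (tgt != "external") delta[tgt] <- delta[tgt] + rates[i]
  }
  new <- state + delta
  neg <- which(new < 0)
  clamp <- if (length(neg)) {
    data.frame(year = year, stock = names(new)[neg], deficit = -new[neg],
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(year = integer(), stock = character(), deficit = numeric(),
               stringsAsFactors = FALSE)
  }
  new[neg] <- 0
  list(state = new, clamp = clamp)
}

#' Advance a model state by one year
#'
#' Forward-Euler update with a fixed one-year step: all flow rates are
#' evaluated simultaneously from the supplied state, then applied. Stock
#' levels that would go negative are clamped at zero and the deficit is
#' reported, never redistributed.
#'
#' @param state Named numeric vector of stock levels (one per stock in `spec`).
#' @param spec An [sf_spec()].
#' @param year Calendar year the state refers to.
#' @return A list with the next-year `state`, the evaluated `flows` rates,
#'   the `outputs` for the supplied year, and a `clamp` data frame of any
#'   zero-clamping deficits.
#' @export
sf_step <- function(state, spec, year) {
  miss <- setdiff(spec$stocks$name, names(state))
  if (length(miss))
    stop("state is missing stock level(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  state <- state[spec$stocks$name]
  ev <- sf_eval_year(spec, state, year)
  ap <- apply_flows(spec, state, ev$rates, year)
  list(state = ap$state, flows = ev$rates, outputs = ev$outputs, clamp = ap$clamp)
}

#' Simulate a model over a clock
#'
#' Repeated application of [sf_step()] from the clock's start year. The
#' initial state is recorded at the start year; simulation is deterministic,
#' so two calls with equal inputs return identical trajectories.
#'
#' @param spec An [sf_spec()].
#' @param clock An [sf_clock()] (default 2010-2060).
#' @return An `sf_trajectory`: year-indexed matrices of stock levels, flow
#'   rates and derived outputs, plus the zero-clamping log.
#' @export
sf_simulate <- function(spec, clock = sf_clock()) {
  findings <- validate_spec(spec)
  bad <- findings[findings$severity == "error", , drop = FALSE]
  if (nrow(bad))
    stop("cannot simulate an invalid spec:\n",
         paste0("  - [", bad$location, "] ", bad$message, collapse = "\n"),
         call. = FALSE)
  years <- clock_years(clock)
  ny <- length(years)
  state <- stats::setNames(as.numeric(spec$stocks$initial), spec$stocks$name)
  stocks_m <- matrix(NA_real_, ny, nrow(spec$stocks),
                     dimnames = list(years, spec$stocks$name))
  flows_m <- matrix(NA_real_, ny, nrow(spec$flows),
                    dimnames = list(years, spec$flows$name))
  outputs_m <- matrix(NA_real_, ny, length(spec$outputs),
                      dimnames = list(years, names(spec$outputs)))
  clamps <- list()
  for (i in seq_len(ny)) {
    ev <- sf_eval_year(spec, state, years[i])
    stocks_m[i, ] <- state
    flows_m[i, ] <- ev$rates
    outputs_m[i, ] <- ev$outputs
    if (i < ny) {
      ap <- apply_flows(spec, state, ev$rates, years[i])
      if (nrow(ap$clamp)) clamps[[length(clamps) + 1L]] <- ap$clamp
      state <- ap$state
    }
  }
  clamp <- if (length(clamps)) do.call(rbind, clamps) else
    data.frame(year = integer(), stock = character(), deficit = numeric(),
               stringsAsFactors = FALSE)
  structure(list(clock = clock, years = years, stocks = stocks_m,
                 flows = flows_m, outputs = outputs_m,
                 clamp = clamp, clamp_total = sum(clamp$deficit)),
            class = "sf_trajectory")
}

#' Extract one annual series from a trajectory
#'
#' Looks the measure up among derived outputs first, then stocks, then flows.
#'
#' @param traj An `sf_trajectory`.
#' @param measure Series name.
#' @return Named numeric vector (names are calendar years).
#' @export
traj_series <- function(traj, measure) {
  for (slot in c("outputs", "stocks", "flows")) {
    m <- traj[[slot]]
    if (measure %in% colnames(m))
      return(stats::setNames(m[, measure], traj$years))
  }
  stop(sprintf("no measure '%s' in trajectory", measure), call. = FALSE)
}

#' @export
as.data.frame.sf_trajectory <- function(x, row.names = NULL, optional = FALSE,
                                        which = c("outputs", "stocks", "flows"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  out <- list()
  for (slot in which) {
    m <- x[[slot]]
    if (!ncol(m)) next
    out[[slot]] <- data.frame(
      measure = rep(colnames(m), each = nrow(m)),
      year = rep(x$years, times = ncol(m)),
      value = as.vector(m),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' @export
print.sf_spec <- function(x, ...) {
  cat(sprintf("<sf_spec> %d stocks, %d flows, %d parameters, %d aux, %d outputs\n",
              nrow(x$stocks), nrow(x$flows), length(x$parameters),
              length(x$aux), length(x$outputs)))
  invisible(x)
}

#' @export
print.sf_trajectory <- function(x, ...) {
  cat(sprintf("<sf_trajectory> %d-%d (%d years), %d stocks, %d outputs",
              min(x$years), max(x$years), length(x$years),
              ncol(x$stocks), ncol(x$outputs)))
  if (x$clamp_total > 0)
    cat(sprintf(", clamped deficit %.6g", x$clamp_total))
  cat("\n")
  invisible(x)
}
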
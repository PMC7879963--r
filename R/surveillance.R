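# External validation: compare model output series with surveillance
# observations, flag substantial and persistent deviations, and recalibrate
# per-measure multipliers without disturbing any other measure's fit.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Surveillance panel
#'
#' @param df Data frame `(measure, year, value, kind, source)` of observed
#'   annual values; `kind` is `"percent"` (values in \[0, 100\]) or `"count"`
#'   (non-negative); years must be strictly increasing within a measure.
#' @export
surveillance_panel <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  miss <- setdiff(c("measure", "year", "value", "kind", "source"), names(df))
  if (length(miss))
    stop("surveillance panel is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!df$kind %in% c("percent", "count")))
    stop("`kind` must be 'percent' or 'count'", call. = FALSE)
  pc <- df$kind == "percent"
  if (any(df$value[pc] < 0 | df$value[pc] > 100))
    stop("percent values must lie in [0, 100]", call. = FALSE)
  if (any(df$value[!pc] < 0))
    stop("count values must be non-negative", call. = FALSE)
  for (m in unique(df$measure)) {
    y <- df$year[df$measure == m]
    if (any(diff(y) <= 0))
      stop(sprintf("years for measure '%s' must be strictly increasing", m),
           call. = FALSE)
  }
  structure(df, class = c("surveillance_panel", "data.frame"))
}

#' Fit-diagnostic thresholds
#'
#' The two-part deviation rule made explicit and configurable: a measure is
#' "deviating" iff its mean absolute percent error exceeds `mape`, or its
#' model and observed trend slopes disagree in sign with both magnitudes
#' above the noise floor (default: the standard error of the observed slope).
#'
#' @param mape MAPE threshold as a fraction (default 0.10).
#' @param noise_floor Absolute slope noise floor; `NULL` (default) uses the
#'   observed slope's standard error per measure.
#' @export
fit_thresholds <- function(mape = 0.10, noise_floor = NULL) {
  if (!is.finite(mape) || mape < 0) stop("`mape` must be >= 0", call. = FALSE)
  list(mape = mape, noise_floor = noise_floor)
}

#' Compare a model series with surveillance observations
#'
#' Computed on overlapping years only (at least 3 required): mean absolute
#' percent error of the model against the observations, ordinary
#' least-squares trend slopes of both series, and the deterministic
#' aligned/deviating verdict under [fit_thresholds()].
#'
#' @param traj An `sf_trajectory` containing the measure.
#' @param panel A [surveillance_panel()].
#' @param measure Measure name.
#' @param thresholds A [fit_thresholds()] configuration.
#' @return A `fit_diagnostic` list: `mape`, `slope_model`, `slope_obs`,
#'   `slope_diff`, `verdict` and the per-year residuals
#'   (observed − model).
#' @export
compare_series <- function(traj, panel, measure, thresholds = fit_thresholds()) {
  obs <- panel[panel$measure == measure, , drop = FALSE]
  if (!nrow(obs))
    stop(sprintf("no surveillance observations for measure '%s'", measure),
         call. = FALSE)
  model_all <- traj_series(traj, measure)
  keep <- obs$year %in% as.integer(names(model_all))
  obs <- obs[keep, , drop = FALSE]
  if (nrow(obs) < 3L)
    stop(sprintf("insufficient overlapping years for '%s' (need >= 3, have %d)",
                 measure, nrow(obs)), call. = FALSE)
  m <- as.numeric(model_all[as.character(obs$year)])
  o <- obs$value
  if (any(o == 0))
    stop(sprintf("observed value of 0 for '%s'; relative error is undefined", measure),
         call. = FALSE)
  mape <- mean(abs(m - o) / abs(o))
  fit_o <- stats::lm(o ~ obs$year)
  fit_m <- stats::lm(m ~ obs$year)
  slope_obs <- unname(stats::coef(fit_o)[2L])
  slope_model <- unname(stats::coef(fit_m)[2L])
  # slope standard error computed directly (avoids summary.lm noise on
  # degenerate, perfectly linear series)
  sxx <- sum((obs$year - mean(obs$year))^2)
  se_obs <- sqrt(sum(stats::residuals(fit_o)^2) / (nrow(obs) - 2L) / sxx)
  floor <- thresholds$noise_floor %||% se_obs
  sign_conflict <- sign(slope_model) != sign(slope_obs) &&
    abs(slope_model) > floor && abs(slope_obs) > floor
  verdict <- if (mape > thresholds$mape || sign_conflict) "deviating" else "aligned"
  structure(list(measure = measure, years = obs$year, n = nrow(obs),
                 mape = mape, slope_model = slope_model, slope_obs = slope_obs,
                 slope_diff = slope_model - slope_obs, slope_se_obs = se_obs,
                 verdict = verdict, thresholds = thresholds,
                 residuals = data.frame(year = obs$year, model = m, observed = o,
                                        residual = o - m)),
            class = "fit_diagnostic")
}

#' Compare every measure in a panel
#'
#' @inheritParams compare_series
#' @return A named list of `fit_diagnostic`s (class `fit_diagnostics`), one
#'   per measure appearing in the panel.
#' @export
compare_panel <- function(traj, panel, thresholds = fit_thresholds()) {
  measures <- unique(panel$measure)
  diags <- lapply(measures, function(m) compare_series(traj, panel, m, thresholds))
  names(diags) <- measures
  structure(diags, class = "fit_diagnostics")
}

#' @export
summary.fit_diagnostics <- function(object, ...) {
  do.call(rbind, lapply(object, function(d)
    data.frame(measure = d$measure, n = d$n, mape = d$mape,
               slope_model = d$slope_model, slope_obs = d$slope_obs,
               verdict = d$verdict, stringsAsFactors = FALSE))) -> out
  rownames(out) <- NULL
  out
}

max_sign_run <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (!length(s)) return(0L)
  r <- rle(s)
  max(r$lengths)
}

#' Select measures for recalibration, guarding against over-calibration
#'
#' Only measures whose verdict is "deviating" *and* whose residual keeps a
#' constant sign over at least `persistence_years` consecutive observations
#' are selected; transient oscillation around the model is deliberately
#' excluded so noise is never calibrated away.
#'
#' @param diagnostics A `fit_diagnostics` list from [compare_panel()].
#' @param persistence_years Minimum run of same-sign residuals (consecutive
#'   observations; default 3).
#' @return Character vector of measures to recalibrate, in panel order.
#' @export
recalibration_review <- function(diagnostics, persistence_years = 3) {
  keep <- vapply(diagnostics, function(d) {
    d$verdict == "deviating" &&
      max_sign_run(d$residuals$residual) >= persistence_years
  }, logical(1))
  names(diagnostics)[keep]
}

#' Recalibrate one measure's multiplier against surveillance data
#'
#' Every toy-nation measure is, by construction, linear in its calibration
#' multiplier (a `mult_<measure>` parameter entering only that measure's
#' output expression). The multiplier is fitted by least squares on the
#' relative error to the observations — so count and percent measures are
#' treated uniformly — either as a constant or log-linear in year
#' (`mode = "linear-trend"`). The model is re-run with the fitted multiplier
#' and the post-fit diagnostic plus a cross-effect report over all other
#' panel measures are returned; if the post-fit verdict is not "aligned" the
#' result is flagged but the multipliers are still reported.
#'
#' @param nation A toy nation from [make_toy_nation()].
#' @param measure Measure to recalibrate.
#' @param panel A [surveillance_panel()].
#' @param mode `"constant"` or `"linear-trend"`.
#' @param thresholds A [fit_thresholds()] configuration.
#' @return A `recalibration_result`: the updated nation, the fitted
#'   per-year `multiplier_path`, the post-fit `diagnostic`, the
#'   `cross_effects` table and a `flagged` indicator.
#' @export
recalibrate_measure <- function(nation, measure, panel,
                                mode = c("constant", "linear-trend"),
                                thresholds = fit_thresholds()) {
  mode <- match.arg(mode)
  mult_param <- paste0("mult_", measure)
  if (!mult_param %in% names(nation$spec$parameters))
    stop(sprintf("measure '%s' has no calibration multiplier parameter '%s'",
                 measure, mult_param), call. = FALSE)
  clock <- nation$clock
  all_years <- clock_years(clock)
  pre_traj <- sf_simulate(nation$spec, clock)
  obs <- panel[panel$measure == measure, , drop = FALSE]
  obs <- obs[obs$year %in% all_years, , drop = FALSE]
  if (nrow(obs) < 3L)
    stop(sprintf("insufficient overlapping years to recalibrate '%s'", measure),
         call. = FALSE)
  cur <- nation$spec$parameters[[mult_param]]
  cur_path <- vapply(obs$year, function(y) {
    v <- cur$value
    if (!is.null(cur$trend)) {
      mlt <- cur$trend[as.character(y)]
      if (!is.na(mlt)) v <- v * as.numeric(mlt)
    }
    v
  }, numeric(1))
  raw <- as.numeric(traj_series(pre_traj, measure)[as.character(obs$year)]) / cur_path
  o <- obs$value
  if (any(raw <= 0) || any(o <= 0))
    stop(sprintf("recalibration of '%s' requires strictly positive model and observed values",
                 measure), call. = FALSE)
  if (mode == "constant") {
    r <- raw / o
    m_hat <- sum(r) / sum(r^2)  # argmin_m sum((m * raw / o - 1)^2)
    nation$spec$parameters[[mult_param]] <- list(value = m_hat, trend = NULL)
    path <- rep(m_hat, length(all_years))
  } else {
    t0 <- obs$year - clock$start_year
    fit <- stats::lm(log(o / raw) ~ t0)
    ab <- stats::coef(fit)
    path <- exp(ab[1L] + ab[2L] * (all_years - clock$start_year))
    nation$spec$parameters[[mult_param]] <-
      list(value = 1, trend = stats::setNames(path, all_years))
  }
  if (any(path <= 0))
    stop("fitted multipliers must be strictly positive", call. = FALSE)
  post_traj <- sf_simulate(nation$spec, clock)
  diagnostic <- compare_series(post_traj, panel, measure, thresholds)
  others <- setdiff(unique(panel$measure), measure)
  cross <- do.call(rbind, lapply(others, function(om) {
    before <- compare_series(pre_traj, panel, om, thresholds)
    after <- compare_series(post_traj, panel, om, thresholds)
    data.frame(measure = om, verdict_before = before$verdict,
               verdict_after = after$verdict,
               series_identical = identical(traj_series(pre_traj, om),
                                            traj_series(post_traj, om)),
               stringsAsFactors = FALSE)
  }))
  rownames(cross) <- NULL
  structure(list(nation = nation, measure = measure, mode = mode,
                 multiplier_path = data.frame(year = all_years, multiplier = unname(path)),
                 diagnostic = diagnostic, cross_effects = cross,
                 flagged = diagnostic$verdict != "aligned"),
            class = "recalibration_result")
}

#' Full external-validation and recalibration cycle over a panel
#'
#' Runs the base model, diagnoses every panel measure, selects persistent
#' deviators via [recalibration_review()], and recalibrates each in turn —
#' constant mode first, escalating to a log-linear trend multiplier when the
#' constant fit cannot reach an "aligned" verdict.
#'
#' @inheritParams recalibrate_measure
#' @param measures Measures to recalibrate; `NULL` (default) lets the review
#'   policy decide.
#' @param persistence_years Passed to [recalibration_review()].
#' @return List with the updated `nation`, the `selected` measures, the
#'   per-measure `results`, and panel-wide diagnostics before and after.
#' @export
recalibrate_panel <- function(nation, panel, measures = NULL,
                              thresholds = fit_thresholds(),
                              persistence_years = 3) {
  traj <- sf_simulate(nation$spec, nation$clock)
  before <- compare_panel(traj, panel, thresholds)
  if (is.null(measures)) measures <- recalibration_review(before, persistence_years)
  results <- list()
  for (m in measures) {
    res <- recalibrate_measure(nation, m, panel, "constant", thresholds)
    if (res$flagged)
      res <- recalibrate_measure(nation, m, panel, "linear-trend", thresholds)
    nation <- res$nation
    results[[m]] <- res
  }
  after <- compare_panel(sf_simulate(nation$spec, nation$clock), panel, thresholds)
  list(nation = nation, selected = measures, results = results,
       diagnostics_before = before, diagnostics_after = after)
}
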
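# Epidemiological layer: risk-factor prevalences with relative risks, the
# non-CVD / post-CVD subpopulation split, and attributable-fraction outcome
# attribution.

#' Risk-factor prevalence and relative-risk tables
#'
#' @param prevalence Data frame `(factor, year, prevalence)` with prevalences
#'   in \[0, 1\].
#' @param rr Data frame `(factor, outcome, rr)` of relative risks (finite,
#'   non-negative) linking each factor to a named outcome.
#' @param reference Optional data frame `(factor, reference)` of reference
#'   prevalences for population-average normalization; defaults to each
#'   factor's earliest-year prevalence.
#' @param groups Optional named list of character vectors naming mutually
#'   exclusive categories of one factor (e.g. current/former smoker); their
#'   prevalences must sum to at most 1 in every year.
#' @return An object of class `risk_factor_table`.
#' @export
risk_factor_table <- function(prevalence, rr, reference = NULL, groups = NULL) {
  prevalence <- as.data.frame(prevalence, stringsAsFactors = FALSE)
  rr <- as.data.frame(rr, stringsAsFactors = FALSE)
  miss <- setdiff(c("factor", "year", "prevalence"), names(prevalence))
  if (length(miss))
    stop("`prevalence` is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(c("factor", "outcome", "rr"), names(rr))
  if (length(miss))
    stop("`rr` is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(prevalence$prevalence)) ||
      any(prevalence$prevalence < 0 | prevalence$prevalence > 1))
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(rr$rr)) || any(rr$rr < 0))
    stop("relative risks must be finite and non-negative", call. = FALSE)
  if (is.null(reference)) {
    reference <- do.call(rbind, lapply(split(prevalence, prevalence$factor), function(d) {
      d <- d[order(d$year), ]
      data.frame(factor = d$factor[1], reference = d$prevalence[1],
                 stringsAsFactors = FALSE)
    }))
    rownames(reference) <- NULL
  }
  if (!is.null(groups)) {
    for (g in names(groups)) {
      sub <- prevalence[prevalence$factor %in% groups[[g]], ]
      sums <- tapply(sub$prevalence, sub$year, sum)
      if (any(sums > 1 + 1e-9))
        stop(sprintf("mutually exclusive categories of '%s' sum to more than 1", g),
             call. = FALSE)
    }
  }
  structure(list(prevalence = prevalence, rr = rr, reference = reference,
                 groups = groups),
            class = "risk_factor_table")
}

prevalence_at <- function(factors, factor, year) {
  hit <- factors$prevalence$factor == factor & factors$prevalence$year == year
  if (!any(hit))
    stop(sprintf("no prevalence for factor '%s' in year %s", factor, year),
         call. = FALSE)
  factors$prevalence$prevalence[which(hit)[1L]]
}

reference_of <- function(factors, factor) {
  hit <- factors$reference$factor == factor
  if (!any(hit))
    stop(sprintf("no reference prevalence for factor '%s'", factor), call. = FALSE)
  factors$reference$reference[which(hit)[1L]]
}

#' Population-average event rate under risk-factor exposure
#'
#' Aggregates relative risks multiplicatively with normalization to the
#' reference prevalences, so that with every prevalence at its reference
#' value the rate equals `base_rate` exactly:
#' `rate = base_rate * prod_i (1 + p_i (RR_i - 1)) / (1 + pref_i (RR_i - 1))`.
#' The rate is monotone non-decreasing in each prevalence when its RR >= 1.
#'
#' @param base_rate Events/person/year at reference exposure (>= 0).
#' @param factors A [risk_factor_table()].
#' @param year Calendar year at which prevalences are looked up.
#' @param outcome Outcome name selecting the RR column (default `"cvd_event"`).
#' @return Events/person/year.
#' @export
event_rate <- function(base_rate, factors, year, outcome = "cvd_event") {
  if (!is.finite(base_rate) || base_rate < 0)
    stop("`base_rate` must be finite and non-negative", call. = FALSE)
  rrt <- factors$rr[factors$rr$outcome == outcome, , drop = FALSE]
  mult <- 1
  for (i in seq_len(nrow(rrt))) {
    rr <- rrt$rr[i]
    if (rr < 0) stop("relative risks must be non-negative", call. = FALSE)
    p <- prevalence_at(factors, rrt$factor[i], year)
    pref <- reference_of(factors, rrt$factor[i])
    mult <- mult * (1 + p * (rr - 1)) / (1 + pref * (rr - 1))
  }
  base_rate * mult
}

#' Population attributable fraction (Levin)
#'
#' Share of an outcome attributable to a harmful exposure with prevalence `p`
#' and relative risk `rr`: `p (rr - 1) / (1 + p (rr - 1))`. Vectorized over
#' both arguments.
#'
#' @param p Exposure prevalence in \[0, 1\].
#' @param rr Relative risk, must be >= 1 (protective exposures are not
#'   attributable and are rejected).
#' @return Fraction in \[0, 1).
#' @examples
#' attributable_fraction(0.2, 3)  # 0.4 / 1.4
#' @export
attributable_fraction <- function(p, rr) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("`p` must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(rr)) || any(rr < 1))
    stop("protective exposures are not attributable (`rr` must be >= 1)",
         call. = FALSE)
  p * (rr - 1) / (1 + p * (rr - 1))
}

#' Attribution specification for one outcome
#'
#' Couples an outcome (e.g. smoking-related non-CVD deaths) to an exposure
#' factor, its mortality/morbidity relative risk, and the baseline annual
#' total of the outcome from which the attributable share is taken.
#'
#' @param outcome Outcome name.
#' @param factor Exposure factor name (must exist in the risk-factor table at
#'   evaluation time).
#' @param rr Relative risk, >= 1.
#' @param baseline Baseline annual total of the outcome (>= 0).
#' @export
attribution_spec <- function(outcome, factor, rr, baseline) {
  if (!is.finite(rr) || rr < 1)
    stop("protective exposures are not attributable (`rr` must be >= 1)",
         call. = FALSE)
  if (!is.finite(baseline) || baseline < 0)
    stop("`baseline` must be finite and non-negative", call. = FALSE)
  structure(list(outcome = outcome, factor = factor, rr = rr,
                 baseline = baseline),
            class = "attribution_spec")
}

#' Attributed annual outcome count
#'
#' `baseline * attributable_fraction(p_year, rr) * multiplier`, where
#' `multiplier` is the measure's calibration multiplier (see
#' [recalibrate_measure()]). Zero whenever the exposure prevalence is zero.
#'
#' @param spec An [attribution_spec()].
#' @param factors A [risk_factor_table()].
#' @param year Calendar year.
#' @param multiplier Calibration multiplier (> 0, default 1).
#' @return Outcome count per year.
#' @export
attributed_outcomes <- function(spec, factors, year, multiplier = 1) {
  if (!inherits(spec, "attribution_spec"))
    stop("`spec` must be an attribution_spec", call. = FALSE)
  p <- prevalence_at(factors, spec$factor, year)
  spec$baseline * attributable_fraction(p, spec$rr) * multiplier
}

#' Subpopulation state
#'
#' Persons with no prior CVD event (`non_cvd`), persons with at least one
#' prior event (`post_cvd`), and the deaths recorded over the preceding year
#' by cause class.
#'
#' @param non_cvd,post_cvd Stock levels (persons, >= 0).
#' @param deaths_cvd,deaths_non_cvd Deaths/year by cause class (>= 0).
#' @export
subpop_state <- function(non_cvd, post_cvd, deaths_cvd = 0, deaths_non_cvd = 0) {
  v <- c(non_cvd, post_cvd, deaths_cvd, deaths_non_cvd)
  if (any(!is.finite(v)) || any(v < 0))
    stop("all subpopulation components must be finite and non-negative",
         call. = FALSE)
  structure(list(non_cvd = non_cvd, post_cvd = post_cvd,
                 deaths_cvd = deaths_cvd, deaths_non_cvd = deaths_non_cvd),
            class = "subpop_state")
}

#' Advance the two-subpopulation state by one year
#'
#' Non-CVD persons experience first CVD events at the population-average
#' [event_rate()]; a case-fatality fraction die and the survivors move to the
#' post-CVD subpopulation. Post-CVD persons face a recurrent fatal-event rate
#' at least as high as the non-CVD rate (`post_rate_ratio >= 1`). Background
#' non-CVD deaths are removed from both subpopulations at per-subpopulation
#' annual rates, any explicitly attributed non-CVD deaths are removed in
#' proportion to subpopulation size, and the net aging/migration inflow is
#' added to the non-CVD stock. Transfers between the subpopulations occur
#' only via first CVD events; deaths leave the system.
#'
#' @param state A [subpop_state()].
#' @param factors A [risk_factor_table()].
#' @param params List with `base_event_rate`, `case_fatality`,
#'   `post_rate_ratio` (>= 1), `bg_mort_non`, `bg_mort_post`, `inflow`.
#' @param year Calendar year.
#' @param attributions Optional list of [attribution_spec()]s whose attributed
#'   deaths are removed as additional outflows.
#' @param multipliers Optional named vector of calibration multipliers keyed
#'   by attribution outcome.
#' @return The next-year [subpop_state()]; any zero-clamped deficit is
#'   attached as attribute `"clamp"`.
#' @export
advance_population <- function(state, factors, params, year,
                               attributions = list(), multipliers = NULL) {
  if (!inherits(state, "subpop_state"))
    stop("`state` must be a subpop_state", call. = FALSE)
  if (params$post_rate_ratio < 1)
    stop("`post_rate_ratio` must be >= 1 (post-CVD rates cannot fall below non-CVD rates)",
         call. = FALSE)
  r <- event_rate(params$base_event_rate, factors, year)
  cf <- params$case_fatality
  events_first <- state$non_cvd * r
  deaths_first <- events_first * cf
  to_post <- events_first - deaths_first
  deaths_post <- state$post_cvd * r * params$post_rate_ratio * cf
  bg_non <- state$non_cvd * params$bg_mort_non
  bg_post <- state$post_cvd * params$bg_mort_post
  attr_total <- 0
  for (a in attributions) {
    m <- if (!is.null(multipliers) && a$outcome %in% names(multipliers))
      multipliers[[a$outcome]] else 1
    attr_total <- attr_total + attributed_outcomes(a, factors, year, m)
  }
  pop <- state$non_cvd + state$post_cvd
  share_non <- if (pop > 0) state$non_cvd / pop else 0
  new_non <- state$non_cvd - events_first - bg_non - attr_total * share_non +
    params$inflow
  new_post <- state$post_cvd + to_post - deaths_post - bg_post -
    attr_total * (1 - share_non)
  clamp <- 0
  if (new_non < 0) { clamp <- clamp - new_non; new_non <- 0 }
  if (new_post < 0) { clamp <- clamp - new_post; new_post <- 0 }
  out <- subpop_state(new_non, new_post,
                      deaths_cvd = deaths_first + deaths_post,
                      deaths_non_cvd = bg_non + bg_post + attr_total)
  attr(out, "clamp") <- clamp
  out
}
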
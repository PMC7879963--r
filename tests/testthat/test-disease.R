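two_factor_table <- function(p_smoke = 0.3, p_dm = 0.1,
                             rr_smoke = 2, rr_dm = 1.8,
                             ref_smoke = p_smoke, ref_dm = p_dm,
                             years = 2010) {
  risk_factor_table(
    prevalence = expand.grid(factor = c("smoking", "diabetes"), year = years,
                             stringsAsFactors = FALSE) |>
      transform(prevalence = ifelse(factor == "smoking", p_smoke, p_dm)),
    rr = data.frame(factor = c("smoking", "diabetes"), outcome = "cvd_event",
                    rr = c(rr_smoke, rr_dm)),
    reference = data.frame(factor = c("smoking", "diabetes"),
                           reference = c(ref_smoke, ref_dm)))
}

test_that("event_rate is the identity when all relative risks are 1", {
  ft <- two_factor_table(rr_smoke = 1, rr_dm = 1, ref_smoke = 0, ref_dm = 0.9)
  expect_equal(event_rate(0.02, ft, 2010), 0.02)
})

test_that("event_rate reaches RR * base in the fully exposed limit", {
  ft <- two_factor_table(p_smoke = 1, rr_smoke = 2, ref_smoke = 0,
                         p_dm = 0, rr_dm = 1.8, ref_dm = 0)
  expect_equal(event_rate(0.01, ft, 2010), 0.02)
})

test_that("event_rate normalization returns base at reference prevalence", {
  ft <- two_factor_table(p_smoke = 0.5, rr_smoke = 3, ref_smoke = 0.5,
                         p_dm = 0.1, rr_dm = 1.8, ref_dm = 0.1)
  expect_equal(event_rate(0.015, ft, 2010), 0.015)
})

test_that("event_rate is monotone non-decreasing in prevalence for RR >= 1", {
  rates <- vapply(seq(0, 1, by = 0.05), function(p)
    event_rate(0.01, two_factor_table(p_smoke = p, ref_smoke = 0.2), 2010),
    numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("attributable_fraction matches its closed form and rejects rr < 1", {
  expect_identical(attributable_fraction(0, 5), 0)
  expect_equal(attributable_fraction(1, 2), 0.5)
  expect_equal(attributable_fraction(0.2, 3), 0.4 / 1.4)
  expect_error(attributable_fraction(0.2, 0.8), "not attributable")
  expect_error(attributable_fraction(1.2, 2), "\\[0, 1\\]")
})

test_that("attributable_fraction equals the two-group mixing oracle on a grid", {
  for (p in seq(0, 1, by = 0.1)) {
    for (rr in c(1, 1.5, 2, 3, 5)) {
      expect_equal(attributable_fraction(p, rr), af_mixing_oracle(p, rr),
                   tolerance = 1e-12,
                   label = sprintf("PAF(p=%.1f, rr=%.1f)", p, rr))
    }
  }
})

test_that("attributed outcomes scale with baseline, PAF and multiplier", {
  ft <- two_factor_table(p_smoke = 0.2, rr_smoke = 3)
  spec <- attribution_spec("smoking_noncvd_deaths", "smoking", rr = 3,
                           baseline = 1000)
  x <- attributed_outcomes(spec, ft, 2010)
  expect_equal(x, 1000 * 0.4 / 1.4)  # ~285.7/yr
  expect_equal(attributed_outcomes(spec, ft, 2010, multiplier = 2), 2 * x)

  zero <- two_factor_table(p_smoke = 0)
  expect_identical(attributed_outcomes(spec, zero, 2010), 0)

  orphan <- attribution_spec("x", "vaping", rr = 2, baseline = 10)
  expect_error(attributed_outcomes(orphan, ft, 2010), "vaping")
})

test_that("advance_population matches hand arithmetic for one year", {
  # 1,000 non-CVD, event rate 0.10, case fatality 0.3:
  # 100 events, 30 CVD deaths, 70 enter post-CVD
  ft <- two_factor_table(rr_smoke = 1, rr_dm = 1)
  params <- list(base_event_rate = 0.10, case_fatality = 0.3,
                 post_rate_ratio = 1, bg_mort_non = 0, bg_mort_post = 0,
                 inflow = 0)
  st <- advance_population(subpop_state(1000, 0), ft, params, 2010)
  expect_equal(st$non_cvd, 900)
  expect_equal(st$post_cvd, 70)
  expect_equal(st$deaths_cvd, 30)
  expect_equal(st$deaths_non_cvd, 0)
})

test_that("zero rates and zero inflow leave the population unchanged", {
  ft <- two_factor_table()
  params <- list(base_event_rate = 0, case_fatality = 0.3, post_rate_ratio = 2,
                 bg_mort_non = 0, bg_mort_post = 0, inflow = 0)
  st <- advance_population(subpop_state(800, 200), ft, params, 2010)
  expect_equal(st$non_cvd, 800)
  expect_equal(st$post_cvd, 200)
})

test_that("persons are conserved: net change equals inflow minus deaths", {
  ft <- two_factor_table(years = 2010:2030)
  params <- list(base_event_rate = 0.02, case_fatality = 0.3,
                 post_rate_ratio = 3, bg_mort_non = 0.008,
                 bg_mort_post = 0.02, inflow = 500)
  attrs <- list(attribution_spec("smoking_deaths", "smoking", 2.2, 400))
  st <- subpop_state(9e5, 1e5)
  for (y in 2010:2030) {
    nxt <- advance_population(st, ft, params, y, attributions = attrs)
    delta <- (nxt$non_cvd + nxt$post_cvd) - (st$non_cvd + st$post_cvd)
    expect_equal(delta, params$inflow - nxt$deaths_cvd - nxt$deaths_non_cvd,
                 tolerance = 1e-9)
    st <- nxt
  }
})

test_that("a higher post-CVD death rate never decreases CVD deaths", {
  ft <- two_factor_table()
  base <- list(base_event_rate = 0.02, case_fatality = 0.3, post_rate_ratio = 2,
               bg_mort_non = 0.005, bg_mort_post = 0.015, inflow = 100)
  harsher <- utils::modifyList(base, list(post_rate_ratio = 4))
  s1 <- advance_population(subpop_state(800, 200), ft, base, 2010)
  s2 <- advance_population(subpop_state(800, 200), ft, harsher, 2010)
  expect_gte(s2$deaths_cvd, s1$deaths_cvd)
  expect_error(advance_population(subpop_state(1, 1), ft,
                                  utils::modifyList(base, list(post_rate_ratio = 0.5)),
                                  2010),
               ">= 1")
})

test_that("risk-factor table invariants are enforced", {
  expect_error(
    risk_factor_table(data.frame(factor = "a", year = 2010, prevalence = 1.2),
                      data.frame(factor = "a", outcome = "o", rr = 2)),
    "\\[0, 1\\]")
  expect_error(
    risk_factor_table(data.frame(factor = "a", year = 2010, prevalence = 0.5),
                      data.frame(factor = "a", outcome = "o", rr = -1)),
    "non-negative")
  expect_error(
    risk_factor_table(
      data.frame(factor = c("cur", "fmr"), year = 2010, prevalence = c(0.6, 0.5)),
      data.frame(factor = "cur", outcome = "o", rr = 2),
      groups = list(smoking = c("cur", "fmr"))),
    "more than 1")
})
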
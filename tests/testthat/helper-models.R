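# Small model builders and independent oracles shared across tests.

# one stock with constant external inflow b and proportional outflow m * level
one_stock_spec <- function(x0 = 100, b = 5, m = 0.1) {
  sf_spec(
    stocks = data.frame(name = "x", initial = x0, units = "persons"),
    flows = data.frame(
      name = c("in_", "out_"),
      source = c("external", "x"),
      target = c("x", "external"),
      rate = c("b", "m * x")),
    parameters = list(b = b, m = m))
}

# closed two-stock system: transfers only, no external flows
closed_two_stock_spec <- function(a0 = 600, b0 = 400, r_ab = 0.3, r_ba = 0.12) {
  sf_spec(
    stocks = data.frame(name = c("a", "b"), initial = c(a0, b0),
                        units = "persons"),
    flows = data.frame(
      name = c("a_to_b", "b_to_a"),
      source = c("a", "b"),
      target = c("b", "a"),
      rate = c("r_ab * a", "r_ba * b")),
    parameters = list(r_ab = r_ab, r_ba = r_ba))
}

# closed-form solution of x_{t+1} = x_t (1 - m) + b
linear_recurrence <- function(x0, b, m, t) {
  (x0 - b / m) * (1 - m)^t + b / m
}

# brute-force two-group mixing oracle for the attributable fraction:
# expected excess cases among the exposed over the total expected cases
af_mixing_oracle <- function(p, rr, base_rate = 0.01, n = 1e6) {
  exposed <- n * p
  unexposed <- n * (1 - p)
  total_cases <- exposed * base_rate * rr + unexposed * base_rate
  excess_cases <- exposed * base_rate * rr - exposed * base_rate
  excess_cases / total_cases
}

# naive re-implementation of the one-way sweep: plain loop, no shared
# structure with one_way() beyond the runner contract
naive_one_way <- function(runner, bounds, outcome = "outcome") {
  base <- runner(list())
  out <- NULL
  for (i in seq_len(nrow(bounds))) {
    p <- bounds$parameter[i]
    lo <- runner(stats::setNames(list(bounds$low[i]), p))
    hi <- runner(stats::setNames(list(bounds$high[i]), p))
    row <- data.frame(parameter = p, outcome = outcome, base = base,
                      value_low = lo, value_high = hi,
                      change_low = (lo - base) / base,
                      change_high = (hi - base) / base,
                      influence = max(abs((lo - base) / base),
                                      abs((hi - base) / base)),
                      failed = FALSE, stringsAsFactors = FALSE)
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  out
}

# five-parameter nonlinear test model for the sensitivity harness
five_param_runner <- function() {
  defaults <- list(a = 2, b = 3, c = 1.5, d = 4, e = 0.5)
  function(overrides = list()) {
    v <- utils::modifyList(defaults, overrides)
    2 * v$a + v$b^2 - 3 * v$c + v$d * v$e
  }
}

five_param_bounds <- function() {
  parameter_bounds(data.frame(
    parameter = c("a", "b", "c", "d", "e"),
    default = c(2, 3, 1.5, 4, 0.5),
    low = c(1, 2.4, 1.2, 3.2, 0.25),
    high = c(3, 3.6, 1.95, 4.8, 1)))
}

toy_nation_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_nation()
    cache
  }
})
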
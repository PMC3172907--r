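test_that("cumulative rate sums width times rate over closed bands", {
  hz <- hazard_table(c(0, 5), c(5, Inf), lambda_C = c(0, 0), lambda_X = c(0, 0))
  expect_equal(cumulative_rate(hz, 5)$value, 0)

  hz1 <- hazard_table(c(0, 5), c(5, Inf), lambda_C = c(0.002, 0),
                      lambda_X = c(0, 0))
  expect_equal(cumulative_rate(hz1, 5)$value, 0.01)

  # brute-force summation oracle on a random 18-band table
  tab <- demo_counts(seed = 21)
  hz18 <- hazards_from_counts(tab)
  hand <- 0
  for (i in 1:17) hand <- hand + (hz18$age_end[i] - hz18$age_start[i]) * hz18$lambda_C[i]
  expect_equal(cumulative_rate(tab, 85)$value, hand, tolerance = 1e-12)
})

test_that("truncation ages must be band boundaries outside the open band", {
  tab <- demo_counts(seed = 22)
  expect_error(cumulative_rate(tab, 72), "nearest.*70 and 75")
  expect_error(cumulative_rate(tab, Inf), "finite upper age")
  expect_error(cumulative_rate(tab, 100), "not a band boundary|open")
})

test_that("cumulative risk is 1 - exp(-rate) and reproduces the published conversions", {
  expect_equal(cumulative_risk(0), 0)
  # all-malignant-neoplasm rates to age 84: 70% (males), 51% (females)
  expect_equal(round_half_away(100 * cumulative_risk(0.70), 1), 50.3)
  expect_equal(round_half_away(100 * cumulative_risk(0.51), 1), 40.0)
  expect_equal(cumulative_risk(0.51), 0.39953, tolerance = 1e-4)
  expect_error(cumulative_risk(-0.1), "non-negative")
})

test_that("the '1 in (x + 1/2)' rule relates rate and risk reciprocals", {
  expect_identical(one_in_x(0.5)$string, "1 in 2.0")
  # a rate of 1 in 10 is a risk of about 1 in 10.5
  gap <- 1 / cumulative_risk(1 / 10) - 10
  expect_equal(gap, 0.508, tolerance = 1e-3)
  # the half-step approximation sharpens as x grows
  err <- sapply(c(3, 5, 10, 50), function(x)
    abs(1 / (1 - exp(-1 / x)) - (x + 0.5)))
  expect_true(all(diff(err) < 0))
  expect_error(one_in_x(0), "positive")
  expect_error(one_in_x(-2), "positive")
})

test_that("current probability reduces to known limits", {
  # no registrations -> 0
  hz0 <- hazard_table(c(0, 5), c(5, Inf), lambda_C = c(0, 0),
                      lambda_X = c(0.01, 0.01), lambda_M = c(0.01, 0.01))
  expect_equal(current_probability(hz0)$value, 0)
  # no mortality, truncated: no attrition, so it equals the cumulative rate
  hzn <- hazard_table(c(0, 5, 10), c(5, 10, Inf),
                      lambda_C = c(0.002, 0.004, 0), lambda_X = c(0, 0, 0),
                      lambda_M = c(0, 0, 0))
  expect_equal(current_probability(hzn, 10)$value,
               cumulative_rate(hzn, 10)$value)
  # constant hazards, cancer never fatal: mean diagnoses per lifetime = c/m
  hzc <- hazard_table(0, Inf, lambda_C = 0.002, lambda_X = 0.01,
                      lambda_M = 0.01)
  expect_equal(current_probability(hzc)$value, 0.2, tolerance = 1e-12)
  # mean-count semantics: warns (not errors) above 1
  hzw <- hazard_table(0, Inf, lambda_C = 0.03, lambda_X = 0.01,
                      lambda_M = 0.01)
  expect_warning(est <- current_probability(hzw), "mean count")
  expect_equal(est$value, 3)
  # non-integrable open tail
  hzt <- hazard_table(0, Inf, lambda_C = 0.01, lambda_X = 0, lambda_M = 0)
  expect_error(current_probability(hzt), "non-integrable")
})

test_that("AMP reduces to closed forms and stays in [0, 1]", {
  hz0 <- hazard_table(0, Inf, lambda_C = 0, lambda_X = 0.02)
  expect_equal(amp_estimate(hz0)$value, 0)
  # registration as the only exit: everyone is eventually registered
  hz1 <- hazard_table(0, Inf, lambda_C = 0.004, lambda_X = 0)
  expect_equal(amp_estimate(hz1)$value, 1, tolerance = 1e-12)
  # competing exponentials
  hz2 <- hazard_table(0, Inf, lambda_C = 0.004, lambda_X = 0.008)
  expect_equal(amp_estimate(hz2)$value, 1 / 3, tolerance = 1e-12)
  # random tables stay within [0, 1]
  for (s in 1:20) {
    v <- amp_estimate(random_hazard_table(s))$value
    expect_true(v >= 0 && v <= 1)
  }
})

test_that("AMP agrees with the fine-grid integral and is refinement-invariant", {
  for (s in 1:10) {
    hz <- random_hazard_table(100 + s)
    a <- amp_estimate(hz)$value
    expect_equal(a, fine_grid_oracle(hz, step = 1 / 256), tolerance = 1e-10)
    # split every closed band in half: exact-within-band formula is unchanged
    n <- nrow(hz)
    mids <- (hz$age_start[-n] + hz$age_end[-n]) / 2
    split_hz <- hazard_table(
      sort(c(hz$age_start, mids)),
      sort(c(hz$age_end[-n], mids, Inf)),
      lambda_C = rep(hz$lambda_C, c(rep(2, n - 1), 1)),
      lambda_X = rep(hz$lambda_X, c(rep(2, n - 1), 1)),
      lambda_M = rep(hz$lambda_M, c(rep(2, n - 1), 1)))
    expect_equal(amp_estimate(split_hz)$value, a, tolerance = 1e-12)
  }
})

test_that("the trapezoid within-band rule is close to, but distinct from, the exact rule", {
  hz <- hazards_from_counts(demo_counts(seed = 23))
  exact <- amp_estimate(hz, 85)$value
  trap <- amp_estimate(hz, 85, rule = "trapezoid")$value
  expect_false(identical(exact, trap))
  expect_equal(trap, exact, tolerance = 0.05)
})

test_that("the proxy survival curve starts at 1, is non-increasing, and telescopes the log", {
  hz0 <- hazard_table(c(0, 1), c(1, Inf), lambda_C = c(0, 0),
                      lambda_X = c(0, 0))
  expect_equal(amp_proxy_survival(hz0)$survival, c(1, 1))
  hz1 <- hazard_table(c(0, 1), c(1, Inf), lambda_C = c(0.04, 0),
                      lambda_X = c(0.06, 0))
  expect_equal(amp_proxy_survival(hz1)$survival[2], exp(-0.1))
  tab <- demo_counts(seed = 24)
  hz <- hazards_from_counts(tab)
  s <- amp_proxy_survival(hz)
  expect_equal(s$survival[1], 1)
  expect_true(all(diff(s$survival) <= 0))
  w <- hz$age_end[1:17] - hz$age_start[1:17]
  expect_equal(log(s$survival[18]),
               -sum((hz$lambda_C + hz$lambda_X)[1:17] * w), tolerance = 1e-10)
})

test_that("gold standard is the current probability algorithm gated on first-primaries data", {
  tab_first <- demo_counts(seed = 25, registration_mode = "first-primaries-only")
  tab_all <- demo_counts(seed = 25)
  gs <- gold_standard(tab_first)
  expect_equal(gs$value, current_probability(tab_first)$value)
  expect_identical(gs$method, "gold_standard")
  expect_error(gold_standard(tab_all), "first-primaries-only")
})

test_that("estimates are non-decreasing in the upper age for every method", {
  tab <- demo_counts(seed = 26)
  ages <- c(50, 65, 75, 85)
  for (f in list(function(a) cumulative_rate(tab, a)$value,
                 function(a) cumulative_risk(cumulative_rate(tab, a))$value,
                 function(a) current_probability(tab, a)$value,
                 function(a) amp_estimate(tab, a)$value)) {
    v <- sapply(ages, f)
    expect_true(all(diff(v) >= 0))
  }
  expect_gte(amp_estimate(tab, Inf)$value, amp_estimate(tab, 85)$value)
})

test_that("the method ordering holds on random registry-like tables", {
  for (s in 1:15) {
    hz <- random_hazard_table(200 + s)
    rate <- cumulative_rate(hz, 85)$value
    risk <- cumulative_risk(rate)
    cp <- suppressWarnings(current_probability(hz)$value)
    amp <- amp_estimate(hz)$value
    expect_lte(risk, rate)
    # S* <= S_all when registrations dominate cancer deaths band by band
    expect_lte(amp, cp + 1e-12)
    # reduction bound: CP - AMP <= CP^2
    expect_lte(cp - amp, cp^2 + 1e-12)
  }
})

test_that("method_comparison reproduces the published grid layout", {
  fx <- make_fixture("baseline", n = 20000, seed = 31,
                     bands = make_bands(seq(0, 90, by = 5)))
  grid <- suppressWarnings(
    method_comparison(fx$counts_all, fx$counts_first, ages = c(65, 75, 85, Inf)))
  expect_setequal(unique(grid$method),
                  c("cumulative_rate", "cumulative_risk",
                    "current_probability", "amp", "gold_standard"))
  # each method's column is monotone in age
  for (m in unique(grid$method)) {
    v <- grid$value[grid$method == m]
    expect_true(all(diff(v) >= -1e-12))
  }
  # multiple primaries present: CP is at least AMP at every age
  cp <- grid$value[grid$method == "current_probability"]
  am <- grid$value[grid$method == "amp"]
  expect_true(all(cp - am >= -1e-12))
  expect_match(grid$percent[1], "^[0-9.]+%$")
  # band mismatch is refused
  other <- demo_counts(seed = 1, registration_mode = "first-primaries-only")
  expect_error(method_comparison(fx$counts_all, other, ages = 65),
               "identical age bands")
})

test_that("with no multiple primaries AMP is a mild undercount of CP = gold standard", {
  fx <- make_fixture("prostate_like", n = 30000, seed = 32)
  expect_equal(fx$counts_all$cases, fx$counts_first$cases)
  cp <- current_probability(fx$counts_all)$value
  gs <- gold_standard(fx$counts_first)$value
  amp <- amp_estimate(fx$counts_all)$value
  expect_equal(cp, gs, tolerance = 1e-12)
  expect_lte(amp, cp)
  expect_gte(amp, cp - cp^2)
})
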
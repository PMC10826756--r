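test_that("the expected line is a tail-anchored pure power law", {
  h <- hist_from_sizes(rep(c(1, 2, 3, 50), c(60, 20, 10, 10)))
  fit <- fake_powerlaw_fit(alpha = 2, xmin = 1, n_tail = 100)
  line <- expected_line(fit, h)

  expect_equal(line$expected[1], 100 / zeta_brute(2, 1), tolerance = 1e-9)
  # tail total reproduces n_tail: C * zeta(alpha, xmin) = n_tail by anchor
  expect_equal(line$C * hurwitz_zeta(2, 1), 100, tolerance = 1e-9)
  # pure power-law ratio at every doubling
  x <- c(1, 2, 5, 10, 25)
  expect_equal(line$expected[2 * x] / line$expected[x], rep(2^-2, 5),
               tolerance = 1e-12)
  expect_equal(length(line$expected), 50L)

  expect_error(expected_line(select_xmin(hist_from_sizes(
    model_rand(exponential_model(0.5, 1), 300)), "exponential",
    min_tail_sizes = 3L), h), "power-law")
})

test_that("outbreak and illness deficits match a hand-computed oracle", {
  # fixture: alpha = 2, xmin = 1, tail of 100; observed concentrated low
  obs_sizes <- rep(c(1, 2, 3, 120), c(30, 15, 7, 2))
  h <- hist_from_sizes(obs_sizes)
  fit <- fake_powerlaw_fit(2, 1, n_tail = 100)
  line <- expected_line(fit, h)

  C <- 100 / zeta_brute(2, 1)
  exp_small <- C / (1:9)^2
  obs_small <- c(30, 15, 7, rep(0, 6))
  d <- outbreak_deficit(line, h)
  expect_equal(d$small_outbreak_deficit_total, sum(exp_small - obs_small),
               tolerance = 1e-9)
  expect_equal(d$large_outbreak_deficit_total,
               C * zeta_brute(2, 100) - 2, tolerance = 1e-9)
  expect_equal(d$small_outbreak_deficit_annual, d$small_outbreak_deficit_total)

  il <- suppressMessages(illness_deficit(line, h))
  expect_equal(il$small_illness_deficit_total,
               sum((1:9) * (exp_small - obs_small)), tolerance = 1e-9)
  # alpha = 2: the closed-form illness tail diverges, so the expectation is
  # truncated at the largest observed size by default
  expect_message(illness_deficit(line, h), "truncated")
  expect_equal(suppressMessages(illness_deficit(line, h))$large_illness_deficit_total,
               C * sum((100:120)^-1) - 2 * 120, tolerance = 1e-9)
  expect_error(illness_deficit(line, h, cap = NULL), "diverges")

  # alpha > 2 uses the closed form
  fit3 <- fake_powerlaw_fit(2.5, 1, n_tail = 100)
  line3 <- expected_line(fit3, h)
  il3 <- illness_deficit(line3, h)
  expect_equal(il3$large_illness_deficit_total,
               line3$C * zeta_brute(1.5, 100) - 2 * 120, tolerance = 1e-8)
})

test_that("strata variants: strict cutoff and observed-points-only expectation", {
  h <- hist_from_sizes(rep(c(1, 5, 100, 150), c(50, 20, 3, 1)))
  fit <- fake_powerlaw_fit(2.2, 1, n_tail = 74)
  line <- expected_line(fit, h)

  d_ge <- outbreak_deficit(line, h, large_cutoff = 100L)
  d_gt <- outbreak_deficit(line, h, large_cutoff = 101L)
  expect_equal(d_gt$large_outbreak_deficit_total - d_ge$large_outbreak_deficit_total,
               3 - line$C * 100^-2.2, tolerance = 1e-9)

  d_obs <- outbreak_deficit(line, h, observed_only = TRUE)
  expect_equal(d_obs$large_outbreak_deficit_total,
               line$C * (100^-2.2 + 150^-2.2) - 4, tolerance = 1e-9)
  # observed-only expectation can only be smaller than the full tail mass
  expect_lt(d_obs$large_outbreak_deficit_total, d_ge$large_outbreak_deficit_total)
})

test_that("deficits respond monotonically to censoring and annualize linearly", {
  set.seed(19)
  x <- model_rand(powerlaw_model(2.15, 1), 5000)
  h <- hist_from_sizes(x)
  fit <- select_xmin(h)
  line <- expected_line(fit, h)
  d0 <- outbreak_deficit(line, h)

  # deleting small observed outbreaks (line held fixed) raises the deficit
  drop <- x[-which(x < 10)[1:200]]
  h_drop <- hist_from_sizes(drop)
  d1 <- outbreak_deficit(line, h_drop)
  expect_gt(d1$small_outbreak_deficit_total, d0$small_outbreak_deficit_total)
  expect_equal(d1$small_outbreak_deficit_total,
               d0$small_outbreak_deficit_total + 200, tolerance = 1e-9)

  # doubling the year span halves every annual figure exactly
  h2 <- h
  h2$n_years <- 2L * h$n_years
  d2 <- outbreak_deficit(line, h2)
  expect_equal(d2$small_outbreak_deficit_annual,
               d0$small_outbreak_deficit_annual / 2)
  il0 <- suppressMessages(illness_deficit(line, h))
  il2 <- suppressMessages(illness_deficit(line, h2))
  expect_equal(il2$small_illness_deficit_annual,
               il0$small_illness_deficit_annual / 2)
})

test_that("an uncensored power-law sample shows no systematic deficit", {
  set.seed(23)
  defs <- replicate(30, {
    x <- model_rand(powerlaw_model(2.15, 1), 10000)
    h <- hist_from_sizes(x)
    line <- expected_line(select_xmin(h), h)
    outbreak_deficit(line, h)$small_outbreak_deficit_total
  })
  se <- stats::sd(defs) / sqrt(length(defs))
  expect_lt(abs(mean(defs)), 2 * se + 1)  # +1 guards the zero-variance corner
})

test_that("the observed/expected table is plot-ready on the full grid", {
  h <- hist_from_sizes(c(1, 1, 2, 8))
  line <- expected_line(fake_powerlaw_fit(2, 1, 4), h)
  tab <- observed_expected_table(line)
  expect_equal(tab$x, 1:8)
  expect_equal(tab$observed, c(2, 1, 0, 0, 0, 0, 0, 1))
  expect_equal(tab$expected, line$expected)
})
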
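test_that("the exact discrete MLE matches the grid-search likelihood oracle", {
  set.seed(2101)
  for (a_true in c(1.9, 2.5)) {
    x <- model_rand(powerlaw_model(a_true, 1), 5000)
    h <- hist_from_sizes(x)
    f <- fit_alpha(h, 1L)
    expect_lt(abs(f$alpha - grid_alpha_oracle(h, 1L)), 5e-4)
    # likelihood value is the one reported
    expect_equal(f$log_lik,
                 -f$alpha * sum(h$counts * log(h$sizes)) -
                   h$total * log(hurwitz_zeta(f$alpha, 1)),
                 tolerance = 1e-8)
  }
  # and at a nontrivial threshold
  x <- model_rand(powerlaw_model(2.15, 4), 5000)
  h <- hist_from_sizes(x)
  expect_lt(abs(fit_alpha(h, 4L)$alpha - grid_alpha_oracle(h, 4L)), 5e-4)
})

test_that("degenerate tails are refused, not fit", {
  h <- hist_from_sizes(rep(7, 50))
  expect_error(fit_alpha(h, 7L), "degenerate")
  expect_error(select_xmin(h), "degenerate")
})

test_that("KS distance equals the exhaustive-support oracle", {
  # small fixture scanned by hand-rolled per-integer oracle
  h <- hist_from_sizes(rep(c(1, 2, 3), c(5, 3, 2)))
  m <- powerlaw_model(2, 1)
  expect_equal(ks_distance(h, m), ks_oracle(h, m), tolerance = 1e-12)

  set.seed(77)
  cases <- list(
    list(h = hist_from_sizes(model_rand(powerlaw_model(2.15, 1), 2000)),
         m = powerlaw_model(2.15, 1)),
    list(h = hist_from_sizes(model_rand(powerlaw_model(2.15, 1), 2000)),
         m = powerlaw_model(2.3, 5)),        # model xmin above data minimum
    list(h = hist_from_sizes(model_rand(exponential_model(0.3, 1), 2000)),
         m = exponential_model(0.25, 2)),
    list(h = hist_from_sizes(model_rand(lognormal_model(0.8, 1.1, 1), 2000)),
         m = lognormal_model(0.8, 1.1, 3)))
  for (cs in cases) {
    expect_equal(ks_distance(cs$h, cs$m), ks_oracle(cs$h, cs$m),
                 tolerance = 1e-10)
  }
  expect_error(ks_distance(hist_from_sizes(1:3), powerlaw_model(2, 10)),
               "no histogram mass")
})

test_that("a histogram proportional to the model pmf has zero KS distance", {
  m <- exponential_model(0.5, 1)
  # counts proportional to the pmf on 1..40; remaining model mass beyond 40
  # is negligible at this rate, so D collapses to rounding error
  counts <- round(model_pmf(m, 1:40) * 1e7)
  h <- hist_from_sizes(rep(1:40, counts))
  expect_lt(ks_distance(h, m), 1e-6)
})

test_that("KS-minimizing threshold selection behaves on clean power-law data", {
  set.seed(41)
  hits <- 0
  for (r in 1:10) {
    x <- model_rand(powerlaw_model(2.5, 1), 10000)
    f <- select_xmin(hist_from_sizes(x), "power_law")
    if (f$model$xmin <= 3L) hits <- hits + 1
  }
  expect_gte(hits, 8)   # uncensored data: threshold stays small
})

test_that("threshold selection is scale invariant and ties break low", {
  set.seed(5)
  x <- model_rand(powerlaw_model(2.15, 1), 3000)
  h1 <- hist_from_sizes(x)
  h3 <- h1
  h3$counts <- h1$counts * 3L
  h3$total <- h1$total * 3L
  f1 <- select_xmin(h1)
  f3 <- select_xmin(h3)
  expect_identical(f1$model$xmin, f3$model$xmin)
  expect_equal(f1$model$alpha, f3$model$alpha, tolerance = 1e-7)
  expect_equal(f1$ks_distance, f3$ks_distance, tolerance = 1e-9)

  # candidate table covers distinct sizes minus the degenerate upper end
  expect_true(all(f1$candidates$xmin %in% h1$sizes))
  expect_lt(max(f1$candidates$xmin), max(h1$sizes))
})

test_that("GoF bootstrap p-value honors its definition and edge cases", {
  set.seed(61)
  x <- model_rand(powerlaw_model(2.15, 1), 800)
  h <- hist_from_sizes(x)
  f <- select_xmin(h)
  g <- gof_bootstrap(h, f, n_boot = 59, seed = 62)
  expect_equal(g$p_value, mean(g$boot_D >= g$observed_D, na.rm = TRUE))
  expect_gte(g$p_value, 0)
  expect_lte(g$p_value, 1)

  # a zero observed distance can never be beaten: p = 1
  f0 <- f
  f0$ks_distance <- 0
  expect_equal(gof_bootstrap(h, f0, n_boot = 19, seed = 63)$p_value, 1)

  # monotonicity: a larger observed D with the same replicates cannot raise p
  ps <- sapply(c(0, stats::median(g$boot_D), max(g$boot_D) + 0.01), function(D) {
    fD <- f
    fD$ks_distance <- D
    gof_bootstrap(h, fD, n_boot = 59, seed = 62)$p_value
  })
  expect_true(all(diff(ps) <= 0))
  expect_equal(ps[3], 0)

  # smoothed estimator is the (k+1)/(n+1) variant
  gs <- gof_bootstrap(h, f, n_boot = 59, seed = 62, smoothed = TRUE)
  expect_equal(gs$p_value, (sum(g$boot_D >= g$observed_D) + 1) / (59 + 1))
})

test_that("family comparison fits all three and isolates failures", {
  set.seed(83)
  x <- model_rand(powerlaw_model(2.15, 1), 2000)
  h <- hist_from_sizes(x)
  fits <- compare_families(h, n_boot = 0)
  expect_named(fits, c("power_law", "lognormal", "exponential"))
  s <- attr(fits, "summary")
  expect_true(all(is.finite(s$ks_distance)))
  # power law should beat the exponential on its own data
  expect_lt(s$ks_distance[s$family == "power_law"],
            s$ks_distance[s$family == "exponential"])

  # single-family request
  one <- compare_families(h, families = "power_law")
  expect_length(one, 1L)

  # a failing family is reported without aborting the others
  tiny <- hist_from_sizes(rep(c(3, 4), c(30, 20)))
  fits2 <- compare_families(tiny, families = c("power_law", "exponential"),
                            min_tail_sizes = 2L)
  expect_false(inherits(fits2$power_law, "error"))
})

test_that("exponential data are not rejected by their own GoF test", {
  set.seed(907)
  ok <- 0
  for (r in 1:12) {
    x <- model_rand(exponential_model(0.35, 1), 600)
    h <- hist_from_sizes(x)
    f <- select_xmin(h, "exponential", min_tail_sizes = 5L)
    p <- gof_bootstrap(h, f, n_boot = 39, seed = 1000 + r,
                       min_tail_sizes = 5L)$p_value
    if (p >= 0.05) ok <- ok + 1
  }
  expect_gte(ok, 10)
})
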
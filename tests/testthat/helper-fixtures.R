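# shared fixtures and independent oracles

hist_from_sizes <- function(sizes, year = 2000L) {
  make_histogram(data.frame(year = year, size = sizes),
                 period = c(year, year))
}

# brute-force Hurwitz zeta: long partial sum + midpoint integral tail;
# independent of the Euler-Maclaurin path in the package
zeta_brute <- function(a, q, M = 1e6) {
  k <- seq(q, q + M - 1)
  sum(k^(-a)) + (q + M - 0.5)^(1 - a) / (a - 1)
}

# grid-search likelihood oracle for the power-law exponent (checks the
# optimizer path; the zeta normalizer is verified separately against
# zeta_brute in test-zeta.R)
grid_alpha_oracle <- function(hist, xmin, grid = seq(1.01, 6, by = 5e-4)) {
  tail_idx <- hist$sizes >= xmin
  s_lnx <- sum(hist$counts[tail_idx] * log(hist$sizes[tail_idx]))
  n <- sum(hist$counts[tail_idx])
  ll <- -grid * s_lnx -
    n * vapply(grid, function(a) log(hurwitz_zeta(a, xmin)), numeric(1))
  grid[which.max(ll)]
}

# exhaustive-support KS oracle: per-integer direct summation, no cumsum
ks_oracle <- function(hist, model) {
  xmin <- model$xmin
  tail_sizes <- rep(hist$sizes, hist$counts)
  tail_sizes <- tail_sizes[tail_sizes >= xmin]
  xmax <- max(tail_sizes)
  D <- 0
  for (x in xmin:xmax) {
    emp <- mean(tail_sizes <= x)
    mod <- sum(model_pmf(model, xmin:x))
    D <- max(D, abs(emp - mod))
  }
  D
}

# minimal power-law tail_fit for deficit tests without running a fit
fake_powerlaw_fit <- function(alpha, xmin, n_tail, n_total = n_tail) {
  structure(list(model = powerlaw_model(alpha, xmin), n_tail = n_tail,
                 ks_distance = NA_real_, log_lik = NA_real_,
                 n_total = n_total, family = "power_law"),
            class = "tail_fit")
}

write_outbreak_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
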
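#' Expected outbreak counts extrapolated from a power-law tail fit
#'
#' Builds the "expected line": \eqn{E(x) = C x^{-\hat\alpha}} for every
#' integer size from 1 to the largest observed size, with
#' \eqn{C = n_{tail} / \zeta(\hat\alpha, \hat x_{min})} so that the expected
#' and observed totals agree exactly on the fitted tail. Below the threshold
#' the line is a pure extrapolation: it is the reference against which
#' underdetection of small outbreaks is measured.
#'
#' @param fit a power-law \code{tail_fit}.
#' @param hist the \code{size_freq_table} the fit came from.
#' @return object of class \code{expected_line}: list with \code{x} (1..max
#'   observed), \code{expected} E(x), \code{C}, \code{alpha}, \code{xmin},
#'   \code{n_tail}, \code{fit}, \code{hist}.
#' @export
expected_line <- function(fit, hist) {
  if (!inherits(fit, "tail_fit") || fit$family != "power_law") {
    stop("'fit' must be a power-law tail_fit", call. = FALSE)
  }
  alpha <- fit$model$alpha
  xmin <- fit$model$xmin
  C <- fit$n_tail / hurwitz_zeta(alpha, xmin)
  x <- seq_len(max(hist$sizes))
  structure(list(x = x, expected = C * x^(-alpha), C = C,
                 alpha = alpha, xmin = xmin, n_tail = fit$n_tail,
                 fit = fit, hist = hist),
            class = "expected_line")
}

#' @export
print.expected_line <- function(x, ...) {
  cat(sprintf("<expected_line> E(x) = %.2f * x^-%.4f on x = 1..%d (tail anchored at xmin = %d)\n",
              x$C, x$alpha, max(x$x), x$xmin))
  invisible(x)
}

# observed count at each integer 1..max(sizes); zeros where unobserved
.observed_on_grid <- function(hist) {
  obs <- numeric(max(hist$sizes))
  obs[hist$sizes] <- hist$counts
  obs
}

#' Deficit of small and large outbreaks relative to the expected line
#'
#' Sums expected-minus-observed outbreak counts over the small stratum
#' (sizes 1 to \code{small_cutoff} - 1) and the large stratum (sizes >=
#' \code{large_cutoff}). Positive values mean fewer outbreaks were observed
#' than the power law predicts; negative values (more observed than
#' expected) are reported as-is, never clipped. By default the large-stratum
#' expectation uses the closed-form tail mass
#' \eqn{C\,\zeta(\hat\alpha, x_{large})} over \emph{all} integers at or above
#' the cutoff, because observed points there are sparse while zero-count
#' sizes still carry expected mass; \code{observed_only = TRUE} restricts
#' both terms to observed sizes for sensitivity analysis.
#'
#' @param line an \code{expected_line}.
#' @param hist the source \code{size_freq_table} (defaults to the one stored
#'   in \code{line}).
#' @param small_cutoff small outbreaks are sizes strictly below this
#'   (default 10).
#' @param large_cutoff large outbreaks are sizes at or above this
#'   (default 100; set 101 for the strict ">100" reading).
#' @param observed_only large-stratum expectation restricted to observed
#'   sizes only.
#' @return object of class \code{deficit_estimate}: totals and annual
#'   (total / n_years) outbreak deficits for both strata, plus the cutoffs
#'   and \code{n_years}.
#' @export
outbreak_deficit <- function(line, hist = line$hist, small_cutoff = 10L,
                             large_cutoff = 100L, observed_only = FALSE) {
  obs <- .observed_on_grid(hist)
  small_x <- seq_len(small_cutoff - 1L)
  small_total <- sum(line$expected[small_x] - obs[small_x])

  big_obs <- sum(hist$counts[hist$sizes >= large_cutoff])
  big_exp <- if (observed_only) {
    big_sizes <- hist$sizes[hist$sizes >= large_cutoff]
    sum(line$C * big_sizes^(-line$alpha))
  } else {
    line$C * hurwitz_zeta(line$alpha, large_cutoff)
  }
  large_total <- big_exp - big_obs

  structure(list(
    small_outbreak_deficit_total = small_total,
    small_outbreak_deficit_annual = small_total / hist$n_years,
    large_outbreak_deficit_total = large_total,
    large_outbreak_deficit_annual = large_total / hist$n_years,
    small_cutoff = small_cutoff, large_cutoff = large_cutoff,
    n_years = hist$n_years, observed_only = observed_only
  ), class = "deficit_estimate")
}

#' @export
print.deficit_estimate <- function(x, ...) {
  cat(sprintf(
    "<deficit_estimate> small (<%d): %.1f total, %.1f/yr; large (>=%d): %.2f total, %.2f/yr (%d years)\n",
    x$small_cutoff, x$small_outbreak_deficit_total, x$small_outbreak_deficit_annual,
    x$large_cutoff, x$large_outbreak_deficit_total, x$large_outbreak_deficit_annual,
    x$n_years))
  invisible(x)
}

#' Deficit of outbreak-associated illnesses
#'
#' Illness-weighted analogue of \code{\link{outbreak_deficit}}: each size-x
#' outbreak contributes x illnesses. The small stratum sums
#' \eqn{x (E(x) - n(x))} over sizes below the cutoff. The large stratum's
#' expected illnesses are the closed form
#' \eqn{C\,\zeta(\hat\alpha - 1, x_{large})}, which requires
#' \eqn{\hat\alpha > 2}; when \eqn{\hat\alpha \le 2} the expected-illness
#' tail diverges and the sum is truncated at \code{cap} (defaulting to the
#' largest observed size) with a message, or errors if \code{cap} is NULL.
#'
#' @inheritParams outbreak_deficit
#' @param cap truncation bound for the large-stratum expected illnesses when
#'   \eqn{\hat\alpha \le 2}; NULL forbids truncation (divergent-tail error).
#' @return list with \code{small_illness_deficit_annual},
#'   \code{large_illness_deficit_annual} and the matching totals.
#' @export
illness_deficit <- function(line, hist = line$hist, small_cutoff = 10L,
                            large_cutoff = 100L, cap = max(hist$sizes)) {
  obs <- .observed_on_grid(hist)
  small_x <- seq_len(small_cutoff - 1L)
  small_total <- sum(small_x * (line$expected[small_x] - obs[small_x]))

  big_idx <- hist$sizes >= large_cutoff
  big_obs_ill <- sum(hist$sizes[big_idx] * hist$counts[big_idx])
  if (line$alpha > 2) {
    big_exp_ill <- line$C * hurwitz_zeta(line$alpha - 1, large_cutoff)
  } else if (is.null(cap)) {
    stop(sprintf("expected illness tail diverges for alpha = %.3f <= 2 and no cap is configured",
                 line$alpha), call. = FALSE)
  } else {
    message(sprintf("alpha = %.3f <= 2: expected illnesses summed over sizes %d..%d (truncated)",
                    line$alpha, large_cutoff, cap))
    ks <- seq.int(large_cutoff, cap)
    big_exp_ill <- line$C * sum(ks^(1 - line$alpha))
  }
  large_total <- big_exp_ill - big_obs_ill

  list(small_illness_deficit_total = small_total,
       small_illness_deficit_annual = small_total / hist$n_years,
       large_illness_deficit_total = large_total,
       large_illness_deficit_annual = large_total / hist$n_years,
       small_cutoff = small_cutoff, large_cutoff = large_cutoff,
       n_years = hist$n_years)
}

#' Plot-ready observed/expected table
#'
#' @param line an \code{expected_line}.
#' @return data frame with columns \code{x}, \code{observed},
#'   \code{expected}, suitable for a log-log size-frequency plot.
#' @export
observed_expected_table <- function(line) {
  data.frame(x = line$x,
             observed = .observed_on_grid(line$hist),
             expected = line$expected)
}
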
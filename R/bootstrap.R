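#' Percentile summary of bootstrap replicates
#'
#' Median and 90% credible interval (5th and 95th percentiles) using the
#' linear-interpolation quantile definition (R's type 7).
#'
#' @param values non-empty numeric vector of replicate values (NAs from
#'   failed replicates are dropped).
#' @return list with \code{median}, \code{cri_low}, \code{cri_high},
#'   \code{n}.
#' @export
summarize_replicates <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no replicate values to summarize", call. = FALSE)
  q <- stats::quantile(values, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  list(median = q[2], cri_low = q[1], cri_high = q[3], n = length(values))
}

#' Case-resampling bootstrap of the full estimation pipeline
#'
#' Each replicate resamples the N in-period outbreak records with
#' replacement, re-selects the minimum threshold, re-fits the power-law
#' exponent, rebuilds the expected line and recomputes the annual deficits.
#' Re-selecting the threshold every replicate is what yields a bootstrap
#' distribution over the threshold itself, alongside the exponent and the
#' deficit quantities. Per-replicate seeds are derived from \code{seed} by
#' counter offset, so results are reproducible for a given
#' \code{(seed, n_boot)} irrespective of execution order.
#'
#' @param records data frame of outbreak records (\code{year}, \code{size}).
#' @param period \code{c(first_year, last_year)}; defaults to the record
#'   range.
#' @param n_boot number of replicates (default 5000, matching the analysis
#'   convention; scale down for quick runs).
#' @param seed integer seed.
#' @param small_cutoff,large_cutoff deficit strata bounds.
#' @param min_tail_sizes passed to \code{\link{select_xmin}}.
#' @param keep_replicates if TRUE the per-replicate draws are returned for
#'   histogram-style diagnostics of the threshold and slope.
#' @return object of class \code{bootstrap_result}: a named list of
#'   summaries (each from \code{\link{summarize_replicates}}) for
#'   \code{xmin}, \code{alpha}, \code{small_outbreak_deficit_annual},
#'   \code{large_outbreak_deficit_annual},
#'   \code{small_illness_deficit_annual},
#'   \code{large_illness_deficit_annual}; plus \code{n_boot}, \code{seed},
#'   \code{n_failed} and (optionally) \code{replicates}.
#' @export
bootstrap_pipeline <- function(records, period = range(records$year),
                               n_boot = 5000L, seed = 1L,
                               small_cutoff = 10L, large_cutoff = 100L,
                               min_tail_sizes = 10L, keep_replicates = FALSE) {
  stopifnot(n_boot >= 1L)
  keep <- records$year >= period[1] & records$year <= period[2]
  recs <- records[keep, , drop = FALSE]
  N <- nrow(recs)
  if (N == 0L) stop("no records in period", call. = FALSE)

  quantities <- c("xmin", "alpha", "small_outbreak_deficit_annual",
                  "large_outbreak_deficit_annual",
                  "small_illness_deficit_annual",
                  "large_illness_deficit_annual")
  reps <- matrix(NA_real_, nrow = n_boot, ncol = length(quantities),
                 dimnames = list(NULL, quantities))

  for (b in seq_len(n_boot)) {
    set.seed((seed + b) %% 2147483647L)
    idx <- sample.int(N, N, replace = TRUE)
    reps[b, ] <- tryCatch({
      bhist <- make_histogram(recs[idx, , drop = FALSE], period = period)
      fit <- select_xmin(bhist, "power_law", min_tail_sizes = min_tail_sizes)
      line <- expected_line(fit, bhist)
      od <- outbreak_deficit(line, bhist, small_cutoff, large_cutoff)
      id <- suppressMessages(
        illness_deficit(line, bhist, small_cutoff, large_cutoff))
      c(fit$model$xmin, fit$model$alpha,
        od$small_outbreak_deficit_annual, od$large_outbreak_deficit_annual,
        id$small_illness_deficit_annual, id$large_illness_deficit_annual)
    }, error = function(e) rep(NA_real_, length(quantities)))
  }

  n_failed <- sum(is.na(reps[, "alpha"]))
  if (n_failed > 0.01 * n_boot) {
    warning(sprintf("%d of %d bootstrap replicates failed to fit", n_failed, n_boot),
            call. = FALSE)
  }
  out <- lapply(quantities, function(qn) summarize_replicates(reps[, qn]))
  names(out) <- quantities
  structure(list(summaries = out, n_boot = n_boot, seed = seed,
                 n_failed = n_failed,
                 replicates = if (keep_replicates) as.data.frame(reps) else NULL),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %d replicates (%d failed), seed %d\n",
              x$n_boot, x$n_failed, x$seed))
  for (qn in names(x$summaries)) {
    s <- x$summaries[[qn]]
    cat(sprintf("  %-32s median %8.3f  90%% CrI (%.3f, %.3f)\n",
                qn, s$median, s$cri_low, s$cri_high))
  }
  invisible(x)
}

#' Flatten a bootstrap result into a summary table
#'
#' @param x a \code{bootstrap_result}.
#' @return data frame (quantity, median, cri_low, cri_high, n_boot,
#'   failures).
#' @export
bootstrap_table <- function(x) {
  data.frame(
    quantity = names(x$summaries),
    median = vapply(x$summaries, `[[`, numeric(1), "median"),
    cri_low = vapply(x$summaries, `[[`, numeric(1), "cri_low"),
    cri_high = vapply(x$summaries, `[[`, numeric(1), "cri_high"),
    n_boot = x$n_boot, failures = x$n_failed, row.names = NULL)
}
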
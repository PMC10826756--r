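#' Run the full underdetection analysis
#'
#' Orchestrates the pipeline for each analysis era: family comparison with
#' goodness-of-fit testing, power-law threshold selection, expected-line
#' extrapolation, small/large outbreak and illness deficits, and the
#' case-resampling bootstrap for medians and 90% credible intervals.
#' Finishes with an era-contrast table giving the percent change in the
#' annual small-outbreak deficit between the first and last era, computed
#' from unrounded values. All randomness flows from the single \code{seed}:
#' the goodness-of-fit and credible-interval bootstraps receive independent
#' derived streams.
#'
#' @param records data frame of outbreak records, or a path to a CSV file
#'   readable by \code{\link{read_outbreaks}}.
#' @param eras named list of \code{c(first, last)} year pairs (defaults to
#'   the full window plus the pre/post-WGS eras used throughout).
#' @param small_cutoff,large_cutoff deficit strata bounds.
#' @param n_boot_gof goodness-of-fit replicates per family (0 skips GoF).
#' @param n_boot_cri credible-interval bootstrap replicates.
#' @param seed master seed.
#' @param families distribution families to compare.
#' @param min_tail_sizes passed to \code{\link{select_xmin}}.
#' @param out_dir if non-NULL, writes a JSON report, TSV tables
#'   (fit summary, bootstrap summaries, observed/expected lines) and a run
#'   manifest there.
#' @param ... column-mapping arguments forwarded to
#'   \code{\link{read_outbreaks}} when \code{records} is a path.
#' @return list (invisibly when writing) with per-era entries (\code{fits},
#'   \code{fit}, \code{line}, \code{deficit}, \code{illness},
#'   \code{bootstrap}) and \code{era_contrast}.
#' @export
run_full_analysis <- function(records,
                              eras = list(full = c(1998L, 2019L),
                                          era1 = c(1998L, 2017L),
                                          era2 = c(2018L, 2019L)),
                              small_cutoff = 10L, large_cutoff = 100L,
                              n_boot_gof = 1000L, n_boot_cri = 5000L,
                              seed = 1L,
                              families = c("power_law", "lognormal", "exponential"),
                              min_tail_sizes = 10L, out_dir = NULL, ...) {
  if (is.character(records)) records <- read_outbreaks(records, ...)
  hists <- split_eras(records, eras)

  result <- list()
  for (i in seq_along(hists)) {
    nm <- names(hists)[i]
    hist <- hists[[i]]
    fits <- compare_families(hist, families = families, n_boot = n_boot_gof,
                             seed = seed + 100L * i,
                             min_tail_sizes = min_tail_sizes)
    fit <- fits[["power_law"]]
    if (inherits(fit, "error")) stop("power-law fit failed for era ", nm,
                                     ": ", conditionMessage(fit), call. = FALSE)
    line <- expected_line(fit, hist)
    od <- outbreak_deficit(line, hist, small_cutoff, large_cutoff)
    id <- suppressMessages(illness_deficit(line, hist, small_cutoff, large_cutoff))
    bt <- if (n_boot_cri > 0L) {
      bootstrap_pipeline(records, period = hist$period, n_boot = n_boot_cri,
                         seed = seed + 100000L * i,
                         small_cutoff = small_cutoff,
                         large_cutoff = large_cutoff,
                         min_tail_sizes = min_tail_sizes)
    }
    result[[nm]] <- list(hist = hist, fits = fits, fit = fit, line = line,
                         deficit = od, illness = id, bootstrap = bt)
  }

  result$era_contrast <- era_contrast(result)
  if (!is.null(out_dir)) {
    .write_report(result, out_dir, seed = seed,
                  eras = eras, small_cutoff = small_cutoff,
                  large_cutoff = large_cutoff, n_boot_gof = n_boot_gof,
                  n_boot_cri = n_boot_cri, min_tail_sizes = min_tail_sizes)
    return(invisible(result))
  }
  result
}

#' Era contrast of annual small-outbreak deficits
#'
#' Compares the annual small-outbreak deficit between the first and last
#' non-overlapping eras (by convention the pre- and post-regime-change
#' periods); the percent change is
#' \code{100 * (era1 - era2) / era1} on unrounded values.
#'
#' @param result list of per-era results from
#'   \code{\link{run_full_analysis}} (entries with \code{$deficit}).
#' @return one-row data frame with both annual deficits and the percent
#'   change, or NULL when fewer than two comparable eras exist.
#' @export
era_contrast <- function(result) {
  era_names <- names(result)[vapply(result, function(x)
    is.list(x) && !is.null(x$deficit), logical(1))]
  # contrast the earliest/latest pair of mutually disjoint eras; a full-window
  # entry overlapping both is never part of a pair
  spans <- lapply(result[era_names], function(x) x$hist$period)
  pairs <- list()
  for (i in seq_along(era_names)) {
    for (j in seq_along(era_names)) {
      if (i == j) next
      si <- spans[[i]]; sj <- spans[[j]]
      if (si[2] < sj[1]) pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  if (length(pairs) == 0L) return(NULL)
  starts <- vapply(pairs, function(p) spans[[p[1]]][1], numeric(1))
  ends <- vapply(pairs, function(p) spans[[p[2]]][2], numeric(1))
  best <- pairs[[order(starts, -ends)[1]]]
  e1 <- era_names[best[1]]
  e2 <- era_names[best[2]]
  a <- result[[e1]]$deficit$small_outbreak_deficit_annual
  b <- result[[e2]]$deficit$small_outbreak_deficit_annual
  data.frame(era1 = e1, era2 = e2,
             era1_small_deficit_annual = a,
             era2_small_deficit_annual = b,
             percent_change = 100 * (a - b) / a)
}

.write_report <- function(result, out_dir, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- c(list(package = "outbreaklaw",
                     version = as.character(utils::packageVersion("outbreaklaw")),
                     r_version = R.version.string,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                lapply(list(...), function(x) {
                  if (is.list(x)) lapply(x, as.vector) else x
                }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  era_names <- names(result)[vapply(result, function(x)
    is.list(x) && !is.null(x$deficit), logical(1))]
  report <- lapply(result[era_names], function(x) {
    list(period = x$hist$period, n_outbreaks = x$hist$total,
         fit_summary = attr(x$fits, "summary"),
         power_law = list(xmin = x$fit$model$xmin, alpha = x$fit$model$alpha,
                          n_tail = x$fit$n_tail, ks = x$fit$ks_distance),
         deficit = unclass(x$deficit), illness = x$illness,
         bootstrap = if (!is.null(x$bootstrap)) bootstrap_table(x$bootstrap))
  })
  report$era_contrast <- result$era_contrast
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  for (nm in era_names) {
    utils::write.table(observed_expected_table(result[[nm]]$line),
                       file.path(out_dir, paste0("observed_expected_", nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(result[[nm]]$bootstrap)) {
      utils::write.table(bootstrap_table(result[[nm]]$bootstrap),
                         file.path(out_dir, paste0("bootstrap_", nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  invisible(out_dir)
}
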
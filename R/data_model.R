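#' Read an outbreak table
#'
#' Reads a comma-separated outbreak table (one row per outbreak, header row)
#' and validates it into a data frame of outbreak records with columns
#' \code{year} and \code{size} (laboratory-confirmed case count). Rows whose
#' size is missing, non-integer or below 1 are rejected and reported --
#' never silently dropped -- because the inclusion rule (single-confirmed-case
#' outbreaks count) is part of the analysis definition.
#'
#' @param path path to a CSV file with a header row.
#' @param year_col,size_col names of the year and case-count columns
#'   (defaults \code{"year"}, \code{"confirmed_cases"}).
#' @param on_invalid \code{"warn"} (default) drops offending rows with a
#'   warning listing them; \code{"error"} aborts.
#' @return data frame with integer columns \code{year}, \code{size}; the
#'   rejected rows (if any) are attached as attribute \code{"rejected"}.
#' @export
read_outbreaks <- function(path, year_col = "year", size_col = "confirmed_cases",
                           on_invalid = c("warn", "error")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c(year_col, size_col), names(raw))
  if (length(missing_cols) > 0) {
    stop("configured column(s) not present in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as_outbreak_records(data.frame(year = raw[[year_col]], size = raw[[size_col]]),
                      on_invalid = on_invalid)
}

#' Validate a data frame of outbreak records
#'
#' @param df data frame with columns \code{year} and \code{size}.
#' @inheritParams read_outbreaks
#' @return validated data frame of records (see \code{\link{read_outbreaks}}).
#' @export
as_outbreak_records <- function(df, on_invalid = c("warn", "error")) {
  on_invalid <- match.arg(on_invalid)
  stopifnot(all(c("year", "size") %in% names(df)))
  size <- suppressWarnings(as.numeric(df$size))
  year <- suppressWarnings(as.numeric(df$year))
  bad <- is.na(size) | is.na(year) | size < 1 | size != floor(size) |
    year != floor(year)
  if (any(bad)) {
    msg <- sprintf("%d row(s) failed validation (size must be an integer >= 1): rows %s",
                   sum(bad), paste(utils::head(which(bad), 20), collapse = ", "))
    if (on_invalid == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  out <- data.frame(year = as.integer(year[!bad]), size = as.integer(size[!bad]))
  attr(out, "rejected") <- df[bad, , drop = FALSE]
  out
}

#' Size-frequency histogram of outbreaks in a period
#'
#' Tabulates outbreak size against frequency for records falling in
#' \code{period} (inclusive year bounds). The resulting table carries the
#' period and the number of years represented, used later to annualize
#' deficit estimates.
#'
#' @param records data frame of outbreak records (\code{year}, \code{size}).
#' @param period integer vector \code{c(first_year, last_year)}; defaults to
#'   the record range.
#' @return object of class \code{size_freq_table}: list with integer vectors
#'   \code{sizes} (distinct, ascending) and \code{counts}, plus \code{total},
#'   \code{period}, \code{n_years}.
#' @export
make_histogram <- function(records, period = range(records$year)) {
  stopifnot(length(period) == 2L, period[1] <= period[2])
  keep <- records$year >= period[1] & records$year <= period[2]
  if (!any(keep)) {
    stop(sprintf("no outbreak records in period %d-%d", period[1], period[2]),
         call. = FALSE)
  }
  tab <- table(records$size[keep])
  structure(list(
    sizes   = as.integer(names(tab)),
    counts  = as.integer(tab),
    total   = sum(keep),
    period  = as.integer(period),
    n_years = as.integer(period[2] - period[1] + 1L)
  ), class = "size_freq_table")
}

#' @export
print.size_freq_table <- function(x, ...) {
  cat(sprintf("<size_freq_table> %d outbreaks, sizes %d-%d, period %d-%d (%d years)\n",
              x$total, min(x$sizes), max(x$sizes), x$period[1], x$period[2],
              x$n_years))
  invisible(x)
}

#' Expand a histogram back to a vector of sizes
#'
#' Inverse of \code{\link{make_histogram}} up to record order: returns the
#' multiset of sizes, one entry per outbreak.
#'
#' @param hist a \code{size_freq_table}.
#' @return integer vector of length \code{hist$total}.
#' @export
expand_histogram <- function(hist) {
  rep(hist$sizes, hist$counts)
}

#' Split records into analysis eras
#'
#' @param records data frame of outbreak records.
#' @param eras named list of \code{c(first, last)} year pairs; the defaults
#'   are the full study window plus the pre- and post-WGS surveillance eras.
#' @return named list of \code{size_freq_table}s.
#' @export
split_eras <- function(records,
                       eras = list(full  = c(1998L, 2019L),
                                   era1  = c(1998L, 2017L),
                                   era2  = c(2018L, 2019L))) {
  lapply(eras, function(p) make_histogram(records, period = p))
}

#' Write a histogram as a two-column TSV (size, count)
#'
#' @param hist a \code{size_freq_table}.
#' @param path output path.
#' @export
write_histogram <- function(hist, path) {
  utils::write.table(data.frame(size = hist$sizes, count = hist$counts),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
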
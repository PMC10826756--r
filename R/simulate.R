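#' Size-dependent detection curve
#'
#' Detection probability as a linear ramp from a floor at size 1 to full
#' detection at the saturation size:
#' \eqn{d(x) = \min(1,\ p_1 + (1 - p_1)(x - 1)/(s - 1))}.
#' Small outbreaks are the hardest to detect; this two-parameter monotone
#' curve is the simplest mechanism producing the sub-threshold flattening
#' that surveillance size-frequency data show on log-log axes.
#'
#' @param floor_prob detection probability at size 1, in (0, 1].
#' @param saturation size at and beyond which detection is certain
#'   (integer >= 1; 1 means no censoring).
#' @return function d(x), vectorized over integer sizes.
#' @export
detection_curve <- function(floor_prob = 0.2, saturation = 10L) {
  if (!is.numeric(floor_prob) || floor_prob <= 0 || floor_prob > 1) {
    stop("'floor_prob' must be in (0, 1]", call. = FALSE)
  }
  if (saturation < 1 || saturation != floor(saturation)) {
    stop("'saturation' must be an integer >= 1", call. = FALSE)
  }
  force(floor_prob); force(saturation)
  function(x) {
    if (saturation == 1L) return(rep(1, length(x)))
    pmin(1, floor_prob + (1 - floor_prob) * (x - 1) / (saturation - 1))
  }
}

#' Simulation configuration for synthetic surveillance data
#'
#' Defines the study conditions the generator emulates: per era, a year
#' range, a true power-law exponent for outbreak sizes, a true outbreak
#' rate per year, and a size-dependent detection curve. The defaults mirror
#' a two-decade surveillance series with an era regime change in which
#' detection of small outbreaks improves (floor probability 0.2 rising to
#' 0.5) while the size-generating process (alpha = 2.15, about 500 true
#' outbreaks per year) stays fixed.
#'
#' @param eras list of era definitions, each a list with \code{years}
#'   (\code{c(first, last)}), \code{alpha} (> 1), \code{rate} (true
#'   outbreaks/year, > 0) and optionally its own \code{detection} curve.
#' @param detection default detection curve for eras that do not set one.
#' @param xmin_true true lower support of the size distribution.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(eras = list(
                         list(years = c(1998L, 2017L), alpha = 2.15, rate = 500,
                              detection = detection_curve(0.2, 10L)),
                         list(years = c(2018L, 2019L), alpha = 2.15, rate = 500,
                              detection = detection_curve(0.5, 10L))),
                       detection = detection_curve(0.2, 10L),
                       xmin_true = 1L) {
  yrs <- unlist(lapply(eras, function(e) seq.int(e$years[1], e$years[2])))
  if (anyDuplicated(yrs)) stop("era year ranges must be disjoint", call. = FALSE)
  for (e in eras) {
    stopifnot(e$alpha > 1, e$rate > 0, e$years[1] <= e$years[2])
  }
  structure(list(eras = eras, detection = detection,
                 xmin_true = as.integer(xmin_true)),
            class = "sim_config")
}

#' Generate a synthetic surveillance dataset with known ground truth
#'
#' For each year of each era, draws a Poisson number of true outbreaks at
#' the era rate, sizes i.i.d. from the era's discrete power law, and retains
#' each outbreak independently with probability d(size). Both the retained
#' (observed) records and the complete truth are returned, so downstream
#' estimates of underdetection can be checked against the censoring that
#' actually happened.
#'
#' @param config a \code{sim_config}.
#' @param seed integer seed.
#' @return list with \code{records} (observed outbreaks: year, size),
#'   \code{truth} (all true outbreaks: year, size, detected) and
#'   \code{era_truth}, a data frame per era of true/observed/censored
#'   counts overall and in the small (<10) stratum, with annual censored
#'   small-outbreak and illness counts (the true deficits by construction).
#' @export
simulate_surveillance <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  truth_parts <- list()
  for (i in seq_along(config$eras)) {
    era <- config$eras[[i]]
    d <- if (is.null(era$detection)) config$detection else era$detection
    model <- powerlaw_model(era$alpha, config$xmin_true)
    for (yr in seq.int(era$years[1], era$years[2])) {
      n_true <- stats::rpois(1, era$rate)
      sizes <- model_rand(model, n_true)
      detected <- stats::runif(n_true) < d(sizes)
      truth_parts[[length(truth_parts) + 1L]] <-
        data.frame(era = i, year = yr, size = sizes, detected = detected)
    }
  }
  truth <- do.call(rbind, truth_parts)
  records <- truth[truth$detected, c("year", "size")]
  rownames(records) <- NULL

  era_truth <- do.call(rbind, lapply(seq_along(config$eras), function(i) {
    e <- config$eras[[i]]
    t_i <- truth[truth$era == i, ]
    small <- t_i$size < 10
    censored_small <- small & !t_i$detected
    ny <- e$years[2] - e$years[1] + 1L
    data.frame(
      era = i, first_year = e$years[1], last_year = e$years[2],
      true_alpha = e$alpha, n_years = ny,
      n_true = nrow(t_i), n_observed = sum(t_i$detected),
      n_censored = sum(!t_i$detected),
      censored_small_total = sum(censored_small),
      censored_small_annual = sum(censored_small) / ny,
      censored_small_illness_annual = sum(t_i$size[censored_small]) / ny)
  }))
  list(records = records, truth = truth, era_truth = era_truth)
}

#' Write a simulated dataset in the CSV dialect the reader accepts
#'
#' @param sim result of \code{\link{simulate_surveillance}}.
#' @param path CSV output path; the ground truth is written alongside as a
#'   JSON side-car (\code{<path>.truth.json}).
#' @export
write_simulation <- function(sim, path) {
  utils::write.csv(data.frame(year = sim$records$year,
                              confirmed_cases = sim$records$size),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(sim$era_truth, paste0(path, ".truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
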
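#' Discrete heavy-tailed size distributions
#'
#' Constructors for the three candidate models of outbreak size on the
#' positive integers, each truncated to \code{x >= xmin}:
#' \describe{
#'   \item{power law}{\eqn{p(x) = x^{-\alpha} / \zeta(\alpha, xmin)} with
#'     the Hurwitz zeta normalizer.}
#'   \item{discrete log-normal}{the continuous log-normal density evaluated
#'     at integer points and renormalized over \eqn{x \ge xmin}.}
#'   \item{discrete exponential}{geometric decay
#'     \eqn{p(x) = (1 - e^{-\lambda}) e^{-\lambda (x - xmin)}}.}
#' }
#' The log-normal and exponential discretizations normalize the continuous
#' density at integer points (rather than differencing the continuous CDF);
#' this convention is held fixed throughout fitting and simulation.
#'
#' @param alpha power-law exponent, > 1.
#' @param xmin minimum threshold (integer >= 1); the model has support
#'   on integers >= xmin.
#' @param mu,sigma log-scale mean and standard deviation of the log-normal.
#' @param rate decay rate \eqn{\lambda > 0} of the discrete exponential.
#' @return an object of class \code{size_model} (a list with \code{family},
#'   parameters and \code{xmin}).
#' @export
powerlaw_model <- function(alpha, xmin = 1L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 1)
  .check_xmin(xmin)
  structure(list(family = "power_law", alpha = alpha, xmin = as.integer(xmin)),
            class = "size_model")
}

#' @rdname powerlaw_model
#' @export
lognormal_model <- function(mu, sigma, xmin = 1L) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.numeric(sigma),
            length(sigma) == 1L, sigma > 0)
  .check_xmin(xmin)
  structure(list(family = "lognormal", mu = mu, sigma = sigma,
                 xmin = as.integer(xmin)),
            class = "size_model")
}

#' @rdname powerlaw_model
#' @export
exponential_model <- function(rate, xmin = 1L) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate > 0)
  .check_xmin(xmin)
  structure(list(family = "exponential", rate = rate, xmin = as.integer(xmin)),
            class = "size_model")
}

.check_xmin <- function(xmin) {
  if (length(xmin) != 1L || !is.finite(xmin) || xmin < 1 || xmin != floor(xmin))
    stop("'xmin' must be a single integer >= 1", call. = FALSE)
}

#' @export
print.size_model <- function(x, ...) {
  pars <- switch(x$family,
    power_law   = sprintf("alpha = %.4f", x$alpha),
    lognormal   = sprintf("mu = %.4f, sigma = %.4f", x$mu, x$sigma),
    exponential = sprintf("rate = %.4f", x$rate))
  cat(sprintf("<size_model> %s (%s), xmin = %d\n", x$family, pars, x$xmin))
  invisible(x)
}

# un-normalized density at integer points; internal
.model_kernel <- function(model, x) {
  switch(model$family,
    power_law   = x^(-model$alpha),
    lognormal   = stats::dlnorm(x, model$mu, model$sigma),
    exponential = exp(-model$rate * (x - model$xmin)))
}

# normalizer Z = sum_{k >= xmin} kernel(k); closed form where available,
# otherwise exact head sum plus an integral tail correction (log-normal)
.model_normalizer <- function(model) {
  switch(model$family,
    power_law   = hurwitz_zeta(model$alpha, model$xmin),
    exponential = 1 / (1 - exp(-model$rate)),
    lognormal   = .lnorm_normalizer(model$mu, model$sigma, model$xmin))
}

# head sum spans the density mode; beyond K the midpoint-rule identity
# sum_{k>K} f(k) ~ integral_{K+1/2}^inf f makes the tail error negligible
.lnorm_normalizer <- function(mu, sigma, xmin) {
  K <- max(xmin + 999, ceiling(exp(mu + 2 * sigma)) + 999)
  ks <- seq.int(xmin, K)
  sum(stats::dlnorm(ks, mu, sigma)) +
    stats::plnorm(K + 0.5, mu, sigma, lower.tail = FALSE)
}

#' Probability mass, survival and sampling for size models
#'
#' \code{model_pmf} returns \eqn{P(X = x)}; \code{model_surv} returns the
#' survival function \eqn{P(X \ge x)} (so \code{model_surv(m, m$xmin)} is 1);
#' \code{model_cdf} returns \eqn{P(X \le x)}. All require \code{x >= xmin}.
#'
#' @param model a \code{size_model}.
#' @param x integer vector of sizes, all >= \code{model$xmin}.
#' @return numeric vector of probabilities.
#' @export
model_pmf <- function(model, x) {
  .check_support(model, x)
  .model_kernel(model, x) / .model_normalizer(model)
}

#' @rdname model_pmf
#' @export
model_surv <- function(model, x) {
  .check_support(model, x)
  switch(model$family,
    power_law   = hurwitz_zeta(model$alpha, x) / .model_normalizer(model),
    exponential = exp(-model$rate * (x - model$xmin)),
    lognormal   = {
      # 1 - sum of pmf below x keeps the telescoping identity
      # surv(x) - surv(x+1) = pmf(x) exact to machine precision
      Z <- .model_normalizer(model)
      vapply(x, function(xi) {
        if (xi == model$xmin) return(1)
        ks <- seq.int(model$xmin, xi - 1)
        max(0, 1 - sum(stats::dlnorm(ks, model$mu, model$sigma)) / Z)
      }, numeric(1))
    })
}

#' @rdname model_pmf
#' @export
model_cdf <- function(model, x) {
  xp <- x + 1L
  .check_support(model, x)
  1 - switch(model$family,
    power_law   = hurwitz_zeta(model$alpha, xp) / .model_normalizer(model),
    exponential = exp(-model$rate * (xp - model$xmin)),
    lognormal   = model_surv(model, xp))
}

.check_support <- function(model, x) {
  if (length(x) == 0L) return(invisible(NULL))
  if (any(x != floor(x)) || any(x < model$xmin))
    stop(sprintf("'x' must be integers >= xmin = %d", model$xmin), call. = FALSE)
  invisible(NULL)
}

#' @rdname model_pmf
#' @param n number of draws.
#' @details Sampling is exact inverse-CDF on the integer support: draws
#'   falling inside a precomputed CDF table are resolved by table lookup,
#'   and draws beyond it by doubling search then bisection on the survival
#'   function, so no continuous approximation or upper truncation is
#'   involved for the heavy-tailed families.
#' @export
model_rand <- function(model, n) {
  stopifnot(n >= 0)
  n <- as.integer(n)
  if (n == 0L) return(integer(0))
  u <- stats::runif(n)
  if (model$family == "exponential") {
    # closed-form inverse CDF: S(x) = exp(-rate*(x - xmin))
    return(as.integer(model$xmin + floor(log1p(-u) / -model$rate)))
  }
  cap <- model$xmin + 65535L
  xs <- seq.int(model$xmin, cap)
  cdf <- cumsum(.model_kernel(model, xs)) / .model_normalizer(model)
  out <- numeric(n)
  inside <- u <= cdf[length(cdf)]
  # X = min{x : F(x) >= u}
  out[inside] <- xs[findInterval(u[inside], cdf, left.open = TRUE) + 1L]
  if (any(!inside)) {
    out[!inside] <- vapply(u[!inside], function(ui) .tail_quantile(model, ui, cap),
                           numeric(1))
  }
  if (max(out) <= .Machine$integer.max) out <- as.integer(out)
  out
}

# smallest x > cap with F(x) >= u, via doubling then bisection on surv;
# doubles, not ints: extreme quantiles of heavy tails exceed 2^31
.tail_quantile <- function(model, u, cap) {
  v <- 1 - u                       # find smallest x with surv(x + 1) <= v
  lo <- as.numeric(cap)            # F(cap) < u  =>  surv(cap + 1) > v
  hi <- 2 * lo
  while (model_surv(model, hi + 1) > v) {
    lo <- hi
    hi <- 2 * hi
  }
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (model_surv(model, mid + 1) > v) lo <- mid else hi <- mid
  }
  hi
}
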
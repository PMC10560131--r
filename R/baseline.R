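#' Parametric baseline hazard families
#'
#' Constructor for the baseline time-to-event distribution used inside the
#' general hazard structure. The default family is the power generalized
#' Weibull (PGW), a three-parameter distribution whose hazard can be
#' increasing, decreasing, unimodal or bathtub-shaped. Two simpler
#' two-parameter families are available: log-normal (unimodal hazard) and
#' log-logistic.
#'
#' The PGW parametrization used throughout is
#' \deqn{S_0(t) = \exp\{1 - [1 + (t/\sigma)^\nu]^{1/\gamma}\},}
#' so the cumulative hazard is \eqn{H_0(t) = [1 + (t/\sigma)^\nu]^{1/\gamma} - 1}
#' and the quantile function is
#' \eqn{F_0^{-1}(u) = \sigma\,[(1 - \log(1-u))^\gamma - 1]^{1/\nu}}.
#' With \eqn{\nu = \gamma = 1} the family collapses to an exponential
#' distribution with rate \eqn{1/\sigma}.
#'
#' For the log-normal family, \code{sigma} is the median time scale
#' (\code{meanlog = log(sigma)}) and \code{nu} the log-scale standard
#' deviation. For the log-logistic family, \eqn{S_0(t) = 1/(1+(t/\sigma)^\nu)}.
#'
#' @param family one of \code{"pgw"}, \code{"lognormal"}, \code{"loglogistic"}.
#' @param sigma positive scale parameter (time units, years).
#' @param nu positive shape parameter.
#' @param gamma positive second shape parameter; only used by \code{"pgw"}.
#' @return An object of class \code{baseline_params}.
#' @examples
#' bp <- baseline_params("pgw", sigma = 0.75, nu = 1.75, gamma = 8)
#' hazard(bp, c(0.5, 1, 2))
#' cum_hazard(bp, 1)
#' inv_cdf(bp, 0.5)
#' @export
baseline_params <- function(family = c("pgw", "lognormal", "loglogistic"),
                            sigma, nu, gamma = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, is.finite(sigma),
            is.numeric(nu), length(nu) == 1L, is.finite(nu))
  if (sigma <= 0) stop("'sigma' must be positive")
  if (nu <= 0) stop("'nu' must be positive")
  if (family == "pgw") {
    if (is.null(gamma)) stop("the PGW family needs a third parameter 'gamma'")
    stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
    if (gamma <= 0) stop("'gamma' must be positive")
  } else {
    gamma <- NULL
  }
  structure(list(family = family, sigma = sigma, nu = nu, gamma = gamma),
            class = "baseline_params")
}

#' @export
print.baseline_params <- function(x, ...) {
  cat("Baseline hazard family:", x$family, "\n")
  cat("  sigma =", x$sigma, " nu =", x$nu)
  if (!is.null(x$gamma)) cat("  gamma =", x$gamma)
  cat("\n")
  invisible(x)
}

#' Number of parameters of a baseline family
#' @param p a \code{baseline_params} object.
#' @return 2 or 3.
#' @keywords internal
n_baseline_params <- function(p) if (p$family == "pgw") 3L else 2L

check_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t))) stop("'t' must be finite numeric")
  if (any(t < 0)) stop("'t' must be nonnegative")
  invisible(t)
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  out <- x
  small <- x <= 33
  out[small] <- log1p(exp(x[small]))
  out
}

#' Hazard function
#'
#' Generic for the hazard function \eqn{h(t)} of a model object.
#' @param object a model object (e.g. \code{baseline_params}).
#' @param t nonnegative vector of times (years).
#' @param ... passed to methods.
#' @return Nonnegative hazard values, recycled over \code{t}.
#' @export
hazard <- function(object, t, ...) UseMethod("hazard")

#' Cumulative hazard function
#'
#' Generic for the cumulative hazard \eqn{H(t) = -\log S(t)}.
#' @inheritParams hazard
#' @return Nonnegative, nondecreasing values; \eqn{H(0) = 0}.
#' @export
cum_hazard <- function(object, t, ...) UseMethod("cum_hazard")

#' Quantile (inverse CDF) function
#'
#' Generic for the inverse cumulative distribution function of an event-time
#' model, the primitive behind inverse-transform simulation.
#' @param object a model object.
#' @param u vector of probabilities in \eqn{[0, 1)}.
#' @param ... passed to methods.
#' @return Times \eqn{t} with \eqn{F(t) = u}; strictly increasing in \code{u}.
#' @export
inv_cdf <- function(object, u, ...) UseMethod("inv_cdf")

#' @rdname hazard
#' @export
hazard.baseline_params <- function(object, t, ...) {
  check_time(t)
  p <- object
  switch(p$family,
    pgw = {
      out <- numeric(length(t))
      pos <- t > 0
      if (any(!pos)) {
        # analytic limit at the origin: 0 for nu > 1, finite for nu = 1
        if (p$nu > 1) out[!pos] <- 0
        else if (p$nu == 1) out[!pos] <- 1 / (p$sigma * p$gamma)
        else stop("PGW hazard diverges at t = 0 when nu < 1")
      }
      if (any(pos)) {
        lq <- p$nu * (log(t[pos]) - log(p$sigma))
        lR <- log1pexp(lq)                     # log(1 + (t/sigma)^nu)
        lh <- log(p$nu) - log(p$gamma) - log(p$sigma) +
          (p$nu - 1) * (log(t[pos]) - log(p$sigma)) + (1 / p$gamma - 1) * lR
        out[pos] <- exp(lh)
      }
      out
    },
    lognormal = {
      d <- stats::dlnorm(t, meanlog = log(p$sigma), sdlog = p$nu)
      s <- stats::plnorm(t, meanlog = log(p$sigma), sdlog = p$nu,
                         lower.tail = FALSE)
      ifelse(t == 0, 0, d / s)
    },
    loglogistic = {
      out <- numeric(length(t))
      pos <- t > 0
      if (any(!pos)) {
        if (p$nu > 1) out[!pos] <- 0
        else if (p$nu == 1) out[!pos] <- 1 / p$sigma
        else stop("log-logistic hazard diverges at t = 0 when nu < 1")
      }
      if (any(pos)) {
        lq <- p$nu * (log(t[pos]) - log(p$sigma))
        out[pos] <- exp(log(p$nu) - log(p$sigma) +
                          (p$nu - 1) * (log(t[pos]) - log(p$sigma)) -
                          log1pexp(lq))
      }
      out
    })
}

#' @rdname cum_hazard
#' @export
cum_hazard.baseline_params <- function(object, t, ...) {
  check_time(t)
  p <- object
  out <- numeric(length(t))
  pos <- t > 0
  if (!any(pos)) return(out)
  lq <- p$nu * (log(t[pos]) - log(p$sigma))
  out[pos] <- switch(p$family,
    pgw = expm1(log1pexp(lq) / p$gamma),
    lognormal = -stats::plnorm(t[pos], meanlog = log(p$sigma), sdlog = p$nu,
                               lower.tail = FALSE, log.p = TRUE),
    loglogistic = log1pexp(lq))
  out
}

#' @rdname inv_cdf
#' @export
inv_cdf.baseline_params <- function(object, u, ...) {
  if (!is.numeric(u) || any(!is.finite(u)) || any(u < 0) || any(u >= 1))
    stop("'u' must lie in [0, 1)")
  p <- object
  switch(p$family,
    pgw = p$sigma * expm1(p$gamma * log1p(-log1p(-u)))^(1 / p$nu),
    lognormal = stats::qlnorm(u, meanlog = log(p$sigma), sdlog = p$nu),
    loglogistic = p$sigma * (u / (1 - u))^(1 / p$nu))
}

#' Invert a cumulative hazard value
#'
#' Solves \eqn{H_0(t) = H} for \eqn{t}; the quantile function on the
#' cumulative-hazard scale (\eqn{H = -\log(1-u)}).
#' @param p a \code{baseline_params} object.
#' @param H nonnegative cumulative hazard values.
#' @return Times with \code{cum_hazard(p, t) == H}.
#' @keywords internal
inv_cum_hazard <- function(p, H) {
  if (any(H < 0)) stop("'H' must be nonnegative")
  switch(p$family,
    pgw = p$sigma * expm1(p$gamma * log1p(H))^(1 / p$nu),
    lognormal = stats::qlnorm(-H, meanlog = log(p$sigma), sdlog = p$nu,
                              lower.tail = FALSE, log.p = TRUE),
    loglogistic = p$sigma * expm1(H)^(1 / p$nu))
}

#' Serialize baseline parameters to a key-value list
#' @param p a \code{baseline_params} object.
#' @return A named list (family, sigma, nu, and gamma when present).
#' @export
baseline_to_list <- function(p) {
  stopifnot(inherits(p, "baseline_params"))
  out <- list(family = p$family, sigma = p$sigma, nu = p$nu)
  if (!is.null(p$gamma)) out$gamma <- p$gamma
  out
}

#' Deserialize baseline parameters from a key-value list
#' @param x a named list as produced by \code{\link{baseline_to_list}}.
#' @return A \code{baseline_params} object.
#' @export
baseline_from_list <- function(x) {
  baseline_params(x$family, sigma = as.numeric(x$sigma), nu = as.numeric(x$nu),
                  gamma = if (!is.null(x$gamma)) as.numeric(x$gamma))
}
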
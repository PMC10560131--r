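#' Frailty distribution specification
#'
#' Describes the distribution of the individual frailty \eqn{\lambda}, a
#' positive random multiplier on the excess hazard with mean fixed at 1 for
#' identifiability, so the single parameter \code{b} is the frailty variance
#' and indexes the amount of unobserved heterogeneity.
#'
#' @param family \code{"none"} (degenerate at 1, classical model),
#'   \code{"gamma"} or \code{"inverse_gaussian"}.
#' @param b nonnegative frailty variance; ignored for \code{family = "none"}.
#' @return An object of class \code{frailty_spec}.
#' @examples
#' f <- frailty_spec("gamma", b = 0.5)
#' laplace_transform(f, 1)
#' marginal_net_survival(f, HE = 1)
#' @export
frailty_spec <- function(family = c("none", "gamma", "inverse_gaussian"),
                         b = 0) {
  family <- match.arg(family)
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b))
  if (b < 0) stop("'b' must be nonnegative")
  if (family == "none") b <- 0
  structure(list(family = family, b = b), class = "frailty_spec")
}

#' @export
print.frailty_spec <- function(x, ...) {
  if (x$family == "none") cat("No frailty (classical model)\n")
  else cat("Frailty: ", x$family, ", unit mean, variance b = ", x$b, "\n",
           sep = "")
  invisible(x)
}

#' Laplace transform of the frailty distribution
#'
#' \eqn{\mathcal{L}_G(s) = E[e^{-s\lambda}]} for the unit-mean frailty
#' distribution \eqn{G}. Closed forms: gamma
#' \eqn{(1+bs)^{-1/b}}; inverse Gaussian
#' \eqn{\exp\{(1 - \sqrt{1+2bs})/b\}}; no frailty \eqn{e^{-s}}.
#' For \eqn{b < 10^{-8}} the continuity limit \eqn{e^{-s}} is used.
#'
#' @param f a \code{\link{frailty_spec}}.
#' @param s nonnegative argument vector.
#' @return Values in \eqn{(0, 1]}; \eqn{\mathcal{L}_G(0) = 1}, strictly
#'   decreasing and log-convex in \code{s}.
#' @export
laplace_transform <- function(f, s) {
  stopifnot(inherits(f, "frailty_spec"))
  if (any(!is.finite(s)) || any(s < 0)) stop("'s' must be nonnegative")
  b <- f$b
  if (f$family == "none" || b < 1e-8) return(exp(-s))
  switch(f$family,
    gamma = exp(-log1p(b * s) / b),
    inverse_gaussian = exp((1 - sqrt(1 + 2 * b * s)) / b))
}

#' Marginal (frailty-corrected) net survival
#'
#' Net survival marginalized over the frailty distribution but conditional on
#' the covariates: \eqn{\tilde S_N = \mathcal{L}_G\{H_E\}}. For the gamma
#' frailty this is \eqn{(1 + b H_E)^{-1/b}}; as \eqn{b \to 0} it converges to
#' the classical net survival \eqn{e^{-H_E}}.
#'
#' @param f a \code{\link{frailty_spec}}.
#' @param HE nonnegative cumulative excess hazard values.
#' @return Survival probabilities in \eqn{(0, 1]}.
#' @export
marginal_net_survival <- function(f, HE) {
  if (any(!is.finite(HE)) || any(HE < 0)) stop("'HE' must be nonnegative")
  laplace_transform(f, HE)
}

#' Time-dependent frailty weight on the excess hazard
#'
#' The factor \eqn{\omega = -\mathcal{L}_G'\{H_E\}/\mathcal{L}_G\{H_E\}}
#' multiplying the excess hazard in the marginal observed hazard; it equals
#' the conditional frailty mean \eqn{E[\lambda \mid T_o \ge t]} among
#' survivors, so it quantifies the progressive selection of healthier
#' individuals. Gamma: \eqn{1/(1+bH_E)}; inverse Gaussian:
#' \eqn{1/\sqrt{1+2bH_E}}; 1 when there is no frailty.
#'
#' @inheritParams marginal_net_survival
#' @return Weights in \eqn{(0, 1]}; 1 iff \eqn{b = 0} or \eqn{H_E = 0}.
#' @export
frailty_weight <- function(f, HE) {
  stopifnot(inherits(f, "frailty_spec"))
  if (any(!is.finite(HE)) || any(HE < 0)) stop("'HE' must be nonnegative")
  b <- f$b
  if (f$family == "none" || b == 0) return(rep(1, length(HE)))
  switch(f$family,
    gamma = 1 / (1 + b * HE),
    inverse_gaussian = 1 / sqrt(1 + 2 * b * HE))
}

#' Marginal observed survival combining background and excess mortality
#'
#' The all-cause survival of an individual diagnosed at a given age and year,
#' after integrating out the frailty:
#' \deqn{\tilde S(t;x) = \exp\{-[H_P(\mathrm{age}+t) - H_P(\mathrm{age})]\}\,
#'   \mathcal{L}_G\{H_E(t;x)\},}
#' the product of the expected population survival ratio (from the life table)
#' and the marginal net survival.
#'
#' @param f a \code{\link{frailty_spec}}.
#' @param m a \code{\link{gh_model}} for the excess hazard.
#' @param lt a \code{\link{life_table}}.
#' @param t nonnegative follow-up times (years).
#' @param x covariate vector or matrix for the excess hazard.
#' @param age age at diagnosis (years).
#' @param year calendar year of diagnosis.
#' @param strata life-table stratum label(s).
#' @return Survival probabilities in \eqn{(0, 1]}, nonincreasing in \code{t}.
#' @export
marginal_observed_survival <- function(f, m, lt, t, x, age, year,
                                       strata = NULL) {
  HPd <- pop_cum_hazard_increment(lt, age, year, strata, t)
  HE <- excess_cum_hazard(m, t, x)
  exp(-HPd) * marginal_net_survival(f, HE)
}

#' Marginal observed hazard combining background and excess mortality
#'
#' The all-cause hazard after integrating out the frailty:
#' \deqn{\tilde h(t;x) = h_P(\mathrm{age}+t) + \omega(t;x,b)\, h_E(t;x),}
#' with the selection weight \eqn{\omega} of \code{\link{frailty_weight}}.
#'
#' @inheritParams marginal_observed_survival
#' @return Nonnegative hazard values, at least the population rate.
#' @export
marginal_observed_hazard <- function(f, m, lt, t, x, age, year,
                                     strata = NULL) {
  hP <- pop_hazard(lt, age + t, year + t, strata)
  hE <- excess_hazard(m, t, x)
  HE <- excess_cum_hazard(m, t, x)
  hP + frailty_weight(f, HE) * hE
}
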
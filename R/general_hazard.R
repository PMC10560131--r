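#' General hazard model for the excess hazard
#'
#' Builds the general hazard (GH) structure
#' \deqn{h_E(t; x) = h_0(t\,e^{w^\top\alpha})\, e^{x^\top\beta},}
#' where \eqn{x} is the full covariate vector acting at the hazard level and
#' \eqn{w \subseteq x} the subset acting on the time scale. The structure nests
#' proportional hazards (\eqn{\alpha = 0}), accelerated hazards
#' (\eqn{\beta = 0}) and accelerated failure time
#' (\eqn{\alpha = \beta,\ w = x}).
#'
#' @param baseline a \code{\link{baseline_params}} object.
#' @param alpha numeric vector of time-level effects (possibly length 0).
#' @param beta numeric vector of hazard-level effects.
#' @param time_covariate_index integer indices into the columns of the
#'   covariate matrix selecting \eqn{w}; defaults to the first
#'   \code{length(alpha)} columns.
#' @return An object of class \code{gh_model}.
#' @examples
#' bp <- baseline_params("pgw", 0.75, 1.75, 8)
#' m <- gh_model(bp, alpha = c(0.5, 0.2), beta = c(1, 0.3),
#'               time_covariate_index = 1:2)
#' excess_hazard(m, t = 1, x = c(0.1, 1))
#' @export
gh_model <- function(baseline, alpha = numeric(0), beta,
                     time_covariate_index = seq_along(alpha)) {
  stopifnot(inherits(baseline, "baseline_params"), is.numeric(beta))
  alpha <- as.numeric(alpha)
  beta <- as.numeric(beta)
  time_covariate_index <- as.integer(time_covariate_index)
  if (length(alpha) != length(time_covariate_index))
    stop("'alpha' and 'time_covariate_index' must have the same length")
  if (length(time_covariate_index) &&
      (any(time_covariate_index < 1) ||
       any(time_covariate_index > length(beta))))
    stop("'time_covariate_index' must select columns of the covariate matrix")
  if (anyDuplicated(time_covariate_index))
    stop("duplicated indices in 'time_covariate_index'")
  structure(list(baseline = baseline, alpha = alpha, beta = beta,
                 time_covariate_index = time_covariate_index),
            class = "gh_model")
}

#' @rdname gh_model
#' @details \code{gh_ph}, \code{gh_aft} and \code{gh_ah} build the three nested
#'   special cases: proportional hazards, accelerated failure time and
#'   accelerated hazards.
#' @export
gh_ph <- function(baseline, beta)
  gh_model(baseline, alpha = numeric(0), beta = beta,
           time_covariate_index = integer(0))

#' @rdname gh_model
#' @export
gh_aft <- function(baseline, alpha)
  gh_model(baseline, alpha = alpha, beta = alpha,
           time_covariate_index = seq_along(alpha))

#' @rdname gh_model
#' @export
gh_ah <- function(baseline, alpha,
                  time_covariate_index = seq_along(alpha))
  gh_model(baseline, alpha = alpha, beta = rep(0, max(time_covariate_index)),
           time_covariate_index = time_covariate_index)

#' @export
print.gh_model <- function(x, ...) {
  structure_name <- if (!length(x$alpha) || all(x$alpha == 0)) "PH"
    else if (all(x$beta == 0)) "AH"
    else if (length(x$alpha) == length(x$beta) &&
             isTRUE(all.equal(x$alpha, x$beta)) &&
             identical(x$time_covariate_index, seq_along(x$beta))) "AFT"
    else "GH"
  cat("General hazard model (", structure_name, " structure)\n", sep = "")
  print(x$baseline)
  cat("  alpha:", format(x$alpha), "\n")
  cat("  beta: ", format(x$beta), "\n")
  invisible(x)
}

# coerce x to an n-by-p matrix matching the model dimension
as_cov_matrix <- function(m, x) {
  p <- length(m$beta)
  if (is.null(dim(x))) {
    if (length(x) != p && !(p == 0 && length(x) == 0))
      stop("covariate vector has length ", length(x), ", expected ", p)
    x <- matrix(x, nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != p)
    stop("covariate matrix has ", ncol(x), " columns, expected ", p)
  x
}

# linear predictors: A = w'alpha (time level), B = x'beta (hazard level)
gh_linpred <- function(m, x) {
  x <- as_cov_matrix(m, x)
  A <- if (length(m$alpha))
    drop(x[, m$time_covariate_index, drop = FALSE] %*% m$alpha)
  else rep(0, nrow(x))
  B <- if (length(m$beta)) drop(x %*% m$beta) else rep(0, nrow(x))
  list(A = A, B = B, n = nrow(x))
}

#' Excess hazard of a general hazard model
#'
#' Evaluates \eqn{h_E(t; x) = h_0(t\,e^{w^\top\alpha})\,e^{x^\top\beta}}.
#' \code{t} and the rows of \code{x} are recycled to a common length.
#'
#' @param m a \code{gh_model}.
#' @param t nonnegative times (years).
#' @param x covariate vector or matrix (rows = individuals).
#' @return Nonnegative excess hazard values.
#' @export
excess_hazard <- function(m, t, x) {
  stopifnot(inherits(m, "gh_model"))
  check_time(t)
  lp <- gh_linpred(m, x)
  hazard(m$baseline, t * exp(lp$A)) * exp(lp$B)
}

#' Cumulative excess hazard of a general hazard model
#'
#' Evaluates
#' \eqn{H_E(t; x) = H_0(t\,e^{w^\top\alpha})\,e^{x^\top\beta - w^\top\alpha}}.
#'
#' @inheritParams excess_hazard
#' @return Nonnegative, nondecreasing in \code{t}, \eqn{H_E(0)=0}.
#' @export
excess_cum_hazard <- function(m, t, x) {
  stopifnot(inherits(m, "gh_model"))
  check_time(t)
  lp <- gh_linpred(m, x)
  cum_hazard(m$baseline, t * exp(lp$A)) * exp(lp$B - lp$A)
}

#' Simulate event times from a general hazard model by exact inversion
#'
#' Inverse-transform simulation of excess-hazard event times, optionally with
#' an individual frailty multiplier \eqn{\lambda} on the excess hazard:
#' \deqn{t = F_0^{-1}\!\big(1 - \exp\{\log(1-u)\,
#'   e^{w^\top\alpha - x^\top\beta}/\lambda\}\big)\, e^{-w^\top\alpha},}
#' so the returned time satisfies
#' \eqn{\lambda\,H_E(t;x) = -\log(1-u)} exactly.
#'
#' @param m a \code{gh_model}.
#' @param x covariate vector or matrix.
#' @param u uniform draws in \eqn{[0,1)}.
#' @param frailty positive frailty multipliers (default 1, no frailty).
#' @return Simulated event times (years).
#' @export
simulate_event_time <- function(m, x, u, frailty = 1) {
  stopifnot(inherits(m, "gh_model"))
  if (any(!is.finite(u)) || any(u < 0) || any(u >= 1))
    stop("'u' must lie in [0, 1)")
  if (any(frailty <= 0)) stop("'frailty' must be positive")
  lp <- gh_linpred(m, x)
  # target cumulative baseline hazard at the warped time scale
  H <- -log1p(-u) * exp(lp$A - lp$B) / frailty
  inv_cum_hazard(m$baseline, H) * exp(-lp$A)
}
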
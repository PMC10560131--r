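# population (average) net survival values over the rows of Xh
pop_net_surv_values <- function(m, f, Xh, t_grid) {
  lp <- gh_linpred(m, Xh)
  vapply(t_grid, function(tt) {
    HE <- cum_hazard(m$baseline, tt * exp(lp$A)) * exp(lp$B - lp$A)
    mean(marginal_net_survival(f, HE))
  }, numeric(1))
}

#' Net survival curve for a single covariate profile
#'
#' The net survival of an individual with covariates \code{x}: the classical
#' \eqn{S_N(t;x) = e^{-H_E(t;x)}} for a fit (or model) without frailty, or the
#' frailty-marginalized \eqn{\tilde S_N(t;x) = \mathcal{L}_G\{H_E(t;x)\}}
#' (gamma: \eqn{(1+bH_E)^{-1/b}}) for a frailty model.
#'
#' @param object an \code{\link{fit_excess_hazard}} result, or a
#'   \code{\link{gh_model}} (then supply \code{frailty}).
#' @param x covariate vector (one profile).
#' @param t_grid increasing grid of nonnegative times (years).
#' @param frailty a \code{\link{frailty_spec}} when \code{object} is a raw
#'   model; ignored for fits.
#' @return A data frame (t, estimate, variant, scope).
#' @export
individual_net_survival <- function(object, x, t_grid,
                                    frailty = frailty_spec("none")) {
  if (inherits(object, "eh_fit")) {
    m <- gh_from_fit(object); f <- frailty_from_fit(object)
  } else {
    m <- object; f <- frailty
  }
  stopifnot(inherits(m, "gh_model"), inherits(f, "frailty_spec"))
  if (is.unsorted(t_grid, strictly = FALSE)) stop("'t_grid' must be increasing")
  HE <- vapply(t_grid, function(tt) excess_cum_hazard(m, tt, x), numeric(1))
  data.frame(t = t_grid, estimate = marginal_net_survival(f, HE),
             variant = if (f$family == "none") "classical"
             else "frailty_marginal",
             scope = "individual")
}

#' Population and subgroup net survival curves
#'
#' Averages the individual net survival curves over the rows of \code{data}
#' (the plug-in population net survival), optionally within subgroups defined
#' by a stratifying column.
#'
#' @param object an \code{eh_fit}, or a \code{\link{gh_model}} (then supply
#'   \code{frailty}).
#' @param data data frame holding the covariate columns of the model.
#' @param t_grid increasing grid of times (years); default 0 to 5 by 0.05,
#'   the usual 5-year study horizon.
#' @param by optional name of a column of \code{data} defining subgroups; a
#'   curve is returned per level plus nothing else (use \code{by = NULL} for
#'   the whole-population curve).
#' @param frailty a \code{\link{frailty_spec}} for raw models.
#' @return A data frame (t, estimate, variant, scope, group).
#' @export
population_net_survival <- function(object, data,
                                    t_grid = seq(0, 5, by = 0.05),
                                    by = NULL,
                                    frailty = frailty_spec("none")) {
  if (inherits(object, "eh_fit")) {
    m <- gh_from_fit(object); f <- frailty_from_fit(object)
    covs <- object$hazard_covs
  } else {
    m <- object; f <- frailty
    covs <- NULL
  }
  stopifnot(inherits(m, "gh_model"), inherits(f, "frailty_spec"))
  if (is.unsorted(t_grid, strictly = FALSE)) stop("'t_grid' must be increasing")
  Xall <- if (!is.null(covs)) as.matrix(data[covs]) else as.matrix(data)
  variant <- if (f$family == "none") "classical" else "frailty_marginal"
  one <- function(X, group, scope) {
    if (!nrow(X)) stop("empty subgroup: ", group)
    data.frame(t = t_grid, estimate = pop_net_surv_values(m, f, X, t_grid),
               variant = variant, scope = scope, group = group)
  }
  if (is.null(by)) return(one(Xall, "population", "population"))
  g <- data[[by]]
  if (is.null(g)) stop("column '", by, "' not found")
  do.call(rbind, lapply(sort(unique(g)), function(lev)
    one(Xall[g == lev, , drop = FALSE], paste0(by, "=", lev), "subgroup")))
}
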
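# ---- internal: data preparation -------------------------------------------

# Assemble the fixed per-observation quantities used by the likelihood:
# design matrices, event indicator and the background rate at the observed
# time. The background rate is the only life-table quantity entering the
# likelihood (the cumulative population term is parameter-free and drops out
# of the proportional likelihood), so it is computed once, before
# optimization.
make_likelihood_data <- function(data, lt, hazard_covs, time_covs,
                                 strata_col = "strata") {
  stopifnot(is.data.frame(data))
  need <- c("time", "status", "age", "year", hazard_covs)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns in 'data': ",
                         paste(miss, collapse = ", "))
  if (!all(time_covs %in% hazard_covs))
    stop("time-level covariates must be a subset of hazard-level covariates")
  if (any(data$time <= 0)) stop("all observed times must be positive")
  if (!all(data$status %in% c(0, 1))) stop("'status' must be 0/1")
  strata <- if (strata_col %in% names(data)) data[[strata_col]] else NULL
  Xh <- as.matrix(data[hazard_covs])
  storage.mode(Xh) <- "double"
  tidx <- match(time_covs, hazard_covs)
  list(time = as.numeric(data$time), status = as.numeric(data$status),
       Xh = Xh, tidx = tidx,
       hP = pop_hazard(lt, data$age + data$time, data$year + data$time,
                       strata),
       n = nrow(data), n_events = sum(data$status),
       hazard_covs = hazard_covs, time_covs = time_covs,
       fingerprint = c(nrow(data), sum(data$status),
                       signif(sum(data$time), 12)))
}

# ---- internal: transformed parameter vector --------------------------------

# Optimization runs on an unconstrained scale: log(sigma), log(nu),
# log(gamma), raw alpha and beta, log(b). Positivity constraints vanish and
# Wald intervals for positive parameters are formed on the log scale.
par_names <- function(family, time_covs, hazard_covs, frailty) {
  nb <- if (family == "pgw") c("log(sigma)", "log(nu)", "log(gamma)")
  else c("log(sigma)", "log(nu)")
  c(nb,
    if (length(time_covs)) paste0("alpha:", time_covs),
    paste0("beta:", hazard_covs),
    if (frailty) "log(b)")
}

pack_params <- function(psi, family, pt, p, frailty) {
  th <- if (family == "pgw")
    log(c(psi$baseline$sigma, psi$baseline$nu, psi$baseline$gamma))
  else log(c(psi$baseline$sigma, psi$baseline$nu))
  c(th, psi$alpha, psi$beta, if (frailty) log(psi$b))
}

unpack_params <- function(par, family, pt, p, frailty) {
  nb <- if (family == "pgw") 3L else 2L
  baseline <- if (family == "pgw")
    baseline_params("pgw", exp(par[1]), exp(par[2]), exp(par[3]))
  else baseline_params(family, exp(par[1]), exp(par[2]))
  alpha <- if (pt) par[nb + seq_len(pt)] else numeric(0)
  beta <- par[nb + pt + seq_len(p)]
  b <- if (frailty) exp(par[nb + pt + p + 1L]) else NULL
  list(baseline = baseline, alpha = alpha, beta = beta, b = b)
}

# ---- internal: log-likelihood core (PGW, vectorized, analytic gradient) ----

# Returns list(loglik, grad) on the transformed scale; grad is NULL when
# want_grad is FALSE or the family is not PGW.
loglik_core <- function(par, ld, family, frailty, want_grad = FALSE) {
  pt <- length(ld$tidx); p <- ncol(ld$Xh)
  nb <- if (family == "pgw") 3L else 2L
  psi <- unpack_params(par, family, pt, p, frailty)
  A <- if (pt) drop(ld$Xh[, ld$tidx, drop = FALSE] %*% psi$alpha)
  else numeric(ld$n)
  B <- drop(ld$Xh %*% psi$beta)
  delta <- ld$status; hP <- ld$hP

  if (family == "pgw") {
    sg <- psi$baseline$sigma; nu <- psi$baseline$nu; gm <- psi$baseline$gamma
    ls <- log(ld$time) + A
    lq <- nu * (ls - log(sg))
    lR <- log1pexp(lq)
    lP <- lR / gm
    H0 <- expm1(lP)
    lh0 <- log(nu) - log(gm) - log(sg) + (nu - 1) * (ls - log(sg)) +
      (1 / gm - 1) * lR
    eBA <- exp(B - A)
    HE <- H0 * eBA
    hE <- exp(lh0 + B)
  } else {
    warped <- ld$time * exp(A)
    H0 <- cum_hazard(psi$baseline, warped)
    hE <- hazard(psi$baseline, warped) * exp(B)
    eBA <- exp(B - A)
    HE <- H0 * eBA
  }
  if (any(!is.finite(HE)) || any(!is.finite(hE)))
    return(list(loglik = -Inf, grad = NULL))

  if (frailty) {
    b <- psi$b
    om <- 1 / (1 + b * HE)
    D <- hP + hE * om
    ll <- sum(delta * log(D)) - sum(log1p(b * HE)) / b
  } else {
    D <- hP + hE
    ll <- sum(delta * log(D)) - sum(HE)
  }
  if (!is.finite(ll)) return(list(loglik = -Inf, grad = NULL))
  if (!want_grad || family != "pgw") return(list(loglik = ll, grad = NULL))

  # analytic gradient on the transformed scale
  qR <- exp(lq - lR)                 # q / (1 + q), in (0, 1)
  P <- H0 + 1
  PqR <- P * nu * qR / gm
  # d H0 / d {log sigma, log nu, log gamma, A}
  dH0_ls <- -PqR
  dH0_ln <- P * qR * lq / gm
  dH0_lg <- -P * lR / gm
  dH0_A <- PqR
  # d log h0 / d {log sigma, log nu, log gamma, A}
  cg <- (1 / gm - 1)
  dlh0_ls <- -nu - cg * nu * qR
  dlh0_ln <- 1 + lq + cg * qR * lq
  dlh0_lg <- -1 - lR / gm
  dlh0_A <- (nu - 1) + cg * nu * qR

  if (frailty) {
    u1 <- delta * om / D
    u2 <- -delta * hE * om^2 * b / D - om
  } else {
    u1 <- delta / D
    u2 <- rep(-1, ld$n)
  }
  # dHE/dtheta = eBA * dH0/dtheta ; dHE/dalpha_j = w_j (eBA*dH0/dA - HE)
  g <- numeric(length(par))
  g[1] <- sum(u1 * hE * dlh0_ls + u2 * eBA * dH0_ls)
  g[2] <- sum(u1 * hE * dlh0_ln + u2 * eBA * dH0_ln)
  g[3] <- sum(u1 * hE * dlh0_lg + u2 * eBA * dH0_lg)
  if (pt) {
    wA <- u1 * hE * dlh0_A + u2 * (eBA * dH0_A - HE)
    g[nb + seq_len(pt)] <- drop(crossprod(ld$Xh[, ld$tidx, drop = FALSE], wA))
  }
  wB <- u1 * hE + u2 * HE
  g[nb + pt + seq_len(p)] <- drop(crossprod(ld$Xh, wB))
  if (frailty) {
    bHE <- b * HE
    g[nb + pt + p + 1L] <- sum(-delta * hE * om^2 * bHE / D) +
      sum(log1p(bHE) - bHE * om) / b
  }
  if (any(!is.finite(g))) g <- NULL
  list(loglik = ll, grad = g)
}

# objective/gradient pair with a one-slot cache (nlminb asks for them
# separately at the same point)
make_objective <- function(ld, family, frailty) {
  use_grad <- family == "pgw"
  cache_par <- NULL; cache_val <- NULL
  evalc <- function(par) {
    if (!is.null(cache_par) && identical(par, cache_par)) return(cache_val)
    v <- loglik_core(par, ld, family, frailty, want_grad = use_grad)
    cache_par <<- par; cache_val <<- v
    v
  }
  list(
    fn = function(par) {
      v <- evalc(par)
      if (!is.finite(v$loglik)) 1e10 else -v$loglik
    },
    gr = if (use_grad) function(par) {
      v <- evalc(par)
      if (is.null(v$grad)) rep(0, length(par)) else -v$grad
    },
    loglik = function(par) loglik_core(par, ld, family, frailty)$loglik)
}

# ---- exported log-likelihoods ---------------------------------------------

#' Log-likelihood of the frailty excess hazard model
#'
#' The marginal log-likelihood of the gamma-frailty excess hazard model,
#' \deqn{\sum_i \delta_i \log\!\Big(h_{P,i} + \frac{h_{E,i}}{1+bH_{E,i}}\Big)
#'   - \frac{1}{b}\sum_i \log(1 + b H_{E,i}),}
#' where the parameter-free population survival factor is dropped
#' (the likelihood is defined up to proportionality). As \eqn{b \to 0} it
#' converges to \code{\link{loglik_classical}}.
#'
#' @param psi parameter list with elements \code{baseline}
#'   (a \code{\link{baseline_params}}), \code{alpha}, \code{beta} and
#'   \code{b} (frailty variance, \eqn{> 0}).
#' @param data data frame with columns \code{time}, \code{status}, \code{age},
#'   \code{year}, optionally \code{strata}, and the covariates.
#' @param lt a \code{\link{life_table}}.
#' @param hazard_covs names of hazard-level covariate columns.
#' @param time_covs names of time-level covariate columns (subset of
#'   \code{hazard_covs}).
#' @return The log-likelihood value (\code{-Inf} if not finite).
#' @export
loglik_frailty <- function(psi, data, lt, hazard_covs, time_covs = NULL) {
  ld <- make_likelihood_data(data, lt, hazard_covs, time_covs)
  par <- pack_params(psi, psi$baseline$family, length(time_covs),
                     length(hazard_covs), frailty = TRUE)
  loglik_core(par, ld, psi$baseline$family, frailty = TRUE)$loglik
}

#' Log-likelihood of the classical excess hazard model
#'
#' \deqn{\sum_i \delta_i \log(h_{P,i} + h_{E,i}) - \sum_i H_{E,i},}
#' again up to the parameter-free population survival factor.
#'
#' @inheritParams loglik_frailty
#' @export
loglik_classical <- function(psi, data, lt, hazard_covs, time_covs = NULL) {
  ld <- make_likelihood_data(data, lt, hazard_covs, time_covs)
  par <- pack_params(psi, psi$baseline$family, length(time_covs),
                     length(hazard_covs), frailty = FALSE)
  loglik_core(par, ld, psi$baseline$family, frailty = FALSE)$loglik
}

# ---- fitting ---------------------------------------------------------------

#' Fit an excess hazard model by maximum likelihood
#'
#' Fits the classical or gamma-frailty general hazard excess hazard model to
#' individual-level data against life-table background mortality. Optimization
#' (via \code{\link[stats]{nlminb}}) runs on an unconstrained scale
#' (log-transformed positive parameters); standard errors come from the
#' numerical Hessian of the log-likelihood on that scale, and Wald confidence
#' intervals for positive parameters are formed on the log scale and
#' exponentiated, guaranteeing positive endpoints.
#'
#' When no starting values are supplied, a classical proportional hazards
#' model (no time-level effects, no frailty) is fitted first and provides the
#' initial values: its baseline parameters and hazard-level coefficients carry
#' over, the time-level coefficients start from the corresponding
#' hazard-level estimates, and the frailty variance starts at 1.
#'
#' @inheritParams loglik_frailty
#' @param model \code{"classical"} (no frailty) or \code{"frailty"}.
#' @param baseline baseline family, \code{"pgw"}, \code{"lognormal"} or
#'   \code{"loglogistic"}.
#' @param frailty_family \code{"gamma"} or \code{"inverse_gaussian"}
#'   (gamma is the closed-form default; only gamma has an analytic
#'   marginal likelihood here).
#' @param init optional parameter list (as \code{psi} in
#'   \code{\link{loglik_frailty}}) of starting values.
#' @param level confidence level for the Wald intervals.
#' @return An object of class \code{eh_fit}: maximum likelihood estimates,
#'   log-likelihood, AIC, covariance matrix (transformed scale), a summary
#'   table with natural-scale estimates, standard errors and confidence
#'   intervals, and convergence diagnostics.
#' @examples
#' \donttest{
#' lt <- make_gompertz_life_table()
#' sc <- builtin_scenario("Sc1", n = 800)
#' d <- generate_cohort(sc, lt, seed = 1)
#' f <- fit_excess_hazard(d, lt, model = "frailty",
#'                        hazard_covs = c("agec", "sex", "X1", "X2"),
#'                        time_covs = c("agec", "sex", "X1", "X2"))
#' f
#' }
#' @export
fit_excess_hazard <- function(data, lt, model = c("classical", "frailty"),
                              baseline = c("pgw", "lognormal", "loglogistic"),
                              hazard_covs, time_covs = NULL,
                              frailty_family = "gamma",
                              init = NULL, level = 0.95) {
  model <- match.arg(model)
  baseline <- match.arg(baseline)
  if (model == "frailty" && frailty_family != "gamma")
    stop("only the gamma frailty has a closed-form marginal likelihood; ",
         "use frailty_family = 'gamma'")
  frailty <- model == "frailty"
  ld <- make_likelihood_data(data, lt, hazard_covs, time_covs)
  if (ld$n_events < 1) stop("at least one event is required")
  qrX <- qr(ld$Xh)
  if (qrX$rank < ncol(ld$Xh))
    warning("covariate matrix is not full rank; estimates may be unstable")
  pt <- length(ld$tidx); p <- ncol(ld$Xh)

  if (is.null(init)) {
    if (!frailty && pt == 0L) {
      init <- list(baseline = if (baseline == "pgw")
        baseline_params("pgw", 1, 1, 1) else baseline_params(baseline, 1, 1),
        alpha = numeric(0), beta = rep(0, p), b = NULL)
    } else {
      # initialization recipe: classical PH fit without frailty, time-level
      # effects seeded from the PH hazard-level estimates, b from 1
      ph <- fit_excess_hazard(data, lt, model = "classical",
                              baseline = baseline,
                              hazard_covs = hazard_covs, time_covs = NULL,
                              level = level)
      est <- ph$estimate
      init <- list(baseline = est$baseline,
                   alpha = if (pt) est$beta[ld$tidx] else numeric(0),
                   beta = est$beta,
                   b = if (frailty) 1 else NULL)
    }
  }
  start <- pack_params(init, baseline, pt, p, frailty)
  pn <- par_names(baseline, time_covs, hazard_covs, frailty)
  names(start) <- pn

  obj <- make_objective(ld, baseline, frailty)
  opt <- stats::nlminb(start, objective = obj$fn, gradient = obj$gr,
                       control = list(iter.max = 1000, eval.max = 2000))
  # restart from the solution, then a quasi-Newton polish: nlminb's own
  # stopping rule can leave a noticeably nonzero score
  opt2 <- stats::nlminb(opt$par, objective = obj$fn, gradient = obj$gr,
                        control = list(iter.max = 500, eval.max = 1000))
  if (opt2$objective <= opt$objective) opt <- opt2
  if (!is.null(obj$gr)) {
    pol <- tryCatch(stats::optim(opt$par, obj$fn, obj$gr, method = "BFGS",
                                 control = list(maxit = 200,
                                                reltol = 1e-14)),
                    error = function(e) NULL)
    if (!is.null(pol) && pol$value <= opt$objective) {
      opt$par <- pol$par
      opt$objective <- pol$value
    }
  }
  par <- opt$par; names(par) <- pn
  converged <- opt$convergence == 0
  reason <- opt$message

  H <- tryCatch(stats::optimHess(par, fn = obj$fn, gr = obj$gr),
                error = function(e) NULL)
  cov <- NULL; se <- rep(NA_real_, length(par))
  if (is.null(H) || any(!is.finite(H))) {
    converged <- FALSE
    reason <- paste(reason, "| non-finite Hessian")
  } else {
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(cov) || any(!is.finite(cov)) || any(diag(cov) <= 0)) {
      converged <- FALSE
      reason <- paste(reason, "| Hessian not positive definite")
      cov <- NULL
    } else {
      dimnames(cov) <- list(pn, pn)
      se <- sqrt(diag(cov))
    }
  }

  psi <- unpack_params(par, baseline, pt, p, frailty)
  names(psi$beta) <- hazard_covs
  if (pt) names(psi$alpha) <- time_covs
  loglik <- obj$loglik(par)
  k <- length(par)

  z <- stats::qnorm(1 - (1 - level) / 2)
  positive <- grepl("^log\\(", pn)
  nat <- ifelse(positive, exp(par), par)
  se_nat <- ifelse(positive, se * nat, se)   # delta method
  lower <- ifelse(positive, exp(par - z * se), par - z * se)
  upper <- ifelse(positive, exp(par + z * se), par + z * se)
  summ <- data.frame(parameter = sub("^log\\((.*)\\)$", "\\1", pn),
                     estimate = nat, se = se_nat,
                     lower = lower, upper = upper, row.names = NULL)

  structure(list(estimate = psi, par = par, loglik = loglik,
                 aic = 2 * k - 2 * loglik, k = k, cov = cov,
                 summary = summ, level = level,
                 converged = converged, message = reason,
                 n_obs = ld$n, n_events = ld$n_events,
                 model = model, baseline = baseline,
                 frailty_family = if (frailty) frailty_family else "none",
                 hazard_covs = hazard_covs, time_covs = time_covs,
                 tidx = ld$tidx, fingerprint = ld$fingerprint),
            class = "eh_fit")
}

#' @export
print.eh_fit <- function(x, digits = 4, ...) {
  cat("Excess hazard model (", x$model, ", ", x$baseline, " baseline",
      if (x$model == "frailty") paste0(", ", x$frailty_family, " frailty"),
      ")\n", sep = "")
  cat("n =", x$n_obs, " events =", x$n_events,
      " logLik =", format(x$loglik, digits = digits),
      " AIC =", format(x$aic, digits = digits), "\n")
  if (!x$converged) cat("WARNING: not converged (", x$message, ")\n")
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Extract the fitted general hazard model from a fit
#' @param fit an \code{eh_fit}.
#' @return A \code{\link{gh_model}} at the maximum likelihood estimates.
#' @export
gh_from_fit <- function(fit) {
  stopifnot(inherits(fit, "eh_fit"))
  gh_model(fit$estimate$baseline, fit$estimate$alpha, fit$estimate$beta,
           time_covariate_index = fit$tidx)
}

#' Extract the fitted frailty specification from a fit
#' @param fit an \code{eh_fit}.
#' @return A \code{\link{frailty_spec}}.
#' @export
frailty_from_fit <- function(fit) {
  stopifnot(inherits(fit, "eh_fit"))
  if (fit$model == "classical") frailty_spec("none")
  else frailty_spec(fit$frailty_family, b = fit$estimate$b)
}

#' Compare fitted models by AIC
#'
#' Ranks fits of the same data by AIC (ascending), breaking ties in favor of
#' fewer parameters.
#'
#' @param fits a (possibly named) list of \code{eh_fit} objects on the same
#'   data.
#' @return A data frame (model, k, loglik, aic, delta_aic) sorted by AIC.
#' @export
aic_compare <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1,
            all(vapply(fits, inherits, TRUE, "eh_fit")))
  fps <- lapply(fits, `[[`, "fingerprint")
  if (!all(vapply(fps, identical, TRUE, fps[[1]])))
    stop("fits were not obtained on the same data")
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model", seq_along(fits))
  out <- data.frame(model = nm,
                    k = vapply(fits, `[[`, 0, "k"),
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    aic = vapply(fits, `[[`, 0, "aic"))
  out <- out[order(out$aic, out$k), , drop = FALSE]
  out$delta_aic <- out$aic - out$aic[1]
  rownames(out) <- NULL
  out
}

#' Monte-Carlo confidence band for the population net survival curve
#'
#' Draws parameter vectors from the asymptotic normal distribution of the
#' maximum likelihood estimator (on the transformed scale), recomputes the
#' population net survival curve for each draw, and returns pointwise
#' quantile intervals.
#'
#' @param fit a converged \code{eh_fit}.
#' @param data data frame of individuals over which the curve is averaged.
#' @param t_grid increasing grid of times (years).
#' @param n_draws number of parameter draws.
#' @param seed optional integer seed for reproducibility.
#' @param level interval level.
#' @return A data frame (t, estimate, lower, upper).
#' @export
mc_ci_net_survival <- function(fit, data, t_grid, n_draws = 1000,
                               seed = NULL, level = 0.95) {
  stopifnot(inherits(fit, "eh_fit"))
  if (!fit$converged) stop("fit did not converge")
  if (!is.null(seed)) set.seed(seed)
  cov <- fit$cov
  ev <- eigen(cov, symmetric = TRUE)
  if (any(ev$values < 0)) {
    warning("covariance not positive semidefinite; projecting to nearest PSD")
    ev$values <- pmax(ev$values, 0)
    cov <- ev$vectors %*% diag(ev$values, length(ev$values)) %*% t(ev$vectors)
  }
  draws <- MASS::mvrnorm(n_draws, mu = fit$par, Sigma = cov)
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = 1L)
  Xh <- as.matrix(data[fit$hazard_covs])
  pt <- length(fit$tidx); p <- length(fit$hazard_covs)
  frailty <- fit$model == "frailty"
  curves <- matrix(NA_real_, n_draws, length(t_grid))
  for (j in seq_len(n_draws)) {
    psi <- unpack_params(draws[j, ], fit$baseline, pt, p, frailty)
    m <- gh_model(psi$baseline, psi$alpha, psi$beta,
                  time_covariate_index = fit$tidx)
    f <- if (frailty) frailty_spec(fit$frailty_family, psi$b)
    else frailty_spec("none")
    curves[j, ] <- pop_net_surv_values(m, f, Xh, t_grid)
  }
  point <- pop_net_surv_values(gh_from_fit(fit), frailty_from_fit(fit),
                               Xh, t_grid)
  a <- (1 - level) / 2
  data.frame(t = t_grid, estimate = point,
             lower = apply(curves, 2, stats::quantile, probs = a),
             upper = apply(curves, 2, stats::quantile, probs = 1 - a))
}
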
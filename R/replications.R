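# true natural-scale parameter vector of a single-group scenario, in the
# order used by the fit (sigma, nu, gamma, alpha..., beta..., b)
scenario_truth <- function(spec) {
  if (!is.null(spec$subgroup_structure))
    stop("truth vector is defined for single-group scenarios only")
  bl <- spec$baseline[[1]]
  tv <- c(bl$sigma, bl$nu, bl$gamma, spec$alpha[[1]], spec$beta[[1]])
  nm <- c("sigma", "nu", "gamma",
          paste0("alpha:", spec$covariates), paste0("beta:", spec$covariates))
  if (spec$frailty$family != "none") {
    tv <- c(tv, spec$frailty$b); nm <- c(nm, "b")
  }
  stats::setNames(tv, nm)
}

#' Run a Monte-Carlo replication study
#'
#' Generates \code{n_reps} cohorts from a scenario, fits the requested excess
#' hazard model to each (with the classical-PH initialization recipe),
#' excludes replicates where the optimizer failed or the Hessian was not
#' usable, and tabulates the usual performance metrics per parameter: true
#' value, mean and median of the estimates, bias, empirical coverage of the
#' Wald confidence interval, mean estimated standard error and empirical
#' standard deviation.
#'
#' Per-replicate seeds are drawn once from \code{seed}, so results are
#' reproducible and independent of execution order.
#'
#' @param spec a single-group \code{\link{builtin_scenario}} (e.g.
#'   \code{"Sc1"}).
#' @param lt a \code{\link{life_table}}.
#' @param n_reps number of replicates.
#' @param seed integer master seed.
#' @param model \code{"frailty"} (default) or \code{"classical"}.
#' @param level confidence level for the coverage computation.
#' @return An object of class \code{replication_study}: the performance
#'   \code{table}, matrices of per-replicate estimates, standard errors and
#'   interval endpoints (converged replicates only), and the number excluded.
#' @examples
#' \donttest{
#' lt <- make_gompertz_life_table()
#' rs <- run_replications(builtin_scenario("Sc1", n = 500), lt,
#'                        n_reps = 5, seed = 7)
#' rs$table
#' }
#' @export
run_replications <- function(spec, lt, n_reps, seed, model = "frailty",
                             level = 0.95) {
  stopifnot(inherits(spec, "scenario_spec"), n_reps >= 1)
  truth <- scenario_truth(spec)
  if (model == "classical") truth <- truth[names(truth) != "b"]
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  covs <- spec$covariates
  est <- se <- lo <- hi <- NULL
  excluded <- 0L
  for (r in seq_len(n_reps)) {
    d <- generate_cohort(spec, lt, seed = rep_seeds[r])
    fit <- tryCatch(
      fit_excess_hazard(d, lt, model = model, baseline = "pgw",
                        hazard_covs = covs, time_covs = covs, level = level),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || anyNA(fit$summary$se)) {
      excluded <- excluded + 1L
      next
    }
    s <- fit$summary
    est <- rbind(est, s$estimate); se <- rbind(se, s$se)
    lo <- rbind(lo, s$lower); hi <- rbind(hi, s$upper)
  }
  if (is.null(est)) stop("all ", n_reps, " replicates were excluded")
  colnames(est) <- colnames(se) <- colnames(lo) <- colnames(hi) <- names(truth)
  tab <- data.frame(
    parameter = names(truth),
    true = unname(truth),
    mean_mle = colMeans(est),
    bias = colMeans(est) - unname(truth),
    median_mle = apply(est, 2, stats::median),
    coverage = colMeans(sweep(lo, 2, truth) <= 0 & sweep(hi, 2, truth) >= 0),
    mean_se = colMeans(se),
    emp_sd = apply(est, 2, stats::sd),
    row.names = NULL)
  structure(list(table = tab, estimates = est, se = se, lower = lo,
                 upper = hi, n_reps = n_reps, n_excluded = excluded,
                 spec_name = spec$name, n = spec$n, model = model,
                 level = level),
            class = "replication_study")
}

#' @export
print.replication_study <- function(x, digits = 3, ...) {
  cat("Replication study: scenario ", x$spec_name, ", n = ", x$n,
      ", M = ", x$n_reps, " (", x$n_excluded, " excluded)\n", sep = "")
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Average marginal net survival curve of a replication study
#'
#' For each converged replicate, evaluates the subgroup-specific marginal net
#' survival at a fixed covariate profile from the replicate's estimates, and
#' averages across replicates; also returns the true curve from the
#' generating parameters. Used to check that the marginal net survival is
#' recovered on average even when individual parameters are biased.
#'
#' @param study a \code{\link{run_replications}} result (frailty model).
#' @param spec the scenario the study was run on.
#' @param t_grid time grid (years).
#' @param x covariate profile (default the reference profile, all zero).
#' @return A data frame (t, average, truth).
#' @export
average_net_survival <- function(study, spec, t_grid = seq(0, 5, by = 0.1),
                                 x = NULL) {
  stopifnot(inherits(study, "replication_study"))
  p <- length(spec$covariates)
  if (is.null(x)) x <- rep(0, p)
  est <- study$estimates
  curve_for <- function(sigma, nu, gamma, alpha, beta, b) {
    m <- gh_model(baseline_params("pgw", sigma, nu, gamma), alpha, beta,
                  time_covariate_index = seq_len(p))
    f <- if (is.na(b)) frailty_spec("none") else frailty_spec("gamma", b)
    HE <- vapply(t_grid, function(tt) excess_cum_hazard(m, tt, x), numeric(1))
    marginal_net_survival(f, HE)
  }
  acc <- matrix(0, nrow(est), length(t_grid))
  has_b <- "b" %in% colnames(est)
  for (r in seq_len(nrow(est))) {
    e <- est[r, ]
    acc[r, ] <- curve_for(e["sigma"], e["nu"], e["gamma"],
                          e[paste0("alpha:", spec$covariates)],
                          e[paste0("beta:", spec$covariates)],
                          if (has_b) e["b"] else NA)
  }
  truth <- scenario_truth(spec)
  tr <- curve_for(truth["sigma"], truth["nu"], truth["gamma"],
                  truth[paste0("alpha:", spec$covariates)],
                  truth[paste0("beta:", spec$covariates)],
                  if ("b" %in% names(truth)) truth["b"] else NA)
  data.frame(t = t_grid, average = colMeans(acc), truth = tr)
}

# true net survival curves for an Aim-2 style subgroup scenario by
# Monte-Carlo integration over the covariate law (classical net survival per
# subgroup model; the generating model has no frailty)
aim2_true_curves <- function(spec, t_grid, n_draws = 1e5, seed = 1) {
  set.seed(seed)
  comp <- sample.int(3L, n_draws, TRUE, prob = spec$age_law$weights)
  age <- stats::runif(n_draws, spec$age_law$lower[comp],
                      spec$age_law$upper[comp])
  agec <- as.numeric(scale(age))
  sex <- stats::rbinom(n_draws, 1L, spec$p_sex)
  X1 <- stats::rbinom(n_draws, 1L, spec$p_x1[sex + 1L])
  X <- cbind(agec = agec, sex = sex, X1 = X1)
  S <- matrix(NA_real_, n_draws, length(t_grid))
  for (g in 0:1) {
    i <- sex == g
    m <- gh_model(spec$baseline[[g + 1L]], spec$alpha[[g + 1L]],
                  spec$beta[[g + 1L]],
                  time_covariate_index = seq_along(spec$alpha[[g + 1L]]))
    lp <- gh_linpred(m, X[i, , drop = FALSE])
    for (j in seq_along(t_grid)) {
      HE <- cum_hazard(m$baseline, t_grid[j] * exp(lp$A)) * exp(lp$B - lp$A)
      S[i, j] <- exp(-HE)
    }
  }
  rbind(data.frame(t = t_grid, estimate = colMeans(S), model = "truth",
                   analysis = "truth", scope = "population",
                   group = "population"),
        do.call(rbind, lapply(0:1, function(g)
          data.frame(t = t_grid, estimate = colMeans(S[sex == g, , drop = FALSE]),
                     model = "truth", analysis = "truth", scope = "subgroup",
                     group = paste0("sex=", g)))))
}

#' Missing-covariate (Aim 2) replication analysis
#'
#' For each replicate of an Aim-2 scenario: fits the classical and frailty
#' models to the pooled data omitting X1 (covariates agec and sex at both
#' levels), computes the population and per-sex net survival curves; then
#' fits both models separately within each sex stratum (covariate agec only,
#' still omitting X1) and computes the per-sex curves. Curves are averaged
#' across converged replicates and returned alongside the true curves,
#' obtained by Monte-Carlo integration over the covariate law.
#'
#' @param spec an Aim-2 \code{\link{builtin_scenario}}.
#' @param lt a \code{\link{life_table}}.
#' @param n_reps number of replicates.
#' @param seed integer master seed.
#' @param t_grid time grid (years).
#' @param n_truth Monte-Carlo draws for the true curves.
#' @return A list with \code{curves} (tidy data frame of averaged fitted and
#'   true curves: t, estimate, model, analysis, scope, group),
#'   \code{n_excluded}, and \code{per_replicate} maximum absolute deviations
#'   from truth of the pooled and stratified subgroup curves.
#' @export
aim2_analysis <- function(spec, lt, n_reps, seed,
                          t_grid = seq(0, 5, by = 0.25), n_truth = 1e5) {
  stopifnot(inherits(spec, "scenario_spec"),
            !is.null(spec$subgroup_structure))
  truth <- aim2_true_curves(spec, t_grid, n_draws = n_truth, seed = seed)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  pooled_covs <- c("agec", "sex")
  acc <- list(); dev <- NULL; excluded <- 0L
  truth_sub <- lapply(0:1, function(g)
    truth$estimate[truth$group == paste0("sex=", g)])
  for (r in seq_len(n_reps)) {
    d <- generate_cohort(spec, lt, seed = rep_seeds[r])
    fits <- tryCatch({
      out <- list()
      for (mod in c("classical", "frailty")) {
        fit <- fit_excess_hazard(d, lt, model = mod,
                                 hazard_covs = pooled_covs,
                                 time_covs = pooled_covs)
        if (!fit$converged) stop("pooled fit not converged")
        out[[paste0("pooled_", mod)]] <- rbind(
          population_net_survival(fit, d, t_grid),
          population_net_survival(fit, d, t_grid, by = "sex"))
        strat <- lapply(0:1, function(g) {
          dg <- d[d$sex == g, , drop = FALSE]
          fg <- fit_excess_hazard(dg, lt, model = mod,
                                  hazard_covs = "agec", time_covs = "agec")
          if (!fg$converged) stop("stratified fit not converged")
          cg <- population_net_survival(fg, dg, t_grid)
          cg$scope <- "subgroup"; cg$group <- paste0("sex=", g)
          cg
        })
        out[[paste0("stratified_", mod)]] <- do.call(rbind, strat)
      }
      out
    }, error = function(e) NULL)
    if (is.null(fits)) { excluded <- excluded + 1L; next }
    acc[[length(acc) + 1L]] <- fits
    # per-replicate max abs deviation of subgroup curves from truth
    dv <- vapply(c("pooled_frailty", "stratified_frailty"), function(k) {
      cc <- fits[[k]]
      max(vapply(0:1, function(g)
        max(abs(cc$estimate[cc$group == paste0("sex=", g)] -
                  truth_sub[[g + 1L]])), numeric(1)))
    }, numeric(1))
    dev <- rbind(dev, dv)
  }
  if (!length(acc)) stop("all replicates were excluded")
  avg <- do.call(rbind, lapply(names(acc[[1]]), function(k) {
    base <- acc[[1]][[k]]
    base$estimate <- Reduce(`+`, lapply(acc, function(a) a[[k]]$estimate)) /
      length(acc)
    parts <- strsplit(k, "_")[[1]]
    base$analysis <- parts[1]; base$model <- parts[2]
    base
  }))
  list(curves = rbind(avg[c("t", "estimate", "model", "analysis", "scope",
                            "group")],
                      truth[c("t", "estimate", "model", "analysis", "scope",
                              "group")]),
       n_excluded = excluded,
       per_replicate = as.data.frame(dev, row.names = FALSE))
}
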
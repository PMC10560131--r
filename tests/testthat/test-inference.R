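toy_psi <- list(baseline = baseline_params("pgw", 0.8, 1.3, 2.5),
                alpha = c(0.4), beta = c(0.7, -0.3), b = 0.6)
toy <- data.frame(time = c(0.5, 2.1, 4.0), status = c(1, 0, 1),
                  agec = c(0.2, -1.1, 0.8), sex = c(1, 0, 1),
                  age = c(72, 55, 81), year = 2010,
                  strata = c("female", "male", "female"))

test_that("log-likelihoods match a hand-rolled per-observation oracle", {
  # oracle assembled from the closed-form PGW survival, independent of the
  # package's likelihood code
  s <- 0.8; v <- 1.3; g <- 2.5
  A <- 0.4 * toy$agec
  B <- 0.7 * toy$agec - 0.3 * toy$sex
  hE <- pgw_h0(toy$time * exp(A), s, v, g) * exp(B)
  HE <- pgw_H0(toy$time * exp(A), s, v, g) * exp(B - A)
  hP <- 0.8^(toy$sex) * exp(-10 + 0.09 * floor(toy$age + toy$time))
  ll_c <- sum(toy$status * log(hP + hE) - HE)
  b <- 0.6
  ll_f <- sum(toy$status * log(hP + hE / (1 + b * HE)) -
                log(1 + b * HE) / b)
  expect_equal(loglik_classical(toy_psi, toy, lt_gomp, c("agec", "sex"),
                                "agec"), ll_c, tolerance = 1e-10)
  expect_equal(loglik_frailty(toy_psi, toy, lt_gomp, c("agec", "sex"),
                              "agec"), ll_f, tolerance = 1e-10)
})

test_that("single-observation likelihoods reduce to their textbook forms", {
  one <- data.frame(time = 1.7, status = 0, x = 0, age = 60, year = 2010,
                    strata = "male")
  psi <- list(baseline = baseline_params("pgw", 0.9, 1.5, 2),
              alpha = numeric(0), beta = 0, b = NULL)
  # censored, PH, x = 0: -H0(t)
  expect_equal(loglik_classical(psi, one, lt_gomp, "x"),
               -pgw_H0(1.7, 0.9, 1.5, 2), tolerance = 1e-10)
  # death with zero excess hazard: log hP at the observed time
  one2 <- transform(one, status = 1)
  psi2 <- list(baseline = baseline_params("pgw", 1e6, 1, 1),
               alpha = numeric(0), beta = -30, b = NULL)
  expect_equal(loglik_classical(psi2, transform(one2, x = 1), lt_gomp, "x"),
               log(exp(-10 + 0.09 * 61)), tolerance = 1e-4)
})

test_that("the frailty likelihood converges to the classical one as b -> 0", {
  set.seed(9)
  sc <- builtin_scenario("Sc1", n = 200)
  for (s in 1:5) {
    d <- generate_cohort(sc, lt_gomp, seed = 400 + s)
    psi <- list(baseline = baseline_params("pgw", runif(1, 0.5, 1.5),
                                           runif(1, 1, 2), runif(1, 2, 8)),
                alpha = rnorm(4, 0, 0.5), beta = rnorm(4, 0, 0.5), b = 1e-10)
    lf <- loglik_frailty(psi, d, lt_gomp, sc1_covs, sc1_covs)
    lc <- loglik_classical(psi, d, lt_gomp, sc1_covs, sc1_covs)
    expect_equal(lf, lc, tolerance = 1e-6)
  }
})

test_that("analytic gradients agree with finite differences", {
  d <- generate_cohort(builtin_scenario("Sc1", n = 300), lt_gomp, seed = 77)
  ld <- frailtyEH:::make_likelihood_data(d, lt_gomp, sc1_covs, sc1_covs)
  par <- c(log(0.9), log(1.5), log(6), rnorm(8, 0.8, 0.2), log(0.7))
  for (frail in c(TRUE, FALSE)) {
    pp <- if (frail) par else par[-13]
    an <- frailtyEH:::loglik_core(pp, ld, "pgw", frail, want_grad = TRUE)$grad
    fd <- vapply(seq_along(pp), function(j) {
      e <- 1e-6; hi <- pp; lo <- pp; hi[j] <- hi[j] + e; lo[j] <- lo[j] - e
      (frailtyEH:::loglik_core(hi, ld, "pgw", frail)$loglik -
         frailtyEH:::loglik_core(lo, ld, "pgw", frail)$loglik) / (2 * e)
    }, numeric(1))
    expect_equal(an, fd, tolerance = 1e-5)
  }
})

test_that("maximum likelihood fitting recovers known generating parameters", {
  sc <- builtin_scenario("Sc1", n = 2000)
  d <- generate_cohort(sc, lt_gomp, seed = 123)
  fit <- fit_excess_hazard(d, lt_gomp, model = "frailty",
                           hazard_covs = sc1_covs, time_covs = sc1_covs)
  expect_true(fit$converged)
  truth <- c(0.75, 1.75, 8, rep(1, 8), 0.5)
  z <- abs(fit$summary$estimate - truth) / fit$summary$se
  expect_true(all(z < 3.5))
  # the frailty variance lies inside its log-scale Wald interval
  brow <- fit$summary[fit$summary$parameter == "b", ]
  expect_true(brow$lower > 0)
  expect_true(brow$lower < 0.5 && brow$upper > 0.5)
  # stationarity: refitting from the optimum does not move the likelihood,
  # and the gradient at the optimum is numerically zero
  refit <- fit_excess_hazard(d, lt_gomp, model = "frailty",
                             hazard_covs = sc1_covs, time_covs = sc1_covs,
                             init = fit$estimate)
  expect_lt(abs(refit$loglik - fit$loglik), 1e-6)
  ld <- frailtyEH:::make_likelihood_data(d, lt_gomp, sc1_covs, sc1_covs)
  gr <- frailtyEH:::loglik_core(fit$par, ld, "pgw", TRUE,
                                want_grad = TRUE)$grad
  expect_lt(max(abs(gr)), 1e-4)
  # AIC identity: 3 baseline + 4 time-level + 4 hazard-level + b
  expect_equal(fit$aic, 2 * 12 - 2 * fit$loglik)
})

test_that("AIC comparison ranks fits and guards against mixed data", {
  sc <- builtin_scenario("Sc1", n = 600)
  d <- generate_cohort(sc, lt_gomp, seed = 55)
  fc <- fit_excess_hazard(d, lt_gomp, model = "classical",
                          hazard_covs = sc1_covs)
  ff <- fit_excess_hazard(d, lt_gomp, model = "frailty",
                          hazard_covs = sc1_covs)
  cmp <- aic_compare(list(classical = fc, frailty = ff))
  expect_equal(cmp$aic, sort(cmp$aic))
  expect_equal(cmp$delta_aic[1], 0)
  d2 <- generate_cohort(sc, lt_gomp, seed = 56)
  f2 <- fit_excess_hazard(d2, lt_gomp, model = "classical",
                          hazard_covs = sc1_covs)
  expect_error(aic_compare(list(fc, f2)), "same data")
  # equal log-likelihoods: fewer parameters ranked first
  ff_tie <- ff; ff_tie$loglik <- fc$loglik; ff_tie$aic <- 2 * ff$k - 2 * fc$loglik
  cmp2 <- aic_compare(list(big = ff_tie, small = fc))
  expect_equal(cmp2$model[1], "small")
})

test_that("Monte-Carlo net-survival bands are reproducible and calibrated", {
  sc <- builtin_scenario("Sc1", n = 800)
  d <- generate_cohort(sc, lt_gomp, seed = 31)
  fit <- fit_excess_hazard(d, lt_gomp, model = "frailty",
                           hazard_covs = sc1_covs, time_covs = sc1_covs)
  tg <- seq(0, 5, by = 0.5)
  ci <- mc_ci_net_survival(fit, d, tg, n_draws = 200, seed = 42)
  ci2 <- mc_ci_net_survival(fit, d, tg, n_draws = 200, seed = 42)
  expect_identical(ci, ci2)
  expect_true(all(ci$lower <= ci$estimate & ci$estimate <= ci$upper))
  # degenerate covariance collapses the band onto the point curve
  fit0 <- fit
  fit0$cov[] <- 0
  ci0 <- mc_ci_net_survival(fit0, d, tg, n_draws = 50, seed = 1)
  expect_equal(ci0$lower, ci0$estimate, tolerance = 1e-12)
  expect_equal(ci0$upper, ci0$estimate, tolerance = 1e-12)
})

test_that("interval width shrinks roughly like 1/sqrt(n)", {
  tg <- c(1, 2.5, 4)
  # classical model (its estimator is in the asymptotic regime at these n;
  # the frailty variance reaches it much later, as the replication study
  # shows) and median across seeds, since single-replicate widths are noisy
  width <- vapply(c(500, 2000, 8000), function(n) {
    median(vapply(1:5, function(s) {
      d <- generate_cohort(builtin_scenario("Sc1", n = n), lt_gomp,
                           seed = 8 + s)
      fit <- fit_excess_hazard(d, lt_gomp, model = "classical",
                               hazard_covs = sc1_covs, time_covs = sc1_covs)
      ci <- mc_ci_net_survival(fit, d, tg, n_draws = 400, seed = 2)
      mean(ci$upper - ci$lower)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(width[1] / width[2], 1.5)
  expect_lt(width[1] / width[2], 2.5)
  expect_gt(width[2] / width[3], 1.5)
  expect_lt(width[2] / width[3], 2.5)
})
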
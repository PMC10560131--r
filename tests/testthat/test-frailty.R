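test_that("Laplace transforms match their closed forms and axioms", {
  fg <- frailty_spec("gamma", b = 1)
  fi <- frailty_spec("inverse_gaussian", b = 0.5)
  expect_equal(laplace_transform(fg, 0), 1)
  expect_equal(laplace_transform(fi, 0), 1)
  expect_equal(laplace_transform(fg, 1), 0.5)
  # frozen quadrature oracles over the unit-mean densities
  expect_equal(laplace_transform(frailty_spec("gamma", 0.25), 2),
               0.197530864198, tolerance = 1e-8)
  expect_equal(laplace_transform(fi, 1.3), 0.355884094773, tolerance = 1e-8)
  # strictly decreasing and log-convex
  s <- seq(0, 5, by = 0.25)
  for (f in list(fg, fi)) {
    L <- laplace_transform(f, s)
    expect_true(all(diff(L) < 0))
    expect_true(all(diff(diff(log(L))) > -1e-12))
  }
  expect_error(laplace_transform(fg, -1), "nonnegative")
})

test_that("complete monotonicity holds up to third-order differences", {
  s <- seq(0.1, 4, by = 0.05)
  for (f in list(frailty_spec("gamma", 0.7),
                 frailty_spec("inverse_gaussian", 1.2))) {
    L <- laplace_transform(f, s)
    expect_true(all(diff(L, differences = 1) < 0))
    expect_true(all(diff(L, differences = 2) > 0))
    expect_true(all(diff(L, differences = 3) < 0))
  }
})

test_that("marginal net survival has the gamma closed form and b -> 0 limit", {
  fg <- frailty_spec("gamma", b = 1)
  expect_equal(marginal_net_survival(fg, 0), 1)
  expect_equal(marginal_net_survival(fg, 1), 0.5)
  expect_equal(marginal_net_survival(frailty_spec("gamma", 1e-12), 2),
               exp(-2), tolerance = 1e-6)
  expect_equal(marginal_net_survival(frailty_spec("none"), 2), exp(-2))
  # frailty-corrected survival dominates the classical one (log-convexity)
  HE <- seq(0, 4, by = 0.1)
  expect_true(all(marginal_net_survival(fg, HE) >= exp(-HE)))
})

test_that("the frailty weight is the conditional frailty mean -L'/L", {
  fg <- frailty_spec("gamma", b = 1)
  expect_equal(frailty_weight(fg, 1), 0.5)
  expect_equal(frailty_weight(frailty_spec("gamma", 0), 3), 1)
  expect_equal(frailty_weight(frailty_spec("none"), 3), 1)
  HE <- c(0.2, 0.8, 1.7, 3.1)
  e <- 1e-5
  for (f in list(frailty_spec("gamma", 0.6),
                 frailty_spec("inverse_gaussian", 0.9))) {
    fd <- -(log(laplace_transform(f, HE + e)) -
              log(laplace_transform(f, HE - e))) / (2 * e)
    expect_equal(frailty_weight(f, HE), fd, tolerance = 1e-6)
  }
  # selection effect: weight nonincreasing along any nondecreasing HE path
  expect_true(all(diff(frailty_weight(fg, seq(0, 5, 0.1))) <= 0))
})

test_that("marginal observed survival multiplies population and net pieces", {
  bp <- baseline_params("pgw", 0.75, 1.75, 8)
  m <- gh_ph(bp, beta = c(0.5, 0.3))
  f <- frailty_spec("gamma", b = 0.5)
  x <- c(1, 0.4); age <- 76.3; yr <- 2010
  expect_equal(marginal_observed_survival(f, m, lt_gomp, 0, x, age, yr,
                                          "female"), 1)
  # against Monte-Carlo marginalization over the gamma frailty
  tt <- 2.5
  HPd <- pop_cum_hazard_increment(lt_gomp, age, yr, "female", tt)
  HE <- excess_cum_hazard(m, tt, x)
  set.seed(5)
  lam <- rgamma(1e5, shape = 2, scale = 0.5)
  mc <- mean(exp(-HPd - lam * HE))
  expect_equal(marginal_observed_survival(f, m, lt_gomp, tt, x, age, yr,
                                          "female"), mc, tolerance = 2e-3)
  # b = 0 with (essentially) no background: the classical net survival
  lt0 <- lt_const(1e-12)
  expect_equal(marginal_observed_survival(frailty_spec("none"), m, lt0,
                                          tt, x, age, yr), exp(-HE),
               tolerance = 1e-9)
})

test_that("marginal observed hazard is the weighted hazard decomposition", {
  bp <- baseline_params("pgw", 0.6, 1.4, 3)
  m <- gh_ph(bp, beta = c(0.5))
  x <- 1; age <- 70.4; yr <- 2011
  tt <- c(0.7, 1.9, 3.3)
  hP <- pop_hazard(lt_gomp, age + tt, yr + tt, "male")
  hE <- excess_hazard(m, tt, x)
  HE <- excess_cum_hazard(m, tt, x)
  # no frailty: plain additive decomposition
  expect_equal(marginal_observed_hazard(frailty_spec("none"), m, lt_gomp,
                                        tt, x, age, yr, "male"), hP + hE)
  f <- frailty_spec("gamma", 0.8)
  h <- marginal_observed_hazard(f, m, lt_gomp, tt, x, age, yr, "male")
  expect_equal(h, hP + hE / (1 + 0.8 * HE))
  expect_true(all(h >= hP))
  # large b and large HE: the excess contribution is selected away
  fbig <- frailty_spec("gamma", 5000)
  expect_equal(marginal_observed_hazard(fbig, m, lt_gomp, 4, x, age, yr,
                                        "male"),
               pop_hazard(lt_gomp, age + 4, yr + 4, "male"),
               tolerance = 0.01)
  # consistency with -d/dt log of the marginal observed survival
  e <- 1e-5
  fd <- -(log(marginal_observed_survival(f, m, lt_gomp, tt + e, x, age, yr,
                                         "male")) -
            log(marginal_observed_survival(f, m, lt_gomp, tt - e, x, age, yr,
                                           "male"))) / (2 * e)
  expect_equal(h, fd, tolerance = 1e-4)
})
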
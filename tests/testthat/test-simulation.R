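test_that("built-in scenarios encode the study designs", {
  sc <- builtin_scenario("Sc1", n = 1000)
  expect_equal(sc$frailty$b, 0.5)
  expect_equal(sc$baseline[[1]]$sigma, 0.75)
  expect_equal(sc$baseline[[1]]$nu, 1.75)
  expect_equal(sc$baseline[[1]]$gamma, 8)
  expect_equal(sc$alpha[[1]], rep(1, 4))
  far <- builtin_scenario("Aim2_far")
  expect_equal(far$baseline[[1]]$gamma, 0.75)   # sex = 0 subgroup
  expect_equal(far$baseline[[2]]$gamma, 5)      # sex = 1 subgroup
  expect_equal(far$beta[[2]], c(1, 0.5, 1))
  expect_error(builtin_scenario("Sc9"))
  # age mixture: share of draws in (75, 85) close to its 0.40 weight
  d <- generate_cohort(builtin_scenario("Sc1", n = 1e5), lt_gomp, seed = 1)
  expect_equal(mean(d$age > 75 & d$age < 85), 0.40, tolerance = 0.025)
  expect_equal(mean(d$age > 30 & d$age < 65), 0.25, tolerance = 0.04)
  expect_equal(mean(d$sex), 0.5, tolerance = 0.02)
  # standardized age within the replicate
  expect_equal(mean(d$agec), 0, tolerance = 1e-10)
  expect_equal(sd(d$agec), 1, tolerance = 1e-10)
})

test_that("Sc1 cohorts show the designed censoring profile", {
  sc <- builtin_scenario("Sc1", n = 5000)
  stats <- vapply(1:8, function(s) {
    d <- generate_cohort(sc, lt_gomp, seed = s)
    lat <- attr(d, "latent")
    c(drop = mean(lat$cause == "dropout"), cens = mean(d$status == 0))
  }, numeric(2))
  # around 5% random drop-out
  expect_gt(mean(stats["drop", ]), 0.04)
  expect_lt(mean(stats["drop", ]), 0.06)
  # roughly 40-45% total censoring (synthetic background table)
  expect_gt(mean(stats["cens", ]), 0.38)
  expect_lt(mean(stats["cens", ]), 0.47)
  # administrative censoring is exactly at the 5-year horizon
  d <- generate_cohort(sc, lt_gomp, seed = 1)
  lat <- attr(d, "latent")
  expect_true(all(d$time[lat$cause == "admin"] == 5))
  expect_true(all(d$status[lat$cause %in% c("dropout", "admin")] == 0))
  expect_true(all(d$status[lat$cause %in% c("cancer", "population")] == 1))
})

test_that("cohort generation is deterministic under a seed", {
  sc <- builtin_scenario("Sc1", n = 300)
  d1 <- generate_cohort(sc, lt_gomp, seed = 99)
  d2 <- generate_cohort(sc, lt_gomp, seed = 99)
  d3 <- generate_cohort(sc, lt_gomp, seed = 100)
  expect_identical(d1, d2)
  expect_false(identical(d1$time, d3$time))
})

test_that("cause attribution responds to the generative components", {
  # negligible excess hazard: every death is from other causes
  sc <- builtin_scenario("Sc1", n = 2000)
  sc$beta[[1]] <- rep(0, 4); sc$alpha[[1]] <- rep(0, 4)
  sc$baseline[[1]] <- baseline_params("pgw", 1e8, 1, 1)
  d <- generate_cohort(sc, lt_gomp, seed = 12)
  lat <- attr(d, "latent")
  expect_equal(sum(lat$cause == "cancer"), 0)
  expect_gt(sum(lat$cause == "population"), 0)
})

test_that("with no background, censoring or covariates, simulated times follow
           the frailty-marginal net survival", {
  sc <- builtin_scenario("Sc1", n = 4000)
  sc$alpha[[1]] <- rep(0, 4); sc$beta[[1]] <- rep(0, 4)
  sc$dropout_rate <- 1e-300; sc$admin_censor <- Inf
  lt0 <- lt_const(1e-12, sexes = TRUE)
  d <- generate_cohort(sc, lt0, seed = 17)
  expect_equal(mean(d$status), 1)
  bp <- sc$baseline[[1]]; b <- sc$frailty$b
  ks <- suppressWarnings(stats::ks.test(d$time, function(q)
    1 - (1 + b * cum_hazard(bp, q))^(-1 / b)))
  expect_gt(ks$p.value, 0.01)
})

test_that("replication studies tabulate the performance metrics coherently", {
  sc <- builtin_scenario("Sc1", n = 400)
  rs <- run_replications(sc, lt_gomp, n_reps = 4, seed = 2)
  tab <- rs$table
  expect_equal(nrow(tab), 12)
  expect_equal(tab$bias, tab$mean_mle - tab$true, tolerance = 1e-12)
  expect_true(all(tab$coverage >= 0 & tab$coverage <= 1))
  expect_equal(tab$mean_mle, colMeans(rs$estimates), ignore_attr = TRUE)
  expect_equal(nrow(rs$estimates) + rs$n_excluded, 4)
  # identical master seed reproduces the study exactly
  rs2 <- run_replications(sc, lt_gomp, n_reps = 4, seed = 2)
  expect_identical(rs$table, rs2$table)
})

test_that("the Aim-2 workflow runs end-to-end and stratification helps", {
  sc <- builtin_scenario("Aim2_far", n = 3000)
  a2 <- aim2_analysis(sc, lt_gomp, n_reps = 3, seed = 6, n_truth = 2e4)
  cc <- a2$curves
  expect_setequal(unique(cc$analysis), c("pooled", "stratified", "truth"))
  expect_true(all(cc$estimate >= 0 & cc$estimate <= 1))
  expect_true(all(cc$estimate[cc$t == 0] == 1))
  # subgroup curves from stratified fits track the truth better than the
  # pooled fit that omits X1 (the unobserved-heterogeneity phenomenon)
  pr <- a2$per_replicate
  expect_lt(mean(pr$stratified_frailty), mean(pr$pooled_frailty))
})
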
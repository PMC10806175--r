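test_that("Kaplan-Meier estimate matches hand product-limit arithmetic", {
  # times {1+, 2, 3+, 4}: S = 2/3 after t = 2, 0 after t = 4, median 4
  km <- kmEstimate(c(1, 2, 3, 4), c(0, 1, 0, 1))
  s_at <- function(t) km$surv[max(which(km$time <= t))]
  expect_equal(s_at(2), 2 / 3)
  expect_equal(s_at(4), 0)
  expect_equal(km$median, 4)

  # all censored: S identically 1, median not reached
  km <- kmEstimate(c(2, 5, 7), c(0, 0, 0))
  expect_true(all(km$surv == 1))
  expect_true(is.na(km$median))

  # no censoring: S equals the empirical survivor function
  set.seed(4)
  t <- rexp(60, 0.2)
  km <- kmEstimate(t, rep(1, 60))
  ecdf_surv <- vapply(km$time, function(x) mean(t > x), numeric(1))
  expect_equal(km$surv, ecdf_surv, tolerance = 1e-12)

  # oracle agreement with censoring
  set.seed(5)
  t <- round(rexp(40, 0.2), 1)
  e <- rbinom(40, 1, 0.7)
  if (sum(e) > 0) {
    km <- kmEstimate(t, e)
    o <- oracleKM(t, e)
    expect_equal(km$surv[km$n_event > 0], o$surv, tolerance = 1e-12)
  }
})

test_that("log-rank behaves at the null and under real hazard ratios", {
  set.seed(6)
  t <- rexp(30, 0.1)
  e <- rbinom(30, 1, 0.8)
  g <- rep(c("a", "b"), 15)
  # identical groups: chi-square 0, p = 1
  lr <- logrankTest(c(t, t), c(e, e), rep(c("a", "b"), each = 30))
  expect_equal(lr$chi_square, 0, tolerance = 1e-10)
  expect_equal(lr$p_value, 1, tolerance = 1e-10)
  # no events: warned, p = 1
  expect_warning(lr0 <- logrankTest(t, rep(0, 30), g), "no events")
  expect_equal(lr0$p_value, 1)

  # power at hazard ratio 4 (n = 22 + 22)
  rej <- vapply(1:200, function(k) {
    set.seed(8000 + k)
    t1 <- rexp(22, 0.1); t2 <- rexp(22, 0.4)
    logrankTest(c(t1, t2), rep(1, 44),
                rep(c("lo", "hi"), each = 22))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.8)
})

test_that("Cox fit matches a grid-search partial-likelihood maximizer", {
  # toy of 6 records, single binary covariate, no ties
  df <- data.frame(time = c(1.1, 2.3, 3.2, 4.7, 5.1, 6.9),
                   event = c(1, 1, 0, 1, 1, 1),
                   x = c(1, 0, 1, 0, 1, 0))
  fit <- coxFit(df, "x")
  b_grid <- oracleCoxGrid(df$time, df$event, df$x)
  expect_equal(fit$coef$beta, b_grid, tolerance = 1e-3)
  expect_true(fit$converged)
  expect_gte(fit$coef$ci_high, fit$coef$hr)
  expect_lte(fit$coef$ci_low, fit$coef$hr)

  # more records, still no ties: 3-decimal agreement with the oracle
  set.seed(7)
  n <- 40
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.1 * exp(0.8 * x))
  df <- data.frame(time = t, event = rep(1, n), x = x)
  fit <- coxFit(df, "x")
  expect_equal(fit$coef$beta, oracleCoxGrid(df$time, df$event, df$x),
               tolerance = 1e-3)

  # constant covariate rejected by the collinearity check
  df$k <- 1
  expect_error(coxFit(df, "k"), "collinear|constant")
})

test_that("Cox score test equals the log-rank statistic (classical identity)", {
  set.seed(8)
  n <- 50
  g <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.1 * exp(0.7 * g))  # continuous: no ties
  e <- rep(1, n)
  lr <- logrankTest(t, e, g)
  sc <- survival::coxph(survival::Surv(t, e) ~ g)$score
  expect_equal(lr$chi_square, unname(sc), tolerance = 1e-6)
})

test_that("Cox recovers simulated hazard ratios with small bias", {
  hrs <- c(0.25, 0.5, 1.0)
  for (hr in hrs) {
    est <- vapply(1:60, function(k) {
      set.seed(9000 + k + round(1000 * hr))
      x <- rep(c(1, 0), each = 100)
      t <- rexp(200, 0.1 * exp(log(hr) * x))
      coxFit(data.frame(time = t, event = 1, x = x), "x")$coef$beta
    }, numeric(1))
    if (hr == 1) expect_lt(abs(mean(est)), 0.1)
    else expect_lt(abs(mean(est) - log(hr)) / abs(log(hr)), 0.1)
  }
})

test_that("runPrognosis assembles the full report", {
  cfg <- cohortConfig(seed = 17)
  d <- withr::local_tempdir()
  b <- generateCohort(cfg, d, force = TRUE)
  clin <- b$clinical
  # strong synthetic effect: perfect scores from the response label
  set.seed(1)
  scores <- data.frame(case_id = clin$case_id,
                       score = clin$response * 0.6 +
                         runif(nrow(clin), 0, 0.3))
  rpt <- runPrognosis(scores, 0.5, clin)
  expect_named(rpt, c("pfs", "os"))
  expect_equal(nrow(rpt$pfs$univariate), 7)
  expect_setequal(unique(rpt$pfs$univariate$variable),
                  c("age_group", "sex", "t_stage_group", "n_group",
                    "scc_group", "location_group", "score_group"))
  # high group outlives low group by construction
  med <- rpt$pfs$medians
  expect_true(is.na(med["High"]) || med["High"] > med["Low"])
  expect_lt(rpt$pfs$logrank$p_value, 0.05)
  # score group significant -> enters the multivariate model
  expect_true("score_group" %in% rpt$pfs$multivariate_terms)

  # zero-case stratum is refused with the cutoff named
  expect_error(runPrognosis(scores, 2, clin), "stratum")
  # missing survival columns are refused
  expect_error(runPrognosis(scores, 0.5, clin[, 1:3]), "lacks")

  # null scores: log-rank p is non-degenerate across seeds
  ps <- vapply(1:15, function(k) {
    set.seed(300 + k)
    s0 <- data.frame(case_id = clin$case_id, score = runif(nrow(clin)))
    runPrognosis(s0, 0.5, clin)$pfs$logrank$p_value
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.5)
})
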
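test_that("degenerate covariates and outcomes are handled per contract", {
  set.seed(1)
  tm <- rexp(40, 0.05); ev <- rbinom(40, 1, 0.5)
  # no covariate variation: not identifiable, flagged rather than fitted
  f <- fit_cox_univariable(rep(2.5, 40), tm, ev, n_boot = 10, seed = 1)
  expect_false(f$converged)
  expect_true(is.na(f$hr))
  # all-censored outcome: rejected outright
  expect_error(fit_cox_univariable(rnorm(40), tm, rep(0, 40), n_boot = 0),
               "events")
  # undefined covariates are excluded and counted
  z <- rnorm(40); z[1:7] <- NA
  f2 <- fit_cox_univariable(z, tm, ev, n_boot = 50, seed = 2)
  expect_equal(f2$n_excluded_undefined, 7)
  expect_equal(f2$n_used, 33)
})

test_that("identical seed and inputs give a bit-identical fit", {
  set.seed(3)
  z <- rlnorm(80, 1, 0.5); tm <- rexp(80, 0.04); ev <- rbinom(80, 1, 0.4)
  f1 <- fit_cox_univariable(z, tm, ev, n_boot = 200, seed = 99)
  f2 <- fit_cox_univariable(z, tm, ev, n_boot = 200, seed = 99)
  expect_identical(f1, f2)
  f3 <- fit_cox_univariable(z, tm, ev, n_boot = 200, seed = 100)
  expect_false(identical(f1$ci_low, f3$ci_low))
})

test_that("Cox estimate matches the two-group exponential closed form", {
  # two groups with exponential times: the partial-likelihood estimate of the
  # log-HR converges to log(rate1/rate0); compare at large n
  set.seed(7)
  n <- 80000
  g <- rep(0:1, each = n / 2)
  rate <- ifelse(g == 1, 0.08, 0.05)
  tm <- rexp(n, rate)
  cens <- quantile(tm, 0.8)
  ev <- as.integer(tm <= cens); tmo <- pmin(tm, cens)
  f <- fit_cox_univariable(g, tmo, ev, n_boot = 0)
  expect_equal(f$hr, 0.08 / 0.05, tolerance = 0.02)
})

test_that("median dichotomization follows the stated tie and order rules", {
  d1 <- dichotomize_median(c(1, 2, 3, 4))
  expect_equal(d1$cutoff, 2.5)
  expect_equal(as.character(d1$labels), c("low", "low", "high", "high"))
  d2 <- dichotomize_median(c(1, 2, 2, 5))
  expect_equal(d2$cutoff, 2)
  expect_equal(as.character(d2$labels), c("low", "low", "low", "high"))
  # order invariance
  v <- c(5, 1, 2, 2)
  d3 <- dichotomize_median(v)
  expect_equal(as.character(d3$labels), c("high", "low", "low", "low"))
  expect_error(dichotomize_median(rep(3, 6)), "distinct")
})

test_that("log-rank test matches a hand-tabulated oracle and its null", {
  # identical groups: statistic 0, p = 1
  tm <- c(2, 4, 6, 8, 2, 4, 6, 8); ev <- c(1, 1, 0, 1, 1, 1, 0, 1)
  gr <- factor(rep(c("A", "B"), each = 4))
  km0 <- km_logrank(gr, tm, ev)
  expect_equal(km0$chisq, 0, tolerance = 1e-12)
  expect_equal(km0$logrank_p, 1, tolerance = 1e-9)
  # 6-patient toy, frozen from the O-E/V tabulation
  tm6 <- 1:6; ev6 <- c(1, 1, 1, 1, 0, 0); gr6 <- factor(c("A", "A", "A", "B", "B", "B"))
  km6 <- km_logrank(gr6, tm6, ev6)
  expect_equal(km6$chisq, 5.051661, tolerance = 1e-6)
  expect_equal(km6$chisq, logrank_oracle(tm6, ev6, gr6), tolerance = 1e-12)
  expect_error(km_logrank(factor(rep("A", 6)), tm6, ev6), "two non-empty")
})

test_that("log-rank agrees with the Cox score test on the same data", {
  set.seed(11)
  g <- rep(0:1, each = 60)
  tm <- rexp(120, ifelse(g == 1, 0.09, 0.05))
  ev <- rbinom(120, 1, 0.8)
  km <- km_logrank(factor(g), tm, ev)
  sc <- survival::coxph(survival::Surv(tm, ev) ~ g)
  score_chi <- summary(sc)$sctest[["test"]]
  expect_equal(km$chisq / score_chi, 1, tolerance = 0.005)
})

test_that("strongly separated groups are detected with high power", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    g <- rep(0:1, each = 100)
    tm <- rexp(200, ifelse(g == 1, 0.3 * 0.1, 0.1))
    cens <- runif(200, 0, 40)
    ev <- as.integer(tm <= cens)
    km <- km_logrank(factor(g), pmin(tm, cens), ev)
    if (km$logrank_p < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("cohort summary reports half-up percentages of the cohort", {
  clin <- data.frame(recurrence = rep(c("yes", "no"), c(22, 72)))
  s <- cohort_summary(clin)
  expect_equal(s$pct[s$level == "yes"], 23.4)
  expect_equal(s$pct[s$level == "no"], 76.6)
  # half-up at the boundary: 0.05 rounds up, never to even
  expect_equal(tilquant:::round_half_up(0.05, 1), 0.1)
  expect_equal(tilquant:::round_half_up(61.65, 1), 61.7)
})

test_that("survival and KM tables cover all measures and flag degeneracies", {
  set.seed(13)
  n <- 60
  measures <- data.frame(case_id = sprintf("c%02d", 1:n),
                         CD3_ITA = rlnorm(n, 1, 0.5),
                         CD3_IM1IO = c(rep(NA, 10), rlnorm(n - 10, 0, 0.3)),
                         CD8_ITA = rep(1, n))  # degenerate: zero variance
  outcomes <- data.frame(case_id = measures$case_id,
                         rfs_months = rexp(n, 0.02), rfs_event = rbinom(n, 1, 0.3),
                         os_months = rexp(n, 0.015), os_event = rbinom(n, 1, 0.4))
  outcomes$rfs_months <- pmin(outcomes$rfs_months, outcomes$os_months)
  tab <- til_survival_table(measures, outcomes, n_boot = 50, seed = 5,
                            measure_cols = c("CD3_ITA", "CD3_IM1IO", "CD8_ITA"))
  expect_equal(nrow(tab), 6)
  expect_true(all(!tab$converged[tab$measure == "CD8_ITA"]))
  expect_equal(unique(tab$n_excluded_undefined[tab$measure == "CD3_IM1IO"]), 10)
  ok <- tab$converged & !is.na(tab$ci_low)
  expect_true(all(tab$ci_low[ok] <= tab$hr[ok] & tab$hr[ok] <= tab$ci_high[ok]))
  kmt <- til_km_table(measures, outcomes, measure_cols = "CD3_ITA")
  expect_equal(nrow(kmt), 2)
  expect_true(all(kmt$n_low + kmt$n_high == n))
  expect_true(all(kmt$logrank_p >= 0 & kmt$logrank_p <= 1))
})
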
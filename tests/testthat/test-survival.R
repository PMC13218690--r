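surv_df <- function(time, event, ids = sprintf("P%02d", seq_along(time))) {
  data.frame(sample_id = ids, time = time, event = event,
             stringsAsFactors = FALSE)
}

test_that("Kaplan-Meier reproduces the hand product-limit estimate", {
  km <- km_estimate(surv_df(c(1, 2, 3), c(1, 0, 1)))
  S <- km$surv_fun[["all"]]
  expect_equal(S(0), 1)
  expect_equal(S(1), 2 / 3)     # risk set 3, one event
  expect_equal(S(2.5), 2 / 3)   # censoring at 2 leaves S unchanged
  expect_equal(S(3), 0)         # risk set 1 after the censor

  expect_warning(km0 <- km_estimate(surv_df(c(1, 2), c(0, 0))), "flat")
  expect_equal(km0$surv_fun[["all"]](5), 1)

  # tied event times pool into one step
  km_tie <- km_estimate(surv_df(c(2, 2, 3), c(1, 1, 1)))
  expect_equal(km_tie$surv_fun[["all"]](2), 1 / 3)
  expect_equal(sum(km_tie$table$time == 2), 1L)

  # with no censoring, KM equals 1 - empirical CDF
  set.seed(8)
  t <- rexp(40)
  S2 <- km_estimate(surv_df(t, rep(1, 40)))$surv_fun[["all"]]
  grid <- quantile(t, c(0.1, 0.4, 0.8))
  expect_equal(S2(grid), 1 - ecdf(t)(grid), tolerance = 1e-12)
  # survival is non-increasing
  expect_true(all(diff(S2(sort(t))) <= 0))
})

test_that("log-rank statistic matches the hand O-E/variance computation", {
  d <- surv_df(c(1, 3, 2, 4), c(1, 1, 1, 1))
  g <- c("A", "A", "B", "B")
  lr <- logrank_test(d, g)
  # four event times; O_A = 2, E_A = 1/2 + 1/3 + 1/2, V = 1/4 + 2/9 + 1/4
  e_a <- 0.5 + 1 / 3 + 0.5
  v <- 0.25 + 4 / 18 + 0.25
  expect_equal(lr$statistic, (2 - e_a)^2 / v, tolerance = 1e-9)
  expect_equal(lr$df, 1L)
  expect_equal(lr$p_value, pchisq((2 - e_a)^2 / v, 1, lower.tail = FALSE))

  # identical groups: statistic 0, p = 1
  same <- surv_df(c(1, 2, 1, 2), c(1, 1, 1, 1))
  lr0 <- logrank_test(same, c("A", "A", "B", "B"))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  # invariant to strictly increasing time transforms
  set.seed(14)
  d2 <- surv_df(rexp(30), rbinom(30, 1, 0.8))
  g2 <- rep(c("A", "B"), 15)
  d2t <- d2; d2t$time <- d2$time^2
  expect_equal(logrank_test(d2, g2)$statistic,
               logrank_test(d2t, g2)$statistic, tolerance = 1e-9)

  expect_error(logrank_test(d, rep("A", 4)), "two groups")
})

test_that("Cox fit recovers a planted hazard ratio and flips sign cleanly", {
  set.seed(31)
  x <- rep(c(0, 1), each = 250)
  sv <- sim_survival(0.05 * 3^x, censor_rate = 1e-4, seed = 31)
  res <- cox_univariate(sv, x, name = "group")
  expect_lt(abs(res$hazard_ratio - 3) / 3, 0.2)
  # agrees with the closed-form per-group exponential MLE ratio
  mle_hr <- exp_mle_hazard(sv$time[x == 1], sv$event[x == 1]) /
    exp_mle_hazard(sv$time[x == 0], sv$event[x == 0])
  expect_equal(res$hazard_ratio, mle_hr, tolerance = 0.1)
  expect_equal(res$direction, "risk")

  flipped <- cox_univariate(sv, -x)
  expect_equal(flipped$beta, -res$beta, tolerance = 1e-6)
  expect_equal(abs(flipped$z), abs(res$z), tolerance = 1e-6)
  expect_equal(flipped$direction, "protective")

  expect_error(cox_univariate(sv, rep(1, nrow(sv))), "zero variance")
})

test_that("Cox beta maximizes the Breslow partial likelihood", {
  set.seed(12)
  n <- 25
  x <- rnorm(n)
  sv <- sim_survival(0.1 * exp(0.8 * x), censor_rate = 0.02, seed = 12)
  res <- cox_univariate(sv, x)
  # independent oracle: optimize the directly-summed partial likelihood
  opt <- optimize(function(b) cox_partial_loglik(b, sv$time, sv$event, x),
                  c(-5, 5), maximum = TRUE, tol = 1e-9)
  expect_equal(res$beta, opt$maximum, tolerance = 1e-4)
  expect_gte(cox_partial_loglik(res$beta, sv$time, sv$event, x),
             cox_partial_loglik(0, sv$time, sv$event, x))
})

test_that("restricted mean survival orders groups by prognosis", {
  set.seed(9)
  haz <- rep(c(0.02, 0.1), each = 100)
  sv <- sim_survival(haz, censor_rate = 0.01, seed = 9)
  rm <- restricted_mean_survival(sv, rep(c("good", "poor"), each = 100))
  expect_gt(rm[["good"]], rm[["poor"]])

  # hand check: single event at t=1 out of two, tau = 2
  sv2 <- surv_df(c(1, 2), c(1, 0))
  rm2 <- restricted_mean_survival(sv2, c("g", "g"), tau = 2)
  expect_equal(unname(rm2), 1 * 1 + 1 * 0.5)  # S=1 on [0,1), 0.5 on [1,2)
})
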
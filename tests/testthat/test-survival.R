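test_that("Kaplan-Meier steps and the log-rank null behave classically", {
  # hand product-limit: times 1,2,3 with events 1,1,0 -> S = 2/3 then 1/3
  fit <- survival::survfit(survival::Surv(c(1, 2, 3), c(1, 1, 0)) ~ 1)
  expect_equal(fit$surv, c(2 / 3, 1 / 3, 1 / 3))

  # duplicated data in two groups: observed = expected, p = 1
  tt <- c(1, 2, 3, 4, 5); ev <- c(1, 1, 0, 1, 0)
  lr <- km_logrank(c(tt, tt), c(ev, ev), rep(c("a", "b"), each = 5))
  expect_equal(lr$p, 1, tolerance = 1e-9)
  expect_error(km_logrank(tt, ev, rep("a", 5)), "2 non-empty groups")
})

test_that("Cox fits match an independent Newton-Raphson oracle", {
  set.seed(23)
  n <- 60
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.1 * exp(0.7 * x))
  ev <- rep(1, n)
  d <- data.frame(os_time = tt, os_event = ev, x = x)
  fit <- cox_fit(d, "x")
  beta_oracle <- newton_cox_binary(tt, ev, x)
  expect_equal(fit$coefficients$coef, beta_oracle, tolerance = 1e-6)
  expect_true(fit$coefficients$ci_lo < fit$coefficients$hr &
                fit$coefficients$hr < fit$coefficients$ci_hi)
})

test_that("Cox HRs are invariant to time rescaling and null-centred", {
  set.seed(29)
  n <- 4000
  g <- factor(sample(c("low", "high"), n, TRUE), levels = c("low", "high"))
  d <- data.frame(os_time = rexp(n, 0.1), os_event = rbinom(n, 1, 0.9),
                  g = g)
  f1 <- cox_fit(d, "g")
  expect_lt(abs(f1$coefficients$hr - 1), 0.05)   # simulated under HR = 1
  d2 <- transform(d, os_time = os_time * 52)     # years -> weeks
  f2 <- cox_fit(d2, "g")
  expect_equal(f1$coefficients$hr, f2$coefficients$hr, tolerance = 1e-8)
})

test_that("likelihood-ratio comparison of nested Cox models", {
  set.seed(31)
  n <- 150
  d <- data.frame(os_time = rexp(n, 0.1), os_event = rbinom(n, 1, 0.8),
                  x = rnorm(n), z = rnorm(n))
  f0 <- cox_fit(d, "x"); f1 <- cox_fit(d, c("x", "z"))
  lrt <- lrt_compare(f0, f1)
  expect_equal(lrt$statistic,
               2 * (f1$loglik[["model"]] - f0$loglik[["model"]]))
  expect_equal(lrt$df, 1)
  same <- lrt_compare(f0, f0)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(lrt_compare(f1, f0), "not nested")
})

test_that("bootstrap AUC: separation, null centring and determinism", {
  set.seed(37)
  n <- 200
  out <- rbinom(n, 1, 0.5)
  tt <- ifelse(out == 1, runif(n, 0, 5), runif(n, 5, 10))
  perfect <- bootstrap_auc(out + 0, tt, out, B = 50, seed = 1)
  expect_true(all(perfect$aucs == 1))

  s0 <- rnorm(n)
  rnd <- bootstrap_auc(s0, tt, out, B = 400, seed = 2)
  expect_lt(abs(rnd$median - 0.5), 0.05)
  s <- rnorm(n)
  expect_identical(bootstrap_auc(s, tt, out, B = 100, seed = 4)$aucs,
                   bootstrap_auc(s, tt, out, B = 100, seed = 4)$aucs)
  expect_error(bootstrap_auc(s, tt, rep(1, n), B = 10), "single class")
})

test_that("time-dependent AUC equals the concordant-pair oracle", {
  set.seed(41)
  n <- 150
  tt <- rexp(n, 0.2); ev <- rep(1, n)       # no censoring
  sc <- -tt + rnorm(n, sd = 2)              # noisy risk score
  ts <- quantile(tt, c(0.2, 0.5, 0.8))
  ta <- time_dependent_auc(sc, tt, ev, ts)
  oracle <- vapply(ts, function(t0) pair_count_tauc(sc, tt, t0), numeric(1))
  expect_equal(ta$auc, unname(oracle), tolerance = 1e-12)

  # an oracle score ranking by true event time discriminates perfectly
  ta2 <- time_dependent_auc(-tt, tt, ev, ts)
  expect_true(all(ta2$auc == 1))
  expect_warning(time_dependent_auc(sc, tt, ev, c(1, max(tt) + 1)),
                 "beyond follow-up")
})

test_that("random scores give time-dependent AUC near one half", {
  set.seed(43)
  n <- 600
  tt <- rexp(n, 0.2); ev <- rbinom(n, 1, 0.8)
  ta <- time_dependent_auc(rnorm(n), tt, ev, quantile(tt, c(.25, .5, .75)))
  expect_true(all(abs(ta$auc - 0.5) < 0.05))
})

test_that("Wald chi-square contributions sum to one and split evenly", {
  set.seed(47)
  n <- 6000
  x1 <- rnorm(n); x2 <- rnorm(n)
  tt <- rexp(n, 0.1 * exp(0.4 * x1 + 0.4 * x2))
  d <- data.frame(os_time = tt, os_event = 1, x1 = x1, x2 = x2)
  fit <- cox_fit(d, c("x1", "x2"))
  wc <- wald_contributions(fit)
  expect_equal(sum(wc$proportion), 1, tolerance = 1e-9)
  expect_lt(abs(wc$proportion[1] - 0.5), 0.1)  # equal-strength predictors

  single <- wald_contributions(cox_fit(d, "x1"))
  expect_equal(single$proportion, 1)
})

test_that("optimal-cutoff dichotomisation finds a planted step", {
  set.seed(53)
  n <- 600
  v <- runif(n)
  rate <- ifelse(v > 0.5, 0.05, 0.25)       # true step at the median
  d <- data.frame(time = rexp(n, rate), event = 1)
  oc <- optimal_cutoff_dichotomize(v, d$time, d$event)
  expect_lt(abs(mean(v <= oc$cutoff) - 0.5), 0.10)
  expect_match(oc$note, "optimistic")

  # degenerate window returns the median exactly
  oc2 <- optimal_cutoff_dichotomize(v, d$time, d$event,
                                    window = c(0.5, 0.5))
  expect_equal(oc2$cutoff, unname(quantile(v, 0.5)))
  expect_error(optimal_cutoff_dichotomize(rep(1, n), d$time, d$event),
               "identical")
})

test_that("responder analyses: exact U test, ROC and Spearman", {
  scores <- c(1, 2, 3, 4, 5, 6)
  grp <- factor(rep(c("non", "resp"), each = 3), levels = c("non", "resp"))
  r <- suppressWarnings(   # pROC flags the degenerate AUC == 1 interval
    responder_tests(scores, grp, ordinal = c(1, 1, 1, 2, 3, 3),
                    alternative = "less", boot_n = 50))
  expect_equal(r$u, 0)
  expect_equal(r$p_mw, 0.05)        # exact: 1 of choose(6,3) orderings
  expect_equal(r$auc, 1)

  same <- responder_tests(c(1, 2, 3, 1, 2, 3), grp, boot_n = 50)
  expect_equal(same$auc, 0.5)

  mono <- suppressWarnings(responder_tests(scores, grp, ordinal = 1:6,
                                           boot_n = 50))
  expect_equal(mono$rho, 1)
  expect_error(responder_tests(scores, factor(rep("a", 6))), "two response")
})
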
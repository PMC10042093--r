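test_that("harrell_c matches brute-force pair enumeration on random censored samples", {
  set.seed(101)
  for (rep in 1:25) {
    s <- random_survival_sample(120, tie_prone = rep %% 2 == 0)
    if (!any(s$event)) next
    o <- oracle_concordance(s$time, s$event, s$risk)
    h <- harrell_c(s$time, s$event, s$risk)
    expect_identical(h$c, o$c)
    expect_identical(as.numeric(h$n_comparable_pairs), as.numeric(o$comparable))
    expect_identical(as.numeric(h$n_risk_ties), as.numeric(o$ties))
  }
})

test_that("harrell_c hits the degenerate and toy closed cases", {
  # perfect discrimination: higher risk always fails first, no censoring
  time <- 1:10
  risk <- rev(time) / 10
  expect_equal(harrell_c(time, rep(TRUE, 10), risk)$c, 1)
  # all risks equal: everything is a tie
  expect_equal(harrell_c(time, rep(TRUE, 10), rep(0.3, 10))$c, 0.5)
  # five-participant toy sample, value fixed from explicit pair enumeration
  toy <- list(time = c(2, 4, 6, 8, 10), event = c(1, 1, 0, 1, 0),
              risk = c(0.9, 0.5, 0.6, 0.4, 0.1))
  expect_equal(oracle_concordance(toy$time, toy$event, toy$risk)$c, 0.875)
  h <- harrell_c(toy$time, toy$event, toy$risk)
  expect_equal(h$c, 0.875)
  expect_equal(h$n_comparable_pairs, 8)
  # no comparable pairs is an error, not 0.5
  expect_error(harrell_c(c(1, 2), c(0, 0), c(0.1, 0.2)), "comparable")
})

test_that("without censoring harrell_c equals the rank-based AUC of a binary split", {
  # all events by construction; compare with Wilcoxon AUC of risk vs early/late
  set.seed(7)
  n <- 100
  risk <- runif(n)
  time <- rexp(n, exp(2 * risk))      # informative ranking
  h <- harrell_c(time, rep(TRUE, n), risk)
  o <- oracle_concordance(time, rep(TRUE, n), risk)
  expect_equal(h$c, o$c)
  # analytic and bootstrap intervals agree roughly and bracket the estimate
  hb <- harrell_c(time, rep(TRUE, n), risk, ci = "bootstrap", boot_n = 100,
                  boot_seed = 42)
  expect_lt(hb$ci_lo, h$c)
  expect_gt(hb$ci_hi, h$c)
  expect_identical(
    harrell_c(time, rep(TRUE, n), risk, ci = "bootstrap", boot_seed = 42)$ci_lo,
    harrell_c(time, rep(TRUE, n), risk, ci = "bootstrap", boot_seed = 42)$ci_lo)
})

test_that("km_risk reduces to the empirical proportion without censoring", {
  time <- c(1, 3, 5, 12, 15)
  event <- c(TRUE, TRUE, TRUE, FALSE, FALSE)  # censoring only after t0
  km <- km_risk(time, event, 10)
  expect_equal(km$risk, 3 / 5)
  expect_equal(km$risk, oracle_km_risk(time, event, 10))
  # no events before t0
  km0 <- km_risk(c(2, 4, 11), c(FALSE, FALSE, TRUE), 10)
  expect_equal(km0$risk, 0)
  expect_equal(km0$var, 0)
})

test_that("km_risk matches the hand-rolled product-limit oracle under censoring", {
  set.seed(31)
  for (rep in 1:10) {
    s <- random_survival_sample(80)
    km <- km_risk(s$time, s$event, 10)
    expect_equal(km$risk, oracle_km_risk(s$time, s$event, 10),
                 tolerance = 1e-12)
  }
})

test_that("km_risk ignores follow-up beyond t0 and is monotone in t0", {
  set.seed(37)
  s <- random_survival_sample(200)
  base <- km_risk(s$time, s$event, 10)$risk
  # shift censor times beyond t0 and recode post-t0 events as censored
  t2 <- ifelse(s$time > 10, s$time + 5, s$time)
  e2 <- ifelse(s$time > 10, FALSE, s$event)
  expect_equal(km_risk(t2, e2, 10)$risk, base, tolerance = 1e-12)
  t0s <- c(2, 5, 8, 10, 14)
  risks <- vapply(t0s, function(t0) km_risk(s$time, s$event, t0)$risk,
                  numeric(1))
  expect_true(all(diff(risks) >= 0))
})

test_that("km_risk recovers the closed-form exponential risk under censoring", {
  set.seed(41)
  n <- 30000
  t_ev <- rexp(n, 0.02)
  t_cn <- runif(n, 0, 40)
  time <- pmin(t_ev, t_cn)
  event <- t_ev <= t_cn
  km <- km_risk(time, event, 10)
  truth <- 1 - exp(-0.2)
  expect_lt(abs(km$risk - truth), 3 * km$se)
})

test_that("calibration deciles are equal-sized, ordered, and stable under ties", {
  set.seed(43)
  n <- 200
  risk <- runif(n)
  time <- rexp(n, 0.05)
  event <- time < 12
  cal <- calibration_table(time, event, risk, t0 = 10)
  expect_equal(sum(cal$n), n)
  expect_equal(unique(cal$n), 20)
  expect_true(all(diff(cal$mean_predicted) >= 0))
  expect_equal(cal$expected_cases, cal$n * cal$mean_predicted)
  # constant predicted risk: groups formed by stable order, no errors
  cal2 <- calibration_table(time, event, rep(0.2, n), t0 = 10)
  expect_equal(unique(cal2$mean_predicted), 0.2)
  # n = groups: one participant per group, mean predicted = own risk
  cal3 <- calibration_table(time[1:10], event[1:10], risk[1:10], t0 = 10,
                            n_groups = 10)
  expect_equal(cal3$mean_predicted, sort(risk[1:10]))
  expect_error(calibration_table(time[1:5], event[1:5], risk[1:5]), "fewer")
})

test_that("a perfectly calibrated sample tracks the 45-degree line", {
  set.seed(47)
  n <- 40000
  rate <- 0.02 * exp(rnorm(n, 0, 0.6))
  p_true <- 1 - exp(-10 * rate)
  t_ev <- rexp(n, rate)
  time <- pmin(t_ev, 12)
  event <- t_ev <= 12
  cal <- calibration_table(time, event, p_true, t0 = 10)
  dev <- abs(cal$observed - cal$mean_predicted) /
    sqrt(pmax(cal$greenwood_var, 1e-12))
  expect_lt(max(dev), 4)  # each decile within 4 Greenwood SE of its mean
})

test_that("predicted-to-observed ratio has its closed properties", {
  set.seed(53)
  n <- 20000
  p <- 0.15
  t_ev <- rexp(n, -log(1 - p) / 10)
  time <- pmin(t_ev, 12)
  event <- t_ev <= 12
  ratio <- po_ratio(time, event, rep(p, n), t0 = 10)
  se <- sqrt(p * (1 - p) / n) / p
  expect_lt(abs(ratio - 1), 3 * se)
  expect_equal(po_ratio(time, event, rep(2 * p, n), t0 = 10), 2 * ratio)
  expect_equal(po_ratio(time, event, rep(0, n), t0 = 10), 0)
  expect_error(po_ratio(rep(12, 5), rep(FALSE, 5), rep(0.1, 5), t0 = 10),
               "zero observed")
})

test_that("nam_dagostino is exact on constructed tables and merges zero-event groups", {
  cal <- data.frame(group = 1:10, n = 100,
                    mean_predicted = seq(0.05, 0.5, by = 0.05),
                    observed = seq(0.05, 0.5, by = 0.05),
                    greenwood_var = 0.001, expected_cases = 10,
                    observed_cases = 10, n_events = 5)
  nd <- nam_dagostino(cal)
  expect_equal(nd$chi2, 0)
  expect_equal(nd$df, 10)
  expect_equal(nd$p_value, 1)
  # one group inflated by 3 Greenwood SE: chi-square contribution exactly 9
  cal2 <- cal
  cal2$observed[4] <- cal2$mean_predicted[4] + 3 * sqrt(cal2$greenwood_var[4])
  expect_equal(nam_dagostino(cal2)$chi2, 9)
  # df convention switch
  expect_equal(nam_dagostino(cal2, df_rule = "groups_minus_1")$df, 9)
  # zero-event group merged into adjacent lower-risk group
  cal3 <- cal
  cal3$n_events[5] <- 0
  cal3$greenwood_var[5] <- 0
  nd3 <- nam_dagostino(cal3)
  expect_equal(nd3$n_groups_used, 9)
  expect_equal(nd3$n_merged, 1)
  expect_equal(nd3$df, 9)
  # invariant to relabelling group order
  cal4 <- cal2[sample(1:10), ]
  cal4$group <- 1:10
  expect_equal(nam_dagostino(cal4)$chi2, 9)
  expect_error(nam_dagostino(cal[1, , drop = FALSE]), "fewer than 2")
})

test_that("DerSimonian-Laird pooling matches the hand-computed toy and its properties", {
  # identical regions: pooled equals the common value, no heterogeneity
  same <- pool_c_indices(c(0.7, 0.7, 0.7), c(1e-4, 1e-4, 1e-4))
  expect_equal(same$pooled, 0.7)
  expect_equal(same$tau2, 0)
  # two regions, hand-computed: Q = 8, C = 1e4, tau2 = 7e-4,
  # weights 1/(1e-4 + 7e-4) each -> pooled 0.72, se = sqrt(1/2500) = 0.02
  two <- pool_c_indices(c(0.70, 0.74), c(1e-4, 1e-4))
  expect_equal(two$pooled, 0.72)
  expect_equal(two$tau2, 7e-4)
  expect_equal(two$se, 0.02)
  expect_equal(two$ci_lo, 0.72 - qnorm(0.975) * 0.02)
  expect_equal(two$ci_hi, 0.72 + qnorm(0.975) * 0.02)
  # random-effects CI at least as wide as fixed-effect when tau2 > 0
  fe_se <- sqrt(1 / sum(1 / c(1e-4, 1e-4)))
  expect_gt(two$ci_hi - two$ci_lo, 2 * qnorm(0.975) * fe_se)
  expect_error(pool_c_indices(0.7, 1e-4), "at least 2")
  expect_error(pool_c_indices(c(0.7, 0.72), c(1e-4, NA)), "variance")
})

test_that("delta_c is the difference of concordances and antisymmetric", {
  a <- list(c = 0.674); b <- list(c = 0.749)
  class(a) <- class(b) <- "concordance_result"
  expect_equal(delta_c(a, b), 0.075)
  expect_equal(delta_c(a, a), 0)
  expect_equal(delta_c(b, a), -delta_c(a, b))
})

test_that("metrics are invariant to row permutation of the sample", {
  set.seed(59)
  s <- random_survival_sample(150, tie_prone = FALSE)  # distinct risks
  perm <- sample(150)
  expect_equal(harrell_c(s$time, s$event, s$risk)$c,
               harrell_c(s$time[perm], s$event[perm], s$risk[perm])$c)
  expect_equal(km_risk(s$time, s$event, 8)$risk,
               km_risk(s$time[perm], s$event[perm], 8)$risk)
  c1 <- calibration_table(s$time, s$event, s$risk, t0 = 8, n_groups = 5)
  c2 <- calibration_table(s$time[perm], s$event[perm], s$risk[perm],
                          t0 = 8, n_groups = 5)
  expect_equal(c1$observed, c2$observed)
  expect_equal(c1$mean_predicted, c2$mean_predicted)
})
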
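no_effect_truth <- function(rate_cor = 0.004, rate_str = 0.008,
                            ltfu = 0, horizon = 12) {
  zero <- c(age = 0, smoker = 0, sbp = 0, bmi = 0)
  hazard_spec(
    log_hr = list(female = list(coronary = zero, stroke = zero),
                  male = list(coronary = zero, stroke = zero)),
    baseline_rate = list(female = list(coronary = rate_cor, stroke = rate_str),
                         male = list(coronary = rate_cor, stroke = rate_str)),
    ltfu_prob = ltfu, horizon = horizon)
}

plain_region <- function(id = "r1", mult = c(coronary = 1, stroke = 1)) {
  region_spec(id, hazard_multipliers = mult)
}

test_that("cohort generation is deterministic in the seed", {
  regs <- list(plain_region("a"), plain_region("b"))
  truth <- hazard_spec()
  c1 <- generate_cohort(regs, truth, 300, seed = 11)
  c2 <- generate_cohort(regs, truth, 300, seed = 11)
  c3 <- generate_cohort(regs, truth, 300, seed = 12)
  expect_identical(c1, c2)
  expect_false(identical(c1, c3))
})

test_that("invalid region parameters are rejected naming region and field", {
  cv <- default_region_covariates()
  cv$female$smoking_prev <- 1.4
  expect_error(region_spec("bad_smk", covariates = cv),
               "bad_smk.*smoking_prev")
  expect_error(region_spec("bad_mult",
                           hazard_multipliers = c(coronary = 0, stroke = 1)),
               "bad_mult.*hazard_multipliers")
  cv2 <- default_region_covariates()
  cv2$male$sbp_sd <- -1
  expect_error(region_spec("bad_sd", covariates = cv2), "bad_sd.*sbp_sd")
})

test_that("event risk approaches the closed-form exponential limit", {
  # no covariate effects, censoring only at the horizon
  truth <- no_effect_truth(rate_cor = 0.004, rate_str = 0.008)
  co <- generate_cohort(plain_region(), truth, 100000, seed = 5,
                        inject = c(age_under_40 = 0, prior_cvd = 0,
                                   missing_bmi = 0))
  p_any <- mean(co$followup_time <= 10 & co$event)
  expected <- 1 - exp(-10 * (0.004 + 0.008))
  se <- sqrt(expected * (1 - expected) / nrow(co))
  expect_lt(abs(p_any - expected), 3 * se)
  # subtype-specific proportion follows its own rate (other does not censor)
  oc <- first_event_outcome(co, "stroke_only")
  p_str <- mean(oc$time <= 10 & oc$event)
  exp_str <- 1 - exp(-10 * 0.008)
  expect_lt(abs(p_str - exp_str),
            3 * sqrt(exp_str * (1 - exp_str) / nrow(co)))
})

test_that("a doubled stroke multiplier doubles the 10-year stroke risk", {
  # constant rates so the closed-form exponential risk is the oracle:
  # (1 - exp(-0.16)) / (1 - exp(-0.08)) = 1.92
  truth <- no_effect_truth(rate_cor = 0.004, rate_str = 0.008, ltfu = 0)
  regs <- list(plain_region("base", c(coronary = 1, stroke = 1)),
               plain_region("high", c(coronary = 1, stroke = 2)))
  co <- generate_cohort(regs, truth, 50000, seed = 9,
                        inject = c(age_under_40 = 0, prior_cvd = 0,
                                   missing_bmi = 0))
  oc <- first_event_outcome(co, "stroke_only")
  r <- vapply(c("base", "high"), function(g) {
    i <- co$region_id == g
    km_risk(oc$time[i], oc$event[i], 10)$risk
  }, numeric(1))
  expect_gt(r[["high"]] / r[["base"]], 1.8)
  expect_lt(r[["high"]] / r[["base"]], 2.2)
})

test_that("observed subtype labels match the first latent event", {
  co <- generate_cohort(plain_region(), hazard_spec(), 2000, seed = 3)
  ev <- co[co$event, ]
  expect_true(all(ev$event_subtype != "none"))
  both <- ev[!is.na(ev$event_time_coronary) & !is.na(ev$event_time_stroke), ]
  expect_true(all(
    (both$event_subtype == "coronary") ==
      (both$event_time_coronary <= both$event_time_stroke)))
  expect_equal(ev$followup_time,
               pmin(ev$event_time_coronary, ev$event_time_stroke, na.rm = TRUE))
  expect_true(all(co$followup_time <= hazard_spec()$horizon))
})

test_that("loss to follow-up is rare and censors rather than drops", {
  truth <- no_effect_truth(rate_cor = 1e-6, rate_str = 1e-6, ltfu = 0.01)
  co <- generate_cohort(plain_region(), truth, 50000, seed = 21,
                        inject = c(age_under_40 = 0, prior_cvd = 0,
                                   missing_bmi = 0))
  expect_equal(nrow(co), 50000)
  lost <- mean(!co$event & co$followup_time < truth$horizon)
  expect_lt(abs(lost - 0.01), 3 * sqrt(0.01 * 0.99 / 50000) + 1e-4)
})

test_that("eligibility filters partition exclusions by the fixed reason order", {
  co <- toy_cohort(3)
  # identity case: nothing to exclude
  f <- apply_eligibility_filters(co)
  expect_equal(nrow(f$cohort), 3)
  expect_equal(unname(f$exclusions), c(0L, 0L, 0L))
  # constructed case: one row per reason, one row failing two reasons
  co2 <- toy_cohort(6)
  co2$age[1] <- 35
  co2$prior_cvd[2] <- TRUE
  co2$bmi[3] <- NA
  co2$age[4] <- 30; co2$prior_cvd[4] <- TRUE  # counted under age only
  f2 <- apply_eligibility_filters(co2)
  expect_equal(nrow(f2$cohort), 2)
  expect_equal(f2$exclusions,
               c(age_under_40 = 2L, prior_cvd = 1L, missing_bmi = 1L))
  expect_true(all(f2$cohort$age >= 40))
  expect_false(any(f2$cohort$prior_cvd))
  expect_false(anyNA(f2$cohort$bmi))
})

test_that("injected ineligibility fractions land within binomial bounds", {
  frac <- c(age_under_40 = 0.05, prior_cvd = 0.03, missing_bmi = 0.001)
  n <- 40000
  co <- generate_cohort(plain_region(), hazard_spec(), n, seed = 2,
                        inject = frac)
  f <- apply_eligibility_filters(co)
  expect_equal(nrow(f$cohort) + sum(f$exclusions), n)
  # first-reason-match expectations: prior-cvd and missing-bmi counts are
  # thinned by the preceding reasons (independent injection marks)
  exp_n <- n * c(frac[1],
                 frac[2] * (1 - frac[1]),
                 frac[3] * (1 - frac[1]) * (1 - frac[2]))
  for (k in 1:3) {
    bound <- qnorm(0.995) * sqrt(exp_n[k] * (1 - exp_n[k] / n))
    expect_lt(abs(f$exclusions[k] - exp_n[k]), bound + 3)
  }
})

test_that("first-event outcome follows the min rule and D2 subtype handling", {
  co <- toy_cohort(3)
  co$event_time_coronary <- c(3.2, NA, NA)
  co$event_time_stroke <- c(5.0, NA, NA)
  co$followup_time <- c(3.2, 11.0, 11.0)
  co$event <- c(TRUE, FALSE, FALSE)
  co$event_subtype <- c("coronary", "none", "none")
  co$censor_time <- c(12, 11, 11)
  tot <- first_event_outcome(co, "total_cvd")
  expect_equal(tot$time[1], 3.2)
  expect_true(tot$event[1])
  stk <- first_event_outcome(co, "stroke_only")
  expect_equal(stk$time[1], 5.0)   # coronary event does not censor stroke
  expect_true(stk$event[1])
  cor <- first_event_outcome(co, "coronary_only")
  expect_equal(cor$time[1], 3.2)
  # no events: censored at follow-up under every definition
  for (d in c("total_cvd", "coronary_only", "stroke_only")) {
    oc <- first_event_outcome(co, d)
    expect_equal(oc$time[2:3], c(11, 11))
    expect_false(any(oc$event[2:3]))
  }
  expect_error(first_event_outcome(co, "everything"), "arg")
})

test_that("cohort CSV round-trips with missing bmi as empty fields", {
  co <- generate_cohort(plain_region(), hazard_spec(), 200, seed = 4,
                        inject = c(missing_bmi = 0.1))
  f <- tempfile(fileext = ".csv")
  write_cohort(co, f)
  expect_true(any(is.na(co$bmi)))
  back <- read_cohort(f)
  expect_equal(as.data.frame(back), as.data.frame(co), tolerance = 1e-12)
  unlink(f)
})
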
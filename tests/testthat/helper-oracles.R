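# Independent oracles and small fixtures shared across tests.

# Brute-force all-pairs Harrell's C. A pair (first, second) is comparable if
# the first has an event strictly before the second's time, or at a tied time
# when exactly one of the two has an event (the event member is "first").
# Risk ties contribute 1/2. Deliberately independent of the package path.
oracle_concordance <- function(time, event, risk) {
  n <- length(time)
  ev <- as.integer(event)
  Ei <- matrix(ev, n, n)
  Ej <- t(Ei)
  Tlt <- outer(time, time, "<")
  Teq <- outer(time, time, "==")
  diag(Teq) <- FALSE
  A <- (Tlt & Ei == 1) | (Teq & Ei == 1 & Ej == 0)
  Ri <- matrix(risk, n, n)
  Rj <- t(Ri)
  comp <- sum(A)
  conc <- sum(A & Ri > Rj)
  tie <- sum(A & Ri == Rj)
  list(c = (conc + 0.5 * tie) / comp, comparable = comp, ties = tie)
}

# Hand-rolled Kaplan-Meier risk at t0 (product-limit over event times).
oracle_km_risk <- function(time, event, t0) {
  ut <- sort(unique(time[event & time <= t0]))
  s <- 1
  for (t in ut) {
    d <- sum(time == t & event)
    r <- sum(time >= t)
    s <- s * (1 - d / r)
  }
  1 - s
}

# A random censored sample with time and risk ties for property tests.
random_survival_sample <- function(n, tie_prone = TRUE) {
  if (tie_prone) {
    time <- sample(1:15, n, replace = TRUE)
    risk <- round(runif(n), 1)
  } else {
    time <- rexp(n, 0.1)
    risk <- runif(n)
  }
  list(time = time, event = rbinom(n, 1, 0.6) == 1, risk = risk)
}

# Hand-set submodels with simple coefficients for engine/recalibration tests.
toy_model <- function(ref = list(female = c(coronary = 0.04, stroke = 0.06),
                                 male = c(coronary = 0.05, stroke = 0.07))) {
  sms <- list()
  for (sex in c("female", "male")) for (st in c("coronary", "stroke")) {
    sms[[length(sms) + 1L]] <- submodel(
      sex, st,
      coefficients = c(age = 0.05, smoker = 0.7, sbp = 0.01, bmi = 0.02),
      reference_risk = ref[[sex]][[st]],
      centring = c(age = 60, sbp = 120, bmi = 25))
  }
  risk_model(sms, name = "toy", vintage = "test")
}

# Minimal eligible cohort rows built directly (no simulator).
toy_cohort <- function(n, seed = 1) {
  set.seed(seed)
  d <- data.frame(
    id = sprintf("t%04d", seq_len(n)),
    region_id = "r1",
    sex = sample(c("female", "male"), n, replace = TRUE),
    age = runif(n, 40, 79),
    smoker = runif(n) < 0.3,
    sbp = runif(n, 100, 180),
    bmi = runif(n, 18, 35),
    prior_cvd = FALSE,
    followup_time = runif(n, 1, 12),
    event = runif(n) < 0.3,
    stringsAsFactors = FALSE)
  d$event_subtype <- ifelse(d$event,
                            sample(c("coronary", "stroke"), n, TRUE), "none")
  d$event_time_coronary <- ifelse(d$event & d$event_subtype == "coronary",
                                  d$followup_time, NA_real_)
  d$event_time_stroke <- ifelse(d$event & d$event_subtype == "stroke",
                                d$followup_time, NA_real_)
  d$censor_time <- pmax(d$followup_time, 12)
  class(d) <- c("cohort_table", "data.frame")
  d
}
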
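#' Region specification for the cohort simulator
#'
#' Describes one study region: its label, urban/rural status, per-sex
#' risk-factor distributions, and per-subtype multipliers applied to the
#' baseline hazards of the data-generating truth. Regional heterogeneity in
#' both risk-factor levels (e.g. smoking prevalence) and baseline hazards is
#' what makes a universal risk model miscalibrated region by region, so these
#' knobs are the core of the simulator.
#'
#' @param region_id Character label, e.g. `"region_01"`.
#' @param urban Logical; urban (`TRUE`) or rural (`FALSE`) region.
#' @param covariates Named list with elements `female` and `male`, each a list
#'   with `age_range` (length-2 numeric, years), `smoking_prev` (proportion in
#'   \[0,1\]), `sbp_mean`, `sbp_sd` (mmHg), `bmi_mean`, `bmi_sd` (kg/m^2).
#' @param hazard_multipliers Named positive numeric vector with elements
#'   `coronary` and `stroke`; multiplies the baseline subtype hazards of the
#'   truth specification for this region.
#' @param sex_female_prob Probability that a simulated participant is female.
#'
#' @return An object of class `region_spec`.
#' @seealso [hazard_spec()], [generate_cohort()], [default_region_panel()]
#' @export
region_spec <- function(region_id, urban = FALSE,
                        covariates = default_region_covariates(),
                        hazard_multipliers = c(coronary = 1, stroke = 1),
                        sex_female_prob = 0.586) {
  stopifnot(is.character(region_id), length(region_id) == 1L)
  for (sex in c("female", "male")) {
    cv <- covariates[[sex]]
    if (is.null(cv))
      stop("region '", region_id, "': missing covariate distribution for sex '",
           sex, "'", call. = FALSE)
    if (is.null(cv$age_range) || length(cv$age_range) != 2L ||
        cv$age_range[1] >= cv$age_range[2])
      stop("region '", region_id, "' (", sex, "): invalid field 'age_range'",
           call. = FALSE)
    if (is.null(cv$smoking_prev) || cv$smoking_prev < 0 || cv$smoking_prev > 1)
      stop("region '", region_id, "' (", sex,
           "): field 'smoking_prev' must be in [0, 1]", call. = FALSE)
    for (f in c("sbp_sd", "bmi_sd"))
      if (is.null(cv[[f]]) || cv[[f]] <= 0)
        stop("region '", region_id, "' (", sex, "): field '", f,
             "' must be > 0", call. = FALSE)
    for (f in c("sbp_mean", "bmi_mean"))
      if (is.null(cv[[f]]) || !is.finite(cv[[f]]))
        stop("region '", region_id, "' (", sex, "): field '", f,
             "' must be finite", call. = FALSE)
  }
  hm <- hazard_multipliers[c("coronary", "stroke")]
  if (anyNA(hm) || any(hm <= 0))
    stop("region '", region_id,
         "': field 'hazard_multipliers' must be positive for coronary and stroke",
         call. = FALSE)
  if (sex_female_prob < 0 || sex_female_prob > 1)
    stop("region '", region_id, "': field 'sex_female_prob' must be in [0, 1]",
         call. = FALSE)
  structure(list(region_id = region_id, urban = isTRUE(urban),
                 covariates = covariates, hazard_multipliers = hm,
                 sex_female_prob = sex_female_prob),
            class = "region_spec")
}

#' Default per-sex risk-factor distributions
#'
#' Central values follow a large Chinese middle-aged cohort: median systolic
#' blood pressure near 128/130 mmHg and body mass index near 23.7/23.1 kg/m^2
#' in women/men, smoking common in men and rare in women, ages spanning 40-79.
#'
#' @param smoking_prev_female,smoking_prev_male Current-smoking prevalences.
#' @param sbp_shift,bmi_shift Additive region shifts (mmHg, kg/m^2).
#' @return Named list with `female` and `male` distribution parameter sets.
#' @keywords internal
default_region_covariates <- function(smoking_prev_female = 0.023,
                                      smoking_prev_male = 0.569,
                                      sbp_shift = 0, bmi_shift = 0) {
  list(
    female = list(age_range = c(40, 79), smoking_prev = smoking_prev_female,
                  sbp_mean = 130 + sbp_shift, sbp_sd = 20,
                  bmi_mean = 23.9 + bmi_shift, bmi_sd = 3.4),
    male = list(age_range = c(40, 79), smoking_prev = smoking_prev_male,
                sbp_mean = 132 + sbp_shift, sbp_sd = 20,
                bmi_mean = 23.3 + bmi_shift, bmi_sd = 3.2)
  )
}

#' Data-generating truth for the cohort simulator
#'
#' Defines the true proportional-hazards model that generates latent coronary
#' and stroke event times: per-sex, per-subtype log hazard ratios for age,
#' current smoking, systolic blood pressure and body mass index; per-sex,
#' per-subtype baseline hazards at the reference profile; and the censoring
#' mechanisms (independent loss to follow-up plus an administrative horizon).
#'
#' Latent event times are Weibull with shape `weibull_shape` (exponential at
#' the default shape 1, giving closed-form event risks
#' \eqn{1 - \exp(-\lambda m e^{lp} t)} used by the test oracles).
#'
#' @param log_hr Nested list `[[sex]][[subtype]]`, each a named numeric vector
#'   with elements `age` (per year), `smoker`, `sbp` (per mmHg), `bmi`
#'   (per kg/m^2), on the log hazard-ratio scale.
#' @param baseline_rate Nested list `[[sex]][[subtype]]` of positive baseline
#'   event rates per person-year at the reference profile.
#' @param centring Named numeric vector (`age`, `sbp`, `bmi`) giving the
#'   reference profile at which the baseline rates apply (non-smoker).
#' @param ltfu_prob Probability of loss to follow-up before the horizon;
#'   realised as an independent exponential censoring time.
#' @param extra_censor_rate Additional independent censoring rate per
#'   person-year (0 disables it).
#' @param horizon Administrative follow-up horizon in years.
#' @param weibull_shape Weibull shape of the latent times (1 = exponential).
#'
#' @return An object of class `hazard_spec`.
#' @export
hazard_spec <- function(log_hr = default_true_log_hr(),
                        baseline_rate = default_true_baseline_rates(),
                        centring = c(age = 55, sbp = 130, bmi = 23.5),
                        ltfu_prob = 0.01,
                        extra_censor_rate = 0,
                        horizon = 12,
                        weibull_shape = 1) {
  for (sex in c("female", "male")) for (st in c("coronary", "stroke")) {
    if (is.null(log_hr[[sex]][[st]]))
      stop("hazard_spec: missing log_hr[", sex, "][", st, "]", call. = FALSE)
    br <- baseline_rate[[sex]][[st]]
    if (is.null(br) || br <= 0)
      stop("hazard_spec: baseline_rate[", sex, "][", st, "] must be > 0",
           call. = FALSE)
  }
  stopifnot(horizon > 0, weibull_shape > 0, extra_censor_rate >= 0)
  if (ltfu_prob < 0 || ltfu_prob > 1)
    stop("hazard_spec: ltfu_prob must be in [0, 1]", call. = FALSE)
  structure(list(log_hr = log_hr, baseline_rate = baseline_rate,
                 centring = centring, ltfu_prob = ltfu_prob,
                 extra_censor_rate = extra_censor_rate, horizon = horizon,
                 weibull_shape = weibull_shape),
            class = "hazard_spec")
}

#' @rdname hazard_spec
#' @export
default_true_log_hr <- function() {
  cor <- c(age = 0.070, smoker = 0.45, sbp = 0.016, bmi = 0.035)
  str <- c(age = 0.080, smoker = 0.25, sbp = 0.022, bmi = 0.020)
  list(female = list(coronary = cor, stroke = str),
       male = list(coronary = cor, stroke = str))
}

#' @rdname hazard_spec
#' @export
default_true_baseline_rates <- function() {
  # Crude subtype rates in the emulated population are ~0.009 (coronary) and
  # ~0.017 (stroke) events per person-year; reference-profile rates are lower
  # because the population mean age exceeds the reference age.
  list(female = list(coronary = 0.0060, stroke = 0.0105),
       male = list(coronary = 0.0055, stroke = 0.0110))
}

#' Generate a synthetic multi-region cohort
#'
#' Draws participant covariates from each region's per-sex distributions, then
#' simulates latent coronary and stroke event times from the true
#' proportional-hazards model (baseline subtype hazard x region multiplier x
#' exp(true linear predictor)), censors at the minimum of an independent
#' loss-to-follow-up time and the administrative horizon, and records the
#' first-occurring subtype as the observed event. A stated fraction of rows is
#' injected with ineligibility markers (age under 40, prior cardiovascular
#' disease, missing body mass index) so that eligibility filtering is
#' exercised downstream; see [apply_eligibility_filters()].
#'
#' @param regions List of [region_spec()] objects.
#' @param truth A [hazard_spec()] object.
#' @param n_per_region Number of participants drawn per region.
#' @param seed Integer seed; the same (specs, seed) always reproduces the same
#'   cohort.
#' @param inject Named numeric vector of injection fractions
#'   (`age_under_40`, `prior_cvd`, `missing_bmi`).
#'
#' @return A `cohort_table`: a data.frame with one row per participant and
#'   columns `id`, `region_id`, `sex`, `age`, `smoker`, `sbp`, `bmi`,
#'   `prior_cvd`, `followup_time`, `event`, `event_subtype`,
#'   `event_time_coronary`, `event_time_stroke` (NA when unobserved) and
#'   `censor_time` (the subtype-agnostic censoring time, i.e. min of loss to
#'   follow-up and horizon, needed for subtype-specific outcomes in which the
#'   other subtype does not censor).
#' @export
generate_cohort <- function(regions, truth, n_per_region, seed,
                            inject = c(age_under_40 = 0.15,
                                       prior_cvd = 0.045,
                                       missing_bmi = 0.001)) {
  stopifnot(n_per_region >= 1, inherits(truth, "hazard_spec"))
  if (inherits(regions, "region_spec")) regions <- list(regions)
  lapply(regions, function(r)
    if (!inherits(r, "region_spec")) stop("regions must be region_spec objects"))
  inj <- c(age_under_40 = 0, prior_cvd = 0, missing_bmi = 0)
  inj[names(inject)] <- inject

  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  parts <- lapply(regions, function(rg)
    simulate_region(rg, truth, n_per_region, inj))
  out <- do.call(rbind, parts)
  out$id <- sprintf("p%06d", seq_len(nrow(out)))
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

# One region's draw; RNG state flows from the caller.
simulate_region <- function(rg, truth, n, inj) {
  sex <- ifelse(stats::runif(n) < rg$sex_female_prob, "female", "male")
  age <- sbp <- bmi <- numeric(n)
  smoker <- logical(n)
  for (s in c("female", "male")) {
    i <- sex == s
    cv <- rg$covariates[[s]]
    age[i] <- stats::runif(sum(i), cv$age_range[1], cv$age_range[2])
    smoker[i] <- stats::runif(sum(i)) < cv$smoking_prev
    sbp[i] <- stats::rnorm(sum(i), cv$sbp_mean, cv$sbp_sd)
    bmi[i] <- stats::rnorm(sum(i), cv$bmi_mean, cv$bmi_sd)
  }
  sbp <- pmin(pmax(sbp, 70), 260)
  bmi <- pmin(pmax(bmi, 14), 50)

  # ineligibility injection (independent marks; under-40 ages span 30-39)
  i_age <- stats::runif(n) < inj[["age_under_40"]]
  age[i_age] <- stats::runif(sum(i_age), 30, 40)
  prior_cvd <- stats::runif(n) < inj[["prior_cvd"]]
  bmi[stats::runif(n) < inj[["missing_bmi"]]] <- NA_real_

  cen <- truth$centring
  lp_for <- function(st) {
    out <- numeric(n)
    for (s in c("female", "male")) {
      i <- sex == s
      b <- truth$log_hr[[s]][[st]]
      bmi_c <- ifelse(is.na(bmi[i]), 0, bmi[i] - cen[["bmi"]])
      out[i] <- b[["age"]] * (age[i] - cen[["age"]]) +
        b[["smoker"]] * smoker[i] +
        b[["sbp"]] * (sbp[i] - cen[["sbp"]]) +
        b[["bmi"]] * bmi_c
    }
    out
  }
  base_for <- function(st)
    ifelse(sex == "female", truth$baseline_rate$female[[st]],
           truth$baseline_rate$male[[st]])
  latent_time <- function(st) {
    rate <- base_for(st) * rg$hazard_multipliers[[st]] * exp(lp_for(st))
    e <- stats::rexp(n)  # cumulative hazard draw; invert H(t) = rate * t^shape
    (e / rate)^(1 / truth$weibull_shape)
  }
  t_cor <- latent_time("coronary")
  t_str <- latent_time("stroke")

  ltfu_rate <- if (truth$ltfu_prob > 0)
    -log(1 - truth$ltfu_prob) / truth$horizon else 0
  cens_rate <- ltfu_rate + truth$extra_censor_rate
  t_cens <- if (cens_rate > 0) stats::rexp(n, cens_rate) else rep(Inf, n)
  censor_time <- pmin(t_cens, truth$horizon)

  t_first <- pmin(t_cor, t_str)
  event <- t_first <= censor_time
  followup_time <- pmin(t_first, censor_time)
  event_subtype <- ifelse(!event, "none",
                          ifelse(t_cor <= t_str, "coronary", "stroke"))

  data.frame(
    id = NA_character_, region_id = rg$region_id, sex = sex, age = age,
    smoker = smoker, sbp = sbp, bmi = bmi, prior_cvd = prior_cvd,
    followup_time = followup_time, event = event,
    event_subtype = event_subtype,
    event_time_coronary = ifelse(t_cor <= censor_time, t_cor, NA_real_),
    event_time_stroke = ifelse(t_str <= censor_time, t_str, NA_real_),
    censor_time = censor_time,
    stringsAsFactors = FALSE
  )
}

#' Apply the study eligibility filters
#'
#' Retains participants aged 40 or over, free of prior cardiovascular disease
#' (including stroke and transient ischaemic attack), and with non-missing
#' body mass index. Rows failing several criteria are counted once, under the
#' first matching reason in the fixed order: age, prior disease, missing BMI.
#'
#' @param cohort A `cohort_table` (or any data.frame with columns `age`,
#'   `prior_cvd`, `bmi`).
#' @return A list with `cohort` (the eligible rows, class preserved) and
#'   `exclusions` (named integer vector: `age_under_40`, `prior_cvd`,
#'   `missing_bmi`).
#' @export
apply_eligibility_filters <- function(cohort) {
  r_age <- cohort$age < 40
  r_cvd <- !r_age & cohort$prior_cvd
  r_bmi <- !r_age & !cohort$prior_cvd & is.na(cohort$bmi)
  keep <- !(r_age | r_cvd | r_bmi)
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(cohort = out,
       exclusions = c(age_under_40 = sum(r_age),
                      prior_cvd = sum(r_cvd),
                      missing_bmi = sum(r_bmi)))
}

#' Map a cohort to a (time, event) outcome under a given definition
#'
#' For `total_cvd`, the outcome time is the first cardiovascular event of
#' either subtype (the first-event rule). For `coronary_only` / `stroke_only`,
#' only the named subtype counts as an event and the other subtype does *not*
#' censor: the participant stays at risk until their own-subtype event or
#' their censoring time, so the two subtype analyses consider first coronary
#' and first stroke events separately.
#'
#' @param cohort A `cohort_table`.
#' @param definition One of `"total_cvd"`, `"coronary_only"`, `"stroke_only"`.
#' @return A data.frame with columns `id`, `time`, `event`.
#' @export
first_event_outcome <- function(cohort,
                                definition = c("total_cvd", "coronary_only",
                                               "stroke_only")) {
  definition <- match.arg(definition)
  if (definition == "total_cvd") {
    time <- cohort$followup_time
    event <- cohort$event
  } else {
    st <- if (definition == "coronary_only") "event_time_coronary"
          else "event_time_stroke"
    tev <- cohort[[st]]
    cens <- if (!is.null(cohort$censor_time)) cohort$censor_time
            else cohort$followup_time
    event <- !is.na(tev)
    time <- ifelse(event, tev, cens)
  }
  data.frame(id = cohort$id, time = time, event = as.logical(event),
             stringsAsFactors = FALSE)
}

#' Ten heterogeneous study regions for the synthetic replica
#'
#' A default panel of 10 regions (5 urban, 5 rural) with heterogeneous
#' smoking prevalence (0.2%-10.2% in women, 39%-65% in men, spanning the
#' regional spread observed in large Chinese cohorts), shifted blood-pressure
#' and adiposity distributions, and baseline-hazard multipliers spanning
#' roughly 0.4x-2.5x so that a universal model is well calibrated in some
#' regions and badly miscalibrated in others.
#'
#' @return A list of 10 [region_spec()] objects.
#' @export
default_region_panel <- function() {
  grid <- data.frame(
    region_id = sprintf("region_%02d", 1:10),
    urban = rep(c(TRUE, FALSE), 5),
    smk_f = c(0.002, 0.020, 0.008, 0.102, 0.015,
              0.060, 0.004, 0.035, 0.080, 0.010),
    smk_m = c(0.392, 0.570, 0.480, 0.647, 0.520,
              0.610, 0.430, 0.550, 0.630, 0.500),
    sbp_shift = c(-6, -2, 0, 4, 8, -4, 2, 6, -8, 0),
    bmi_shift = c(1.2, -0.6, 0.4, -1.0, 0.8, 0, -0.4, 0.6, -0.8, 0.2),
    m_cor = c(0.55, 0.80, 1.00, 1.60, 2.10, 0.70, 1.25, 0.90, 1.80, 0.60),
    m_str = c(0.40, 0.75, 1.10, 2.50, 1.90, 0.55, 1.40, 0.85, 2.20, 0.65)
  )
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    region_spec(
      region_id = g$region_id, urban = g$urban,
      covariates = default_region_covariates(g$smk_f, g$smk_m,
                                             g$sbp_shift, g$bmi_shift),
      hazard_multipliers = c(coronary = g$m_cor, stroke = g$m_str)
    )
  })
}

#' Read/write a cohort as CSV
#'
#' Column layout matches [generate_cohort()]; missing body mass index is an
#' empty field.
#'
#' @param cohort A `cohort_table`.
#' @param file Path to a CSV file.
#' @return `write_cohort` returns `file` invisibly; `read_cohort` returns a
#'   `cohort_table`.
#' @export
write_cohort <- function(cohort, file) {
  utils::write.csv(as.data.frame(cohort), file, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(file) {
  out <- utils::read.csv(file, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  need <- c("id", "region_id", "sex", "age", "smoker", "sbp", "bmi",
            "prior_cvd", "followup_time", "event", "event_subtype")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("cohort file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out$id <- as.character(out$id)
  out$smoker <- as.logical(out$smoker)
  out$prior_cvd <- as.logical(out$prior_cvd)
  out$event <- as.logical(out$event)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  ev <- table(factor(x$event_subtype, levels = c("coronary", "stroke", "none")))
  cat("<cohort_table> ", nrow(x), " participants, ",
      length(unique(x$region_id)), " region(s)\n", sep = "")
  cat("  events: coronary ", ev[["coronary"]], ", stroke ", ev[["stroke"]],
      ", censored ", ev[["none"]], "\n", sep = "")
  invisible(x)
}
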
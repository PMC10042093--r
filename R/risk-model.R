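#' Construct a sex- and subtype-specific risk submodel
#'
#' A submodel is a Cox-type score: named log-hazard-ratio coefficients over
#' centred covariate terms, plus the 10-year reference risk at the centring
#' point (where the linear predictor is 0). Supported terms: `age` (per year),
#' `smoker`, `sbp` (per mmHg), `bmi` (per kg/m^2) and the age interactions
#' `age_x_smoker`, `age_x_sbp`, `age_x_bmi`.
#'
#' @param sex `"female"` or `"male"`.
#' @param subtype `"coronary"` or `"stroke"`.
#' @param coefficients Named numeric vector of log hazard ratios.
#' @param reference_risk 10-year risk in (0, 1) at the centring point.
#' @param centring Named numeric vector with `age`, `sbp`, `bmi`.
#' @return An object of class `submodel`.
#' @export
submodel <- function(sex, subtype, coefficients, reference_risk,
                     centring = c(age = 60, sbp = 120, bmi = 25)) {
  sex <- match.arg(sex, c("female", "male"))
  subtype <- match.arg(subtype, c("coronary", "stroke"))
  if (length(coefficients) == 0L || is.null(names(coefficients)))
    stop("submodel: coefficients must be a non-empty named vector")
  known <- c("age", "smoker", "sbp", "bmi",
             "age_x_smoker", "age_x_sbp", "age_x_bmi")
  bad <- setdiff(names(coefficients), known)
  if (length(bad))
    stop("submodel: unknown term(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(reference_risk) || reference_risk <= 0 || reference_risk >= 1)
    stop("submodel: reference_risk must be in (0, 1)")
  if (!all(c("age", "sbp", "bmi") %in% names(centring)) ||
      !all(is.finite(centring)))
    stop("submodel: centring must give finite age, sbp, bmi")
  structure(list(sex = sex, subtype = subtype,
                 coefficients = coefficients,
                 reference_risk = reference_risk,
                 centring = centring[c("age", "sbp", "bmi")]),
            class = "submodel")
}

#' Assemble a full risk model from four submodels
#'
#' @param submodels List of four [submodel()] objects, one per
#'   (sex, subtype) combination.
#' @param name Model name.
#' @param vintage Parameter-vintage label (e.g. `"2017"`).
#' @return An object of class `risk_model` with submodels indexed
#'   `$submodels[[sex]][[subtype]]`.
#' @export
risk_model <- function(submodels, name = "unnamed", vintage = "unversioned") {
  idx <- list(female = list(), male = list())
  for (sm in submodels) {
    if (!inherits(sm, "submodel")) stop("risk_model: expected submodel objects")
    if (!is.null(idx[[sm$sex]][[sm$subtype]]))
      stop("risk_model: duplicate submodel for ", sm$sex, "/", sm$subtype)
    idx[[sm$sex]][[sm$subtype]] <- sm
  }
  for (sex in c("female", "male")) for (st in c("coronary", "stroke"))
    if (is.null(idx[[sex]][[st]]))
      stop("risk_model: missing submodel for ", sex, "/", st)
  structure(list(submodels = idx,
                 metadata = list(name = name, vintage = vintage)),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model> '", x$metadata$name, "' (vintage ", x$metadata$vintage,
      ")\n", sep = "")
  for (sex in c("female", "male")) for (st in c("coronary", "stroke")) {
    sm <- x$submodels[[sex]][[st]]
    cat(sprintf("  %-6s %-8s  %d term(s), reference 10-y risk %.4f\n",
                sex, st, length(sm$coefficients), sm$reference_risk))
  }
  invisible(x)
}

#' Linear predictor of a submodel for one or more covariate profiles
#'
#' Computes \eqn{lp = \sum_k \beta_k z_k} over the submodel's centred terms,
#' so a profile exactly at the centring point scores 0 and `exp(lp)` is the
#' hazard (relative risk) versus the reference profile.
#'
#' @param profile A list or data.frame with `age`, `smoker`, `sbp`, `bmi`
#'   (vectors allowed; recycled jointly).
#' @param sm A [submodel()].
#' @return Numeric vector of linear predictors.
#' @export
linear_predictor <- function(profile, sm) {
  need <- unique(sub("^age_x_", "", names(sm$coefficients)))
  need <- union(need, "age")
  miss <- setdiff(intersect(need, c("age", "smoker", "sbp", "bmi")),
                  names(profile))
  if (length(miss))
    stop("profile is missing covariate(s) referenced by the submodel: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!is.null(profile$sbp) &&
      any(profile$sbp < 60 | profile$sbp > 300, na.rm = TRUE))
    warning("systolic blood pressure outside 60-300 mmHg", call. = FALSE)
  if (!is.null(profile$bmi) &&
      any(profile$bmi < 10 | profile$bmi > 60, na.rm = TRUE))
    warning("body mass index outside 10-60 kg/m^2", call. = FALSE)
  cen <- sm$centring
  z <- list(
    age = profile$age - cen[["age"]],
    smoker = if (is.null(profile$smoker)) NULL else as.numeric(profile$smoker),
    sbp = if (is.null(profile$sbp)) NULL else profile$sbp - cen[["sbp"]],
    bmi = if (is.null(profile$bmi)) NULL else profile$bmi - cen[["bmi"]]
  )
  z$age_x_smoker <- if (!is.null(z$smoker)) z$age * z$smoker
  z$age_x_sbp <- if (!is.null(z$sbp)) z$age * z$sbp
  z$age_x_bmi <- if (!is.null(z$bmi)) z$age * z$bmi
  lp <- 0
  for (term in names(sm$coefficients))
    lp <- lp + sm$coefficients[[term]] * z[[term]]
  unname(lp)
}

#' Ten-year risk from a linear predictor
#'
#' Survival-scale transform \eqn{p = 1 - (1 - p_0)^{\exp(lp)}} with
#' \eqn{p_0} the submodel's reference risk: exact under proportional hazards,
#' strictly increasing in `lp`, and equal to the reference risk at `lp = 0`.
#'
#' @param lp Numeric linear predictor(s).
#' @param sm A [submodel()], or a number taken as the reference risk.
#' @return Risk(s) in \[0, 1\].
#' @export
ten_year_risk <- function(lp, sm) {
  p0 <- if (inherits(sm, "submodel")) sm$reference_risk else sm
  stopifnot(p0 > 0, p0 < 1)
  1 - (1 - p0)^exp(lp)
}

#' Combine coronary and stroke risks into total cardiovascular risk
#'
#' Default rule is the complement product
#' \eqn{p = 1 - (1 - p_c)(1 - p_s)}: total 10-year survival free of any
#' cardiovascular event is the product of the subtype-specific survivals
#' (independent subtypes). It is symmetric and reduces to each submodel when
#' the other risk is 0. A capped-sum alternative is available for sensitivity.
#'
#' @param p_coronary,p_stroke Risks in \[0, 1\].
#' @param rule `"complement_product"` (default) or `"capped_sum"`.
#' @return Total risk(s) in \[0, 1\].
#' @export
combine_subtype_risks <- function(p_coronary, p_stroke,
                                  rule = c("complement_product", "capped_sum")) {
  rule <- match.arg(rule)
  stopifnot(all(p_coronary >= 0 & p_coronary <= 1, na.rm = TRUE),
            all(p_stroke >= 0 & p_stroke <= 1, na.rm = TRUE))
  if (rule == "complement_product") 1 - (1 - p_coronary) * (1 - p_stroke)
  else pmin(p_coronary + p_stroke, 1)
}

#' Score a cohort under a risk model
#'
#' Routes each participant to the submodels matching their sex and computes
#' the coronary and stroke linear predictors, the uncalibrated 10-year
#' subtype risks, and the combined total cardiovascular risk.
#'
#' @param cohort A `cohort_table` that has passed eligibility filtering.
#' @param model A [risk_model()].
#' @param combine_rule Passed to [combine_subtype_risks()].
#' @return A `risk_predictions` data.frame with columns `id`, `lp_coronary`,
#'   `lp_stroke`, `p_coronary`, `p_stroke`, `p_total`, `stage`
#'   (`"uncalibrated"`).
#' @export
score_cohort <- function(cohort, model, combine_rule = "complement_product") {
  stopifnot(inherits(model, "risk_model"))
  n <- nrow(cohort)
  out <- data.frame(id = cohort$id,
                    lp_coronary = numeric(n), lp_stroke = numeric(n),
                    p_coronary = numeric(n), p_stroke = numeric(n),
                    p_total = numeric(n), stage = rep("uncalibrated", n),
                    stringsAsFactors = FALSE)
  if (n == 0) {
    class(out) <- c("risk_predictions", "data.frame")
    return(out)
  }
  bad_sex <- setdiff(unique(cohort$sex), c("female", "male"))
  if (length(bad_sex))
    stop("no submodel for sex value(s): ", paste(bad_sex, collapse = ", "),
         call. = FALSE)
  for (sex in intersect(c("female", "male"), unique(cohort$sex))) {
    i <- cohort$sex == sex
    prof <- cohort[i, c("age", "smoker", "sbp", "bmi")]
    for (st in c("coronary", "stroke")) {
      sm <- model$submodels[[sex]][[st]]
      lp <- linear_predictor(prof, sm)
      out[i, paste0("lp_", st)] <- lp
      out[i, paste0("p_", st)] <- ten_year_risk(lp, sm)
    }
  }
  out$p_total <- combine_subtype_risks(out$p_coronary, out$p_stroke,
                                       rule = combine_rule)
  class(out) <- c("risk_predictions", "data.frame")
  out
}

#' @export
print.risk_predictions <- function(x, ...) {
  cat("<risk_predictions> ", nrow(x), " participants, stage: ",
      paste(unique(x$stage), collapse = "/"), "\n", sep = "")
  if (nrow(x))
    cat(sprintf("  mean 10-y total risk %.4f (coronary %.4f, stroke %.4f)\n",
                mean(x$p_total), mean(x$p_coronary), mean(x$p_stroke)))
  invisible(x)
}

#' Read or write a risk model as JSON
#'
#' Schema: `{metadata: {name, vintage}, submodels: {sex: {subtype:
#' {coefficients, centring, reference_risk}}}}`. Coefficients are data, not
#' code: published chart coefficients live in files of this schema.
#'
#' @param model A [risk_model()].
#' @param file Path to a JSON file.
#' @return `read_risk_model` returns a `risk_model`; `write_risk_model`
#'   returns `file` invisibly.
#' @export
write_risk_model <- function(model, file) {
  body <- list(metadata = model$metadata, submodels = list())
  for (sex in c("female", "male")) for (st in c("coronary", "stroke")) {
    sm <- model$submodels[[sex]][[st]]
    body$submodels[[sex]][[st]] <- list(
      coefficients = as.list(sm$coefficients),
      centring = as.list(sm$centring),
      reference_risk = sm$reference_risk)
  }
  jsonlite::write_json(body, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(file) {
  body <- jsonlite::read_json(file, simplifyVector = FALSE)
  sms <- list()
  for (sex in names(body$submodels)) for (st in names(body$submodels[[sex]])) {
    node <- body$submodels[[sex]][[st]]
    sms[[length(sms) + 1L]] <- submodel(
      sex = sex, subtype = st,
      coefficients = unlist(node$coefficients),
      reference_risk = node$reference_risk,
      centring = unlist(node$centring))
  }
  risk_model(sms, name = body$metadata$name %||% "unnamed",
             vintage = body$metadata$vintage %||% "unversioned")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Illustrative default non-laboratory risk model
#'
#' A plausible set of coefficients and reference risks in the shape of a
#' published non-laboratory cardiovascular chart model (age, smoking,
#' systolic blood pressure, body mass index; per-sex coronary and stroke
#' submodels). The values are illustrative defaults for demonstrations and
#' simulations, not a published coefficient set; analyses of real data should
#' load the published coefficients from a model file via [read_risk_model()].
#'
#' @param reference_rates Optional nested list `[[sex]][[subtype]]` of
#'   baseline event rates per person-year used to set the reference risks as
#'   `1 - exp(-10 * rate)`; defaults to [default_true_baseline_rates()] so
#'   that, by construction, the default model is correctly calibrated for a
#'   region with hazard multipliers of 1.
#' @return A [risk_model()].
#' @export
default_risk_model <- function(reference_rates = default_true_baseline_rates()) {
  lhr <- default_true_log_hr()
  cen <- c(age = 55, sbp = 130, bmi = 23.5)
  sms <- list()
  for (sex in c("female", "male")) for (st in c("coronary", "stroke")) {
    sms[[length(sms) + 1L]] <- submodel(
      sex = sex, subtype = st,
      coefficients = lhr[[sex]][[st]],
      reference_risk = 1 - exp(-10 * reference_rates[[sex]][[st]]),
      centring = cen)
  }
  risk_model(sms, name = "illustrative-nonlab-cvd", vintage = "synthetic")
}
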
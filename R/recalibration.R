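#' Stratum scheme for recalibration
#'
#' Strata are the cross of region (or a single super-region label, for
#' recalibrating a whole territory with one external parameter set), sex, and
#' contiguous age bands partitioning \[40, 80). Default bands are the 10-year
#' bands 40-49, 50-59, 60-69, 70-79.
#'
#' @param age_breaks Increasing numeric break points; band `k` is
#'   `[age_breaks[k], age_breaks[k+1])`.
#' @param by_region Stratify by each region label (`TRUE`) or collapse all
#'   regions into `super_region` (`FALSE`).
#' @param super_region Label used when `by_region = FALSE`.
#' @return An object of class `stratum_scheme`.
#' @export
stratum_scheme <- function(age_breaks = c(40, 50, 60, 70, 80),
                           by_region = TRUE, super_region = "all") {
  if (length(age_breaks) < 2 || any(diff(age_breaks) <= 0))
    stop("age_breaks must be strictly increasing with at least one band")
  structure(list(age_breaks = age_breaks, by_region = isTRUE(by_region),
                 super_region = super_region),
            class = "stratum_scheme")
}

# Per-row stratum labels (region|sex|band) under a scheme.
assign_strata <- function(cohort, scheme) {
  br <- scheme$age_breaks
  band <- findInterval(cohort$age, br, rightmost.closed = FALSE)
  band[cohort$age >= br[length(br)] | band == 0] <- NA_integer_
  if (anyNA(band))
    stop("participant age outside the stratum scheme's age bands",
         call. = FALSE)
  region <- if (scheme$by_region) cohort$region_id
            else rep(scheme$super_region, nrow(cohort))
  data.frame(region = region, sex = cohort$sex,
             age_lo = br[band], age_hi = br[band + 1L],
             stringsAsFactors = FALSE)
}

#' Expected risk over a horizon from a constant incidence rate
#'
#' Converts a stratum's annual incidence rate into the expected cumulative
#' risk over `horizon` years under a constant hazard:
#' \eqn{\bar p = 1 - \exp(-\mathrm{rate} \cdot \mathrm{horizon})}.
#' [rate_from_expected_risk()] is the exact inverse.
#'
#' @param rate Events per person-year (>= 0).
#' @param horizon Years (> 0).
#' @return Probability in \[0, 1).
#' @export
expected_risk_from_rates <- function(rate, horizon = 10) {
  if (any(rate < 0)) stop("incidence rate must be non-negative", call. = FALSE)
  stopifnot(horizon > 0)
  1 - exp(-rate * horizon)
}

#' @rdname expected_risk_from_rates
#' @param risk Probability in \[0, 1).
#' @export
rate_from_expected_risk <- function(risk, horizon = 10) {
  stopifnot(all(risk >= 0 & risk < 1), horizon > 0)
  -log(1 - risk) / horizon
}

#' Estimate recalibration parameters from a cohort
#'
#' For every stratum (region x sex x age band) and event subtype, computes
#' the two recalibration parameters: the mean relative risk
#' \eqn{\bar r_s = \mathrm{mean}(\exp(lp_i))} over stratum members
#' (arithmetic mean, so the stratum's expected events match the sum of
#' relative risks; a geometric-mean option is provided), and the expected
#' 10-year risk \eqn{\bar p_s}, the Kaplan-Meier observed subtype risk within
#' the stratum. Strata with zero events receive the small-sample floor
#' \eqn{\bar p_s = 0.5 / n_s} with a warning, keeping the downstream power
#' transform defined.
#'
#' @param cohort An eligible `cohort_table`.
#' @param predictions Uncalibrated [score_cohort()] output aligned to
#'   `cohort` rows.
#' @param scheme A [stratum_scheme()].
#' @param horizon Risk horizon in years.
#' @param mean_rr One of `"arithmetic"` (default) or `"geometric"`.
#' @param provenance Label recorded in the table (default `"empirical"`).
#' @return A `recal_table` data.frame with columns `region`, `sex`, `age_lo`,
#'   `age_hi`, `subtype`, `expected_risk`, `mean_rr`, `n`, `n_events`,
#'   `provenance`.
#' @export
estimate_recalibration_table <- function(cohort, predictions,
                                         scheme = stratum_scheme(),
                                         horizon = 10,
                                         mean_rr = c("arithmetic", "geometric"),
                                         provenance = "empirical") {
  mean_rr <- match.arg(mean_rr)
  stopifnot(nrow(cohort) == nrow(predictions))
  if (!all(predictions$stage == "uncalibrated"))
    stop("recalibration parameters must be estimated from uncalibrated predictions",
         call. = FALSE)
  st_lab <- assign_strata(cohort, scheme)
  key <- interaction(st_lab$region, st_lab$sex, st_lab$age_lo, drop = TRUE)
  rows <- list()
  floored <- character(0)
  for (k in levels(key)) {
    i <- key == k
    n_s <- sum(i)
    if (n_s == 0) stop("empty stratum: ", k, call. = FALSE)
    lab <- st_lab[which(i)[1], ]
    for (st in c("coronary", "stroke")) {
      lp <- predictions[[paste0("lp_", st)]][i]
      rbar <- if (mean_rr == "arithmetic") mean(exp(lp)) else exp(mean(lp))
      oc <- first_event_outcome(cohort[i, , drop = FALSE],
                                paste0(st, "_only"))
      km <- km_risk(oc$time, oc$event, horizon)
      pbar <- km$risk
      if (km$n_events == 0) {
        pbar <- 0.5 / n_s
        floored <- c(floored, paste0(k, "/", st))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        region = lab$region, sex = lab$sex,
        age_lo = lab$age_lo, age_hi = lab$age_hi, subtype = st,
        expected_risk = pbar, mean_rr = rbar,
        n = n_s, n_events = km$n_events,
        provenance = provenance, stringsAsFactors = FALSE)
    }
  }
  if (length(floored))
    warning("zero events; applied small-sample risk floor in: ",
            paste(floored, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, rows)
  out <- out[order(out$region, out$sex, out$age_lo, out$subtype), ]
  rownames(out) <- NULL
  class(out) <- c("recal_table", "data.frame")
  out
}

#' Recalibrate predicted risks to stratum-level expected risks
#'
#' Rescales each participant's subtype risks on the cumulative-hazard scale:
#' with stratum parameters \eqn{(\bar p_s, \bar r_s)} and participant weight
#' \eqn{w_i = \exp(lp_i) / \bar r_s}, the recalibrated risk is
#' \eqn{p_i' = 1 - (1 - \bar p_s)^{w_i}}. A participant exactly at the
#' stratum mean relative risk receives exactly \eqn{\bar p_s}. The transform
#' is monotone in the linear predictor, so within any stratum the ranking of
#' participants — and hence stratum-level discrimination — is unchanged;
#' across strata, risks move to match local incidence, which is what repairs
#' calibration and (when strata differ in baseline hazard) improves pooled
#' discrimination. Total risk is recombined from the recalibrated subtype
#' risks.
#'
#' @param predictions [score_cohort()] output.
#' @param table A `recal_table` (estimated or loaded).
#' @param cohort The matching `cohort_table` (supplies region, sex, age).
#' @param scheme The [stratum_scheme()] whose bands the table uses.
#' @param combine_rule Passed to [combine_subtype_risks()].
#' @return A `risk_predictions` data.frame, stage `"recalibrated"`.
#' @export
recalibrate <- function(predictions, table, cohort,
                        scheme = stratum_scheme(),
                        combine_rule = "complement_product") {
  stopifnot(nrow(cohort) == nrow(predictions))
  st_lab <- assign_strata(cohort, scheme)
  out <- predictions
  for (st in c("coronary", "stroke")) {
    tb <- table[table$subtype == st, , drop = FALSE]
    idx <- match(paste(st_lab$region, st_lab$sex, st_lab$age_lo),
                 paste(tb$region, tb$sex, tb$age_lo))
    if (anyNA(idx)) {
      missing_strata <- unique(paste(st_lab$region, st_lab$sex,
                                     st_lab$age_lo)[is.na(idx)])
      stop("no recalibration parameters for stratum/subtype ", st, ": ",
           paste(missing_strata, collapse = ", "), call. = FALSE)
    }
    w <- exp(out[[paste0("lp_", st)]]) / tb$mean_rr[idx]
    out[[paste0("p_", st)]] <- 1 - (1 - tb$expected_risk[idx])^w
  }
  out$p_total <- combine_subtype_risks(out$p_coronary, out$p_stroke,
                                       rule = combine_rule)
  out$stage <- "recalibrated"
  class(out) <- c("risk_predictions", "data.frame")
  out
}

#' Read or write a recalibration table as CSV
#'
#' Columns: `region`, `sex`, `age_lo`, `age_hi`, `subtype`, `expected_risk`,
#' `mean_rr`, `provenance` (plus optional `n`, `n_events`). Loading validates
#' the schema: risks must lie in (0, 1), mean relative risks must be
#' positive, and every violation is reported with its stratum.
#'
#' @param table A `recal_table`.
#' @param file Path to a CSV file.
#' @return `read_recalibration_table` returns a validated `recal_table`;
#'   `write_recalibration_table` returns `file` invisibly.
#' @export
write_recalibration_table <- function(table, file) {
  utils::write.csv(as.data.frame(table), file, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_recalibration_table
#' @export
read_recalibration_table <- function(file) {
  tb <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c(provenance = "character"))
  for (col in c("region", "sex", "subtype"))
    if (col %in% names(tb)) tb[[col]] <- as.character(tb[[col]])
  need <- c("region", "sex", "age_lo", "age_hi", "subtype",
            "expected_risk", "mean_rr", "provenance")
  miss <- setdiff(need, names(tb))
  if (length(miss))
    stop("recalibration table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  lab <- paste0(tb$region, "/", tb$sex, "/", tb$age_lo, "-", tb$age_hi,
                "/", tb$subtype)
  bad_p <- tb$expected_risk <= 0 | tb$expected_risk >= 1
  if (any(bad_p))
    stop("expected_risk outside (0, 1) in stratum: ",
         paste(lab[bad_p], collapse = ", "), call. = FALSE)
  bad_r <- !(tb$mean_rr > 0)
  if (any(bad_r))
    stop("mean_rr must be > 0 in stratum: ",
         paste(lab[bad_r], collapse = ", "), call. = FALSE)
  bad_st <- !tb$subtype %in% c("coronary", "stroke")
  if (any(bad_st))
    stop("unknown subtype in stratum: ", paste(lab[bad_st], collapse = ", "),
         call. = FALSE)
  class(tb) <- c("recal_table", "data.frame")
  tb
}

#' @export
print.recal_table <- function(x, ...) {
  cat("<recal_table> ", nrow(x), " stratum x subtype rows (",
      length(unique(x$region)), " region(s); provenance: ",
      paste(unique(x$provenance), collapse = ", "), ")\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ... ", nrow(x) - 4, " more rows\n", sep = "")
  invisible(x)
}
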
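#' Study configuration for the two-component validation design
#'
#' Bundles everything one end-to-end run needs: a cohort source (a simulation
#' specification or a CSV file), the risk model, the recalibration mode —
#' `"none"` (validation of the universal model only), `"external_table"`
#' (one parameter set for the whole territory, the first study component) or
#' `"per_region_empirical"` (parameters re-estimated in every region, the
#' second component) — the outcome definition, and the validation settings.
#'
#' @param regions List of [region_spec()] (simulation source), or `NULL` when
#'   `cohort_file` is given.
#' @param truth A [hazard_spec()] (simulation source).
#' @param n_per_region Participants per region to simulate.
#' @param seed Integer seed driving all randomness of the run.
#' @param cohort_file Optional CSV path; exactly one of (`regions`,
#'   `cohort_file`) must be supplied.
#' @param model A [risk_model()] or path to a model JSON file.
#' @param recalibration `"none"`, `"external_table"` or
#'   `"per_region_empirical"`.
#' @param recal_table A `recal_table` or CSV path (for `"external_table"`).
#' @param scheme [stratum_scheme()] used for recalibration strata.
#' @param outcome `"total_cvd"`, `"coronary_only"` or `"stroke_only"`.
#' @param horizon Risk/validation horizon in years (default 10).
#' @param n_groups Calibration risk groups (default 10).
#' @param vintage Provenance label carried into estimated tables.
#' @return An object of class `study_config`.
#' @export
study_config <- function(regions = NULL, truth = hazard_spec(),
                         n_per_region = 2000, seed = 1L,
                         cohort_file = NULL,
                         model = default_risk_model(),
                         recalibration = c("per_region_empirical",
                                           "external_table", "none"),
                         recal_table = NULL,
                         scheme = stratum_scheme(),
                         outcome = c("total_cvd", "coronary_only",
                                     "stroke_only"),
                         horizon = 10, n_groups = 10,
                         vintage = "empirical") {
  recalibration <- match.arg(recalibration)
  outcome <- match.arg(outcome)
  if (is.null(regions) == is.null(cohort_file))
    stop("supply exactly one cohort source: regions or cohort_file",
         call. = FALSE)
  if (recalibration == "external_table" && is.null(recal_table))
    stop("external_table recalibration needs recal_table", call. = FALSE)
  if (is.character(model)) model <- read_risk_model(model)
  if (is.character(recal_table))
    recal_table <- read_recalibration_table(recal_table)
  structure(list(regions = regions, truth = truth,
                 n_per_region = n_per_region, seed = as.integer(seed),
                 cohort_file = cohort_file, model = model,
                 recalibration = recalibration, recal_table = recal_table,
                 scheme = scheme, outcome = outcome, horizon = horizon,
                 n_groups = n_groups, vintage = vintage),
            class = "study_config")
}

#' Run the full validation-and-recalibration study
#'
#' Executes the study design end to end: obtain the cohort (simulate or
#' load), apply the eligibility filters, map outcomes under the configured
#' definition, score every participant with the universal model, validate
#' before recalibration (per region and sex, and in the overall population
#' per sex), recalibrate under the configured mode, validate after, and pool
#' the per-region concordance indices by random-effects meta-analysis.
#' Deterministic given the config and seed.
#'
#' @param config A [study_config()].
#' @return A `validation_report`: list with `metrics` (one row per stratum x
#'   stage: Harrell's C with CI, predicted/observed ratio, Nam-D'Agostino
#'   chi-square), `calibration` (named list of [calibration_table()]s),
#'   `exclusions`, `recal_table`, `cohort_n`, and `metadata`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  raw <- if (!is.null(config$cohort_file)) read_cohort(config$cohort_file)
         else generate_cohort(config$regions, config$truth,
                              config$n_per_region, config$seed)
  filt <- apply_eligibility_filters(raw)
  cohort <- filt$cohort
  if (!nrow(cohort)) stop("no eligible participants after filtering")

  preds_before <- score_cohort(cohort, config$model)
  stages <- list(before = preds_before)
  recal_tb <- NULL
  if (config$recalibration != "none") {
    if (config$recalibration == "per_region_empirical") {
      scheme <- config$scheme
      if (!scheme$by_region)
        scheme <- stratum_scheme(scheme$age_breaks, by_region = TRUE)
      recal_tb <- estimate_recalibration_table(
        cohort, preds_before, scheme, horizon = config$horizon,
        provenance = config$vintage)
    } else {
      scheme <- config$scheme
      recal_tb <- config$recal_table
    }
    stages$after <- recalibrate(preds_before, recal_tb, cohort, scheme)
  }

  outcome <- first_event_outcome(cohort, config$outcome)
  risk_col <- switch(config$outcome,
                     total_cvd = "p_total",
                     coronary_only = "p_coronary",
                     stroke_only = "p_stroke")

  metrics <- list(); cal_tables <- list()
  for (stage in names(stages)) {
    preds <- stages[[stage]]
    units <- c(lapply(unique(cohort$region_id), function(r)
                 list(region = r, idx = cohort$region_id == r)),
               list(list(region = "overall", idx = rep(TRUE, nrow(cohort)))))
    for (sex in intersect(c("female", "male"), unique(cohort$sex))) {
      for (u in units) {
        i <- u$idx & cohort$sex == sex
        if (sum(i) < config$n_groups || sum(outcome$event[i]) == 0) next
        m <- validate_stratum(outcome$time[i], outcome$event[i],
                              preds[[risk_col]][i],
                              config$horizon, config$n_groups)
        metrics[[length(metrics) + 1L]] <-
          cbind(data.frame(region = u$region, sex = sex, stage = stage,
                           n = sum(i), n_events = sum(outcome$event[i]),
                           stringsAsFactors = FALSE),
                m$row)
        cal_tables[[paste(u$region, sex, stage, sep = "_")]] <- m$cal
      }
    }
  }
  metrics <- do.call(rbind, metrics)

  # random-effects pooling of the per-region C indices, per sex and stage
  pooled <- list()
  for (stage in names(stages)) for (sex in unique(metrics$sex)) {
    rows <- metrics[metrics$stage == stage & metrics$sex == sex &
                      !metrics$region %in% "overall", , drop = FALSE]
    if (nrow(rows) < 2) next
    pl <- pool_c_indices(rows$c, rows$c_se^2)
    pooled[[length(pooled) + 1L]] <- data.frame(
      region = "pooled_meta", sex = sex, stage = stage,
      n = sum(rows$n), n_events = sum(rows$n_events),
      c = pl$pooled, c_lo = pl$ci_lo, c_hi = pl$ci_hi, c_se = pl$se,
      po = NA_real_, nd_chi2 = NA_real_, nd_df = NA_integer_,
      nd_p = NA_real_, stringsAsFactors = FALSE)
  }
  metrics <- rbind(metrics, do.call(rbind, pooled))
  rownames(metrics) <- NULL

  structure(list(
    metrics = metrics, calibration = cal_tables,
    exclusions = filt$exclusions, recal_table = recal_tb,
    cohort_n = c(input = nrow(raw), eligible = nrow(cohort)),
    metadata = list(seed = config$seed, outcome = config$outcome,
                    recalibration = config$recalibration,
                    model = config$model$metadata,
                    horizon = config$horizon,
                    config_fingerprint = config_fingerprint(config),
                    package_version = as.character(
                      utils::packageVersion("cvdrecal")))),
    class = "validation_report")
}

# discrimination + calibration block for one stratum
validate_stratum <- function(time, event, risk, horizon, n_groups) {
  cc <- harrell_c(time, event, risk)
  cal <- calibration_table(time, event, risk, t0 = horizon,
                           n_groups = n_groups)
  nd <- tryCatch(nam_dagostino(cal),
                 error = function(e) list(chi2 = NA_real_, df = NA_integer_,
                                          p_value = NA_real_))
  list(row = data.frame(c = cc$c, c_lo = cc$ci_lo, c_hi = cc$ci_hi,
                        c_se = cc$se,
                        po = po_ratio(time, event, risk, t0 = horizon),
                        nd_chi2 = nd$chi2, nd_df = nd$df, nd_p = nd$p_value),
       cal = cal)
}

config_fingerprint <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "model")]),
               collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_len(nchar(txt)) %% 97 + 1)) %% .Machine$integer.max)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", x$cohort_n[["eligible"]],
      " eligible participants (of ", x$cohort_n[["input"]], ")\n", sep = "")
  ov <- x$metrics[x$metrics$region %in% c("overall", "pooled_meta"), ]
  if (nrow(ov)) {
    cat("  overall / pooled discrimination and calibration:\n")
    print.data.frame(ov[, c("region", "sex", "stage", "c", "c_lo", "c_hi",
                            "po")],
                     row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Compare outcome definitions on the same study configuration
#'
#' Re-runs the study once per outcome definition (same cohort source and
#' seed) and returns the per-variant reports plus a side-by-side summary of
#' overall discrimination and calibration.
#'
#' @param config A [study_config()].
#' @param variants Character vector of outcome definitions (length >= 2).
#' @return List with `reports` (named by variant) and `summary` (data.frame).
#' @export
outcome_definition_sensitivity <- function(config, variants) {
  if (length(variants) < 1) stop("no outcome-definition variants supplied")
  ok <- c("total_cvd", "coronary_only", "stroke_only")
  bad <- setdiff(variants, ok)
  if (length(bad))
    stop("unknown outcome definition(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (length(variants) < 2)
    stop("need at least 2 variants to compare", call. = FALSE)
  reports <- lapply(variants, function(v) {
    cfg <- config
    cfg$outcome <- v
    run_study(cfg)
  })
  names(reports) <- make.unique(variants)
  summ <- do.call(rbind, lapply(seq_along(reports), function(i) {
    m <- reports[[i]]$metrics
    ov <- m[m$region == "overall", c("sex", "stage", "c", "po")]
    cbind(variant = variants[i], ov)
  }))
  rownames(summ) <- NULL
  list(reports = reports, summary = summ)
}

#' Write a validation report to disk
#'
#' Produces `metrics.csv` (one row per stratum x stage), `exclusions.csv`,
#' one calibration plot `calibration_<stratum>.svg` per stored calibration
#' table (mean predicted vs Kaplan-Meier observed decile risks with a
#' 45-degree reference line), `recal_table.csv` when recalibration was run,
#' and a `report.md` summary laid out as a before/after discrimination table.
#' Re-rendering overwrites; the CSV bytes are identical across renders.
#'
#' @param report A `validation_report`.
#' @param out_dir Output directory (created if needed).
#' @param plots Write SVG calibration plots (default `TRUE`).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(report, out_dir, plots = TRUE) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- character(0)
  p <- file.path(out_dir, "metrics.csv")
  utils::write.csv(format_metrics(report$metrics), p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "exclusions.csv")
  utils::write.csv(data.frame(reason = names(report$exclusions),
                              n = as.integer(report$exclusions)),
                   p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(report$recal_table)) {
    p <- file.path(out_dir, "recal_table.csv")
    write_recalibration_table(report$recal_table, p)
    paths <- c(paths, p)
  }
  if (plots) for (nm in names(report$calibration)) {
    p <- file.path(out_dir, paste0("calibration_", nm, ".svg"))
    grDevices::svg(p, width = 5, height = 5)
    plot_calibration(report$calibration[[nm]], main = nm)
    grDevices::dev.off()
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "report.md")
  writeLines(report_markdown(report), p)
  paths <- c(paths, p)
  invisible(paths)
}

format_metrics <- function(m) {
  num <- vapply(m, is.numeric, logical(1))
  m[num] <- lapply(m[num], function(x) formatC(x, digits = 6, format = "g"))
  m
}

#' Decile calibration plot
#'
#' Mean predicted versus Kaplan-Meier observed 10-year risk per risk group,
#' with a 45-degree ideal-calibration reference line.
#'
#' @param cal A [calibration_table()].
#' @param main Plot title.
#' @export
plot_calibration <- function(cal, main = "Calibration") {
  lim <- c(0, max(cal$mean_predicted, cal$observed) * 1.05)
  graphics::plot(cal$mean_predicted, cal$observed, xlim = lim, ylim = lim,
                 xlab = "Mean predicted 10-year risk",
                 ylab = "Observed 10-year risk (Kaplan-Meier)",
                 main = main, pch = 19)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  se <- sqrt(cal$greenwood_var)
  graphics::segments(cal$mean_predicted, cal$observed - 1.96 * se,
                     cal$mean_predicted, cal$observed + 1.96 * se)
  invisible(NULL)
}

report_markdown <- function(report) {
  m <- report$metrics
  lines <- c("# Validation report", "",
             sprintf("- participants: %d eligible of %d input",
                     report$cohort_n[["eligible"]], report$cohort_n[["input"]]),
             sprintf("- outcome definition: %s; recalibration: %s; seed: %d",
                     report$metadata$outcome, report$metadata$recalibration,
                     report$metadata$seed),
             sprintf("- config fingerprint: %s; package version: %s",
                     report$metadata$config_fingerprint,
                     report$metadata$package_version),
             "", "## Discrimination before and after recalibration", "",
             "| Region | Sex | n cases | C before (95% CI) | C after (95% CI) |",
             "|---|---|---|---|---|")
  key <- unique(m[, c("region", "sex")])
  for (i in seq_len(nrow(key))) {
    b <- m[m$region == key$region[i] & m$sex == key$sex[i] &
             m$stage == "before", ]
    a <- m[m$region == key$region[i] & m$sex == key$sex[i] &
             m$stage == "after", ]
    fmt <- function(r) if (nrow(r) == 0) "-" else
      sprintf("%.3f (%.3f-%.3f)", r$c[1], r$c_lo[1], r$c_hi[1])
    lines <- c(lines, sprintf("| %s | %s | %s | %s | %s |",
                              key$region[i], key$sex[i],
                              if (nrow(b)) b$n_events[1] else "-",
                              fmt(b), fmt(a)))
  }
  po <- m[m$region == "overall", ]
  if (nrow(po)) {
    lines <- c(lines, "", "## Overall predicted/observed ratio", "",
               "| Sex | Stage | P/O |", "|---|---|---|")
    for (i in seq_len(nrow(po)))
      lines <- c(lines, sprintf("| %s | %s | %.3f |",
                                po$sex[i], po$stage[i], po$po[i]))
  }
  lines
}
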
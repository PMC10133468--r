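#' Full pipeline configuration
#'
#' Bundles the knobs of every stage: the Greenwood map, the FAT rule set, the
#' cohort generator, and the analysis settings.
#'
#' @param greenwood A [greenwood_params()] object.
#' @param rules A [fat_rules()] object.
#' @param cohort A [cohort_config()] object (used when simulating).
#' @param representative Mismatch representative frequency, `"geomean"` or
#'   `"lower"` (see [mismatch_profile()]).
#' @param n_boot Bootstrap resamples for confidence intervals.
#' @param alpha Family-wise error rate for Holm-Bonferroni decisions.
#' @param seed Seed for the analysis-stage randomness (bootstrap).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(greenwood = greenwood_params(),
                            rules = fat_rules(),
                            cohort = cohort_config(),
                            representative = c("geomean", "lower"),
                            n_boot = 1000, alpha = 0.05, seed = 1) {
  structure(list(greenwood = greenwood, rules = rules, cohort = cohort,
                 representative = match.arg(representative),
                 n_boot = n_boot, alpha = alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Curve-parameter table for every subject/fitting of one measure.
subject_curve_params <- function(cleaned, measure, span = c(0, 84)) {
  d <- cleaned[cleaned$measure == measure & !is.na(cleaned$value), ]
  out <- lapply(split(d, list(d$subject_id, d$fitting), drop = TRUE),
                function(s) {
    if (sum(!is.na(s$value)) < 2L) return(NULL)
    cp <- curve_params(learning_curve(s$visit_day, s$value, span = span))
    data.frame(subject_id = s$subject_id[1L], fitting = s$fitting[1L],
               begin = cp$begin, end = cp$end, auc = cp$auc,
               learning_rate = cp$learning_rate)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

# Paired comparison of one curve parameter between arms, over the subjects
# having both arms.
compare_param <- function(params, column, n_boot, seed) {
  wide <- merge(params[params$fitting == "test", c("subject_id", column)],
                params[params$fitting == "control", c("subject_id", column)],
                by = "subject_id", suffixes = c("_test", "_control"))
  paired_compare(wide[[paste0(column, "_test")]],
                 wide[[paste0(column, "_control")]],
                 n_boot = n_boot, seed = seed)
}

#' Run the complete fitting-and-analysis pipeline
#'
#' Executes map -> schedule -> (simulate) -> analyze: builds the per-subject
#' imaging-based FATs from electrode geometry, audits them against the rule
#' set, summarises frequency-to-place mismatch for both fittings, audits
#' schedule compliance against diaries, applies the scoring rules, extracts
#' learning-curve parameters, and compares the two fittings per measure with
#' Wilcoxon signed-rank tests and Holm-Bonferroni correction of Begin and End.
#'
#' @param config A [pipeline_config()].
#' @param input_dir Directory holding `geometry.csv`, `schedules.csv`,
#'   `diaries.csv`, `visits.csv` (the [generate_cohort()] layout). `NULL`
#'   simulates a cohort from `config$cohort` instead.
#' @param out_dir Optional output directory; when given, FAT tables, the
#'   mismatch summary, compliance table and the analysis report (JSON) are
#'   written there (and the simulated input tables when simulating).
#' @return A list of class `pipeline_result` with elements `fats`,
#'   `mismatch` (per-fitting [mismatch_summary()] plus per-subject pooled
#'   medians), `compliance`, `curve_params` (per measure), `comparisons`
#'   (per measure and parameter), and `holm` (corrected Begin/End decisions).
#' @export
run_pipeline <- function(config = pipeline_config(), input_dir = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(input_dir)) {
    cohort <- generate_cohort(config$cohort, greenwood = config$greenwood,
                              rules = config$rules)
    geometry <- cohort$geometry
    schedules <- cohort$schedules
    diaries <- cohort$diaries
    visits <- cohort$visits
  } else {
    geometry <- read_geometry(file.path(input_dir, "geometry.csv"))
    schedules <- read_schedule(file.path(input_dir, "schedules.csv"))
    diaries <- read_diary(file.path(input_dir, "diaries.csv"))
    visits <- read_visits(file.path(input_dir, "visits.csv"))
    cohort <- NULL
  }

  ids <- names(geometry)
  std <- standard_fat(rules = config$rules)
  fats <- list(); prof_img <- list(); prof_std <- list()
  for (id in ids) {
    pf <- place_frequencies(geometry[[id]], config$greenwood)
    fats[[id]] <- build_tonotopic_fat(pf, config$rules, subject_id = id)
    prof_img[[id]] <- mismatch_profile(fats[[id]], pf,
                                       representative = config$representative)
    prof_std[[id]] <- mismatch_profile(std, pf,
                                       representative = config$representative)
  }
  mismatch <- list(
    imaging = mismatch_summary(prof_img),
    standard = mismatch_summary(prof_std),
    per_subject = data.frame(
      subject_id = ids,
      imaging_median_abs = vapply(prof_img, `[[`, numeric(1), "median_abs_octaves"),
      standard_median_abs = vapply(prof_std, `[[`, numeric(1), "median_abs_octaves"),
      row.names = NULL))

  compliance <- data.frame(
    subject_id = names(schedules),
    deviation_pct = vapply(names(schedules), function(id) {
      d <- diaries[diaries$subject_id == id, , drop = FALSE]
      if (!nrow(d)) return(NA_real_)
      compliance_deviation(schedules[[id]], d)
    }, numeric(1)), row.names = NULL)

  cleaned <- apply_score_rules(visits)
  measures <- intersect(c("cnc", "sentence_quiet", "sentence_noise"),
                        unique(cleaned$measure))
  span <- c(0, config$cohort$period_length)
  cparams <- list(); comparisons <- list()
  for (m in measures) {
    prm <- subject_curve_params(cleaned, m, span = span)
    cparams[[m]] <- prm
    cols <- if (m == "cnc") c("begin", "end", "auc", "learning_rate")
            else c("begin", "end", "auc")
    comparisons[[m]] <- lapply(stats::setNames(cols, cols), function(cl) {
      compare_param(prm, cl, n_boot = config$n_boot, seed = config$seed)
    })
  }
  holm <- do.call(rbind, lapply(measures, function(m) {
    ps <- vapply(c("begin", "end"), function(cl) {
      comparisons[[m]][[cl]]$p_value
    }, numeric(1))
    cbind(data.frame(measure = m, parameter = c("begin", "end")),
          holm_bonferroni(ps, alpha = config$alpha))
  }))
  rownames(holm) <- NULL

  res <- structure(list(fats = fats, standard_fat = std, mismatch = mismatch,
                        compliance = compliance, cleaned_visits = cleaned,
                        curve_params = cparams, comparisons = comparisons,
                        holm = holm, config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(cohort)) write_cohort(cohort, file.path(out_dir, "data"))
    write_fat(fats, file.path(out_dir, "fats_imaging.csv"))
    write_plain_csv(mismatch$per_subject, file.path(out_dir, "mismatch_per_subject.csv"))
    write_plain_csv(mismatch$standard$per_contact,
                    file.path(out_dir, "mismatch_standard_per_contact.csv"))
    write_plain_csv(mismatch$imaging$per_contact,
                    file.path(out_dir, "mismatch_imaging_per_contact.csv"))
    write_plain_csv(compliance, file.path(out_dir, "compliance.csv"))
    report <- list(
      mismatch = list(imaging_median = mismatch$imaging$median_octaves,
                      standard_median = mismatch$standard$median_octaves),
      compliance_median_pct = stats::median(compliance$deviation_pct, na.rm = TRUE),
      comparisons = lapply(comparisons, function(m) {
        lapply(m, function(pc) {
          pc[c("n", "median_test", "median_control", "iqr_test", "iqr_control",
               "median_difference", "p_value")]
        })
      }),
      holm = holm)
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, dataframe = "rows"),
               file.path(out_dir, "report.json"))
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d subjects\n", length(x$fats)))
  cat(sprintf("  mismatch (median octaves): standard %.2f, imaging-based %.2f\n",
              x$mismatch$standard$median_octaves,
              x$mismatch$imaging$median_octaves))
  cat(sprintf("  median compliance deviation: %.2f%%\n",
              stats::median(x$compliance$deviation_pct, na.rm = TRUE)))
  for (m in names(x$comparisons)) {
    end <- x$comparisons[[m]]$end
    cat(sprintf("  %s End: control %.2f vs test %.2f, p = %.3g\n",
                m, end$median_control, end$median_test, end$p_value))
  }
  invisible(x)
}
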
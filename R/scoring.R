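# Measures known to the scoring and analysis layer, with their scales.
measure_scales <- function() {
  data.frame(
    measure = c("cnc", "sentence_quiet", "sentence_noise",
                "preference_speech", "preference_quality",
                "listening_effort", "loudness"),
    unit = c("%", "%", "dB SNR", "VAS 0-10", "VAS 0-10", "0-12", "CU"),
    min = c(0, 0, -Inf, 0, 0, 0, 0),
    max = c(100, 100, Inf, 10, 10, 12, 50),
    lower_is_better = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, NA))
}

#' Apply the trial's scoring and substitution rules to raw visit records
#'
#' Cleans a raw longitudinal visit table into one record per subject, fitting,
#' measure and visit:
#'
#' * sentence recognition in quiet flagged `"not_measured_too_difficult"`
#'   (skipped after CNC evaluation) receives a score of 20% to correct for
#'   guessing;
#' * sentence recognition in noise (SRT) is only accepted as measured when the
#'   same visit's quiet score is at or above 50%; otherwise an SRT of
#'   15 dB SNR is recorded (flag `"assigned"`);
#' * measured SRTs above 15 dB SNR, or outside the range of presented levels,
#'   are marked `"invalid"` and excluded (value set to `NA`);
#' * CNC rows are averaged over the test and retest lists of a visit.
#'
#' The rules are idempotent: applying them to an already cleaned table changes
#' nothing.
#'
#' @param visits Data frame with columns `subject_id`, `fitting` (`"test"` or
#'   `"control"`), `measure` (see Details), `visit_day`, `value`, `flag`
#'   (`"measured"`, `"not_measured_too_difficult"`, `"assigned"`,
#'   `"invalid"`). Optional columns `level_min`, `level_max` give the range of
#'   presented levels for SRT rows (defaults `srt_range`).
#' @param srt_range Default presented-level range for SRT validity, dB SNR.
#' @param srt_assign Value assigned when sentence recognition in noise is not
#'   measurable (default 15 dB SNR).
#' @param quiet_gate Quiet score (\%) required before an SRT is accepted
#'   (default 50).
#' @param guess_score Score recorded for a too-difficult quiet test (default
#'   20\%, chance level of the closed-set matrix test).
#' @return Cleaned data frame, one row per subject/fitting/measure/visit.
#' @details Recognised measures: `cnc`, `sentence_quiet`, `sentence_noise`,
#'   `preference_speech`, `preference_quality`, `listening_effort`,
#'   `loudness`. Any other measure name is an error.
#' @export
apply_score_rules <- function(visits, srt_range = c(-15, 20),
                              srt_assign = 15, quiet_gate = 50,
                              guess_score = 20) {
  need <- c("subject_id", "fitting", "measure", "visit_day", "value", "flag")
  if (!is.data.frame(visits) || !all(need %in% names(visits))) {
    stop("visits must be a data frame with columns ", paste(need, collapse = ", "))
  }
  known <- measure_scales()$measure
  unknown <- setdiff(unique(visits$measure), known)
  if (length(unknown)) {
    stop("unknown measure type(s): ", paste(unknown, collapse = ", "))
  }
  if (!"level_min" %in% names(visits)) visits$level_min <- srt_range[1L]
  if (!"level_max" %in% names(visits)) visits$level_max <- srt_range[2L]
  visits$level_min[is.na(visits$level_min)] <- srt_range[1L]
  visits$level_max[is.na(visits$level_max)] <- srt_range[2L]

  # rule 1: too-difficult quiet tests scored at chance level
  td <- visits$measure == "sentence_quiet" &
    visits$flag == "not_measured_too_difficult"
  visits$value[td] <- guess_score
  visits$flag[td] <- "assigned"

  # rule 4: CNC = mean of test/retest lists per visit
  key <- interaction(visits$subject_id, visits$fitting, visits$measure,
                     visits$visit_day, drop = TRUE)
  cleaned <- do.call(rbind, lapply(split(visits, key), function(d) {
    if (d$measure[1L] == "cnc" && nrow(d) > 1L) {
      d$value[1L] <- mean(d$value, na.rm = !all(is.na(d$value)))
      d <- d[1L, , drop = FALSE]
    }
    d
  }))
  rownames(cleaned) <- NULL

  # rules 2-3: SRT gating on the quiet score, then validity of measured SRTs
  quiet <- cleaned[cleaned$measure == "sentence_quiet", ]
  qkey <- paste(quiet$subject_id, quiet$fitting, quiet$visit_day)
  srt <- which(cleaned$measure == "sentence_noise")
  for (i in srt) {
    qi <- match(paste(cleaned$subject_id[i], cleaned$fitting[i],
                      cleaned$visit_day[i]), qkey)
    qv <- if (is.na(qi)) NA_real_ else quiet$value[qi]
    if (!is.na(qv) && qv < quiet_gate) {
      cleaned$value[i] <- srt_assign
      cleaned$flag[i] <- "assigned"
    } else if (cleaned$flag[i] == "measured" && !is.na(cleaned$value[i])) {
      v <- cleaned$value[i]
      if (v > srt_assign || v < cleaned$level_min[i] || v > cleaned$level_max[i]) {
        cleaned$value[i] <- NA_real_
        cleaned$flag[i] <- "invalid"
      }
    }
  }
  ord <- order(cleaned$subject_id, cleaned$fitting, cleaned$measure,
               cleaned$visit_day)
  cleaned <- cleaned[ord, ]
  rownames(cleaned) <- NULL
  cleaned
}

#' Proportion of subjects preferring a fitting, with exact CI
#'
#' @param n_prefer Number of subjects choosing the fitting.
#' @param n_total Cohort size.
#' @param conf_level Confidence level for the exact (Clopper-Pearson)
#'   binomial interval.
#' @return List with `percent`, `ci_low`, `ci_high` (proportions for the CI).
#' @examples
#' preference_proportion(2, 14) # 14.3%
#' @export
preference_proportion <- function(n_prefer, n_total, conf_level = 0.95) {
  stopifnot(n_total >= 1, n_prefer >= 0, n_prefer <= n_total)
  bt <- stats::binom.test(n_prefer, n_total, conf.level = conf_level)
  list(percent = 100 * n_prefer / n_total,
       ci_low = bt$conf.int[1L], ci_high = bt$conf.int[2L])
}
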
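#' Configuration of a synthetic trial cohort
#'
#' Parameters of the synthetic-data generator that emulates the study
#' conditions: cochlear anatomy and 16-contact insertion geometries,
#' constrained daily wearing schedules with self-report diaries, and
#' longitudinal outcomes for both fittings following saturating learning
#' curves with visit-level noise and missingness.
#'
#' The default learning models are negatively accelerated exponentials,
#' `S(t) = asymptote * (1 - exp(-t / tau))` for measures where higher is
#' better, and `S(t) = asymptote + (start - asymptote) * exp(-t / tau)` for
#' the speech reception threshold (lower is better). Default asymptotes put
#' the control arm near a 68% CNC end score and the test arm near 47%,
#' a 3-month trajectory typical of post-lingual CI rehabilitation.
#'
#' @param n_subjects Cohort size (default 14).
#' @param cdl_mean,cdl_sd,cdl_range Cochlear duct length prior: normal
#'   (mm), truncated to `cdl_range`.
#' @param apical_depth_mean,apical_depth_sd,apical_depth_min Apical-contact
#'   insertion depth prior (mm), truncated to
#'   `[max(apical_depth_min, (n_contacts-1)*contact_spacing), CDL - 1]`.
#' @param contact_spacing Centre-to-centre contact spacing, mm.
#' @param n_contacts Contacts per array (default 16).
#' @param learning Data frame of per-measure, per-arm curve parameters with
#'   columns `measure`, `arm`, `start`, `asymptote`, `tau_days`, `noise_sd`,
#'   `min`, `max`. `NULL` uses the defaults described above.
#' @param visit_weeks Measurement schedule in weeks after activation.
#' @param missingness Probability that a visit's measurement is missing.
#' @param too_difficult_below Quiet score below which the sentence-in-quiet
#'   test is skipped as too difficult (flagged, later scored at 20%).
#' @param diary_error_prob Probability per day that the diary reports the
#'   other fitting than scheduled.
#' @param period_length Randomization period, days.
#' @param srt_range Presented-level range of the adaptive sentence-in-noise
#'   procedure, dB SNR.
#' @param master_seed Integer seed from which per-subject seeds are drawn.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 14,
                          cdl_mean = 35, cdl_sd = 2, cdl_range = c(28, 42),
                          apical_depth_mean = 22, apical_depth_sd = 2,
                          apical_depth_min = 12,
                          contact_spacing = 0.95, n_contacts = 16,
                          learning = NULL,
                          visit_weeks = c(0:8, 10, 12),
                          missingness = 0.1,
                          too_difficult_below = 25,
                          diary_error_prob = 0.05,
                          period_length = 84,
                          srt_range = c(-15, 20),
                          master_seed = 1) {
  if (is.null(learning)) {
    learning <- rbind(
      data.frame(measure = "cnc", arm = c("control", "test"), start = 0,
                 asymptote = c(68, 47), tau_days = 21, noise_sd = 6,
                 min = 0, max = 100),
      data.frame(measure = "sentence_quiet", arm = c("control", "test"),
                 start = 0, asymptote = c(89, 79), tau_days = 18,
                 noise_sd = 7, min = 0, max = 100),
      data.frame(measure = "sentence_noise", arm = c("control", "test"),
                 start = 15, asymptote = c(0.25, 1.9), tau_days = 21,
                 noise_sd = 1.5, min = -15, max = 20))
  }
  need <- c("measure", "arm", "start", "asymptote", "tau_days", "noise_sd",
            "min", "max")
  stopifnot(is.data.frame(learning), all(need %in% names(learning)),
            all(learning$noise_sd >= 0),
            missingness >= 0, missingness <= 1,
            diary_error_prob >= 0, diary_error_prob <= 1,
            contact_spacing > 0, cdl_sd >= 0, apical_depth_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 cdl_mean = cdl_mean, cdl_sd = cdl_sd, cdl_range = cdl_range,
                 apical_depth_mean = apical_depth_mean,
                 apical_depth_sd = apical_depth_sd,
                 apical_depth_min = apical_depth_min,
                 contact_spacing = contact_spacing,
                 n_contacts = as.integer(n_contacts),
                 learning = learning,
                 visit_weeks = visit_weeks,
                 missingness = missingness,
                 too_difficult_below = too_difficult_below,
                 diary_error_prob = diary_error_prob,
                 period_length = as.integer(period_length),
                 srt_range = srt_range,
                 master_seed = as.integer(master_seed)),
            class = "cohort_config")
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (lo > hi) stop(sprintf("infeasible truncation range [%.2f, %.2f]", lo, hi))
  if (sd == 0) {
    x <- min(max(mean, lo), hi)
    return(x)
  }
  for (i in seq_len(10000L)) {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  stop("truncated-normal rejection sampling failed (range too far in the tail)")
}

#' Sample a synthetic electrode insertion geometry
#'
#' Draws a cochlear duct length and an apical insertion depth from truncated
#' normal priors and places the remaining contacts at fixed spacing toward the
#' base. Uses the current RNG state (seed management belongs to
#' [generate_cohort()]).
#'
#' @param config A [cohort_config()].
#' @param subject_id Optional identifier.
#' @return An [electrode_geometry()].
#' @export
sample_geometry <- function(config = cohort_config(),
                            subject_id = NA_character_) {
  stopifnot(inherits(config, "cohort_config"))
  cdl <- rtruncnorm1(config$cdl_mean, config$cdl_sd,
                     config$cdl_range[1L], config$cdl_range[2L])
  apical_lo <- max(config$apical_depth_min,
                   (config$n_contacts - 1L) * config$contact_spacing)
  apical <- rtruncnorm1(config$apical_depth_mean, config$apical_depth_sd,
                        apical_lo, cdl - 1)
  depths <- apical - (seq_len(config$n_contacts) - 1L) * config$contact_spacing
  electrode_geometry(depths, cdl, subject_id = subject_id)
}

#' Simulate observed longitudinal outcomes for one subject
#'
#' Evaluates the per-arm true learning curves at the visit schedule, adds
#' Gaussian visit noise, clips to each measure's scale, drops visits
#' independently with the configured missingness probability, and emits raw
#' visit records in the format consumed by [apply_score_rules()]: CNC visits
#' produce two list scores (test and retest), sentence-in-quiet visits whose
#' underlying score is below `too_difficult_below` are flagged
#' `"not_measured_too_difficult"`, and sentence-in-noise rows carry the
#' presented-level range. Gating and substitution themselves are left to
#' [apply_score_rules()]. Uses the current RNG state.
#'
#' @param config A [cohort_config()].
#' @param subject_id Identifier written into the records.
#' @return Data frame of raw visit records.
#' @export
simulate_outcomes <- function(config = cohort_config(),
                              subject_id = "S01") {
  stopifnot(inherits(config, "cohort_config"))
  days <- config$visit_weeks * 7
  rows <- list()
  for (i in seq_len(nrow(config$learning))) {
    m <- config$learning[i, ]
    lower_better <- m$start > m$asymptote
    true <- if (lower_better) {
      m$asymptote + (m$start - m$asymptote) * exp(-days / m$tau_days)
    } else {
      m$start + (m$asymptote - m$start) * (1 - exp(-days / m$tau_days))
    }
    n_lists <- if (m$measure == "cnc") 2L else 1L
    for (v in seq_along(days)) {
      if (stats::runif(1L) < config$missingness) next
      vals <- pmin(pmax(true[v] + stats::rnorm(n_lists, 0, m$noise_sd),
                        m$min), m$max)
      flag <- rep("measured", n_lists)
      if (m$measure == "sentence_quiet" &&
          true[v] < config$too_difficult_below) {
        vals <- NA_real_
        flag <- "not_measured_too_difficult"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subject_id, fitting = m$arm, measure = m$measure,
        visit_day = days[v], value = vals, flag = flag,
        level_min = if (m$measure == "sentence_noise") config$srt_range[1L] else NA_real_,
        level_max = if (m$measure == "sentence_noise") config$srt_range[2L] else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a self-report wearing diary
#'
#' Each day follows the schedule except that, with the configured diary error
#' probability, the other fitting is recorded (covering both reporting errors
#' and actual non-compliance). Uses the current RNG state.
#'
#' @param schedule A [generate_schedule()] result.
#' @param error_prob Per-day probability of recording the other fitting.
#' @return Data frame `day_index`, `worn_fitting`, `hours`.
#' @export
simulate_diary <- function(schedule, error_prob = 0.05) {
  stopifnot(inherits(schedule, "wearing_schedule"),
            error_prob >= 0, error_prob <= 1)
  a <- schedule$assignments
  flip <- stats::runif(nrow(a)) < error_prob
  worn <- ifelse(flip, ifelse(a$assigned_fitting == "test", "control", "test"),
                 a$assigned_fitting)
  data.frame(day_index = a$day_index, worn_fitting = worn,
             hours = round(pmin(pmax(stats::rnorm(nrow(a), 12, 2), 4), 16), 1))
}

#' Generate a complete synthetic cohort
#'
#' Produces, for every subject, an insertion geometry, the imaging-based FAT
#' built from its place frequencies, a constrained wearing schedule, a
#' self-report diary, a per-visit processor-label map, and raw longitudinal
#' outcomes for both fittings. Per-subject seeds are drawn once from the
#' master seed, and each subject is generated under its own seed, so the
#' dataset is fully reproducible and swapping one subject's seed changes only
#' that subject.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional directory; when given, all tables are written as
#'   CSV plus a `manifest.json` recording the configuration and per-subject
#'   seeds.
#' @param greenwood A [greenwood_params()] object.
#' @param rules A [fat_rules()] object for the imaging-based FATs.
#' @return (Invisibly when writing) a list with `geometry` (named list of
#'   [electrode_geometry()]), `fats` (named list of imaging-based `fat`
#'   objects), `standard_fat`, `schedules`, `diaries`, `label_maps`, `visits`
#'   (one raw visit table), `subject_seeds`, and `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 3, master_seed = 7))
#' names(cohort$geometry)
#' @export
generate_cohort <- function(config = cohort_config(), out_dir = NULL,
                            greenwood = greenwood_params(),
                            rules = fat_rules()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  ids <- sprintf("S%02d", seq_len(n))
  subject_seeds <- with_seed(config$master_seed,
                             sample.int(.Machine$integer.max - 1L, n))
  geometry <- list(); fats <- list(); schedules <- list()
  diaries <- list(); label_maps <- list(); visits <- list()
  for (i in seq_len(n)) {
    id <- ids[i]
    with_seed(subject_seeds[i], {
      geometry[[id]] <- sample_geometry(config, subject_id = id)
      pf <- place_frequencies(geometry[[id]], greenwood)
      fats[[id]] <- build_tonotopic_fat(pf, rules, subject_id = id)
      schedules[[id]] <- generate_schedule(config$period_length,
                                           subject_id = id)
      diaries[[id]] <- cbind(subject_id = id,
                             simulate_diary(schedules[[id]],
                                            config$diary_error_prob))
      lm <- shuffle_labels(config$visit_weeks * 7)
      label_maps[[id]] <- cbind(subject_id = id, lm)
      visits[[id]] <- simulate_outcomes(config, subject_id = id)
    })
  }
  out <- list(geometry = geometry, fats = fats,
              standard_fat = standard_fat(),
              schedules = schedules,
              diaries = do.call(rbind, c(diaries, make.row.names = FALSE)),
              label_maps = do.call(rbind, c(label_maps, make.row.names = FALSE)),
              visits = do.call(rbind, c(visits, make.row.names = FALSE)),
              subject_seeds = stats::setNames(subject_seeds, ids),
              config = config)
  if (!is.null(out_dir)) {
    write_cohort(out, out_dir)
    return(invisible(out))
  }
  out
}
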
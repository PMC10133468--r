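# Run a block with a private, restorable RNG state. A NULL seed leaves the
# caller's RNG stream untouched and in control.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# cache for feasibility tables, keyed by (period, caps, boundary)
.schedule_cache <- new.env(parent = emptyenv())

# Backward-induction feasibility table for constrained daily randomization.
# State before day d: t = test days assigned so far, last label (1 test,
# 2 control), and the trailing same-label run length *within the current
# phase* (0 right after the phase boundary or at the start).
# feasible[d, t+1, last, run+1] == TRUE iff the remaining days can be
# completed under the run caps and the 1:1 balance (|#test - #control| <= 1).
schedule_feasibility <- function(period_length, caps = c(2L, 4L),
                                 phase_boundary = 28L) {
  key <- paste(period_length, caps[1L], caps[2L], phase_boundary, sep = "_")
  if (!is.null(.schedule_cache[[key]])) return(.schedule_cache[[key]])
  n <- period_length
  cap_max <- max(caps)
  day_cap <- ifelse(seq_len(n) <= phase_boundary, caps[1L], caps[2L])
  # feas[[d]] is a [t+1, last, run+1] logical array for state entering day d
  feas <- vector("list", n + 1L)
  tgrid <- 0:n
  end_ok <- abs(tgrid - (n - tgrid)) <= 1L
  feas[[n + 1L]] <- array(rep(end_ok, times = 2L * (cap_max + 1L)),
                          dim = c(n + 1L, 2L, cap_max + 1L))
  for (d in n:1) {
    cap <- day_cap[d]
    nxt <- feas[[d + 1L]]
    cur <- array(FALSE, dim = c(n + 1L, 2L, cap_max + 1L))
    reset <- (d + 1L) == (phase_boundary + 1L) # run counter resets after day d
    for (last in 1:2) {
      for (run in 0:cap_max) {
        ok <- rep(FALSE, n + 1L)
        for (lab in 1:2) {
          newrun <- if (lab == last && run > 0L) run + 1L else 1L
          if (newrun > cap) next
          nextrun <- if (reset) 0L else newrun
          if (lab == 1L) {
            # t -> t + 1; valid for t in 0..(d-1), and t+1 <= n
            shifted <- c(nxt[-1L, lab, nextrun + 1L], FALSE)
            ok <- ok | shifted
          } else {
            ok <- ok | nxt[, lab, nextrun + 1L]
          }
        }
        cur[, last, run + 1L] <- ok
      }
    }
    feas[[d]] <- cur
  }
  .schedule_cache[[key]] <- list(feas = feas, day_cap = day_cap,
                                 phase_boundary = phase_boundary,
                                 caps = caps, n = n)
  .schedule_cache[[key]]
}

#' Generate a constrained daily wearing schedule
#'
#' Within-subject daily crossover randomization between the test
#' (imaging-based) and control (standard) fitting. The schedule satisfies:
#' a 1:1 overall ratio (`|#test - #control| <= 1`, exact equality on even
#' lengths); no more than `caps[1]` consecutive days on the same fitting
#' within the first `phase_boundary` days (default 2 within the first four
#' weeks); no more than `caps[2]` consecutive days thereafter (default 4),
#' with runs straddling the boundary judged per phase.
#'
#' Labels are drawn day by day, uniformly among those that keep the remaining
#' schedule completable (constrained sequential sampling with exact lookahead
#' feasibility), so generation never dead-ends and every constraint-satisfying
#' schedule has positive probability.
#'
#' @param period_length Randomization period in days (default 84: first fit to
#'   +12 weeks).
#' @param seed Optional integer seed; the same seed reproduces the schedule
#'   exactly.
#' @param caps Length-2 integer vector: maximum run length in the early and
#'   late phase.
#' @param phase_boundary Last day (inclusive) governed by the stricter cap.
#' @param subject_id Optional identifier.
#' @return An object of class `wearing_schedule`: a list with `assignments`
#'   (data frame `day_index`, `assigned_fitting` in `"test"`/`"control"`),
#'   `period_length`, `phase_boundary`, `caps`.
#' @examples
#' s <- generate_schedule(84, seed = 1)
#' table(s$assignments$assigned_fitting)
#' @export
generate_schedule <- function(period_length = 84, seed = NULL,
                              caps = c(2L, 4L), phase_boundary = 28L,
                              subject_id = NA_character_) {
  period_length <- as.integer(period_length)
  if (is.na(period_length) || period_length < 1L) {
    stop("period_length must be a positive number of days")
  }
  caps <- as.integer(caps)
  stopifnot(length(caps) == 2L, all(caps >= 1L))
  fz <- schedule_feasibility(period_length, caps, as.integer(phase_boundary))
  labels <- integer(period_length)
  with_seed(seed, {
    t <- 0L; last <- 1L; run <- 0L
    for (d in seq_len(period_length)) {
      cap <- fz$day_cap[d]
      reset <- (d + 1L) == (fz$phase_boundary + 1L)
      cand <- integer(0)
      for (lab in 1:2) {
        newrun <- if (lab == last && run > 0L) run + 1L else 1L
        if (newrun > cap) next
        nextrun <- if (reset) 0L else newrun
        t2 <- t + (lab == 1L)
        if (fz$feas[[d + 1L]][t2 + 1L, lab, nextrun + 1L]) cand <- c(cand, lab)
      }
      if (!length(cand)) stop("internal error: schedule generation dead-ended")
      lab <- if (length(cand) == 1L) cand else cand[sample.int(2L, 1L)]
      newrun <- if (lab == last && run > 0L) run + 1L else 1L
      labels[d] <- lab
      t <- t + (lab == 1L)
      last <- lab
      run <- if (reset) 0L else newrun
    }
  })
  assignments <- data.frame(
    day_index = seq_len(period_length),
    assigned_fitting = c("test", "control")[labels])
  structure(list(assignments = assignments,
                 period_length = period_length,
                 phase_boundary = as.integer(phase_boundary),
                 caps = caps,
                 subject_id = subject_id),
            class = "wearing_schedule")
}

#' @export
print.wearing_schedule <- function(x, ...) {
  tab <- table(x$assignments$assigned_fitting)
  cat(sprintf("Wearing schedule%s: %d days (%s)\n",
              if (!is.na(x$subject_id)) paste0(" [", x$subject_id, "]") else "",
              x$period_length,
              paste(names(tab), tab, sep = " = ", collapse = ", ")))
  cat(sprintf("  run caps: <= %d days within days 1-%d, <= %d thereafter\n",
              x$caps[1L], x$phase_boundary, x$caps[2L]))
  invisible(x)
}

#' Maximum same-fitting run lengths per schedule phase
#'
#' Utility used to audit schedules: the longest run of identical assignments,
#' counting only the portion of each run falling inside each phase.
#'
#' @param assignments Character vector of daily labels.
#' @param phase_boundary Last day of the early phase.
#' @return Named numeric vector `c(early = ..., late = ...)`.
#' @export
max_run_lengths <- function(assignments, phase_boundary = 28L) {
  n <- length(assignments)
  phase <- ifelse(seq_len(n) <= phase_boundary, 1L, 2L)
  r <- rle(paste(assignments, phase, sep = "/"))
  lens <- tapply(r$lengths, sub(".*/", "", r$values), max)
  c(early = unname(if ("1" %in% names(lens)) lens[["1"]] else 0),
    late = unname(if ("2" %in% names(lens)) lens[["2"]] else 0))
}

#' Randomize the fitting-to-processor label mapping per visit
#'
#' Two physical processors are distinguished only by a printed circle or
#' triangle. At every fitting visit a fair coin decides which processor
#' carries the test (imaging-based) program until the next visit, supporting
#' subject blinding.
#'
#' @param visit_days Sorted numeric vector of visit days.
#' @param seed Optional integer seed.
#' @return Data frame with one row per visit: `visit_day`, `test_label`,
#'   `control_label` (each `"circle"` or `"triangle"`).
#' @export
shuffle_labels <- function(visit_days, seed = NULL) {
  visit_days <- as.numeric(visit_days)
  if (length(visit_days) && is.unsorted(visit_days, strictly = TRUE)) {
    stop("visit_days must be sorted and distinct")
  }
  coin <- with_seed(seed, stats::runif(length(visit_days)) < 0.5)
  data.frame(visit_day = visit_days,
             test_label = ifelse(coin, "circle", "triangle"),
             control_label = ifelse(coin, "triangle", "circle"))
}

#' Compliance deviation between a wearing schedule and a diary
#'
#' The absolute difference, in percentage points, between the intended share
#' of test-fitting days and the self-reported share, both computed over the
#' days with a diary report (unreported days are excluded from numerator and
#' denominator alike).
#'
#' @param schedule A [generate_schedule()] result.
#' @param diary Data frame with columns `day_index` and `worn_fitting`
#'   (`"test"`, `"control"`, or `NA` for no report).
#' @return Deviation in percent (0 = perfect compliance, 50 = fully inverted).
#' @examples
#' s <- generate_schedule(84, seed = 2)
#' d <- data.frame(day_index = 1:84, worn_fitting = s$assignments$assigned_fitting)
#' compliance_deviation(s, d) # 0
#' @export
compliance_deviation <- function(schedule, diary) {
  stopifnot(inherits(schedule, "wearing_schedule"), is.data.frame(diary),
            all(c("day_index", "worn_fitting") %in% names(diary)))
  m <- merge(schedule$assignments, diary[, c("day_index", "worn_fitting")],
             by = "day_index")
  m <- m[!is.na(m$worn_fitting), , drop = FALSE]
  if (!nrow(m)) stop("diary contains no reported days overlapping the schedule")
  intended <- mean(m$assigned_fitting == "test")
  reported <- mean(m$worn_fitting == "test")
  abs(intended - reported) * 100
}
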
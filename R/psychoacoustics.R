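#' Presentation levels for the listening-effort task
#'
#' Six signal-to-noise ratios set around a subject's individual speech
#' reception threshold: SRT - 6, SRT - 3, SRT, SRT + 3, SRT + 6, SRT + 9 dB.
#'
#' @param srt Speech reception threshold, dB SNR.
#' @return Numeric vector of six presentation SNRs, 3 dB apart.
#' @examples
#' effort_levels(1.9)
#' @export
effort_levels <- function(srt) {
  stopifnot(is.numeric(srt), length(srt) == 1L, is.finite(srt))
  srt + c(-6, -3, 0, 3, 6, 9)
}

#' Loudness-growth AUC from categorical loudness scaling
#'
#' Quantifies loudness perception measured with adaptive categorical loudness
#' scaling (ACALOS): per 1/3-octave noise band, loudness in categorical units
#' (CU, 0-50) as a function of stimulus level is integrated over the level
#' range (trapezoidal rule, flat extrapolation beyond the sampled levels). The
#' across-frequency AUC interpolates the per-frequency AUCs linearly on a
#' log-frequency grid and sums them over the grid.
#'
#' @param surface Data frame with columns `freq_hz`, `level_db`,
#'   `loudness_cu`: samples of the loudness-growth functions at the measured
#'   centre frequencies (defaults in the trial: 250, 500, 1000, 2000,
#'   4000 Hz).
#' @param level_range Integration range in dB HL (default `c(0, 105)`).
#' @param freq_grid_n Number of log-spaced grid frequencies for the overall
#'   AUC (default 17).
#' @param freq_range Frequency range of the grid, Hz (default
#'   `c(250, 4000)`).
#' @return List with `overall` (sum of interpolated per-frequency AUCs over
#'   the grid, CU x dB), `per_frequency` (data frame `freq_hz`, `auc`), and
#'   `grid` (data frame `freq_hz`, `auc`).
#' @examples
#' flat <- expand.grid(freq_hz = c(250, 500, 1000, 2000, 4000),
#'                     level_db = c(0, 105))
#' flat$loudness_cu <- 25
#' acalos_auc(flat)$per_frequency$auc # all 2625
#' @export
acalos_auc <- function(surface, level_range = c(0, 105), freq_grid_n = 17,
                       freq_range = c(250, 4000)) {
  need <- c("freq_hz", "level_db", "loudness_cu")
  if (!is.data.frame(surface) || !all(need %in% names(surface))) {
    stop("surface must be a data frame with columns ", paste(need, collapse = ", "))
  }
  per <- do.call(rbind, lapply(split(surface, surface$freq_hz), function(d) {
    d <- d[order(d$level_db), ]
    if (nrow(d) < 2L) stop(sprintf("frequency %g Hz has < 2 level samples", d$freq_hz[1L]))
    if (any(diff(d$level_db) <= 0)) {
      stop(sprintf("non-monotone level grid at %g Hz", d$freq_hz[1L]))
    }
    xs <- sort(unique(c(level_range, d$level_db[d$level_db >= level_range[1L] &
                                                  d$level_db <= level_range[2L]])))
    ys <- stats::approx(d$level_db, d$loudness_cu, xout = xs, rule = 2)$y
    data.frame(freq_hz = d$freq_hz[1L], auc = trapz(xs, ys))
  }))
  rownames(per) <- NULL
  per <- per[order(per$freq_hz), ]
  grid_f <- exp(seq(log(freq_range[1L]), log(freq_range[2L]),
                    length.out = freq_grid_n))
  grid_auc <- stats::approx(log(per$freq_hz), per$auc, xout = log(grid_f),
                            rule = 2)$y
  list(overall = sum(grid_auc),
       per_frequency = per,
       grid = data.frame(freq_hz = grid_f, auc = grid_auc))
}

#' Spectral ripple discrimination threshold via a 1-up/1-down staircase
#'
#' Simulates the adaptive track of the spectral-temporally modulated ripple
#' test: the target stimulus starts at 0.5 ripples per octave and moves up by
#' one step after each correct response and down after each incorrect one
#' (never below the floor). The track stops after `n_reversals` direction
#' reversals (or `max_trials` as a non-convergence guard); the threshold is
#' the mean of the last `n_last` reversal values.
#'
#' @param respond Function of one argument (the target ripple density, ripples
#'   per octave) returning `TRUE` for a correct discrimination. May be
#'   stochastic; it is evaluated under the supplied seed.
#' @param seed Optional integer seed making stochastic oracles reproducible.
#' @param start Starting ripple density (default 0.5 rpo).
#' @param step Step size (default 0.2 rpo).
#' @param floor Lowest allowed ripple density (default 0.5 rpo).
#' @param n_reversals Reversals after which the track stops (default 10).
#' @param n_last Number of final reversals averaged into the threshold
#'   (default 6).
#' @param max_trials Hard trial cap guarding against non-convergence
#'   (default 150).
#' @return List with `threshold` (rpo), `reversals`, `trials` (data frame
#'   `trial`, `target_rpo`, `correct`), and `converged`.
#' @examples
#' smrt_staircase(function(rpo) rpo < 3)$threshold # ~3.0
#' @export
smrt_staircase <- function(respond, seed = NULL, start = 0.5, step = 0.2,
                           floor = 0.5, n_reversals = 10, n_last = 6,
                           max_trials = 150) {
  stopifnot(is.function(respond))
  with_seed(seed, {
    target <- start
    last_dir <- 0L
    reversals <- numeric(0)
    trials <- vector("list", max_trials)
    t <- 0L
    while (t < max_trials && length(reversals) < n_reversals) {
      t <- t + 1L
      correct <- isTRUE(respond(target))
      dir <- if (correct) 1L else -1L
      trials[[t]] <- data.frame(trial = t, target_rpo = target,
                                correct = correct)
      if (last_dir != 0L && dir != last_dir) {
        reversals <- c(reversals, target)
      }
      # at the floor a further "down" is not a track movement
      if (!(dir == -1L && target <= floor)) last_dir <- dir
      target <- max(floor, target + dir * step)
    }
    converged <- length(reversals) >= n_reversals
    threshold <- if (length(reversals)) {
      mean(utils::tail(reversals, n_last))
    } else {
      target # pinned track (e.g., oracle never correct at the floor)
    }
    list(threshold = threshold, reversals = reversals,
         trials = do.call(rbind, trials[seq_len(t)]), converged = converged)
  })
}
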
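#' Low-frequency rule set for frequency allocation tables
#'
#' The trade-off rules guaranteeing minimum low-frequency coverage when a FAT
#' is aligned to tonotopy: a minimum number of enabled channels (the virtual
#' channel counts as one) must be stimulated below each threshold, and the most
#' basal enabled channel must be stimulated at or below `basal_max`.
#'
#' Defaults: at least 2 channels below 1,000 Hz, 4 below 2,000 Hz, 7 below
#' 4,000 Hz, and a basal ceiling of 8,598 Hz.
#'
#' @param thresholds_hz Strictly increasing thresholds in Hz.
#' @param min_counts Non-decreasing minimum channel counts, same length.
#' @param basal_max Maximum allowed lower bound of the most basal enabled
#'   channel, Hz.
#' @return An object of class `fat_rules`.
#' @export
fat_rules <- function(thresholds_hz = c(1000, 2000, 4000),
                      min_counts = c(2, 4, 7),
                      basal_max = 8598) {
  stopifnot(length(thresholds_hz) == length(min_counts),
            is.numeric(thresholds_hz), is.numeric(min_counts),
            is.numeric(basal_max), length(basal_max) == 1L)
  if (length(thresholds_hz) && any(diff(thresholds_hz) <= 0)) {
    stop("rule thresholds must be strictly increasing")
  }
  if (length(min_counts) > 1L && any(diff(min_counts) < 0)) {
    stop("rule minimum counts must be non-decreasing")
  }
  structure(list(thresholds_hz = as.numeric(thresholds_hz),
                 min_counts = as.integer(min_counts),
                 basal_max = as.numeric(basal_max)),
            class = "fat_rules")
}

#' Construct a frequency allocation table object
#'
#' A FAT is an ordered set of channels, each with a lower and upper frequency
#' bound and an enabled flag. Channel index 0 denotes the virtual (phantom)
#' channel, which delivers content apical to the most apical physical contact;
#' physical channels are indexed 1 (apical) to n (basal). Enabled channels
#' must tile a contiguous band starting at `global_min`.
#'
#' @param channels Data frame with columns `channel_index`, `lower_hz`,
#'   `upper_hz`, `enabled`.
#' @param global_min Processor floor in Hz (default 238).
#' @param global_max Processor ceiling in Hz (default 8598).
#' @param subject_id Optional identifier.
#' @return An object of class `fat`.
#' @export
fat <- function(channels, global_min = 238, global_max = 8598,
                subject_id = NA_character_) {
  need <- c("channel_index", "lower_hz", "upper_hz", "enabled")
  if (!is.data.frame(channels) || !all(need %in% names(channels))) {
    stop("channels must be a data frame with columns ",
         paste(need, collapse = ", "))
  }
  channels <- channels[order(channels$channel_index), need]
  rownames(channels) <- NULL
  channels$channel_index <- as.integer(channels$channel_index)
  channels$enabled <- as.logical(channels$enabled)
  structure(list(channels = channels,
                 global_min = global_min,
                 global_max = global_max,
                 has_virtual_channel = 0L %in% channels$channel_index,
                 subject_id = subject_id),
            class = "fat")
}

#' @export
print.fat <- function(x, ...) {
  en <- x$channels[x$channels$enabled, ]
  cat(sprintf("Frequency allocation table%s: %d channels (%d enabled%s)\n",
              if (!is.na(x$subject_id)) paste0(" [", x$subject_id, "]") else "",
              nrow(x$channels), nrow(en),
              if (x$has_virtual_channel) ", incl. virtual channel" else ""))
  if (nrow(en)) {
    cat(sprintf("  enabled band: %.0f - %.0f Hz\n",
                min(en$lower_hz), max(en$upper_hz)))
  }
  print(x$channels, digits = 6)
  invisible(x)
}

#' The fixed standard (control) frequency allocation table
#'
#' The clinical default FAT ignores electrode position: 16 enabled channels
#' tiling 238--8,598 Hz, no virtual channel. Band edges default to log
#' spacing, `lower_k = 238 * (8598/238)^((k-1)/16)`, which places four
#' physical channels below 782 Hz as in the clinical default; a custom edge
#' table can be supplied instead.
#'
#' @param table Optional data frame of channels (as in [fat()]) overriding the
#'   log-spaced default; it is validated against `rules`.
#' @param n_channels Number of physical channels (default 16).
#' @param global_min,global_max Processor frequency range in Hz.
#' @param rules A [fat_rules()] object used to validate a supplied table.
#' @return A `fat` object with all channels enabled.
#' @examples
#' standard_fat()
#' @export
standard_fat <- function(table = NULL, n_channels = 16,
                         global_min = 238, global_max = 8598,
                         rules = fat_rules()) {
  if (is.null(table)) {
    k <- seq_len(n_channels)
    lower <- global_min * (global_max / global_min)^((k - 1) / n_channels)
    upper <- c(lower[-1L], global_max)
    table <- data.frame(channel_index = k, lower_hz = lower,
                        upper_hz = upper, enabled = TRUE)
  }
  out <- fat(table, global_min = global_min, global_max = global_max)
  v <- validate_fat(out, rules)
  if (nrow(v)) {
    stop("supplied standard FAT violates its invariants:\n",
         paste(v$message, collapse = "\n"))
  }
  out
}

#' Build a subject-specific imaging-based (tonotopic) FAT
#'
#' Allocates each contact's tonotopic place frequency to the lower bound of
#' its channel, then applies the device and rule-set constraints:
#'
#' 1. the virtual channel (index 0) is enabled from `global_min` (238 Hz) up
#'    to the most apical contact's place frequency, delivering low-frequency
#'    content apical to the array;
#' 2. each physical channel's lower bound is its contact's place frequency
#'    (clamped up to `global_min` where a very deep contact falls below the
#'    processor floor);
#' 3. channels whose lower bound would reach `global_max` (8,598 Hz) or above
#'    are disabled (basal contacts outside the processor range);
#' 4. unmet low-frequency rules are repaired deterministically: working
#'    apically from each unmet threshold, the offending channels' bounds are
#'    lowered to geometric spacing between the last compliant bound and the
#'    threshold, leaving all other channels untouched;
#' 5. enabled channels are made contiguous (each upper bound equals the next
#'    enabled lower bound; the top enabled channel is capped at `global_max`).
#'
#' The result always passes [validate_fat()] with zero violations.
#'
#' @param place_freqs Per-contact place frequencies in Hz, ordered apical to
#'   basal and strictly increasing (as returned by [place_frequencies()]).
#' @param rules A [fat_rules()] object.
#' @param global_min,global_max Processor frequency range, Hz.
#' @param virtual_channel Enable the virtual (phantom) channel? Default TRUE.
#' @param subject_id Optional identifier.
#' @return A `fat` object.
#' @examples
#' pf <- place_frequencies(electrode_geometry(seq(22, 7.75, by = -0.95), 35))
#' build_tonotopic_fat(pf)
#' @export
build_tonotopic_fat <- function(place_freqs, rules = fat_rules(),
                                global_min = 238, global_max = 8598,
                                virtual_channel = TRUE,
                                subject_id = NA_character_) {
  pf <- as.numeric(place_freqs)
  n <- length(pf)
  if (n < 2L || any(!is.finite(pf)) || any(pf <= 0)) {
    stop("place_freqs must be >= 2 positive frequencies")
  }
  if (any(diff(pf) <= 0)) {
    stop("place_freqs must be strictly increasing from the apical contact")
  }

  # Virtual channel: floor of the processor range up to the apical place
  # frequency. Degenerate (apical place at or below the floor) -> disabled.
  v_upper <- max(pf[1L], global_min)
  has_virtual <- isTRUE(virtual_channel) && pf[1L] > global_min

  lower <- pmax(pf, global_min)
  enabled <- lower < global_max
  if (!has_virtual) {
    # without a usable virtual channel the apical-most enabled channel must
    # reach down to the processor floor
    lower[which(enabled)[1L]] <- global_min
  }
  # clamping can create ties at the floor; spread them geometrically up to the
  # first unclamped bound so bounds stay strictly increasing
  tied <- which(enabled & duplicated(lower))
  if (length(tied)) {
    j <- max(tied)
    target <- if (j < n) min(lower[j + 1L], global_max) else global_max
    base <- lower[min(tied) - 1L]
    idx <- c(min(tied) - 1L, tied)
    lower[idx] <- base * (target / base)^(seq(0, length(idx) - 1L) /
                                            length(idx))
  }

  ch <- data.frame(channel_index = seq_len(n), lower_hz = lower,
                   upper_hz = NA_real_, enabled = enabled)
  if (isTRUE(virtual_channel)) {
    ch <- rbind(data.frame(channel_index = 0L, lower_hz = global_min,
                           upper_hz = v_upper, enabled = has_virtual), ch)
  }

  max_count <- if (length(rules$min_counts)) max(rules$min_counts) else 0L
  if (sum(ch$enabled) < max_count + 1L) {
    stop(sprintf(
      "unsatisfiable rule set: %d usable channels but the rules require at least %d",
      sum(ch$enabled), max_count + 1L))
  }

  ch <- repair_rules(ch, rules)

  # contiguity: enabled channels tile [global_min, global_max]
  en <- which(ch$enabled)
  ch$upper_hz[en] <- c(ch$lower_hz[en][-1L], global_max)
  ch$lower_hz[!ch$enabled & ch$channel_index > 0L] <-
    pf[ch$channel_index[!ch$enabled & ch$channel_index > 0L]]
  ch$upper_hz[!ch$enabled] <- NA_real_

  out <- fat(ch, global_min = global_min, global_max = global_max,
             subject_id = subject_id)
  v <- validate_fat(out, rules)
  if (nrow(v)) {
    stop("internal error: built FAT fails validation:\n",
         paste(v$message, collapse = "\n"))
  }
  out
}

# Deterministic rule repair: for each (threshold, count) in ascending order,
# if fewer than `count` enabled channels lie below the threshold, lower the
# offending bounds among the first `count` enabled channels to geometric
# spacing between the last compliant bound and the threshold.
repair_rules <- function(ch, rules) {
  for (r in seq_along(rules$thresholds_hz)) {
    thr <- rules$thresholds_hz[r]
    m <- rules$min_counts[r]
    en <- which(ch$enabled)
    below <- sum(ch$lower_hz[en] < thr)
    if (below >= m) next
    head_idx <- en[seq_len(m)]
    offending <- head_idx[ch$lower_hz[head_idx] >= thr]
    j <- offending[1L]
    base <- if (which(head_idx == j) == 1L) {
      ch$lower_hz[head_idx[1L]] # first enabled channel already at the floor
    } else {
      ch$lower_hz[head_idx[which(head_idx == j) - 1L]]
    }
    if (base >= thr) base <- thr / 2 # defensive; cannot occur for valid rules
    k <- length(offending)
    ch$lower_hz[offending] <- base * (thr / base)^(seq_len(k) / (k + 1L))
  }
  ch
}

#' Validate a FAT against structural invariants and the rule set
#'
#' Never throws on content: every structural defect and every unmet rule is
#' returned as one row of a violations table. An empty table means the FAT is
#' compliant.
#'
#' @param x A `fat` object.
#' @param rules A [fat_rules()] object.
#' @return Data frame with columns `type`, `threshold_hz`, `required`,
#'   `observed`, `message`; zero rows iff compliant.
#' @export
validate_fat <- function(x, rules = fat_rules()) {
  stopifnot(inherits(x, "fat"))
  viol <- list()
  add <- function(type, threshold = NA_real_, required = NA_real_,
                  observed = NA_real_, message) {
    viol[[length(viol) + 1L]] <<- data.frame(
      type = type, threshold_hz = threshold, required = required,
      observed = observed, message = message)
  }
  ch <- x$channels
  en <- ch[ch$enabled, , drop = FALSE]
  if (!nrow(en)) {
    add("structure", message = "no enabled channels")
  } else {
    if (any(en$lower_hz <= 0, na.rm = TRUE)) {
      add("structure", message = "non-positive lower bound on an enabled channel")
    }
    if (any(!is.finite(en$lower_hz)) || any(!is.finite(en$upper_hz))) {
      add("structure", message = "missing bound on an enabled channel")
    } else {
      if (any(en$lower_hz >= en$upper_hz)) {
        add("structure", message = "enabled channel with lower bound >= upper bound")
      }
      if (nrow(en) > 1L) {
        gaps <- abs(en$upper_hz[-nrow(en)] - en$lower_hz[-1L])
        if (any(gaps > 1e-6 * en$lower_hz[-1L])) {
          add("structure",
              message = "enabled channels are not contiguous (gap or overlap between bands)")
        }
      }
      if (abs(min(en$lower_hz) - x$global_min) > 1e-6 * x$global_min) {
        add("structure", threshold = x$global_min,
            required = x$global_min, observed = min(en$lower_hz),
            message = sprintf("lowest enabled lower bound is %.3f Hz, not the %.0f Hz floor",
                              min(en$lower_hz), x$global_min))
      }
      if (max(en$upper_hz) > x$global_max * (1 + 1e-9)) {
        add("structure", threshold = x$global_max,
            required = x$global_max, observed = max(en$upper_hz),
            message = sprintf("highest enabled upper bound %.3f Hz exceeds the %.0f Hz ceiling",
                              max(en$upper_hz), x$global_max))
      }
      for (r in seq_along(rules$thresholds_hz)) {
        thr <- rules$thresholds_hz[r]
        req <- rules$min_counts[r]
        obs <- sum(en$lower_hz < thr)
        if (obs < req) {
          add("rule", threshold = thr, required = req, observed = obs,
              message = sprintf("only %d enabled channels below %.0f Hz (rule requires %d)",
                                obs, thr, req))
        }
      }
      basal_lower <- max(en$lower_hz)
      if (basal_lower > rules$basal_max * (1 + 1e-9)) {
        add("rule", threshold = rules$basal_max, required = rules$basal_max,
            observed = basal_lower,
            message = sprintf("most basal enabled channel stimulated at %.3f Hz, above the %.0f Hz cap",
                              basal_lower, rules$basal_max))
      }
    }
  }
  if (!length(viol)) {
    return(data.frame(type = character(), threshold_hz = numeric(),
                      required = numeric(), observed = numeric(),
                      message = character()))
  }
  do.call(rbind, viol)
}

#' Frequency-to-place mismatch of a FAT in octaves
#'
#' For each enabled physical channel, the signed mismatch is
#' `log2(place_frequency / assigned_frequency)` where the assigned frequency
#' representing the channel is either the geometric mean of its band edges
#' (the band centre on a log axis; default) or its lower bound. Positive
#' values mean the electrode sits at a place tuned higher than the frequencies
#' routed to it. The virtual channel has no physical contact and is excluded.
#'
#' @param x A `fat` object.
#' @param place_freqs Per-contact place frequencies (Hz), ordered apical to
#'   basal, one per physical channel of `x`.
#' @param representative `"geomean"` (default) or `"lower"`.
#' @return An object of class `mismatch_profile`: a list with `per_contact`
#'   (data frame of contact, assigned and place frequency, octave offset),
#'   `median_octaves`, `iqr_octaves`, and the pooled absolute-mismatch summary
#'   `median_abs_octaves`.
#' @examples
#' pf <- place_frequencies(electrode_geometry(seq(22, 7.75, by = -0.95), 35))
#' mismatch_profile(standard_fat(), pf)
#' @export
mismatch_profile <- function(x, place_freqs,
                             representative = c("geomean", "lower")) {
  stopifnot(inherits(x, "fat"))
  representative <- match.arg(representative)
  phys <- x$channels[x$channels$channel_index > 0L, , drop = FALSE]
  if (nrow(phys) != length(place_freqs)) {
    stop(sprintf("FAT has %d physical channels but %d place frequencies were given",
                 nrow(phys), length(place_freqs)))
  }
  en <- phys$enabled
  assigned <- switch(representative,
                     geomean = sqrt(phys$lower_hz * phys$upper_hz),
                     lower = phys$lower_hz)
  per <- data.frame(contact_index = phys$channel_index,
                    enabled = en,
                    assigned_hz = ifelse(en, assigned, NA_real_),
                    place_hz = as.numeric(place_freqs),
                    octaves = ifelse(en, log2(place_freqs / assigned), NA_real_))
  oct <- per$octaves[per$enabled]
  structure(list(per_contact = per,
                 representative = representative,
                 median_octaves = stats::median(oct),
                 iqr_octaves = stats::IQR(oct),
                 median_abs_octaves = stats::median(abs(oct))),
            class = "mismatch_profile")
}

#' @export
print.mismatch_profile <- function(x, ...) {
  cat(sprintf(
    "Frequency-to-place mismatch (%s representative): median %.2f octaves (IQR %.2f), median |mismatch| %.2f\n",
    x$representative, x$median_octaves, x$iqr_octaves, x$median_abs_octaves))
  invisible(x)
}

#' Per-contact mismatch summary across subjects
#'
#' Pools [mismatch_profile()] results from several subjects and summarises
#' signed octave mismatch per contact position (median and IQR across subjects
#' among whom the contact was enabled) plus the pooled across-array summary.
#'
#' @param profiles List of `mismatch_profile` objects.
#' @return List with `per_contact` (data frame: contact index, n enabled,
#'   median and IQR of octaves) and pooled `median_octaves`, `iqr_octaves`.
#' @export
mismatch_summary <- function(profiles) {
  stopifnot(length(profiles) > 0L,
            all(vapply(profiles, inherits, logical(1), "mismatch_profile")))
  per <- do.call(rbind, lapply(profiles, `[[`, "per_contact"))
  per <- per[per$enabled, , drop = FALSE]
  agg <- do.call(rbind, lapply(split(per, per$contact_index), function(d) {
    data.frame(contact_index = d$contact_index[1L], n_enabled = nrow(d),
               median_octaves = stats::median(d$octaves),
               iqr_octaves = stats::IQR(d$octaves))
  }))
  rownames(agg) <- NULL
  list(per_contact = agg[order(agg$contact_index), ],
       median_octaves = stats::median(per$octaves),
       iqr_octaves = stats::IQR(per$octaves))
}
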
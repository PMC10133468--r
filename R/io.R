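# Schema-checked CSV reader shared by all table formats.
read_checked_csv <- function(path, columns) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(columns, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")))
  }
  df
}

write_plain_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write electrode geometry tables
#'
#' Geometry CSV columns: `subject_id`, `contact_index` (1 = most apical),
#' `insertion_depth_mm`, `cdl_mm`.
#'
#' @param path CSV file path.
#' @return `read_geometry()`: named list of [electrode_geometry()] objects.
#' @examples
#' # two synthetic example subjects shipped with the package
#' g <- read_geometry(system.file("extdata", "example_geometry.csv",
#'                                package = "tonofit"))
#' place_frequencies(g[[1]])
#' @export
read_geometry <- function(path) {
  df <- read_checked_csv(path, c("subject_id", "contact_index",
                                 "insertion_depth_mm", "cdl_mm"))
  out <- lapply(split(df, df$subject_id), function(d) {
    d <- d[order(d$contact_index), ]
    if (!identical(d$contact_index, seq_len(nrow(d)))) {
      if (any(duplicated(d$contact_index))) {
        stop(sprintf("%s: subject %s: duplicate contact_index", path,
                     d$subject_id[1L]))
      }
    }
    if (length(unique(d$cdl_mm)) != 1L) {
      stop(sprintf("%s: subject %s: cdl_mm differs across rows", path,
                   d$subject_id[1L]))
    }
    electrode_geometry(d$insertion_depth_mm, d$cdl_mm[1L],
                       subject_id = d$subject_id[1L])
  })
  out[order(names(out))]
}

#' @rdname read_geometry
#' @param geometries Named list of [electrode_geometry()] objects (or one).
#' @export
write_geometry <- function(geometries, path) {
  if (inherits(geometries, "electrode_geometry")) {
    geometries <- list(geometries)
  }
  df <- do.call(rbind, lapply(geometries, function(g) {
    data.frame(subject_id = g$subject_id,
               contact_index = seq_len(g$contact_count),
               insertion_depth_mm = g$insertion_depths,
               cdl_mm = g$cochlear_duct_length)
  }))
  write_plain_csv(df, path)
}

#' Read and write frequency allocation tables
#'
#' FAT CSV columns: `subject_id`, `channel_index` (0 = virtual channel),
#' `lower_bound_hz`, `upper_bound_hz`, `enabled`. [fat_to_json()] and
#' [fat_from_json()] mirror the CSV as JSON for a single table.
#'
#' @param path File path.
#' @param global_min,global_max Processor frequency range, Hz.
#' @return `read_fat()`: named list of `fat` objects.
#' @export
read_fat <- function(path, global_min = 238, global_max = 8598) {
  df <- read_checked_csv(path, c("subject_id", "channel_index",
                                 "lower_bound_hz", "upper_bound_hz", "enabled"))
  out <- lapply(split(df, df$subject_id), function(d) {
    fat(data.frame(channel_index = d$channel_index,
                   lower_hz = d$lower_bound_hz,
                   upper_hz = d$upper_bound_hz,
                   enabled = as.logical(d$enabled)),
        global_min = global_min, global_max = global_max,
        subject_id = d$subject_id[1L])
  })
  out[order(names(out))]
}

fat_table <- function(f, subject_id = NULL) {
  id <- if (!is.null(subject_id)) subject_id else f$subject_id
  data.frame(subject_id = id,
             channel_index = f$channels$channel_index,
             lower_bound_hz = f$channels$lower_hz,
             upper_bound_hz = f$channels$upper_hz,
             enabled = f$channels$enabled)
}

#' @rdname read_fat
#' @param fats Named list of `fat` objects (or a single one).
#' @export
write_fat <- function(fats, path) {
  if (inherits(fats, "fat")) fats <- list(fats)
  df <- do.call(rbind, Map(function(f, nm) {
    fat_table(f, subject_id = if (is.na(f$subject_id)) nm else f$subject_id)
  }, fats, if (is.null(names(fats))) as.character(seq_along(fats)) else names(fats)))
  write_plain_csv(df, path)
}

#' @rdname read_fat
#' @param x A `fat` object.
#' @export
fat_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "fat"))
  obj <- list(subject_id = x$subject_id, global_min = x$global_min,
              global_max = x$global_max, channels = x$channels)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(path))
  }
  json
}

#' @rdname read_fat
#' @export
fat_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  fat(obj$channels, global_min = obj$global_min, global_max = obj$global_max,
      subject_id = if (is.null(obj$subject_id)) NA_character_ else obj$subject_id)
}

#' Read and write wearing schedules
#'
#' Schedule CSV columns: `subject_id`, `day_index`, `assigned_fitting`.
#'
#' @param path CSV file path.
#' @param caps,phase_boundary Constraint parameters recorded in the objects.
#' @return `read_schedule()`: named list of `wearing_schedule` objects.
#' @export
read_schedule <- function(path, caps = c(2L, 4L), phase_boundary = 28L) {
  df <- read_checked_csv(path, c("subject_id", "day_index", "assigned_fitting"))
  bad <- !df$assigned_fitting %in% c("test", "control")
  if (any(bad)) {
    stop(sprintf("%s: row %d: assigned_fitting must be 'test' or 'control'",
                 path, which(bad)[1L]))
  }
  out <- lapply(split(df, df$subject_id), function(d) {
    d <- d[order(d$day_index), ]
    structure(list(assignments = data.frame(day_index = d$day_index,
                                            assigned_fitting = d$assigned_fitting),
                   period_length = nrow(d),
                   phase_boundary = as.integer(phase_boundary),
                   caps = as.integer(caps),
                   subject_id = d$subject_id[1L]),
              class = "wearing_schedule")
  })
  out[order(names(out))]
}

#' @rdname read_schedule
#' @param schedules Named list of `wearing_schedule` objects (or one).
#' @export
write_schedule <- function(schedules, path) {
  if (inherits(schedules, "wearing_schedule")) schedules <- list(schedules)
  df <- do.call(rbind, lapply(schedules, function(s) {
    cbind(subject_id = s$subject_id, s$assignments)
  }))
  write_plain_csv(df, path)
}

#' Read and write self-report diaries
#'
#' Diary CSV columns: `subject_id`, `day_index`, `worn_fitting`, `hours`.
#'
#' @param path CSV file path.
#' @param diary Data frame in the diary format.
#' @return `read_diary()`: the diary data frame.
#' @export
read_diary <- function(path) {
  read_checked_csv(path, c("subject_id", "day_index", "worn_fitting"))
}

#' @rdname read_diary
#' @export
write_diary <- function(diary, path) write_plain_csv(diary, path)

#' Read and write longitudinal visit tables
#'
#' Visit CSV columns: `subject_id`, `fitting`, `measure`, `visit_day`,
#' `value`, `flag`, and optionally `level_min`, `level_max` for SRT validity.
#'
#' @param path CSV file path.
#' @param visits Data frame in the visit format.
#' @return `read_visits()`: the visits data frame.
#' @export
read_visits <- function(path) {
  df <- read_checked_csv(path, c("subject_id", "fitting", "measure",
                                 "visit_day", "value", "flag"))
  bad <- !df$fitting %in% c("test", "control")
  if (any(bad)) {
    stop(sprintf("%s: row %d: fitting must be 'test' or 'control'",
                 path, which(bad)[1L]))
  }
  df
}

#' @rdname read_visits
#' @export
write_visits <- function(visits, path) write_plain_csv(visits, path)

#' Write all tables of a generated cohort to a directory
#'
#' Emits `geometry.csv`, `fats_imaging.csv`, `fat_standard.csv`,
#' `schedules.csv`, `diaries.csv`, `label_maps.csv`, `visits.csv` and a
#' `manifest.json` with the configuration and per-subject seeds.
#'
#' @param cohort A [generate_cohort()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_geometry(cohort$geometry, p("geometry.csv"))
  write_fat(cohort$fats, p("fats_imaging.csv"))
  write_fat(list(standard = cohort$standard_fat), p("fat_standard.csv"))
  write_schedule(cohort$schedules, p("schedules.csv"))
  write_diary(cohort$diaries, p("diaries.csv"))
  write_plain_csv(cohort$label_maps, p("label_maps.csv"))
  write_visits(cohort$visits, p("visits.csv"))
  manifest <- list(config = unclass(cohort$config),
                   subject_seeds = as.list(cohort$subject_seeds))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), p("manifest.json"))
  invisible(vapply(c("geometry.csv", "fats_imaging.csv", "fat_standard.csv",
                     "schedules.csv", "diaries.csv", "label_maps.csv",
                     "visits.csv", "manifest.json"), p, character(1)))
}
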
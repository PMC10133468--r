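#' Lateral-wall trace of the cochlear duct
#'
#' An ordered 3-D polyline marking the lateral wall of the cochlea from the
#' round window up to the helicotrema. Arc length along this polyline defines
#' insertion depth, and its total length is the cochlear duct length (CDL).
#'
#' @param points Numeric matrix with 3 columns (x, y, z in mm) and at least
#'   two rows, ordered from the round window (first row) to the helicotrema.
#' @return An object of class `lateral_wall_trace` with elements `points` and
#'   `arc_length` (cumulative arc length at each vertex, mm).
#' @export
lateral_wall_trace <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L || nrow(points) < 2L) {
    stop("a lateral-wall trace needs a numeric matrix of >= 2 points x 3 coordinates")
  }
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  if (any(seg <= 0)) stop("trace arc length must be strictly increasing (duplicate points?)")
  structure(list(points = points, arc_length = c(0, cumsum(seg))),
            class = "lateral_wall_trace")
}

#' @export
print.lateral_wall_trace <- function(x, ...) {
  cat(sprintf("Lateral-wall trace: %d points, total arc length %.2f mm\n",
              nrow(x$points), max(x$arc_length)))
  invisible(x)
}

#' Insertion depth of an electrode marker along a lateral-wall trace
#'
#' Projects a 3-D marker (typically the centre of an electrode contact) onto
#' the nearest point of the trace polyline -- the projection is taken on the
#' segments, not just the vertices -- and returns the arc length from the
#' round window (first trace vertex) to that projection.
#'
#' @param trace A [lateral_wall_trace()].
#' @param marker Numeric length-3 vector, mm.
#' @return Insertion depth in mm from the round window.
#' @examples
#' tr <- lateral_wall_trace(rbind(c(0, 0, 0), c(5, 0, 0), c(5, 5, 0)))
#' insertion_depth(tr, c(6, 2, 0))  # nearest point (5, 2, 0) -> 7 mm
#' @export
insertion_depth <- function(trace, marker) {
  stopifnot(inherits(trace, "lateral_wall_trace"))
  marker <- as.numeric(marker)
  if (length(marker) != 3L || any(!is.finite(marker))) {
    stop("marker must be a finite 3-D point")
  }
  p <- trace$points
  n <- nrow(p)
  best_d2 <- Inf
  best_arc <- 0
  for (i in seq_len(n - 1L)) {
    a <- p[i, ]
    v <- p[i + 1L, ] - a
    len2 <- sum(v * v)
    t <- sum((marker - a) * v) / len2
    t <- min(max(t, 0), 1)
    foot <- a + t * v
    d2 <- sum((marker - foot)^2)
    if (d2 < best_d2) {
      best_d2 <- d2
      best_arc <- trace$arc_length[i] + t * sqrt(len2)
    }
  }
  best_arc
}

#' Electrode array insertion geometry for one ear
#'
#' Per-contact insertion depths along the lateral wall, measured in mm from
#' the round window, together with the cochlear duct length (CDL). Contacts
#' are indexed 1..n with contact 1 the most apical (deepest) and contact n the
#' most basal, so depths strictly decrease with contact index.
#'
#' @param insertion_depths Numeric vector of per-contact depths in mm, ordered
#'   by contact index (apical first). Must be strictly decreasing, with every
#'   depth in `[0, cochlear_duct_length]`.
#' @param cochlear_duct_length CDL in mm.
#' @param subject_id Optional identifier carried through I/O tables.
#' @return An object of class `electrode_geometry`.
#' @export
electrode_geometry <- function(insertion_depths, cochlear_duct_length,
                               subject_id = NA_character_) {
  d <- as.numeric(insertion_depths)
  cdl <- as.numeric(cochlear_duct_length)
  if (length(cdl) != 1L || !is.finite(cdl) || cdl <= 0) {
    stop("cochlear_duct_length must be a single positive number (mm)")
  }
  if (length(d) < 1L || any(!is.finite(d))) stop("insertion depths must be finite")
  bad <- which(d < 0 | d > cdl)
  if (length(bad)) {
    stop(sprintf("contact %d: insertion depth %.3f mm outside [0, CDL = %.3f] mm",
                 bad[1L], d[bad[1L]], cdl))
  }
  if (length(d) > 1L && any(diff(d) >= 0)) {
    stop("insertion depths must strictly decrease from the apical contact (index 1) to the base")
  }
  structure(list(insertion_depths = d,
                 cochlear_duct_length = cdl,
                 contact_count = length(d),
                 subject_id = subject_id),
            class = "electrode_geometry")
}

#' @export
print.electrode_geometry <- function(x, ...) {
  cat(sprintf("Electrode geometry%s: %d contacts, CDL %.2f mm\n",
              if (!is.na(x$subject_id)) paste0(" [", x$subject_id, "]") else "",
              x$contact_count, x$cochlear_duct_length))
  cat(sprintf("  apical contact at %.2f mm, basal contact at %.2f mm from the round window\n",
              x$insertion_depths[1L], x$insertion_depths[x$contact_count]))
  invisible(x)
}

#' Tonotopic place frequencies of an electrode array
#'
#' Converts each contact's insertion depth `d` (mm from the round window) to
#' the relative position from the apex `x = (CDL - d) / CDL`, optionally
#' rescaled by a multiplicative length-correction factor, and evaluates the
#' Greenwood function there. Deeper contacts therefore receive lower
#' frequencies.
#'
#' @param geom An [electrode_geometry()].
#' @param params A [greenwood_params()] object.
#' @param length_correction Multiplicative correction applied to the relative
#'   distance from the apex before evaluating the Greenwood map. Default 1
#'   (lateral-wall distance used as is, with no organ-of-Corti rescaling).
#' @return Numeric vector of per-contact frequencies in Hz, ordered like the
#'   contacts (apical first, hence increasing).
#' @examples
#' geom <- electrode_geometry(seq(22, 7.75, by = -0.95), 35)
#' place_frequencies(geom)
#' @export
place_frequencies <- function(geom, params = greenwood_params(),
                              length_correction = 1) {
  stopifnot(inherits(geom, "electrode_geometry"))
  if (!is.numeric(length_correction) || length(length_correction) != 1L ||
      length_correction <= 0) {
    stop("length_correction must be a single positive factor")
  }
  x <- (geom$cochlear_duct_length - geom$insertion_depths) /
    geom$cochlear_duct_length
  x <- pmin(x * length_correction, 1)
  greenwood_frequency(x, params)
}
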
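# Independent oracles used across tests.

# Arc-length insertion depth by dense sampling of the polyline at ~1 um.
brute_insertion_depth <- function(points, marker, res = 1e-3) {
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  best <- Inf; best_arc <- 0
  for (i in seq_len(nrow(points) - 1)) {
    n <- max(2L, ceiling(seg[i] / res))
    t <- seq(0, 1, length.out = n)
    pts <- cbind(points[i, 1] + t * (points[i + 1, 1] - points[i, 1]),
                 points[i, 2] + t * (points[i + 1, 2] - points[i, 2]),
                 points[i, 3] + t * (points[i + 1, 3] - points[i, 3]))
    d2 <- (pts[, 1] - marker[1])^2 + (pts[, 2] - marker[2])^2 +
      (pts[, 3] - marker[3])^2
    j <- which.min(d2)
    if (d2[j] < best) {
      best <- d2[j]
      best_arc <- cum[i] + t[j] * seg[i]
    }
  }
  best_arc
}

# Two-sided exact signed-rank p-value by full enumeration of the 2^n sign
# assignments (average ranks; distribution symmetric about sum(r)/2).
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12)
  r <- rank(abs(d))
  M <- sum(r) / 2
  t_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  t_all <- as.vector(signs %*% r)
  mean(abs(t_all - M) >= abs(t_obs - M) - 1e-9)
}

# A mid-range reference geometry: apical contact 22 mm deep, CDL 35 mm,
# 16 contacts at 0.95 mm spacing.
mean_geometry <- function() {
  electrode_geometry(seq(22, by = -0.95, length.out = 16), 35,
                     subject_id = "REF")
}

# Raw visit records for one subject/fitting built from explicit values.
visit_rows <- function(measure, days, values, flag = "measured",
                       fitting = "test", subject_id = "S01",
                       level_min = NA_real_, level_max = NA_real_) {
  data.frame(subject_id = subject_id, fitting = fitting, measure = measure,
             visit_day = days, value = values, flag = flag,
             level_min = level_min, level_max = level_max)
}
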
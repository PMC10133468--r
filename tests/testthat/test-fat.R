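test_that("the standard FAT spans 238-8598 Hz with 16 log-spaced enabled channels", {
  f <- standard_fat()
  en <- f$channels[f$channels$enabled, ]
  expect_equal(nrow(en), 16)
  expect_false(f$has_virtual_channel)
  expect_equal(min(en$lower_hz), 238)
  expect_equal(max(en$upper_hz), 8598)
  # closed-form log spacing: lower_k = 238 * (8598/238)^((k-1)/16)
  expect_equal(en$lower_hz, 238 * (8598 / 238)^((0:15) / 16), tolerance = 1e-12)
  expect_equal(en$lower_hz[9], 1430.498, tolerance = 1e-6)
  expect_equal(nrow(validate_fat(f)), 0)
})

test_that("a rule-satisfying tonotopic FAT keeps place frequencies as lower bounds", {
  pf <- place_frequencies(mean_geometry())
  f <- build_tonotopic_fat(pf, subject_id = "REF")
  phys <- f$channels[f$channels$channel_index > 0, ]
  expect_true(all(phys$enabled)) # all within range for this geometry
  expect_equal(phys$lower_hz, pf, tolerance = 1e-12)
  v <- f$channels[f$channels$channel_index == 0, ]
  expect_true(v$enabled)
  expect_equal(v$lower_hz, 238)
  expect_equal(v$upper_hz, pf[1], tolerance = 1e-12)
  expect_equal(nrow(validate_fat(f)), 0)
})

test_that("basal contacts outside the processor range are disabled", {
  pf <- place_frequencies(mean_geometry())
  pf[15:16] <- c(9000, 12000)
  f <- build_tonotopic_fat(pf)
  ch <- f$channels
  expect_false(any(ch$enabled[ch$channel_index %in% 15:16]))
  en <- ch[ch$enabled, ]
  expect_lte(max(en$lower_hz), 8598)
  expect_equal(max(en$upper_hz), 8598)
  expect_equal(nrow(validate_fat(f)), 0)
})

test_that("a shallow insertion triggers deterministic rule repair", {
  geom <- electrode_geometry(seq(14.25, 0, by = -0.95), 35)
  pf <- place_frequencies(geom)
  expect_gt(pf[1], 2000) # apical place above 2 kHz: rules initially unmet
  f <- build_tonotopic_fat(pf)
  en <- f$channels[f$channels$enabled, ]
  expect_gte(sum(en$lower_hz < 1000), 2)
  expect_gte(sum(en$lower_hz < 2000), 4)
  expect_gte(sum(en$lower_hz < 4000), 7)
  expect_equal(nrow(validate_fat(f)), 0)
  # deterministic: same inputs, identical table
  expect_identical(f$channels, build_tonotopic_fat(pf)$channels)
})

test_that("the virtual channel counts toward the rule set and spans 238 Hz to the apical place", {
  # shallow insertion with apical place near 957 Hz
  x <- greenwood_position(957)
  depth_ap <- 35 * (1 - x)
  geom <- electrode_geometry(seq(depth_ap, by = -0.95, length.out = 16), 35)
  pf <- place_frequencies(geom)
  f <- build_tonotopic_fat(pf)
  v <- f$channels[f$channels$channel_index == 0, ]
  expect_equal(v$lower_hz, 238)
  expect_equal(v$upper_hz, f$channels$lower_hz[2], tolerance = 1e-9)
  en <- f$channels[f$channels$enabled, ]
  expect_gte(sum(en$lower_hz < 1000), 2) # virtual + repaired channel 1
})

test_that("validate_fat reports one violation per unmet rule with counts", {
  tab <- data.frame(channel_index = 1:8,
                    lower_hz = c(900, seq(4100, 8800, length.out = 7)),
                    upper_hz = c(seq(4100, 8800, length.out = 7), 9500),
                    enabled = TRUE)
  f <- fat(tab, global_min = 900, global_max = 9500) # structure itself valid
  v <- validate_fat(f)
  rule <- v[v$type == "rule", ]
  expect_equal(nrow(rule), 4) # 1000/2000/4000 counts + basal cap
  r1000 <- rule[rule$threshold_hz == 1000 & !is.na(rule$threshold_hz), ]
  expect_equal(r1000$required, 2)
  expect_equal(r1000$observed, 1)
  expect_gt(rule$observed[rule$threshold_hz == 8598], 8598)
})

test_that("fuzzed tonotopic FATs always validate and never beat the basal cap", {
  cfg <- cohort_config()
  set.seed(101)
  for (i in 1:300) {
    g <- sample_geometry(cfg)
    f <- build_tonotopic_fat(place_frequencies(g))
    expect_equal(nrow(validate_fat(f)), 0)
    en <- f$channels[f$channels$enabled, ]
    # contiguity: enabled bands tile [238, 8598] with no gaps or overlaps
    expect_equal(en$upper_hz[-nrow(en)], en$lower_hz[-1], tolerance = 1e-9)
    expect_equal(en$lower_hz[1], 238)
    expect_equal(en$upper_hz[nrow(en)], 8598)
  }
})

test_that("raising one contact's place frequency never re-enables a basal channel", {
  pf <- place_frequencies(mean_geometry())
  pf[14:16] <- c(8000, 9500, 11000)
  f1 <- build_tonotopic_fat(pf)
  pf2 <- pf; pf2[13] <- 7990 # push a mid contact close to the ceiling
  f2 <- build_tonotopic_fat(pf2)
  was_disabled <- f1$channels$channel_index[!f1$channels$enabled]
  expect_true(all(!f2$channels$enabled[f2$channels$channel_index %in% was_disabled]))
})

test_that("mismatch is zero when assignment equals place and follows log2 ratios", {
  pf <- place_frequencies(mean_geometry())
  f <- build_tonotopic_fat(pf)
  mp <- mismatch_profile(f, pf, representative = "lower")
  phys <- mp$per_contact[mp$per_contact$enabled, ]
  expect_equal(phys$octaves, rep(0, nrow(phys)), tolerance = 1e-12)
  expect_equal(mp$median_octaves, 0)
  # a 238 Hz channel representing a 1710.3 Hz place is ~2.845 octaves off
  expect_equal(log2(1710.267 / 238), 2.845, tolerance = 1e-3)
  expect_error(mismatch_profile(f, pf[-1]), "place frequencies")
})

test_that("imaging-based FATs reduce pooled mismatch against the standard FAT on every subject", {
  cfg <- cohort_config()
  std <- standard_fat()
  set.seed(202)
  for (i in 1:60) {
    g <- sample_geometry(cfg)
    pf <- place_frequencies(g)
    f <- build_tonotopic_fat(pf)
    m_img <- mismatch_profile(f, pf)$median_abs_octaves
    m_std <- mismatch_profile(std, pf)$median_abs_octaves
    expect_lte(m_img, m_std)
  }
})

test_that("unsatisfiable rule sets are rejected with a clear error", {
  pf <- c(8700, 8800, 9000, 9500, 10000, 11000, 12000, 13000)
  expect_error(build_tonotopic_fat(pf), "unsatisfiable")
  expect_error(build_tonotopic_fat(c(500, 400, 600)), "strictly increasing")
})
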
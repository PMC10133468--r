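test_that("sampled geometries honour anatomy priors and pass their invariants", {
  cfg <- cohort_config()
  set.seed(55)
  for (i in 1:500) {
    g <- sample_geometry(cfg)
    expect_s3_class(g, "electrode_geometry")
    expect_true(g$cochlear_duct_length >= 28 && g$cochlear_duct_length <= 42)
    expect_true(all(g$insertion_depths >= 0))
    expect_lte(g$insertion_depths[1], g$cochlear_duct_length - 1)
  }
  # zero-variance priors are deterministic at the means
  cfg0 <- cohort_config(cdl_sd = 0, apical_depth_sd = 0)
  g1 <- sample_geometry(cfg0); g2 <- sample_geometry(cfg0)
  expect_equal(g1$insertion_depths, g2$insertion_depths)
  expect_equal(g1$cochlear_duct_length, 35)
  expect_equal(g1$insertion_depths[1], 22)
  # apical place frequency of the mean geometry by direct Greenwood evaluation
  expect_equal(place_frequencies(g1)[1],
               165.4 * (10^(2.1 * (35 - 22) / 35) - 0.88), tolerance = 1e-9)
  expect_error(cohort_config(cdl_range = c(28, 42), cdl_mean = 35, cdl_sd = -1))
})

test_that("noise-free simulation reproduces the saturating curve at the knots", {
  lrn <- cohort_config()$learning
  lrn$noise_sd <- 0
  cfg <- cohort_config(learning = lrn, missingness = 0,
                       too_difficult_below = -Inf)
  set.seed(1)
  v <- simulate_outcomes(cfg, "S01")
  cnc_t <- v[v$measure == "cnc" & v$fitting == "test", ]
  expect_equal(unique(cnc_t$value[cnc_t$visit_day == 84]),
               47 * (1 - exp(-84 / 21)), tolerance = 1e-9)
  # control CNC asymptote 68 puts the 3-month score near 66.8
  cnc_c <- v[v$measure == "cnc" & v$fitting == "control", ]
  expect_equal(unique(cnc_c$value[cnc_c$visit_day == 84]), 66.75454,
               tolerance = 1e-4)
  # SRT is mirrored: starts high (15), decreases toward the asymptote
  srt <- v[v$measure == "sentence_noise" & v$fitting == "control", ]
  expect_equal(srt$value[srt$visit_day == 0], 15)
  expect_true(all(diff(srt$value[order(srt$visit_day)]) < 0))
})

test_that("diary errors translate to the expected compliance deviation", {
  s <- generate_schedule(84, seed = 9)
  set.seed(2)
  d0 <- simulate_diary(s, error_prob = 0)
  expect_equal(compliance_deviation(s, d0), 0)
  # every day flipped swaps both fittings, leaving total exposure balanced
  d1 <- simulate_diary(s, error_prob = 1)
  expect_equal(compliance_deviation(s, d1), 0)
  # Monte-Carlo mean deviation vs the binomial closed form at error rate 0.05:
  # share shift = |flips_control->test - flips_test->control| / 84, so the
  # expected deviation is E|X - Y| * 100 / 84 with X,Y ~ Bin(42, 0.05).
  set.seed(3)
  dev <- replicate(800, compliance_deviation(s, simulate_diary(s, 0.05)))
  x <- rbinom(2e5, 42, 0.05); y <- rbinom(2e5, 42, 0.05)
  oracle <- mean(abs(x - y)) * 100 / 84
  expect_lt(abs(mean(dev) - oracle), 0.25)
})

test_that("cohorts are reproducible from the master seed, subject streams independent", {
  cfg <- cohort_config(n_subjects = 4, master_seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$visits, b$visits)
  expect_identical(a$subject_seeds, b$subject_seeds)
  expect_identical(lapply(a$fats, `[[`, "channels"),
                   lapply(b$fats, `[[`, "channels"))
  c2 <- generate_cohort(cohort_config(n_subjects = 4, master_seed = 124))
  expect_false(identical(a$visits, c2$visits))
})

test_that("a default 50-subject cohort exercises every scoring rule", {
  cohort <- generate_cohort(cohort_config(n_subjects = 50, master_seed = 11))
  raw <- cohort$visits
  expect_equal(length(unique(raw$subject_id)), 50)
  cleaned <- apply_score_rules(raw)
  expect_true(any(cleaned$measure == "sentence_quiet" & cleaned$value == 20 &
                    cleaned$flag == "assigned"))
  expect_true(any(cleaned$measure == "sentence_noise" & cleaned$value == 15 &
                    cleaned$flag == "assigned"))
  expect_true(any(cleaned$flag == "invalid" &
                    cleaned$measure == "sentence_noise"))
  # every emitted imaging-based FAT validates
  for (f in cohort$fats) expect_equal(nrow(validate_fat(f)), 0)
})
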
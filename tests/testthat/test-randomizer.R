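test_that("generated schedules satisfy ratio and per-phase run caps", {
  for (seed in 1:400) {
    s <- generate_schedule(84, seed = seed)
    a <- s$assignments$assigned_fitting
    expect_equal(sum(a == "test"), 42)
    runs <- max_run_lengths(a, 28)
    expect_lte(runs[["early"]], 2)
    expect_lte(runs[["late"]], 4)
  }
})

test_that("odd and tiny period lengths respect the near-1:1 balance", {
  s1 <- generate_schedule(1, seed = 5)
  expect_equal(nrow(s1$assignments), 1)
  for (seed in 1:50) {
    s <- generate_schedule(29, seed = seed)
    tab <- table(factor(s$assignments$assigned_fitting,
                        levels = c("test", "control")))
    expect_lte(abs(tab[["test"]] - tab[["control"]]), 1)
    expect_lte(max_run_lengths(s$assignments$assigned_fitting, 28)[["early"]], 2)
  }
  expect_error(generate_schedule(0), "positive")
})

test_that("schedules are reproducible from the seed and vary across seeds", {
  s1 <- generate_schedule(84, seed = 11)
  s2 <- generate_schedule(84, seed = 11)
  expect_identical(s1$assignments, s2$assignments)
  s3 <- generate_schedule(84, seed = 12)
  expect_false(identical(s1$assignments, s3$assignments))
})

test_that("both fittings occur on every calendar day across seeds", {
  mat <- sapply(1:300, function(seed) {
    generate_schedule(84, seed = seed)$assignments$assigned_fitting == "test"
  })
  frac_test <- rowMeans(mat)
  expect_true(all(frac_test > 0 & frac_test < 1))
})

test_that("label shuffling is a reproducible fair coin per visit", {
  lm <- shuffle_labels(c(0, 7, 14), seed = 3)
  expect_identical(lm, shuffle_labels(c(0, 7, 14), seed = 3))
  expect_true(all(lm$test_label != lm$control_label))
  expect_true(all(lm$test_label %in% c("circle", "triangle")))
  # proportion of circle=test over many draws is ~0.5 (binomial 3 sd band)
  p <- mean(sapply(1:4000, function(s) {
    shuffle_labels(0, seed = s)$test_label == "circle"
  }))
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 4000))
  expect_error(shuffle_labels(c(7, 0)), "sorted")
})

test_that("compliance deviation compares intended and reported test-day shares", {
  s <- generate_schedule(84, seed = 21)
  diary <- data.frame(day_index = 1:84,
                      worn_fitting = s$assignments$assigned_fitting)
  expect_equal(compliance_deviation(s, diary), 0)
  # two scheduled test days reported as control: 42/84 -> 40/84
  flip <- which(diary$worn_fitting == "test")[1:2]
  diary$worn_fitting[flip] <- "control"
  expect_equal(compliance_deviation(s, diary), abs(50 - 100 * 40 / 84),
               tolerance = 1e-12)
  # control worn on every scheduled test day: share deviation |50 - 0| = 50
  inv <- data.frame(day_index = 1:84, worn_fitting = "control")
  expect_equal(compliance_deviation(s, inv), 50)
  # swapping both fittings everywhere keeps total exposure balanced: 0
  swap <- data.frame(day_index = 1:84,
                     worn_fitting = ifelse(s$assignments$assigned_fitting == "test",
                                           "control", "test"))
  expect_equal(compliance_deviation(s, swap), 0)
  # unreported days are excluded from both shares
  part <- diary
  part$worn_fitting[61:84] <- NA
  m <- merge(s$assignments, part, by = "day_index")
  m <- m[!is.na(m$worn_fitting), ]
  expect_equal(compliance_deviation(s, part),
               abs(mean(m$assigned_fitting == "test") -
                     mean(m$worn_fitting == "test")) * 100)
  empty <- data.frame(day_index = 1:84, worn_fitting = NA_character_)
  expect_error(compliance_deviation(s, empty), "no reported days")
})
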
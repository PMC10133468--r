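test_that("exact signed-rank p matches full enumeration of sign assignments", {
  set.seed(77)
  for (rep in 1:30) {
    n <- sample(5:12, 1)
    d <- round(rnorm(n, sd = 3), if (rep %% 3 == 0) 0 else 2) # thirds with ties
    d <- d[d != 0]
    if (length(d) < 5) next
    pc <- paired_compare(d, rep(0, length(d)), n_boot = 0)
    expect_equal(pc$p_value, enum_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("five positive differences give the textbook exact p of 0.0625", {
  pc <- paired_compare(c(1, 2, 3, 4, 5), rep(0, 5), n_boot = 0)
  expect_equal(pc$p_value, 0.0625)
  # symmetry: negating every difference leaves p unchanged, mirrors the medians
  pn <- paired_compare(rep(0, 5), c(1, 2, 3, 4, 5), n_boot = 0)
  expect_equal(pn$p_value, 0.0625)
  expect_equal(pn$median_difference, -pc$median_difference)
})

test_that("identical arms give p = 1 with a warning and zero differences drop", {
  expect_warning(pc <- paired_compare(1:6, 1:6, n_boot = 0), "zero")
  expect_equal(pc$p_value, 1)
  # zero differences dropped before ranking
  pc2 <- paired_compare(c(5, 5, 1:5), c(5, 5, rep(0, 5)), n_boot = 0)
  expect_equal(pc2$n_nonzero, 5)
  expect_equal(pc2$p_value, 0.0625)
})

test_that("the exact p agrees with the base wilcox.test when no ties occur", {
  set.seed(13)
  for (rep in 1:10) {
    d <- rnorm(10)
    ref <- wilcox.test(d, exact = TRUE)$p.value
    expect_equal(paired_compare(d, rep(0, 10), n_boot = 0)$p_value, ref,
                 tolerance = 1e-12)
  }
  # large n: normal approximation path
  d <- rnorm(40, mean = 0.4)
  p_norm <- paired_compare(d, rep(0, 40), n_boot = 0)$p_value
  ref <- wilcox.test(d, exact = FALSE, correct = FALSE)$p.value
  expect_equal(p_norm, ref, tolerance = 1e-9)
})

test_that("bootstrap CIs bracket the medians and are seed-reproducible", {
  set.seed(5)
  x <- rnorm(14, 60, 10); y <- rnorm(14, 50, 10)
  a <- paired_compare(x, y, n_boot = 500, seed = 42)
  b <- paired_compare(x, y, n_boot = 500, seed = 42)
  expect_identical(a$ci95_test, b$ci95_test)
  expect_lte(a$ci95_test[1], median(x))
  expect_gte(a$ci95_test[2], median(x))
  expect_lte(a$ci95_control[1], median(y))
  expect_gte(a$ci95_control[2], median(y))
})

test_that("Holm correction follows the step-down arithmetic", {
  h <- holm_bonferroni(c(0.01, 0.04), alpha = 0.05)
  expect_equal(h$p_adjusted, c(0.02, 0.04))
  expect_true(all(h$reject))
  # first compared at alpha/2: not rejected, so the second is retained too
  h2 <- holm_bonferroni(c(0.03, 0.04), alpha = 0.05)
  expect_false(any(h2$reject))
  h3 <- holm_bonferroni(0.021)
  expect_equal(h3$p_adjusted, 0.021) # single p unchanged
})

test_that("Holm adjusted p is between the raw and Bonferroni values, monotone in rank", {
  set.seed(19)
  for (rep in 1:20) {
    p <- runif(sample(2:8, 1))
    h <- holm_bonferroni(p)
    expect_true(all(h$p_adjusted >= p))
    expect_true(all(h$p_adjusted <= pmin(length(p) * p, 1) + 1e-12))
    o <- order(p)
    expect_true(all(diff(h$p_adjusted[o]) >= -1e-12))
  }
})
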
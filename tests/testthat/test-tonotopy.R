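test_that("Greenwood map reproduces its closed-form values and rejects bad input", {
  gp <- greenwood_params()
  # apex: A(1 - K); base and midpoint by direct evaluation of A(10^(a x) - K)
  expect_equal(greenwood_frequency(0, gp), 19.848, tolerance = 1e-9)
  expect_equal(greenwood_frequency(1, gp), 20677.07, tolerance = 1e-6)
  expect_equal(greenwood_frequency(0.5, gp), 1710.267, tolerance = 1e-6)
  expect_error(greenwood_frequency(-0.01, gp), "within")
  expect_error(greenwood_frequency(1.01, gp), "within")
  expect_error(greenwood_params(K = 1), "K")
  expect_error(greenwood_params(A = 0), "A")
})

test_that("Greenwood frequency is strictly increasing and inverts analytically", {
  gp <- greenwood_params()
  x <- seq(0, 1, length.out = 201)
  f <- greenwood_frequency(x, gp)
  expect_true(all(diff(f) > 0))
  expect_equal(greenwood_position(f, gp), x, tolerance = 1e-9)
  # a different parameterisation round-trips too
  gp2 <- greenwood_params(A = 150, a = 2.4, K = 0.5)
  f2 <- greenwood_frequency(x, gp2)
  expect_equal(greenwood_position(f2, gp2), x, tolerance = 1e-9)
})

test_that("insertion depth projects markers onto polyline segments", {
  straight <- lateral_wall_trace(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(insertion_depth(straight, c(0, 0, 0)), 0)
  expect_equal(insertion_depth(straight, c(4, 1, 0)), 4)
  bent <- lateral_wall_trace(rbind(c(0, 0, 0), c(5, 0, 0), c(5, 5, 0)))
  expect_equal(insertion_depth(bent, c(6, 2, 0)), 7)
  expect_error(lateral_wall_trace(rbind(c(0, 0, 0))), ">= 2 points")
  expect_error(lateral_wall_trace(rbind(c(0, 0, 0), c(0, 0, 0))), "increasing")
})

test_that("insertion depth matches a dense-sampling oracle on random traces", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    pts <- cbind(cumsum(runif(n, 0.5, 3)), cumsum(runif(n, -1, 1)),
                 cumsum(runif(n, -1, 1)))
    tr <- lateral_wall_trace(pts)
    marker <- pts[sample(n, 1), ] + runif(3, -1, 1)
    expect_lt(abs(insertion_depth(tr, marker) -
                    brute_insertion_depth(pts, marker)), 2e-3) # within 2 um
  }
})

test_that("place frequencies map depth to Greenwood frequency via x = (CDL - d)/CDL", {
  g <- electrode_geometry(c(35, 17.5, 0.001), 35)
  pf <- place_frequencies(g)
  expect_equal(pf[1], 19.848, tolerance = 1e-9)
  expect_equal(pf[2], 1710.267, tolerance = 1e-6)
  expect_equal(pf[3], 20677.07, tolerance = 1e-3)
  expect_true(all(diff(pf) > 0)) # deeper contacts -> lower frequencies
})

test_that("electrode geometry enforces its invariants and names offenders", {
  expect_error(electrode_geometry(c(36, 20), 35), "contact 1")
  expect_error(electrode_geometry(c(20, -1), 35), "contact 2")
  expect_error(electrode_geometry(c(10, 20), 35), "strictly decrease")
  # monotonicity of place frequency in depth at fixed CDL
  depths <- seq(30, 2, length.out = 12)
  pf <- place_frequencies(electrode_geometry(depths, 35))
  expect_true(all(diff(pf) > 0))
})

test_that("length correction rescales the relative place before the Greenwood map", {
  g <- mean_geometry()
  pf1 <- place_frequencies(g, length_correction = 1)
  pf09 <- place_frequencies(g, length_correction = 0.9)
  expect_true(all(pf09 < pf1)) # scaled-down x -> lower frequency everywhere
  x <- (35 - g$insertion_depths) / 35
  expect_equal(pf09, greenwood_frequency(x * 0.9), tolerance = 1e-12)
})
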
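test_that("framewise DVR-1 follows the activity-ratio closed form", {
  n <- 10
  ref <- seq(10, 12, length.out = n)
  act <- rbind(A = ref, B = 3 * ref)
  bp <- framewise_bpnd(ts_with_reference(act, ref))
  expect_equal(unname(bp$values["A", ]), rep(0, n))   # identical to reference
  expect_equal(unname(bp$values["B", ]), rep(2, n))   # DVR 3 -> BP 2
  expect_false("Cer" %in% rownames(bp$values))
  expect_equal(bp$reference, "Cer")
})

test_that("framewise DVR-1 errors name the offending frame", {
  ref <- c(10, 10, 0, 10)
  act <- rbind(A = rep(5, 4))
  expect_error(framewise_bpnd(ts_with_reference(act, ref)), "frame")
  ts <- ts_with_reference(rbind(A = rep(5, 4)), rep(10, 4))
  expect_error(framewise_bpnd(ts, reference = "XX"), "not found")
})

test_that("framewise DVR-1 is scale invariant", {
  set.seed(3)
  n <- 30
  ref <- 10 + runif(n)
  act <- rbind(A = 15 + runif(n), B = 25 + runif(n))
  bp1 <- framewise_bpnd(ts_with_reference(act, ref))
  bp2 <- framewise_bpnd(ts_with_reference(act * 7.3, ref * 7.3))
  expect_equal(bp1$values, bp2$values)
})

test_that("equilibrium BP estimate is unbiased under frame noise", {
  # planted BP = 1.5 with 5% frame noise on target and reference; the
  # time-mean estimate distribution over 500 replicates must cover 1.5
  set.seed(99)
  n <- 60
  ref0 <- rep(20, n)
  est <- replicate(500, {
    ref <- ref0 * (1 + 0.05 * rnorm(n))
    act <- rbind(A = ref0 * 2.5 * (1 + 0.05 * rnorm(n)))
    mean(framewise_bpnd(ts_with_reference(act, abs(ref)))$values)
  })
  ci <- quantile(est, c(0.025, 0.975))
  expect_gt(1.5, ci[1])
  expect_lt(1.5, ci[2])
  expect_lt(abs(mean(est) - 1.5), 0.02)
})

test_that("detrending removes exact piecewise-linear input", {
  t <- seq(0.5, 79.5, by = 1)
  # continuous piecewise-linear with knots on the 20-min grid
  f <- 2 + 0.05 * (t - 20) - 0.08 * pmax(0, t - 40) + 0.03 * pmax(0, t - 60)
  bp <- bp_series(rbind(A = f, B = 2 * f), 1:2, t)
  out <- discard_and_detrend(bp)
  expect_lt(max(abs(out$values)), 1e-9)
  expect_equal(out$retained_window_min[1], 20)
  expect_true(all(out$frame_mid_min >= 20))
  expect_equal(abs(rowMeans(out$values)), c(A = 0, B = 0), tolerance = 1e-12)
})

test_that("detrending preserves oscillations and matches an lm oracle", {
  t <- seq(0.5, 79.5, by = 1)
  sine <- sin(2 * pi * t / 10)
  y <- 1 + 0.02 * t + sine
  bp <- bp_series(rbind(A = y), 1L, t)
  out <- discard_and_detrend(bp)
  keep <- t >= 20
  expect_gt(cor(out$values[1, ], sine[keep]), 0.95)
  # independent oracle: lm with explicit hinge basis on the retained window
  tr <- t[keep]
  fit <- lm(y[keep] ~ I(tr - 20) + I(pmax(0, tr - 40)) + I(pmax(0, tr - 60)))
  expect_equal(unname(out$values[1, ]), unname(residuals(fit)),
               tolerance = 1e-8)
})

test_that("detrending is idempotent and falls back to a single line", {
  set.seed(5)
  t <- seq(0.5, 79.5, by = 1)
  bp <- bp_series(matrix(rnorm(3 * length(t)), 3), 1:3, t)
  once <- discard_and_detrend(bp)
  twice <- discard_and_detrend(once)
  expect_equal(twice$values, once$values, tolerance = 1e-8)
  # retained span below two knot intervals -> warning + single line
  short <- bp_series(matrix(rnorm(2 * 35), 2), 1:2, seq(0.5, 34.5, by = 1))
  expect_warning(out <- discard_and_detrend(short, discard_min = 5),
                 "single line")
  expect_equal(unname(rowMeans(out$values)), c(0, 0), tolerance = 1e-12)
})

test_that("independent per-segment detrend also zeroes segmentwise lines", {
  t <- seq(20.5, 79.5, by = 1)
  y <- ifelse(t < 40, 1 + 0.1 * t, ifelse(t < 60, 8 - 0.2 * t, -3 + 0.05 * t))
  bp <- bp_series(rbind(A = y), 1L, t)
  out <- discard_and_detrend(bp, continuous = FALSE)
  expect_lt(max(abs(out$values)), 1e-9)
})

test_that("static uptake sums the windowed frames and normalizes", {
  d <- c(4, 4, 3)
  img <- tiny_image(array(2, dim = c(d, 80)))
  st <- static_uptake(img, c(50, 60))
  expect_equal(unique(as.vector(st$data)), 1)   # normalized constant
  raw <- static_uptake(img, c(50, 60), normalization = "none")
  expect_equal(unique(as.vector(raw$data)), 20) # exactly 10 one-min frames
  set.seed(11)
  arr <- array(rnorm(prod(d) * 80), dim = c(d, 80))
  img2 <- tiny_image(arr)
  st2 <- static_uptake(img2, c(50, 60), normalization = "none")
  # frame-loop oracle
  oracle <- array(0, dim = d)
  for (fr in which(seq(0.5, 79.5) >= 50 & seq(0.5, 79.5) < 60)) {
    oracle <- oracle + arr[, , , fr]
  }
  expect_equal(st2$data, oracle)
  expect_error(static_uptake(img, c(90, 100)), "no frames")
})

test_that("static uptake is additive over disjoint windows", {
  set.seed(12)
  d <- c(3, 3, 2)
  img <- tiny_image(array(rnorm(prod(d) * 40), dim = c(d, 40)))
  a <- static_uptake(img, c(0, 20), normalization = "none")$data
  b <- static_uptake(img, c(20, 40), normalization = "none")$data
  both <- static_uptake(img, c(0, 40), normalization = "none")$data
  expect_equal(a + b, both)
})
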
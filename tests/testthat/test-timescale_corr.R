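test_that("resampling interpolates linearly and refuses extrapolation", {
  x <- list(times = c(0, 10), values = c(0, 10))
  expect_equal(resample_to(x, 5), 5)
  expect_equal(resample_to(x, c(0, 10)), c(0, 10))
  expect_error(resample_to(x, 11), "extrapolation")
  # step signal resampled onto a finer grid: linear between step values,
  # checked against a hand interpolation on a 6-point example
  sig <- step_signal(c(10, 20, 10, 30, 20, 10), 40.8)
  tt <- c(0, 20.4, 40.8, 61.2, 102, 163.2)
  expect_equal(resample_to(sig, tt),
               approx(sig$step_times, sig$values, xout = tt)$y)
  expect_equal(resample_to(sig, 20.4), 15)
})

test_that("windowed differentials match hand computation", {
  t30 <- seq(0, 150, by = 30)
  expect_equal(as.numeric(windowed_differential(c(1, 2, 4, 4, 6, 8), t30, 60)),
               c(2.5, 3))
  expect_equal(as.numeric(windowed_differential(rep(2, 6), t30, 60)), c(0, 0))
  # unit-slope ramp: every differential equals the window width
  tt <- seq(0, 590, by = 10)
  expect_equal(as.numeric(windowed_differential(tt, tt, 60)), rep(60, 9))
  expect_error(windowed_differential(1:3, c(0, 30, 60), 200), "two windows")
})

test_that("trailing empty windows are dropped, interior ones are errors", {
  # 30.6 s sampling with 30 s windows leaves the 51st window empty
  tt <- (0:49) * 30.6
  expect_message(d <- windowed_differential(sin(tt / 100), tt, 30),
                 "trailing empty")
  expect_length(d, 49)
  # interior empty window: irregular sampling with a gap
  tt2 <- c(0, 10, 20, 95, 100, 110, 120, 130, 140, 150, 160, 170)
  expect_error(windowed_differential(seq_along(tt2), tt2, 30),
               "contains no samples")
})

test_that("overlapping-stride mode differences means one window apart", {
  tt <- seq(0, 570, by = 30)
  x <- sin(tt / 80)
  full <- windowed_differential(x, tt, 60)
  slid <- windowed_differential(x, tt, 60, stride = 30)
  # sliding at half-window stride: every second value matches the tiling mode
  expect_equal(as.numeric(slid)[seq(1, length(slid), by = 2)],
               as.numeric(full))
})

test_that("normalization produces exact z-scores", {
  expect_equal(as.numeric(normalize_differential(c(-1, 1))), c(-1, 1))
  expect_equal(as.numeric(normalize_differential(c(2.5, 3))), c(-1, 1))
  set.seed(2)
  v <- normalize_differential(rnorm(40))
  expect_lt(abs(mean(v)), 1e-10)
  expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-10)
  expect_error(normalize_differential(rep(3, 5)), "constant")
})

test_that("correlation maps are exact on copies and negations of the input", {
  sig <- sample_step_signal(15, 5.75, 30, 2100, seed = 4)
  tt <- (0:49) * 30.6
  v <- resample_to(sig, tt)
  m <- rbind(same = v, opposite = -v + 40)
  cmap <- timescale_correlations(sig, trace_set(tt, m))
  expect_true(all(abs(cmap["same", ] - 1) < 1e-12))
  expect_true(all(abs(cmap["opposite", ] + 1) < 1e-12))
  expect_true(all(cmap >= -1 & cmap <= 1))
})

test_that("positive affine transforms leave correlations unchanged", {
  set.seed(6)
  sig <- sample_step_signal(15, 5.75, 45, 2400, seed = 6)
  tt <- (0:49) * 30.6
  base <- resample_to(sig, tt) + rnorm(length(tt))
  m <- rbind(a = base, b = 3.2 * base + 7, c = -2 * base + 100)
  cmap <- timescale_correlations(sig, trace_set(tt, m))
  expect_equal(cmap["a", ], cmap["b", ], tolerance = 1e-12)
  expect_equal(cmap["a", ], -cmap["c", ], tolerance = 1e-12)
})

test_that("a slow first-order responder correlates best at long windows", {
  # one-state linear system dy/dt = (u - y)/200 driven by a multi-timescale
  # stepwise input; its windowed-differential correlation to the input should
  # rise monotonically from the 30 s to the 150 s window
  comps <- lapply(c(30, 60, 120), function(dt)
    sample_step_signal(15, 5.75, dt, 9000, seed = dt + 1))
  sig <- superimpose_signals(comps, 15, 5.75)
  dt <- 1
  tt <- seq(0, 8900, by = dt)
  u <- eval_signal(sig, tt)
  y <- numeric(length(tt))
  for (i in 2:length(tt)) y[i] <- y[i - 1] + dt * (u[i - 1] - y[i - 1]) / 200
  keep <- tt >= 1500 & tt <= 8800
  grid <- tt[keep][seq(1, sum(keep), by = 30)]
  m <- rbind(slow = y[match(grid, tt)])
  cmap <- timescale_correlations(sig, trace_set(grid, m))
  # a responder much slower than every window anti-correlates with the input
  # differential at short windows and climbs monotonically toward the long
  # ones, where the input's slow content dominates
  r <- as.numeric(cmap["slow", ])
  expect_true(all(diff(r) > 0))
  expect_gt(r[5], r[1] + 0.3)
})
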
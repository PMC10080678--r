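test_that("step signals are piecewise constant, left-closed", {
  sig <- step_signal(c(1, 2, 3), 45)
  expect_equal(sig$step_times, c(0, 45, 90))
  expect_equal(eval_signal(sig, c(0, 44.999, 45, 89, 90, 135)),
               c(1, 1, 2, 2, 3, 3))
  expect_error(eval_signal(sig, 136), "span")
  expect_error(step_signal(c(1, -1), 45), "non-negative")
  expect_error(step_signal(1, 0), "positive")
})

test_that("an unperturbed program is exactly constant at the mean", {
  sig <- sample_step_signal(15, 0, 45, 180, seed = 1)
  expect_length(sig$values, 4)
  expect_true(all(sig$values == 15))
  zero <- sample_step_signal(0, 0, 45, 180, seed = 1)
  expect_true(all(zero$values == 0))
})

test_that("sampled signals recover the generating mean and SD", {
  n <- 1e4
  sig <- sample_step_signal(15, 5.75, 45, 45 * n, seed = 42)
  expect_length(sig$values, n)
  raw <- attr(sig, "raw_values")
  expect_lt(abs(mean(raw) - 15) / 15, 0.01)
  expect_lt(abs(sd(raw) - 5.75) / 5.75, 0.03)
  # truncation at zero is rare at these parameters (~0.45% of draws) and
  # every reported clip corresponds to a negative raw draw
  expect_equal(attr(sig, "n_clipped"), sum(raw < 0))
  expect_lt(attr(sig, "n_clipped") / n, 0.01)
  expect_true(all(sig$values >= 0))
})

test_that("sampling is deterministic given the seed", {
  a <- sample_step_signal(15, 5.75, 45, 4500, seed = 7)
  b <- sample_step_signal(15, 5.75, 45, 4500, seed = 7)
  expect_identical(a, b)
  c <- sample_step_signal(15, 5.75, 45, 4500, seed = 8)
  expect_false(identical(a$values, c$values))
})

test_that("invalid sampler parameters are rejected", {
  expect_error(sample_step_signal(15, -1, 45, 450), "non-negative")
  expect_error(sample_step_signal(15, 1, 0, 450), "positive")
  expect_error(sample_step_signal(15, 1, 45, 10), "one step")
})

test_that("superimposing constant signals returns the target constant", {
  comps <- replicate(3, step_signal(rep(15, 10), 60), simplify = FALSE)
  out <- superimpose_signals(comps, target_mean = 15, target_sigma = 0)
  expect_true(all(out$values == 15))
  expect_error(superimpose_signals(comps, 15, 5), "zero variance")
})

test_that("superimposition lands on the finest grid with rescaled moments", {
  comps <- lapply(c(30, 60, 120), function(dt)
    sample_step_signal(15, 5.75, dt, 3600, seed = dt))
  out <- superimpose_signals(comps, target_mean = 15, target_sigma = 5.75)
  expect_equal(out$step_interval, 30)
  expect_equal(out$step_times, seq(0, 3570, by = 30))
  # affine rescaling pins the population moments exactly (before clipping;
  # clipped steps are rare) and the sample SD within 3%
  expect_lt(abs(mean(out$values) - 15) / 15, 0.01)
  expect_lt(abs(sd(out$values) - 5.75) / 5.75, 0.03)
  # step boundaries include the union of component boundaries
  expect_true(all(c(30, 60, 120) %in% out$step_times))
})

test_that("flow programs satisfy the mass-balance arithmetic", {
  sig <- step_signal(rep(15, 4), 45)
  fp <- program_flows(sig, inlet_spec(), reactor_spec())
  s <- fp$schedule
  F_tot <- 411 / 120
  expect_equal(s$F_formaldehyde[1] + s$F_DHA[1] + s$F_NaOH[1] +
                 s$F_CaCl2[1] + s$F_water[1], F_tot)
  expect_equal(s$F_CaCl2[1] / F_tot, 15 / 120)
  expect_equal(s$F_NaOH[1] / F_tot, 30 / 240)
  expect_equal(s$F_water[1] / F_tot, 1 - 50 / 198 - 50 / 198 - 0.125 - 0.125)
})

test_that("zero calcium input routes its share to the water channel", {
  sig <- step_signal(rep(0, 3), 45)
  fp <- program_flows(sig, inlet_spec(), reactor_spec())
  s <- fp$schedule
  expect_true(all(s$F_CaCl2 == 0) && all(s$F_NaOH == 0))
  expect_equal(s$F_water + s$F_formaldehyde + s$F_DHA,
               rep(411 / 120, 3))
})

test_that("program constraints hold at every step of a long random program", {
  sig <- sample_step_signal(15, 5.75, 45, 45 * 1e4, seed = 11)
  fp <- program_flows(sig, inlet_spec(), reactor_spec())
  s <- fp$schedule
  total <- s$F_formaldehyde + s$F_DHA + s$F_NaOH + s$F_CaCl2 + s$F_water
  expect_true(all(abs(total - 411 / 120) / (411 / 120) < 1e-9))
  expect_true(all(s$F_water >= 0))
  pos <- s$F_CaCl2 > 0
  # hydroxide is fed at exactly twice the calcium concentration
  expect_equal(s$naoh_in_mM[pos] / s$cacl2_in_mM[pos],
               rep(2, sum(pos)))
  # implied inlet concentrations reconstruct from flows and stocks
  expect_equal(implied_inlet(fp, "cacl2"), s$cacl2_in_mM)
  expect_equal(implied_inlet(fp, "naoh"), s$naoh_in_mM)
})

test_that("infeasible steps are clipped jointly, infeasible means rejected", {
  sig <- step_signal(c(15, 40), 45) # 40 mM exceeds the feasible maximum
  fp <- program_flows(sig, inlet_spec(), reactor_spec())
  expect_equal(fp$n_clipped_steps, 1L)
  s <- fp$schedule
  expect_true(all(s$F_water >= -1e-12))
  expect_equal(s$naoh_in_mM[2] / s$cacl2_in_mM[2], 2) # ratio preserved
  mean_high <- step_signal(rep(35, 4), 45, mean_target = 35)
  expect_error(program_flows(mean_high, inlet_spec(), reactor_spec()),
               "infeasible")
})

test_that("flow programs round-trip through CSV", {
  sig <- sample_step_signal(15, 2.89, 45, 900, seed = 3)
  fp <- program_flows(sig, inlet_spec(), reactor_spec())
  path <- tempfile(fileext = ".csv")
  write_flow_program(fp, path)
  fp2 <- read_flow_program(path)
  expect_equal(fp2$schedule$F_CaCl2, fp$schedule$F_CaCl2, tolerance = 1e-12)
  expect_equal(fp2$step_interval, 45)
})
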
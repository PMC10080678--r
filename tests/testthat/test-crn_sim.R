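test_that("the default network has five modules and conserves carbon", {
  model <- build_formose_model()
  labels <- module_labels(model)
  expect_length(labels, 28)
  expect_setequal(unique(labels), c("core", "II", "III", "IV", "V"))
  expect_true(all(carbon_audit(model)$balanced))
  # at least one gating reaction feeds each branch from the core
  roots <- c("II_C5", "III_C7", "IV_C5", "V_C5")
  feeds <- vapply(roots, function(r) {
    any(vapply(model$reactions, function(rx) r %in% names(rx$products),
               logical(1)))
  }, logical(1))
  expect_true(all(feeds))
  expect_error(build_formose_model(branch_sensitivities =
                                     c(II = -1, III = 0, IV = 0, V = 0)),
               ">= 0")
})

test_that("the explicit-enolate variant builds and conserves carbon", {
  model <- build_formose_model(explicit_enolates = TRUE)
  expect_true(all(c("E32", "E33", "E34", "E35") %in% model$species$id))
  expect_true(all(carbon_audit(model)$balanced))
  expect_false(any(model$species$measured[model$species$id %in%
                                            paste0("E3", 2:5)]))
})

test_that("disconnected branches leave only core species populated", {
  model <- build_formose_model(rate_constants = list(
    k_gate_II = 0, k_gate_III = 0, k_gate_IV = 0, k_gate_V1 = 0,
    k_gate_V2 = 0))
  fp <- constant_flow_program()
  ss <- steady_state(model, fp)
  labels <- module_labels(model)
  branch <- names(labels)[labels != "core"]
  expect_true(all(ss$concentrations[branch] == 0))
  expect_true(all(ss$concentrations[c("ERY", "THR", "ERO", "THO")] > 0))
})

test_that("effective rates follow the catalyst power law", {
  expect_equal(effective_rate(1, 15, 3, 15), 1)
  expect_equal(effective_rate(2, 30, 1, 15), 4)
  expect_equal(effective_rate(1, 7.5, 2, 15), 0.25)
  expect_equal(effective_rate(5, 0, 2, 15), 0)
  expect_equal(effective_rate(5, 0, 0, 15), 5)
  expect_error(effective_rate(1, -1, 1, 15), ">= 0")
})

test_that("washout follows the closed-form CSTR response", {
  empty <- build_formose_model(rate_constants = as.list(setNames(
    rep(0, length(default_rate_constants())),
    names(default_rate_constants()))))
  expect_length(empty$reactions, 0)
  fp <- constant_flow_program(ca = 15, duration = 800)
  ts <- simulate_cstr(empty, fp, t_span = c(0, 400),
                      output_times = c(0, 120, 240, 360),
                      rtol = 1e-10, atol = 1e-12, measured_only = FALSE)
  tau <- 120
  for (sp in c("C1", "DHA", "ca")) {
    cin <- c(C1 = 50, DHA = 50, ca = 15)[[sp]]
    expected <- cin * (1 - exp(-c(120, 240, 360) / tau))
    expect_lt(max(abs(ts$concentrations[sp, 2:4] - expected) / expected), 1e-6)
  }
  # a species present at t = 0 with no inflow washes out exponentially
  ts2 <- simulate_cstr(empty, fp, t_span = c(0, 360),
                       output_times = c(0, 120, 240, 360),
                       y0 = c(GLA = 5), rtol = 1e-10, atol = 1e-12,
                       measured_only = FALSE)
  expect_lt(max(abs(ts2$concentrations["GLA", ] -
                      5 * exp(-c(0, 120, 240, 360) / tau)) / 5), 1e-6)
})

test_that("a two-species toy model matches a fine-step Euler oracle", {
  model <- toy_two_species_model(k = 0.01)
  fp <- constant_flow_program(ca = 15, duration = 1200,
                              formaldehyde_in = 50, dha_in = 50)
  # species A is not a fed species in this toy model; inject via y0
  ts <- simulate_cstr(model, fp, t_span = c(0, 600),
                      output_times = seq(0, 600, by = 60),
                      y0 = c(A = 10), rtol = 1e-10, atol = 1e-12)
  oracle <- euler_cstr_two_species(c_in_A = 0, k = 0.01, tau = 120,
                                   t_end = 600, dt = 1e-3, A0 = 10)
  expect_lt(max(abs(ts$concentrations["A", ] - oracle[, "A"]) / 10), 1e-4)
  expect_lt(max(abs(ts$concentrations["B", ] - oracle[, "B"]) / 10), 1e-4)
})

test_that("constant input converges to an algebraic steady state", {
  model <- build_formose_model()
  fp <- constant_flow_program()
  ss <- steady_state(model, fp)
  expect_lt(ss$residual, 1e-8)
  expect_true(all(ss$concentrations >= 0))
})

test_that("outlet sampling hits the stated grid and is unbiased", {
  model <- build_formose_model()
  sig <- step_signal(rep(15, 40), 100)
  fp <- program_flows(sig, inlet_spec(), reactor_spec())
  st <- 1800 + (0:49) * 40.8
  ts <- simulate_cstr(model, fp, t_span = c(0, 3900),
                      output_times = sort(unique(c(seq(0, 3900, 10), st))))
  sm <- sample_outlet(ts, 1800, 40.8, 50, noise_cv = 0)
  expect_length(sm$times, 50)
  expect_equal(sm$times[50], 1800 + 49 * 40.8)
  expect_false("ca" %in% rownames(sm$concentrations))
  # noiseless sampling returns the interpolated simulation values
  expect_equal(sm$concentrations[, 1],
               ts$concentrations[rownames(sm$concentrations), which(ts$times == 1800)])
  expect_error(sample_outlet(ts, 3800, 40.8, 50), "beyond")
})

test_that("multiplicative noise reproduces the requested CV", {
  tt <- seq(0, 990, by = 10)
  const <- trace_set(tt, matrix(5, 1, length(tt), dimnames = list("x", NULL)))
  vals <- unlist(lapply(1:100, function(i) {
    sample_outlet(const, 0, 10, 100, noise_cv = 0.05,
                  seed = i)$concentrations
  }))
  cv <- sd(vals) / mean(vals)
  expect_lt(abs(cv - 0.05) / 0.05, 0.05)
  expect_gt(min(vals), 0)
})

test_that("identical seeds give identical sampled trace sets", {
  model <- build_formose_model()
  cfg <- exp_preset("EXP003")
  m1 <- suppressMessages(run_pipeline(cfg, stages = c("generate", "simulate"),
                                      out_dir = tempfile(), model = model))
  m2 <- suppressMessages(run_pipeline(cfg, stages = c("generate", "simulate"),
                                      out_dir = tempfile(), model = model))
  expect_identical(m1$results$samples$concentrations,
                   m2$results$samples$concentrations)
})

test_that("output fluctuations attenuate with input frequency", {
  # low-pass property: for gated branch species, the amplitude transferred
  # from a 30 s input program is smaller than from a 120 s program
  model <- build_formose_model()
  ratio <- sapply(c(30, 120), function(rate) {
    cfg <- exp_preset("EXP003")
    cfg$step_rate_s <- rate
    cfg$seed <- 42
    cfg$noise_cv <- 0
    man <- suppressMessages(run_pipeline(cfg, stages = c("generate", "simulate"),
                                         out_dir = tempfile(), model = model))
    m <- man$results$samples$concentrations
    sig <- man$results$signal
    out_cv <- apply(m[c("IV_C5", "II_C5", "ERY"), ], 1,
                    function(x) sd(x) / mean(x))
    out_cv / (sd(sig$values) / mean(sig$values))
  })
  expect_true(all(ratio[, 1] < ratio[, 2]))
})

test_that("branch variance increases with its gate's catalyst sensitivity", {
  vars <- sapply(c(1, 3), function(s2) {
    bs <- default_branch_sensitivities()
    bs["II"] <- s2
    model <- build_formose_model(branch_sensitivities = bs)
    cfg <- exp_preset("EXP003")
    cfg$seed <- 42
    cfg$noise_cv <- 0
    man <- suppressMessages(run_pipeline(cfg, stages = c("generate", "simulate"),
                                         out_dir = tempfile(), model = model))
    var(log(man$results$samples$concentrations["II_C5", ]))
  })
  expect_lt(vars[1], vars[2])
})
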
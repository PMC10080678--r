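# Shared helpers: independent oracles and small synthetic fixtures.

# random symmetric distance matrix with zero diagonal and distinct entries
random_dist_matrix <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 1.95)
  d + t(d)
}

# independent UPGMA oracle: stats::hclust with average linkage. Heights are
# d(A,B), i.e. twice the package's d/2 convention.
hclust_oracle <- function(d) {
  stats::hclust(stats::as.dist(d), method = "average")
}

# fixed-step explicit Euler integrator for a CSTR with mass-action kinetics;
# brute-force oracle for the ODE solver
euler_cstr_two_species <- function(c_in_A, k, tau, t_end, dt, A0 = 0) {
  n <- round(t_end / dt)
  A <- A0; B <- 0
  keep_t <- seq(0, t_end, by = 60)
  out <- matrix(NA_real_, length(keep_t), 3)
  j <- 1L
  t <- 0
  for (i in 0:n) {
    if (j <= length(keep_t) && abs(t - keep_t[j]) < dt / 2) {
      out[j, ] <- c(t, A, B)
      j <- j + 1L
    }
    r <- k * A
    A <- A + dt * ((c_in_A - A) / tau - r)
    B <- B + dt * (-B / tau + r)
    t <- t + dt
  }
  colnames(out) <- c("t", "A", "B")
  out
}

# hand-built two-species model A -> B (first order) in the package's
# network_model layout
toy_two_species_model <- function(k = 0.01) {
  structure(
    list(
      species = data.frame(id = c("A", "B"), carbon = c(1, 1),
                           module = c("core", "II"),
                           measured = c(TRUE, TRUE)),
      reactions = list(list(reactants = c(A = 1), products = c(B = 1),
                            k = k, sensitivity = 0)),
      catalyst_reference = 15
    ),
    class = "network_model"
  )
}

# flow program with constant inlet concentrations, for toy simulations
constant_flow_program <- function(ca = 15, duration = 1200,
                                  formaldehyde_in = 50, dha_in = 50) {
  sig <- step_signal(rep(ca, 2), duration / 2)
  program_flows(sig,
                inlet_spec(formaldehyde_in = formaldehyde_in, dha_in = dha_in),
                reactor_spec())
}

# planted-module trace set: five groups of noisy copies of five distinct
# deterministic waveforms (no simulator involved)
planted_trace_set <- function(n_per = 4, n_t = 50, noise_sd = 0.05,
                              seed = 1) {
  set.seed(seed)
  t <- seq_len(n_t)
  shapes <- list(
    sin(t / 4), cos(t / 4), sin(t / 9), cumsum(rnorm(n_t)) / 5,
    rep(c(1, -1), length.out = n_t)
  )
  m <- do.call(rbind, lapply(seq_along(shapes), function(g) {
    t(replicate(n_per, shapes[[g]] + 10 + rnorm(n_t, sd = noise_sd)))
  }))
  rownames(m) <- paste0("g", rep(seq_along(shapes), each = n_per), "_",
                        rep(seq_len(n_per), length(shapes)))
  list(traces = trace_set((t - 1) * 30, m),
       labels = rep(seq_along(shapes), each = n_per))
}
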
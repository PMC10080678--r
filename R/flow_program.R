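# Dynamic inlet programs for a CSTR: stepwise-Gaussian concentration signals
# and their conversion to balanced per-channel volumetric flow schedules.

#' Construct a piecewise-constant step signal
#'
#' A step signal is a concentration-versus-time program for an inlet species:
#' a sequence of values held constant over consecutive intervals of equal
#' width. Steps are left-closed/right-open in seconds from program start.
#'
#' @param values Numeric vector of step values (mM), all non-negative.
#' @param step_interval Width of each step in seconds (> 0).
#' @param t0 Time of the first step boundary in seconds (default 0).
#' @param mean_target,sigma_target The generating distribution parameters, if
#'   any (stored as metadata; `NA` for signals not drawn from a distribution).
#' @return An object of class `step_signal` with fields `step_times`,
#'   `values`, `step_interval`, `mean_target`, `sigma_target`.
#' @seealso [sample_step_signal()], [superimpose_signals()], [eval_signal()]
#' @export
step_signal <- function(values, step_interval, t0 = 0,
                        mean_target = NA_real_, sigma_target = NA_real_) {
  if (!is.numeric(values) || length(values) < 1L)
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  if (!is.numeric(step_interval) || length(step_interval) != 1L ||
      step_interval <= 0)
    stop("`step_interval` must be a single positive number", call. = FALSE)
  if (any(values < 0))
    stop("step values must be non-negative concentrations", call. = FALSE)
  structure(
    list(
      step_times = t0 + (seq_along(values) - 1) * step_interval,
      values = as.numeric(values),
      step_interval = step_interval,
      mean_target = mean_target,
      sigma_target = sigma_target
    ),
    class = "step_signal"
  )
}

#' @export
print.step_signal <- function(x, ...) {
  cat(sprintf(
    "<step_signal> %d steps of %g s (span %g-%g s)\n",
    length(x$values), x$step_interval, x$step_times[1], signal_end(x)
  ))
  cat(sprintf("  mean %.4g mM, pop. SD %.4g mM", mean(x$values), pop_sd(x$values)))
  if (!is.na(x$mean_target))
    cat(sprintf("  (targets: mean %g, sigma %g)", x$mean_target, x$sigma_target))
  cat("\n")
  invisible(x)
}

#' End time (seconds) of a step signal's span
#' @param signal A `step_signal`.
#' @return The time at which the final step ends.
#' @export
signal_end <- function(signal) {
  signal$step_times[length(signal$step_times)] + signal$step_interval
}

#' Evaluate a step signal at arbitrary times
#'
#' Piecewise-constant evaluation: `eval_signal(s, t)` returns the value of the
#' step containing `t`, with steps left-closed/right-open. The right edge of
#' the final step is mapped to the final value so that integrators may query
#' the closed span.
#'
#' @param signal A `step_signal`.
#' @param t Numeric vector of times in seconds, within the signal span.
#' @return Numeric vector of signal values at `t`.
#' @export
eval_signal <- function(signal, t) {
  t0 <- signal$step_times[1]
  tend <- signal_end(signal)
  if (any(t < t0 | t > tend))
    stop(sprintf("evaluation times outside signal span [%g, %g]", t0, tend),
         call. = FALSE)
  idx <- findInterval(t, signal$step_times)
  idx[idx > length(signal$values)] <- length(signal$values)
  signal$values[idx]
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    genv <- globalenv()
    if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      old <- get(".Random.seed", envir = genv, inherits = FALSE)
      on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

# Population (divisor n) standard deviation.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Sample a stepwise-Gaussian input signal
#'
#' Draws one independent Gaussian value per step. Negative draws are clipped
#' to zero (concentrations are physical); the raw draws and the clip count are
#' retained as attributes `raw_values` and `n_clipped` so that the statistics
#' of the generating distribution can be audited before truncation.
#'
#' @param mean Mean of the generating Gaussian (mM).
#' @param sigma Standard deviation of the generating Gaussian (mM, >= 0).
#' @param step_interval Step width in seconds (> 0).
#' @param duration Total program duration in seconds (>= `step_interval`);
#'   the number of steps is `floor(duration / step_interval)`.
#' @param seed Integer seed; identical seeds give bit-identical signals.
#' @return A `step_signal`; attribute `raw_values` holds the untruncated
#'   draws and `n_clipped` the number of draws clipped at zero.
#' @examples
#' sig <- sample_step_signal(15, 5.75, 45, 4500, seed = 1)
#' mean(sig$values)
#' @export
sample_step_signal <- function(mean, sigma, step_interval, duration,
                               seed = NULL) {
  if (!is.numeric(sigma) || sigma < 0)
    stop("`sigma` must be non-negative", call. = FALSE)
  if (!is.numeric(step_interval) || step_interval <= 0)
    stop("`step_interval` must be positive", call. = FALSE)
  if (duration < step_interval)
    stop("`duration` must cover at least one step", call. = FALSE)
  n <- floor(duration / step_interval)
  raw <- with_seed(seed, stats::rnorm(n, mean = mean, sd = sigma))
  clipped <- pmax(raw, 0)
  sig <- step_signal(clipped, step_interval,
                     mean_target = mean, sigma_target = sigma)
  attr(sig, "raw_values") <- raw
  attr(sig, "n_clipped") <- sum(raw < 0)
  sig
}

#' Superimpose step signals varying on different timescales
#'
#' Combines two or more step signals (typically drawn on different step
#' intervals) into a single program: the weighted sum is evaluated on the
#' finest common time grid and affinely rescaled so that its mean equals
#' `target_mean` and its population SD equals `target_sigma` over the program
#' duration. This is how a multi-timescale input (e.g. 30/60/120 s
#' components) is constructed.
#'
#' @param components List of at least two `step_signal` objects sharing a
#'   common start time; the output duration is the shortest component span.
#' @param target_mean Desired mean of the combined signal (mM).
#' @param target_sigma Desired population SD of the combined signal (mM).
#' @param weights Component weights; default equal (`1/n` each).
#' @return A `step_signal` on the finest component grid, with attribute
#'   `n_clipped` counting values clipped at zero after rescaling.
#' @export
superimpose_signals <- function(components, target_mean, target_sigma,
                                weights = NULL) {
  if (!is.list(components) || length(components) < 2L)
    stop("need at least two component signals", call. = FALSE)
  if (!all(vapply(components, inherits, logical(1), "step_signal")))
    stop("all components must be `step_signal` objects", call. = FALSE)
  n <- length(components)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n)
    stop("`weights` must match the number of components", call. = FALSE)
  t0 <- components[[1]]$step_times[1]
  if (any(vapply(components, function(s) s$step_times[1], numeric(1)) != t0))
    stop("components must share a common start time", call. = FALSE)
  dt <- min(vapply(components, `[[`, numeric(1), "step_interval"))
  tend <- min(vapply(components, signal_end, numeric(1)))
  grid <- seq(t0, tend - dt, by = dt)
  combo <- rowSums(mapply(
    function(s, w) w * eval_signal(s, grid),
    components, weights
  ))
  s0 <- pop_sd(combo)
  if (target_sigma > 0 && s0 == 0)
    stop("combined signal has zero variance; cannot rescale to target sigma",
         call. = FALSE)
  scaled <- if (target_sigma == 0) {
    rep(target_mean, length(combo))
  } else {
    (combo - mean(combo)) / s0 * target_sigma + target_mean
  }
  clipped <- pmax(scaled, 0)
  sig <- step_signal(clipped, dt, t0 = t0,
                     mean_target = target_mean, sigma_target = target_sigma)
  attr(sig, "n_clipped") <- sum(scaled < 0)
  sig
}

#' Inlet specification: stock concentrations and target inlet concentrations
#'
#' @param stocks Named numeric vector of syringe stock concentrations in mM:
#'   `formaldehyde`, `dha`, `naoh`, `cacl2` (water is implicit). Defaults are
#'   the study stocks (198, 198, 240, 120 mM).
#' @param formaldehyde_in,dha_in Fixed target inlet concentrations (mM).
#' @param ca_in_mean Mean target inlet CaCl2 concentration (mM).
#' @param ca_to_oh_ratio Fixed Ca:OH ratio, stored as Ca/OH (default 0.5,
#'   i.e. hydroxide is fed at twice the calcium concentration).
#' @return An object of class `inlet_spec`.
#' @export
inlet_spec <- function(stocks = c(formaldehyde = 198, dha = 198,
                                  naoh = 240, cacl2 = 120),
                       formaldehyde_in = 50, dha_in = 50, ca_in_mean = 15,
                       ca_to_oh_ratio = 0.5) {
  need <- c("formaldehyde", "dha", "naoh", "cacl2")
  if (!all(need %in% names(stocks)))
    stop("`stocks` must name formaldehyde, dha, naoh and cacl2", call. = FALSE)
  if (formaldehyde_in > stocks[["formaldehyde"]] || dha_in > stocks[["dha"]])
    stop("target inlet concentration exceeds its stock concentration",
         call. = FALSE)
  if (ca_in_mean > stocks[["cacl2"]] ||
      ca_in_mean / ca_to_oh_ratio > stocks[["naoh"]])
    stop("mean Ca/OH inlet target exceeds a stock concentration", call. = FALSE)
  structure(
    list(stocks = stocks[need], formaldehyde_in = formaldehyde_in,
         dha_in = dha_in, ca_in_mean = ca_in_mean,
         ca_to_oh_ratio = ca_to_oh_ratio),
    class = "inlet_spec"
  )
}

#' Reactor specification
#'
#' @param volume_uL Reactor volume in microlitres (> 0; default 411).
#' @param residence_time_s Residence time tau in seconds (> 0; default 120).
#'   Total volumetric flow is `volume_uL / residence_time_s`.
#' @param temperature_C Temperature in degrees Celsius (metadata only).
#' @return An object of class `reactor_spec`.
#' @export
reactor_spec <- function(volume_uL = 411, residence_time_s = 120,
                         temperature_C = 21) {
  if (volume_uL <= 0 || residence_time_s <= 0)
    stop("reactor volume and residence time must be positive", call. = FALSE)
  structure(
    list(volume_uL = volume_uL, residence_time_s = residence_time_s,
         temperature_C = temperature_C,
         total_flow_uL_s = volume_uL / residence_time_s),
    class = "reactor_spec"
  )
}

#' Convert a Ca(OH)2 inlet program into balanced volumetric flow schedules
#'
#' For each step of the calcium signal the five channel flows are set so that
#' (i) the total flow is constant at `V / tau`, (ii) formaldehyde and DHA hit
#' their fixed inlet targets, (iii) the implied NaOH inlet concentration is
#' exactly twice the implied CaCl2 inlet concentration, and (iv) the water
#' channel absorbs the remainder. Steps whose calcium draw would drive the
#' water flow negative are clipped jointly (Ca and NaOH reduced together,
#' preserving the 1:2 ratio) to the maximum feasible calcium concentration,
#' and the number of clipped steps is reported.
#'
#' @param ca_signal A `step_signal` of target inlet CaCl2 concentrations (mM).
#' @param inlet An [inlet_spec()].
#' @param reactor A [reactor_spec()].
#' @return An object of class `flow_program`: a list with `schedule` (a
#'   data frame with per-step channel flows in uL/s and implied inlet
#'   concentrations in mM), `reactor`, `inlet`, `step_interval`, and
#'   `n_clipped_steps`.
#' @examples
#' sig <- sample_step_signal(15, 5.75, 45, 900, seed = 7)
#' fp <- program_flows(sig, inlet_spec(), reactor_spec())
#' head(fp$schedule)
#' @export
program_flows <- function(ca_signal, inlet = inlet_spec(),
                          reactor = reactor_spec()) {
  stopifnot(inherits(ca_signal, "step_signal"), inherits(inlet, "inlet_spec"),
            inherits(reactor, "reactor_spec"))
  F_tot <- reactor$total_flow_uL_s
  f_formaldehyde <- inlet$formaldehyde_in / inlet$stocks[["formaldehyde"]]
  f_dha <- inlet$dha_in / inlet$stocks[["dha"]]
  oh_per_ca <- 1 / inlet$ca_to_oh_ratio
  # per-mM-of-Ca fraction of total flow consumed by the CaCl2 + NaOH channels
  frac_per_ca <- 1 / inlet$stocks[["cacl2"]] + oh_per_ca / inlet$stocks[["naoh"]]
  budget <- 1 - f_formaldehyde - f_dha
  if (budget < 0)
    stop("formaldehyde/DHA inlet targets alone exceed the total flow",
         call. = FALSE)
  ca_max <- budget / frac_per_ca
  ca_mean <- if (!is.na(ca_signal$mean_target)) ca_signal$mean_target
             else mean(ca_signal$values)
  if (ca_mean > ca_max)
    stop(sprintf(
      "infeasible configuration: mean Ca inlet %.3g mM exceeds the maximum feasible %.3g mM",
      ca_mean, ca_max), call. = FALSE)

  ca <- pmin(ca_signal$values, ca_max)
  n_clipped <- sum(ca_signal$values > ca_max)
  oh <- oh_per_ca * ca
  schedule <- data.frame(
    time_s = ca_signal$step_times,
    F_formaldehyde = F_tot * f_formaldehyde,
    F_DHA = F_tot * f_dha,
    F_NaOH = F_tot * oh / inlet$stocks[["naoh"]],
    F_CaCl2 = F_tot * ca / inlet$stocks[["cacl2"]],
    F_water = NA_real_,
    formaldehyde_in_mM = inlet$formaldehyde_in,
    dha_in_mM = inlet$dha_in,
    cacl2_in_mM = ca,
    naoh_in_mM = oh
  )
  schedule$F_water <- pmax(
    F_tot - schedule$F_formaldehyde - schedule$F_DHA - schedule$F_NaOH -
      schedule$F_CaCl2, 0) # clamp rounding residue on clipped steps
  structure(
    list(schedule = schedule, reactor = reactor, inlet = inlet,
         step_interval = ca_signal$step_interval,
         n_clipped_steps = n_clipped),
    class = "flow_program"
  )
}

#' @export
print.flow_program <- function(x, ...) {
  cat(sprintf(
    "<flow_program> %d steps of %g s, total flow %.4g uL/s (tau = %g s)\n",
    nrow(x$schedule), x$step_interval, x$reactor$total_flow_uL_s,
    x$reactor$residence_time_s
  ))
  cat(sprintf("  mean Ca inlet %.4g mM; %d step(s) clipped for feasibility\n",
              mean(x$schedule$cacl2_in_mM), x$n_clipped_steps))
  invisible(x)
}

#' Implied inlet concentration of a species over a flow program
#'
#' Returns the per-step inlet concentration of a species as seen by the
#' reactor, i.e. channel flow times stock concentration divided by total flow.
#'
#' @param program A `flow_program`.
#' @param species One of `"formaldehyde"`, `"dha"`, `"naoh"`, `"cacl2"`.
#' @return Numeric vector (mM), one value per step.
#' @export
implied_inlet <- function(program,
                          species = c("formaldehyde", "dha", "naoh", "cacl2")) {
  species <- match.arg(species)
  col <- c(formaldehyde = "F_formaldehyde", dha = "F_DHA",
           naoh = "F_NaOH", cacl2 = "F_CaCl2")[[species]]
  program$schedule[[col]] * program$inlet$stocks[[species]] /
    program$reactor$total_flow_uL_s
}

#' Write a flow program to CSV
#'
#' @param program A `flow_program`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_flow_program <- function(program, path) {
  utils::write.csv(program$schedule, path, row.names = FALSE)
  invisible(path)
}

#' Read a flow program schedule from CSV
#'
#' Reads a schedule written by [write_flow_program()]. The reactor and inlet
#' specifications must be supplied (they are not stored in the CSV).
#'
#' @param path CSV path.
#' @param inlet An [inlet_spec()].
#' @param reactor A [reactor_spec()].
#' @return A `flow_program`.
#' @export
read_flow_program <- function(path, inlet = inlet_spec(),
                              reactor = reactor_spec()) {
  schedule <- utils::read.csv(path)
  need <- c("time_s", "F_formaldehyde", "F_DHA", "F_NaOH", "F_CaCl2",
            "F_water", "cacl2_in_mM", "naoh_in_mM")
  missing <- setdiff(need, names(schedule))
  if (length(missing))
    stop("flow program CSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  dt <- unique(round(diff(schedule$time_s), 9))
  if (length(dt) != 1L)
    stop("flow program time steps are not uniform", call. = FALSE)
  structure(
    list(schedule = schedule, reactor = reactor, inlet = inlet,
         step_interval = dt, n_clipped_steps = NA_integer_),
    class = "flow_program"
  )
}
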
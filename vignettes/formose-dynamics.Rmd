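---
title: "Dynamic environmental forcing of a formose-like network: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic environmental forcing of a formose-like network: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A continuous stirred-tank reactor (CSTR) running a formose-type sugar
network is driven by a fluctuating supply of its catalyst, Ca(OH)₂: the
inlet CaCl₂ concentration is redrawn from a Gaussian at fixed intervals
(the *step rate*), NaOH tracks it at a fixed 1:2 Ca²⁺:OH⁻ ratio, and a
water channel absorbs the flow variation so the residence time never
changes. The outlet is sampled at fixed intervals and ~28 sugar
concentrations are quantified per sample. The scientific questions are
(i) how the *magnitude* and *rate* of catalyst fluctuations shift the
product distribution away from its steady-state composition, and (ii)
how groups of compounds, gated by differently catalyst-sensitive
reactions branching off the autocatalytic Breslow cycle, respond
collectively — transferring some input timescales and filtering out
others.

`formosedyn` implements this study design as a reusable, fully synthetic
pipeline: input-program generation, a schematic gated reaction-network
simulator standing in for the chromatographic data, the quantification
rules, and the two bespoke analyses (correlation-distance hierarchical
clustering and multi-timescale windowed-differential correlation), plus
distribution comparison with significance stars.

```{r}
library(formosedyn)
cfg <- exp_preset("EXP013")            # the multi-timescale condition
man <- run_pipeline(cfg, out_dir = "exp013")
man$results$clusters                   # k = 5 flat clusters
man$results$corrmap                    # compounds x window widths
```

# Input programs

`sample_step_signal(mean, sigma, step_interval, duration, seed)` draws
one independent Gaussian value per step (left-closed/right-open steps,
seconds from program start). Negative draws are clipped to zero —
concentrations are physical — and both the raw draws and the clip count
are retained (`raw_values`, `n_clipped` attributes), because the
generating statistics should be auditable before truncation. At the
study's largest setting (mean 15 mM, σ 5.75 mM) about 0.45% of draws
clip.

Multi-timescale programs are built by `superimpose_signals()`: equal
weights on the components (30, 60 and 120 s by default; the
configuration accepts any set), evaluated on the finest component grid,
then affinely rescaled so the combined program hits the target mean and
population SD exactly. The weights are a design choice — only "a linear
combination" is prescribed by the study design — and the post-hoc
rescaling guarantees the stated σ regardless of them.

`program_flows()` converts a concentration program into five channel
flow schedules for stocks of formaldehyde (198 mM), DHA (198 mM), NaOH
(240 mM) and CaCl₂ (120 mM): at every step the total flow equals
V/τ = 411 µL / 120 s, formaldehyde and DHA hit their fixed targets,
NaOH is exactly twice CaCl₂, and water absorbs the rest. A draw high
enough to exhaust the water channel (≈ 29.7 mM Ca at 50 mM formaldehyde)
is clipped *jointly* — Ca and OH reduced together — because the 1:2
ratio is a hard constraint of the design; clipped steps are counted and
reported. A mean that is already infeasible is a configuration error,
not a clipping case. Programs include a 30-minute equilibration prefix
before the sampling window (configurable).

# The synthetic reaction network

## Structure

`build_formose_model()` returns a schematic mass-action network with

* a Breslow-cycle core: formaldehyde (`C1`) + glycolaldehyde (`GLA`) →
  glyceraldehyde (`GLY`) ⇌ DHA; `C1 + DHA` → erythrulose (`ERY`) ⇌
  threose (`THR`) → 2 `GLA` (the autocatalytic closure), plus two
  further C4 isomers (`ERO`, `THO`) in fast exchange;
* four branches gated from the core by enolate chemistry: II
  (formaldehyde aldol additions onto the C4 pool), III (C3-enolate + C4
  additions paired with a strongly catalyst-sensitive retro-cleavage),
  IV (C3-enolate + glycolaldehyde, the xylulose-like route, into slowly
  draining pools) and V (catalyst-insensitive C2-enolate additions onto
  DHA, erythrulose, or further glycolaldehyde units);
* condensation of branch pools and C4 sugars into unreactive tar
  (browning material), which conserves carbon without recycling mass
  into the network.

Every reaction's rate constant is modulated by the in-reactor catalyst
level through a power law, `k_eff = k (ca / 15 mM)^s` with sensitivity
exponent `s ≥ 0` (`effective_rate()`). The catalyst itself is a
non-consumed species with its own CSTR mass balance, so the reactor
low-pass filters the applied program with time constant τ before the
chemistry sees it — an essential feature the analyses must contend
with. Enolates are folded into effective gating rate laws by default;
`explicit_enolates = TRUE` models them as fast explicit species
(`E32`–`E35`) with the catalyst sensitivity carried by enolate
formation. Carbon is conserved in every reaction (`carbon_audit()`),
and Cannizzaro chemistry is deliberately absent.

The measured set is 28 compounds: the four C4 core sugars and six
species per branch. The fed species (formaldehyde, DHA) and the C2/C3
intermediates are treated as unmeasured inputs/intermediates. This
deviates from the experimental study, where the DHA feed is itself
quantified; in a schematic model a 50 mM-fed species' concentration is
pinned by its feed and cannot respond to the catalyst like the produced
sugars do, so including it in a response cluster would be artificial.

## Why these kinetics

No rate constants are published for this chemistry, so the defaults are
a design, not a fit, chosen against three goals: produced species sit
at observable levels under the unperturbed condition; core relaxation
is slower than the branch gates but all pools relax within a few
residence times; and, centrally, the five modules respond to the
applied dynamics with *distinct, internally coherent* shapes. The last
goal is the hard one, and drove the structure:

* Because the reactor pre-filters the input at τ = 120 s, two same-sign
  first-order responders can never decorrelate much: over the
  achievable 10–110 s range of pool lifetimes their correlation stays
  above ≈ 0.75. Five distinguishable modules therefore need five
  *shape classes*, not five lifetimes: fast-positive (II, gate s = 3,
  pool lifetimes ~15 s), fast-negative (III, weakly sensitive gate but
  drain s = 4, lifetimes ~10 s), slow-positive (IV, gate s = 1.5,
  lifetimes ~100 s), slow-strong-negative (core: a small but highly
  cooperative base-mediated degradation, s = 7, drains the C4 pool, so
  it responds strongly yet relaxes slowly), and a band-pass follower
  (V): the retro-aldol closure is catalyst-promoted (s = 2.5) while
  glycolaldehyde's consumption is only mildly promoted, leaving the
  unmeasured C2 pool with a near-cancelling, derivative-like response
  that the fully insensitive branch V inherits.
* Within a branch, all members are parallel pools fed by the same
  gating reactants (deeper members as lumped multi-additions of
  formaldehyde or glycolaldehyde) and drained at one rate: identical
  dynamics, different levels. Sequential chains were tried and
  rejected — each chain stage adds a full pool-lifetime lag, which
  decoheres the module.
* Isomerisations within the core are symmetrically promoted (equal
  forward/reverse sensitivity), so the C4 pool's internal composition
  is catalyst-independent and its four members move as one block.

The produced species span roughly 0.01–6 mM at the EXP001 steady state.
That is narrower at the bottom than the 0.1–10 mM envelope we aimed
for: raising the dilute branch members requires gate fluxes large
enough to perturb the core species they feed from, which destroys the
core's coherence. We kept the coherent dynamics and accept that the
deepest branch members are dilute.

## Integration

`simulate_cstr()` integrates
`dCᵢ/dt = (C_in,i(t) − Cᵢ)/τ + Σ_r ν_ir rate_r(C, ca)` segment by
segment between flow-program breakpoints with `deSolve::lsoda`
(defaults `rtol 1e-8`, `atol 1e-10`) — no smoothing across the step
discontinuities, no event detection needed. Values below −1e-12 are
clamped to zero with a warning. The washout closed form is reproduced
to better than 1e-6 relative and a two-species toy model matches a
1 ms explicit-Euler oracle to 1e-4 (see the test suite).
`sample_outlet()` then interpolates the traces at the sampling grid (50
samples at 40.8 s, or 30.6 s for the multi-timescale condition) and
applies mean-one multiplicative lognormal noise with a default
coefficient of variation of 0.05 — a typical replicate-level CV for
derivatization GC–MS quantification.

# Measurement model

Quantification follows the instrument-side rules: a quadratic
calibration `conc = a·A² + b·A + c` per compound; for a compound with
several chromatographic peaks only the largest integral is used; for
compounds without their own calibration, the coefficient-wise mean of
the calibrations in the same molecular-weight class (we group by carbon
count). Curves must be monotone increasing over their declared working
range — a non-monotone curve is rejected at load rather than silently
inverted ambiguously. Negative quantifications are floored at zero with
a warning. Because no instrument calibration table is published, the
package ships *synthetic* curves (`synthetic_calibration_curves()`,
small positive curvature, unit-order slope, zero intercept) and accepts
user tables via `read_calibration_table()`. The forward model
`synthesize_peaks()` inverts each quadratic on its increasing branch so
that `quantify(synthesize_peaks(traces))` is an exact round trip on
noiseless data (≤ 1e-6 relative), which lets the whole pipeline be
exercised end to end.

# Clustering

Traces are compared with the correlation distance
`d(u, v) = 1 − (u−ū)·(v−v̄) / (‖u−ū‖‖v−v̄‖) ∈ [0, 2]`. A constant trace
has no defined correlation; it raises an error naming the offending
compound rather than adopting a silent convention, because a
conventional 0 or 1 corrupts the dendrogram invisibly. Agglomeration is
size-weighted average linkage (UPGMA): after merging A and B,
`d(A∪B, Y) = (|A| d(A,Y) + |B| d(B,Y)) / (|A| + |B|)`. Exact ties break
toward the lowest pair of cluster indices in creation order; this is
documented because tie handling differs between implementations. Merge
heights are recorded as `d(A,B)/2` — each child sits at half the merge
distance — which is *half* the conventional cophenetic height; use
`as_hclust()` and multiply by two to compare with other tools. The test
suite verifies exact equivalence of merge structure and (doubled)
heights against `stats::hclust(..., method = "average")` on hundreds of
random matrices. Flat clusters come from `cut_clusters()` either as
exactly `k` groups (merge truncation, well defined even under height
inversions, though UPGMA itself is monotone) or by a height threshold;
the cut parameter is recorded in the result. The study assigned
clusters by inspection; the automated cut at k = 5 recovers the
generator's planted modules with a mean adjusted Rand index above 0.9
over 20 seeded replicates of the multi-timescale condition.

# Timescale correlation

For each window width w ∈ {30, 60, 90, 120, 150} s the input program is
resampled by linear interpolation onto the output time axis, the time
axis is tiled with consecutive non-overlapping windows of width w
starting at the first sample, per-window means are taken, and their
first differences form the differential vector; it is standardized with
the *population* SD (divisor n), and the Pearson correlation between
the input's and each compound's standardized differential is reported
per window. Positive r means the compound moves with the input at that
timescale. Choices worth flagging:

* *Tiling vs sliding.* The windowing description is ambiguous between
  sliding windows and consecutive tiles; differencing "each window
  minus the previous window" implies tiles, which is the default. An
  overlapping mode (`stride` smaller than the width) is available; it
  differences means one full window apart.
* *Partial and empty windows.* A trailing window not covered by the
  span is dropped with a message (unequal support biases means). On the
  30.6 s grid a 30 s window drifts by 0.6 s per tile, so the 51st tile
  is empty — dropped as trailing. An *interior* empty window is an
  error naming the window: it means the width is incompatible with the
  sampling grid (e.g. 30 s windows on 40.8 s samples), and the pipeline
  pre-checks and drops such widths with a message.
* *Input trace.* The correlation uses the implied inlet Ca(OH)₂
  program (pre-reactor). The reactor-filtered catalyst trace is also
  simulated (compound `ca` in the simulation output) if the filtered
  view is wanted instead.
* With 50 samples the long windows leave only 9–16 differences, so a
  single |r| of 0.3–0.5 is within the noise band of the estimator;
  judgements about "no correlation" should use the z-scale
  `r·sqrt(n−1)` per window, as the acceptance suite does for the
  insensitive branch.

# Distribution comparison

`condition_report()` compares every compound between every pair of
conditions: per-condition mean ± SD, a two-sided p-value, and the star
annotation ns (p > 0.05), * (0.01 < p ≤ 0.05), ** (0.001 < p ≤ 0.01),
*** (1e-4 < p ≤ 1e-3), **** (p ≤ 1e-4), boundaries inclusive on the
more significant side. The test behind the study's panels is not named;
the default here is Welch's unequal-variance t test (the panel spreads
are visibly heteroscedastic), with a Mann–Whitney option — so p-values
are not expected to match the study's numerically. No multiple-testing
correction is applied by default, matching per-panel annotation; a
Benjamini–Hochberg option exists. All 50 timepoint samples are pooled
as replicates, as the study appears to do; consecutive samples are
autocorrelated (the reactor time constant spans ~3 samples), so the
effective sample size is smaller than 50 and p-values are
anti-conservative in absolute terms. Within the pipeline, `compare`
runs a matching σ = 0 steady-state control with the same seed and
reports perturbed-vs-control comparisons.

# What the generator does and does not emulate

It emulates: the stepwise-Gaussian input with feasibility clipping and
the exact flow-balance constraints; reactor low-pass filtering of the
catalyst; collective, differently-gated responses of compound groups
with transfer that depends on input timescale; multiplicative
measurement noise; quadratic calibration. It does not emulate: real
formose kinetics or stereochemistry (rate constants are schematic, not
fitted; no quantitative concentration predictions), Cannizzaro
chemistry, calcium-salt precipitation, derivatization artefacts,
sample-to-sample instrument drift, or peak assignment errors. Passing
tests therefore demonstrate that the *analysis* machinery recovers
planted structure of the kind the study relies on — not that the
chemistry is predicted.

# Numerical choices and problem sizes

Solver tolerances default to `rtol 1e-8 / atol 1e-10`; acceptance
checks tighten them where closed forms are compared. Randomness is
confined to `sample_step_signal()`, `sample_outlet()`,
`synthetic_calibration_curves()` and the statistical simulations; all
take explicit seeds, and pipelines are bit-reproducible given a config
and seed. Statistical recovery checks use 10⁴-step programs; module
recovery uses 20 seeded replicates of the 50-sample multi-timescale
condition, the study's own measurement size. Type-I calibration of the
default test uses 10⁴ replicate null pairs.

# Known limitations

* The clustering recovery margin is finite: single compounds
  (typically the erythrulose node, which carries the branch II gate
  load) occasionally defect to a neighbouring cluster in a given seed;
  the 20-seed mean ARI sits near 0.93.
* The insensitive branch is "near zero" relative to the estimator's
  noise band, not identically zero: it inherits a band-passed shadow of
  the input through the glycolaldehyde pool it feeds from. In a
  mass-coupled network a branch cannot be both clusterable (it needs a
  coherent signal) and perfectly input-silent.
* Height-threshold cuts under non-metric distances are only well
  defined in the absence of inversions; UPGMA is monotone, but
  user-supplied linkages may not be.
* The p-values pool autocorrelated timepoints, as noted above.
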
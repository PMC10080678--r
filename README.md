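# formosedyn

Tools for studying how *dynamic* environmental conditions shape the
composition of a model prebiotic reaction network. A formose-type sugar
network runs in a continuous stirred-tank reactor (CSTR, V = 411 µL,
τ = 120 s) whose catalyst supply — Ca(OH)₂, delivered as coupled CaCl₂
and NaOH inlets at a fixed 1:2 Ca²⁺:OH⁻ ratio — is redrawn from a
Gaussian (mean 15 mM, σ up to 5.75 mM) every 30–120 s, with a water
channel balancing the flows so the residence time never changes. The
package generates those input programs, simulates a schematic gated
reaction network driven by them, emulates GC–MS quantification, and
analyses the resulting concentration time series the way such
experiments are analysed:

* **Input programs** — stepwise-Gaussian signals (`sample_step_signal`),
  multi-timescale superimpositions (`superimpose_signals`), and
  residence-time-balanced five-channel flow schedules (`program_flows`).
* **Network simulator** — a Breslow-cycle core with four enolate-gated
  branches of differing catalyst sensitivity
  (`build_formose_model`, `simulate_cstr`, `sample_outlet`); mass-action
  ODEs with power-law catalyst modulation
  `k_eff = k (ca / ca_ref)^s`, integrated segment-wise across the input
  steps with deSolve.
* **Measurement** — quadratic peak-area calibration, averaged-curve
  fallback, largest-peak rule, and an exact forward/inverse round trip
  (`quantify`, `averaged_curve`, `synthesize_peaks`).
* **Clustering** — correlation distance
  `d = 1 − cor(u, v) ∈ [0, 2]`, size-weighted average linkage (UPGMA)
  with the size-proportional update
  `d(A∪B, Y) = (|A| d(A,Y) + |B| d(B,Y)) / (|A|+|B|)` and merge heights
  recorded as `d(A,B)/2` (`pairwise_distances`, `average_linkage`,
  `cut_clusters`).
* **Timescale correlation** — windowed-differential Pearson correlation
  of every compound against the input at window widths 30–150 s
  (`windowed_differential`, `normalize_differential`,
  `timescale_correlations`).
* **Distribution comparison** — Welch tests with the standard
  significance-star bins (`compare_means`, `star_annotation`,
  `condition_report`).

`run_pipeline()` ties the stages together; `exp_preset("EXP001")` …
`exp_preset("EXP013")` reproduce the thirteen study conditions. A thin
command-line front end lives in `inst/cli/formose-dyn.R`.

## Worked example

The multi-timescale condition (σ = 5.75 mM superimposed from 30, 60 and
120 s components, 50 outlet samples at 30.6 s):

```r
library(formosedyn)

cfg <- exp_preset("EXP013")
cfg$seed <- 101
man <- run_pipeline(cfg, stages = c("generate", "simulate", "cluster", "correlate"),
                    out_dir = "exp013")
man$results$clusters
#> <cluster_assignment> 5 clusters over 28 compounds (cut: k = 5)
#> $`1`
#> [1] "ERY" "THR" "ERO" "THO"
#> $`2`
#> [1] "II_C5"  "II_C6a" "II_C6b" "II_C6c" "II_C7a" "II_C7b"
#> $`3`
#> [1] "III_C7"  "III_C8a" "III_C8b" "III_C8c" "III_C9a" "III_C9b"
#> $`4`
#> [1] "IV_C5"  "IV_C6a" "IV_C6b" "IV_C6c" "IV_C7a" "IV_C7b"
#> $`5`
#> [1] "V_C5"  "V_C6a" "V_C6b" "V_C6c" "V_C7a" "V_C7b"
```

The flat cut at k = 5 recovers the generator's five planted modules
exactly here (adjusted Rand index 1; the mean over 20 seeds is ≈ 0.93):
the C4 core sugars, the four gated branches. The per-timescale
correlation map shows how differently they transfer the input dynamics:

```r
round(man$results$corrmap[c("ERY", "II_C5", "III_C7", "IV_C5", "V_C5"), ], 2)
#>           30    60    90   120   150
#> ERY     0.30  0.42  0.48  0.48  0.09
#> II_C5  -0.03  0.22  0.14  0.29  0.34
#> III_C7  0.37  0.20  0.24  0.12 -0.19
#> IV_C5  -0.29 -0.45 -0.55 -0.62 -0.34
#> V_C5    0.01 -0.04 -0.10 -0.16  0.06
```

Rows are compounds, columns window widths in seconds, entries the
Pearson correlation between the standardized windowed differentials of
the compound trace and the Ca(OH)₂ input: the slow branch IV moves
against the input most strongly at long windows, while the
catalyst-insensitive branch V sits at the noise level of the estimator
at every window. `man$paths` lists the CSV artifacts (flow program,
traces, samples, peak tables, clusters, correlation map, comparison
report) plus a JSON run manifest.

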
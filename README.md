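# heatrr

Mechanistic discrimination of **atrial fibrillation (AFib)** from **atrial
flutter with irregular ventricular response (AFlu)** using nothing but a
short series of RR intervals.

The two arrhythmias produce confusingly similar surface ECGs and pulse
patterns, but their physiology differs upstream: in AFlu the atria beat fast
and *regularly* (cycle length around 240 ms), and the irregular pulse arises
from structured, cascaded blocking in the AV node; in AFib the atrial
activity itself is chaotic (mean cycle near 182 ms).  `heatrr` turns that
difference into features: it fits a **multilevel atrioventricular block
(MAVB)** model to the observed RR series by exact inverse simulation, and
the residual of the best fit — plus the fitted, clinically interpretable
parameters — feeds an ordinary classifier.

## The model and the fit

Atrial impulses form a regular train `t_j = t_s + j·Δa`.  Up to three block
levels are cascaded; each conducts `n` of every `n+1` incoming signals
(cyclic ratio patterns, e.g. fixed 2:1 or alternating 2:1/3:2), and a
conducted signal at Wenckebach position `k` of its cycle is delayed by
`c + (k−1)·δ` (Type I; Type II has `δ = 0`).  The ventricular RR intervals
are the differences of the final level's conducted times.

The inverse problem

```
F(x*) = min over x = (Δa, blocktype, oc)  ‖ RR_sim(x) − RR_obs ‖₂
```

is solved to *global optimality* on the millisecond grid: Δa ∈ [175, 400] ms,
five clinically motivated blocktype presets, per-level ratios, phase
offsets and delay increments, with candidates discarded ("clipped") when any
single interval deviates by more than 150 ms.  Because blocking is purely
combinatorial and all times are integer-linear in the parameters, the solver
eliminates the Δa dimension analytically per combinatorial structure and is
provably identical to the shipped brute-force oracle, with exact
deterministic tie-breaking.

On top of the fit the package provides the derived feature sets (objective
only; objective + encoded solution + RR statistics; moving-horizon series
with cross-window generalization; N-gram subsequence statistics), a
leakage-free repeated stratified 10-fold CV harness with nested grid-search
tuning (SVM via LIBSVM, a 1-D threshold classifier, and a compact native
CNN baseline), and a seeded synthetic benchmark generator with ground truth
that emulates the study population (190 + 190 samples of 22 intervals,
including pseudo-regular high-rate AFib failure cases).

## Worked example

Simulate a classic 4:3 Wenckebach rhythm (Δa = 250 ms, increment 20 ms),
add measurement jitter, and recover the mechanism:

```r
library(heatrr)
p  <- mavb_params(250, list(block_level("I", list(c(4, 3)),
                                        delay = 50, increment = 20)))
forward_simulate(p, 6)$ventricular_rr
#> [1] 270 270 460 270 270 460

rr  <- forward_simulate(p, 22)$ventricular_rr
set.seed(42)
obs <- round(rr + rnorm(22, 0, 5))          # 5 ms measurement jitter
fit <- heat_fit(obs, heat_control(blocktype_ids = 1:2))
fit
#> HEAT fit: objective 30.299 ms over 22 intervals
#>   delta_a = 250 ms, blocktype 1, oc = (n1=3, o1=0, d1=20)
```

The fit recovers the generating mechanism exactly — atrial cycle 250 ms,
4:3 Wenckebach (`n1 = 3`), increment 20 ms — and its objective (30.3 ms,
about 6.5 ms RMS per interval) is pure measurement noise.  An AFib-like
irregular series admits no such explanation: its objective is large or the
fit is infeasible, which is precisely the classification signal.  On the
default synthetic benchmark the one-dimensional threshold classifier on the
fitted objective reaches ROC area 1.00 under 3× stratified 10-fold CV, and
the SVM on HEAT features outperforms an SVM on raw N-gram RR features
(99.9% vs 95.4% accuracy) — the qualitative ordering reported for clinical
data, on a benchmark that is cleanly separable by construction.

A thin CLI wraps the same functions
(`system.file("cli", "heat", package = "heatrr")`):

```sh
heat simulate --out bench/ --seed 1
heat fit      --input bench/samples.csv --out solutions.json
heat features --input bench/samples.csv --set heatSolution --out features.csv
heat cv       --input bench/samples.csv --set heatSolution --model svm --out cv.json
heat scan     --input bench/samples.csv --index 8 --lo -400 --hi 400 --out scan.csv
```

## Package layout

- `R/mavb.R`, `R/blocktypes.R` — forward model: impulse trains, block
  levels, cascades, the deviation objective, the preset registry (YAML
  round-trip).
- `R/structures.R`, `src/solver.cpp` — the exact grid solver: combinatorial
  structures, integer coefficient systems, analytic Δa elimination and the
  brute-force oracle.
- `R/heat-fit.R` — `heat_fit()` and its S3 methods (`print`, `summary`,
  `coef`, `fitted`, `residuals`, `predict`, `simulate`, `plot`), bounds and
  the sensitivity scan.
- `R/features.R` — feature sets, moving horizon, N-grams, standardization.
- `R/ml.R`, `R/cnn.R` — SVM/threshold/CNN and the CV harness.
- `R/synth.R` — synthetic benchmark and recovery-case generators.
- `R/io.R`, `R/cli.R` — CSV/JSON/YAML IO and the CLI.
- `vignettes/mavb-inverse-simulation.Rmd` — the methods vignette: model
  assumptions, solver exactness, identifiability and aliasing, generator
  calibration, limitations.
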
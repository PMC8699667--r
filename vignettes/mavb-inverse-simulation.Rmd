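---
title: "Inverse simulation of multilevel AV block for AFib/AFlu discrimination"
author: "heatrr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse simulation of multilevel AV block for AFib/AFlu discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatrr)
```

## The problem

Atrial fibrillation (AFib) and atrial flutter with irregular ventricular
response (AFlu) both present as a fast, irregular pulse, and their surface
ECGs are notoriously hard to tell apart — yet the two call for different
treatments.  The discriminating physiology is upstream of what the RR
intervals show directly: in AFlu the atria beat fast but *regularly*
(cycle length around 240 ms, varying by only a few milliseconds), and the
irregular ventricular response arises because the atrioventricular (AV)
node blocks impulses in structured, cascaded patterns.  In AFib the atrial
activity itself is chaotic (mean cycle near 182 ms).

`heatrr` exploits this: it fits a mechanistic model of multilevel AV block
(MAVB) to an observed RR series by inverse simulation.  If a regular atrial
rhythm filtered through a plausible block cascade can reproduce the
ventricular intervals almost exactly, the sample looks like AFlu; if no
such explanation exists, it looks like AFib.  The residual of the best fit
— a single interpretable number in milliseconds — is the decisive
classification feature, and the fitted parameters (atrial cycle length,
blocktype, conduction constants) are clinically meaningful quantities.

## The forward model

Atrial activations form a regular train $t_{0j} = t_s + j\,\Delta_a$.  Each
block level conducts according to a cyclic ratio pattern: a ratio
$(n{+}1){:}n$ means $n$ of every $n{+}1$ incoming signals pass.  A
conducted signal at position $k$ of its cycle leaves the level at

$$t_{ij} = t_{i-1,j} + c_i + (k-1)\,\delta_i ,$$

where $c_i$ is a base conduction delay and $\delta_i$ a linear Wenckebach
increment that resets after each dropped beat.  Type II (Mobitz) levels
have $\delta_i = 0$; Type I (Wenckebach) levels have $\delta_i \ge 0$.  Up
to three levels are cascaded — the conducted output of one level is the
input of the next — and the ventricular RR intervals are the differences of
the final level's conducted times.

Five blocktype presets span the clinically observed combinations: a single
Type I level with free ratio, a single Type II level with free ratio, a
fixed 2:1 Type II level feeding a free Type I level, a three-level cascade
of alternating Type II patterns (2:1/3:2 then twice 1:1/2:1), and two
stacked free Type I levels.  The registry is data, not code: it can be
serialized to YAML, edited, and passed back through `heat_control()`.

```{r presets}
vapply(mavb_blocktypes(), `[[`, character(1), "name")
```

A classic 4:3 Wenckebach at $\Delta_a = 250$ ms with $\delta = 20$ ms gives
the textbook "group beating" pattern:

```{r wenckebach}
p <- mavb_params(250, list(block_level("I", list(c(4, 3)),
                                       delay = 50, increment = 20)))
forward_simulate(p, 6)$ventricular_rr
```

## The inverse problem and why the solver is exact

The fit minimizes the Euclidean norm of the residuals between simulated and
observed RR intervals over the discrete feasible set: $\Delta_a$ on a 1 ms
grid within the physiological bounds [175, 400] ms, the blocktype, and the
per-level free parameters (ratio, phase offset, increment on [0, 100] ms).
Candidates whose simulation deviates by more than 150 ms in any single
interval are *clipped* — discarded, not capped — which is what produces the
characteristic jumps in the objective landscape.

Two structural facts make an exact global search affordable:

1. **Blocking is combinatorial.**  Whether a signal is conducted depends
   only on counts, never on times.  Fixing blocktype, ratios and phases
   ("a structure") fixes which atrial impulse reaches the ventricles and at
   which Wenckebach position of each level.
2. **Times are linear in the parameters.**  Within a structure every
   simulated RR interval is an integer combination
   $a_m\,\Delta_a + \sum_l b_{ml}\,\delta_l$.  The base delays $c_l$ and
   the train offset $t_s$ cancel from every difference — they are not
   identifiable from RR data, so the solver fixes them at zero (they remain
   forward-model parameters).

Per structure and increment assignment the squared objective is a convex
quadratic in $\Delta_a$ with all-integer residuals; its grid minimizer is
the clamped floor/ceiling of the continuous argmin, and the clipping
constraints plus the monotonicity of each intermediate level's conducted
times are linear inequalities that shrink the admissible $\Delta_a$
interval.  The default path enumerates structures and increments and
solves $\Delta_a$ analytically; `brute_force_solve()` runs the
definitional triple loop (with an optional monotone prefix-sum prune) over
the *same* candidate set.  Because squared objectives are exact integers,
ties are exact, and the deterministic tie-break (smaller objective, lower
blocktype id, lower $\Delta_a$, lexicographically smaller free parameters)
makes the two paths provably identical — which the test suite checks on
randomized instances.

A per-structure restriction narrows the $\Delta_a$ grid to
$\rho\,\overline{RR}\,(1 \pm 0.25)$, where $\rho$ is the structure's
conducted fraction: increments cancel over full conduction cycles, so
$\overline{RR} \approx \Delta_a/\rho$ up to boundary effects, and the 25%
slack is far wider than both those effects and the 150 ms clip allows.
The restriction is applied identically in both solver paths, keeping the
oracle equivalence well defined; it can be disabled
(`restrict_delta_a = FALSE`), which never changes the result, only the
runtime.

### Identifiability and aliasing

The model has exact degeneracies.  A leading 2:1 level is indistinguishable
from doubling $\Delta_a$ (when both candidates lie inside [175, 400] ms); a
Type I level with a 2:1 ratio conducts one beat per cycle, so its increment
never enters any time difference (the canonical grid for such an inert
dimension is {0}); and particular increment values can make the output
constant, which several cycle lengths explain equally well.  Blocktype
labels therefore alias — a Type II level is a Type I level with zero
increment, and the tie-break deliberately resolves such ties toward the
lowest preset id.  Parameter *recovery* is only meaningful in the
identifiable regime, so the recovery harness (`gen_recovery_cases()`)
draws $\Delta_a$ from [205, 395] ms (putting the doubled alias out of
bounds) and rejects draws with constant output.  Within that regime the
optimal $\Delta_a$ is unique even where the blocktype label is not, and
the solver recovers it exactly on noiseless input.

## Features

From each fit the package derives the feature sets used for
classification:

* `heatObjective` — the optimal objective $F(x^*)$ alone; infeasible
  (all-clipped) samples saturate at $\sqrt{n}\cdot 150$ ms, the largest
  value a feasible candidate could attain.
* `heatSolution` — $F(x^*)$, the encoded solution
  ($\Delta_a^*$, blocktype id, free parameters padded to 4 values), plus
  RR variance and mean: 9 features.  The two-level Type I preset has 6
  free values and is truncated to the configured encoding length; the
  length is configurable because no single choice reconciles all of the
  published dimension counts.
* `heatSeries` / `heatSerAvg` — a moving horizon: all windows of length
  `n_sub` (default 17, stride 1) are fitted independently, giving
  per-window series of the objective, the encoded solution, and the
  cross-window generalization `HEATfit` — window $k$'s solution scored on
  window $k{+}1$ (the last window on its predecessor).  Cross-window
  evaluation shifts the simulation along the series; backward shifts use
  the exact periodicity of the conduction cascade (the joint phase state
  evolves under an invertible map on a finite set, hence is purely
  periodic), so on stationary noiseless data HEATfit is exactly zero.
  `heatSerAvg` is the mean/sd of each component series (16 features with
  the default encoding), optionally with age appended.
* N-gram features — means of all contiguous subsequences and sample
  standard deviations of those with length $\ge 2$: exactly $n^2$ features
  in a canonical order (start, then length), so standardization parameters
  align across runs.

Standardization (zero mean, unit sd) is always fitted on training rows
only; constant features get scale 1 with a warning.  Sample (n−1)
standard deviations are used throughout so length-2 subsequences are
well defined.

## Classification

`cross_validate()` runs repeated stratified 10-fold cross-validation.
Hyperparameters (kernel, cost, gamma, optionally `n_sub`) are chosen per
outer fold by an inner stratified grid-search CV on the training folds
only — the nested, leakage-free reading of grid-search tuning.  The SVM is
LIBSVM via `e1071`; AFib is the positive class, so sensitivity is AFib
recall and specificity is AFlu recall, with thresholds at 0 (SVM margin)
and 0.5 (sigmoid).  The ROC area is the rank (Wilcoxon) statistic,
identical to the trapezoidal area and invariant under monotone transforms
of the scores.

The CNN baseline follows the stated reference architecture (two blocks of
two width-2, five-filter ReLU convolutions with max pooling and dropout,
a dense ReLU layer, a sigmoid output) and is trained with Adam at default
parameters.  No deep-learning framework is required: the implementation is
a compact native one, with exact gradients verified against numerical
differentiation in the tests.  Unstated details are recorded in its
arguments: pool size 2, valid padding, batch size 32, hidden width 8.

## The synthetic benchmark

The reference dataset of the underlying study is private, so the package
ships a generator that emulates its statistical structure and provides
ground truth:

* **AFlu** (190 samples): the forward MAVB model with $\Delta_a \sim
  N(240, 15^2)$ ms (truncated to the solver bounds, constant within a
  sample), a uniformly drawn blocktype preset with random on-grid
  conduction parameters (increments uniform on [0, 80] ms), and
  independent Gaussian measurement jitter (sd 5 ms, mirroring the
  documented "atrial variation below 5 ms" regularity bound) rounded to
  the 1 ms grid.
* **AFib** (190 samples): a gamma renewal atrial process with mean cycle
  182 ms and coefficient of variation 0.25, filtered by concealed
  conduction — an impulse conducts only if the time since the last
  conducted beat exceeds a refractory period redrawn per beat, uniform on
  [300, 700] ms.  The renewal-plus-refractory construction is this
  package's own; the study describes its AFib data only statistically, and
  these choices give a mean ventricular rate near 100–120 bpm with the
  qualitative irregularity contrast the study reports.
* **Pseudo-regular AFib** (5% of the AFib class by default): the same
  mechanism with a narrow refractory window of [265, 290] ms, tuned a
  priori so the mean ventricular rate lands near 160 bpm.  These samples
  are fast, nearly regular, and fit the MAVB model much better than
  ordinary AFib — reproducing the method's documented failure mode.

Everything is a deterministic function of one seed, class proportions are
exact by construction, and a truth sidecar records the generating
parameters of every AFlu sample for recovery scoring.

What passing tests on this benchmark do *not* show: real RR series carry
measurement artifacts, premature beats, and nonstationary conduction that
the generator does not emulate, and the synthetic classes are separated
more cleanly than clinical data (the raw-feature SVM scores far above the
~60% reported on clinical material).  The benchmark validates the
machinery and the qualitative orderings — HEAT features above raw
features, pseudo-regular samples below ordinary AFib in objective — not
clinical performance numbers.

## Numerical choices and problem sizes

* All intervals are integers on the 1 ms grid; squared objectives are
  exact integers, so equality tests and tie-breaks involve no floating
  point tolerance.
* Infeasible fits return a sentinel (`feasible = FALSE`, objective `Inf`)
  rather than raising; feature generation saturates them at
  $\sqrt{n}\cdot 150$ ms.
* Window indices are 1-based and inclusive throughout, matching R
  conventions.
* The test suite and the acceptance script use the study's structural
  sizes directly (22-interval samples, 190 + 190 benchmark, 10 draws per
  preset for recovery, ±400 ms scans at 1 ms for the count and ±60 ms for
  the segment-structure check, 12-interval instances on 5 ms grids for the
  brute-force oracle, and 2-repeat 10-fold CV for the two SVM comparison
  runs alongside 3-repeat CV for the threshold classifier) —
  sizes chosen so the full suite replays the relevant findings on one CPU
  in minutes.

## Limitations

* The five presets cover the explicitly described blocktype combinations,
  but the authoritative preset composition lives in sources not machine
  readable here; the registry is deliberately configuration, not code.
* Whether the published objective is the Euclidean norm or its square is
  ambiguous in the source material; the norm is implemented (the
  piecewise-quadratic landscape structure is identical either way).
* Clipped candidates are discarded rather than penalized; a capped-penalty
  variant would change the landscape between feasible islands.
* The CNN baseline is a faithful but small reference implementation; it is
  not performance-tuned and is excluded from the deterministic end-to-end
  guarantees (minibatch order and dropout are stochastic).
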
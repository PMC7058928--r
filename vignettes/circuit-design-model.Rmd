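---
title: "The gate model behind norcircuit: interference, dynamics and power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The gate model behind norcircuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(norcircuit)
lib <- builtin_library()
```

## The signal and the gate

Everything in this package is denominated in relative promoter units
(RPU), a standardized measure of promoter activity that serves as a proxy
for RNA polymerase flux. A transcriptional NOT/NOR gate is a repressor
gene driven by one or two input promoters; the repressor closes the gate's
output promoter. At steady state the gate is a declining Hill function of
its total input flux $x$:

$$y = y_{\min} + (y_{\max}-y_{\min})\frac{K^n}{K^n + x^n}.$$

All four parameters are empirical and live in a `GateRecord` row of the
library, together with the interference parameters and timescales
described below. The packaged library transcribes 18 characterized gates
across 10 repressor families; `validate_library()` enforces the record
invariants ($0 < y_{\min} < y_{\max}$, $K>0$, $n>0$, $\alpha,\beta \in
(0,1]$, positive timescales).

## Tandem promoters and roadblock interference

A NOR gate's two input promoters sit in series on the DNA. The baseline
model adds their fluxes, $x = x_1 + x_2$. That approximation fails
exactly for the promoters that make good gates: a cooperatively bound,
slow-off-rate repressor at the *downstream* promoter physically blocks
RNAP elongating from the *upstream* promoter. The corrected composition is

$$x = \underbrace{\alpha\,\frac{K_2^{n_2} + \beta\, x_2^{n_2}}
{K_2^{n_2} + x_2^{n_2}}}_{\text{occupancy factor of promoter 2}}\; y_1 + y_2,$$

where $\alpha$ is repressor-independent suppression (pause sites,
antisense transcription, ...), $\beta$ is the roadblocking factor, and
$K_2, n_2, x_2$ belong to the downstream node — its own input flux $x_2$
sets its repressor occupancy. The factor falls from $\alpha$ (repressor
clear) to $\alpha\beta$ (fully bound); at $\alpha=\beta=1$ the additive
model is recovered exactly, which the test suite verifies to $10^{-12}$
relative tolerance on randomized circuits. The microscopic constants that
underlie $\beta$ (repressor off-rate, RNAP dissociation rate, DNA
concentration) are deliberately not modeled separately: they are
unidentifiable from circuit-level data and are subsumed into the fitted
$\beta$.

Design choices worth stating explicitly:

* **Orientation contract.** The occupancy factor is always computed from
  the position-2 (downstream) node's parameters and input, and multiplies
  the position-1 (upstream) flux. Netlists label slots explicitly;
  synthesis assigns positions deterministically (lexicographically smaller
  node id upstream), since no placement restriction is imposed on
  roadblocking promoters.
* **Sensor promoters.** Sensor output promoters can also roadblock, but
  only their OFF/ON endpoint behavior is characterized, so they follow a
  two-state rule: a repressor-based sensor contributes $\alpha$ when
  induced and $\alpha\beta$ when not; an activator-based sensor always
  contributes $\alpha$. The shipped library leaves sensor
  $\alpha=\beta=1$ (flagged in its metadata) because no characterized
  values are available — sensors therefore compose additively unless the
  user supplies data.
* **Output stage.** A two-driver reporter stage is a tandem pair and uses
  the same composition rule.
* **NOT nodes** feed their single input straight into the Hill function —
  there is no second promoter to interfere with.

## Steady-state prediction and scoring

`evaluate_state()` walks the netlist in topological order;
`truth_table_prediction()` tabulates all $2^n$ input states in canonical
binary order (input 1 is the least-significant bit, so state 4 = `0100`
means only input 3 is on). The separation score returned by
`circuit_score()` is the minimum predicted ON-state flux divided by the
maximum predicted OFF-state flux, with don't-care rows excluded — the
conventional choice where the exact industrial scoring function is not
public; it is isolated behind one function so it can be swapped. Don't-care
exclusion matters for the decoder circuits, whose input states 10–15 fall
outside the decimal range.

## Logic synthesis

`synthesize()` converts a truth table with don't-cares into a NOT/NOR2
netlist, with an optional two-driver tandem-OR reporter stage that costs
no gate. The search is an exhaustive breadth-first sweep over total gate
count with truth-table-signature memoization (signatures are $2^{2^n}$-bit
integers, $n \le 4$): cost-0 signatures are the inputs, each level adds
NOT of the previous level and NOR of every cost-split pair, and a
realization is accepted as soon as a signature — or the OR of two — matches
the specification on all care bits. Identical subexpressions are merged
into shared nodes on reconstruction, so the emitted gate count never
exceeds the minimal formula cost; on every 2-input function the result
matches an independent brute-force DAG minimum in the test suite (XOR, for
instance, comes out at 3 gates via a shared NOR). Ties are broken by
fewest NOT nodes, then shallowest depth, then canonical signature order,
making output bytes deterministic. `mode = "minimize"` runs the same
search as `mode = "enumerate"`: because the sweep is already an exact
minimizer, an algebraic pre-simplification pass would not change its
result, only its runtime on inputs far larger than the 4-input circuits
this gate technology supports.

## Gate assignment

Assignment maps netlist gate nodes to library gates under two hard
feasibility rules: one gate per repressor family (same-family gates differ
only in RBS and cross-react) and no prohibited family pair (the library
prohibits CymR with SrpR). Small instances — up to a configurable bound of
$10^6$ candidate assignments — are solved exhaustively in canonical library
order, which also fixes tie-breaking among equal scores. Larger instances
use seeded simulated annealing: proposals either reassign one node to a
feasible gate or swap two nodes' gates; the initial temperature is the
score spread of 100 random feasible assignments; cooling is geometric at
0.98 per step with $10^4$ steps by default. These are conventional values,
exposed through `options`, chosen once and not tuned: the test suite
checks that annealing never beats exhaustive search and reaches the
optimum on at least 95% of small random instances. Scoring defaults to
the interference model — the model that actually changes assignment
decisions — with the additive model on request.

`layout_plan()` then orders the chosen gates by the enforced
family order (VanR—PhlF—SrpR—AmtR—AmeR—BM3R1—LmrA—HlyIIR—BetI—CymR) and
attaches type-IIS cloning scars in their declared order, A always leftmost
and C rightmost. With seven intermediate scars the construct can carry at
most eight gates, which bounds the circuits this backbone supports.

## Dynamics

Kinetic gene-regulation models usually need many unmeasurable parameters;
this package instead uses a two-timescale relaxation per gate:

$$\frac{dy}{dt} = \begin{cases}\tau_{ON}(y_{ss}-y) & y < y_{ss}\\
\tau_{OFF}(y_{ss}-y) & \text{otherwise}\end{cases}$$

where $y_{ss}$ is the steady-state Hill response to the node's
*instantaneous* total input, computed with the interference composition
from the other nodes' instantaneous outputs. The branch structure reflects
different rate-limiting mechanisms (repressor dilution/degradation when
rising, transcription/translation when falling); at $y = y_{ss}$ both
branches give zero derivative, so the tie is inert. Sensors relax toward
their scheduled OFF/ON flux with a single induction timescale, and the
reporter integrates the output flux with first-order decay.

Numerical choices: integration uses `deSolve` (`lsoda`) segment by
segment, with the state vector chained across schedule boundaries so
trajectories are continuous; relative tolerance defaults to $10^{-8}$
(exposed via `options`). The initial condition defaults to the steady
state of the first schedule segment, matching the usual pre-growth of
cultures in their starting state. The coupling uses instantaneous upstream
outputs rather than lagged ones — the simplest reading of a per-node ODE
system coupled through steady-state responses; transport delays between
gates are not modeled. Against the closed-form exponential
$y_{ss} + (y_0-y_{ss})e^{-\tau t}$ the integrator agrees to $10^{-6}$
relative, and long-horizon runs converge to the steady-state solver to
$10^{-4}$.

Two choices are defaults rather than measurements: the sensor induction
timescale (2 h⁻¹) and the reporter degradation rate (0.5 h⁻¹, the scale
of growth dilution for a stable fluorescent protein). Both are exposed on
the records and should be refit (`fit_timescales()`, or directly) when
time-course data are available.

## Power accounting

`state_power()` sums RNAP flux over every promoter instance physically
present in the construct: each tandem input promoter separately (the
upstream instance interference-corrected), plus the reporter-driving
output promoter(s). A promoter feeding two gates is two physical instances
and is counted twice. Constitutive promoters on the sensor plasmids
(regulator expression) are outside the circuit construct and excluded.
The module only reports $J_{RNAP}$; no safety threshold is asserted,
because there is no defensible value to assert — the metric is meant for
comparing designs and states, not for pass/fail calls.

## Parameter fitting and the synthetic-data generators

Three fitters mirror the three characterization experiments:

* `fit_hill()` — dose-response sweeps, nonlinear least squares on
  *log*-output residuals (outputs span orders of magnitude and
  cytometry-derived RPU errors are multiplicative), bounded
  Levenberg–Marquardt with 10 seeded multi-starts to avoid local minima in
  $n$; bounds $n \in [0.5, 8]$, all fluxes positive. Flat data are flagged
  non-identifiable rather than raising.
* `fit_interference()` — the four-point tandem-quadrant experiment: an
  upstream sensor promoter (P_Tet levels) in series with the evaluated
  gate's output promoter, the gate driven by a second sensor (P_Tac
  levels). The model is linear in $(\alpha, \alpha\beta)$, so the
  unconstrained linear-space least-squares solution is computed first
  (with four points a variance-stabilizing transform has nothing to gain)
  and projected into $\alpha,\beta \in (0,1]$ by bounded refinement only
  when it falls outside. Estimates at the boundary 1 — additive behavior —
  are flagged. The fitter takes the downstream gate plus per-condition
  promoter levels rather than two gate records: in the characterization
  protocol the upstream partner is a sensor with known flux, not a gate,
  and the estimates are assumed independent of upstream identity.
* `fit_timescales()` — switching time courses, fitting the relevant
  $\tau$ by 1-D least squares between the observed and simulated full
  measurement chain (sensor induction → gate relaxation → reporter
  integration), both normalized at $t=0$, which makes the fit invariant to
  absolute reporter scale.

The generators (`generate_sweep()`, `generate_quadrants()`,
`generate_timecourse()`) evaluate the forward model exactly and apply
multiplicative lognormal noise with a configurable coefficient of
variation — the conventional error model for flow-cytometry medians — with
unit mean so zero CV returns exact model values and fixed seeds reproduce
datasets bit for bit. Their defaults are the characterization conditions:
18 dose points spanning the range reachable with a tandem sensor pair
(0.01–3.65 RPU), quadrant promoter levels at the printed sensor OFF/ON
values, and **three replicate measurements averaged per quadrant
condition**, mirroring the triplicate experimental protocol. The replicate
structure matters: with a single measurement per condition, $\alpha$ of a
strong gate is identified almost entirely by the one condition where the
gate's large $y_{\max}$ dominates the observation, and no estimator can
beat roughly 0.11 median absolute error at 5% CV; triplicate averaging
brings the recovery within the intended bounds.

What the generators do *not* emulate: cell-to-cell distribution shape
(only medians), growth-state dependence of RPU, day effects and instrument
drift, or correlated errors across conditions. Recovery results on
synthetic data therefore demonstrate estimator correctness and
identifiability under the stated noise model, not performance on raw
cytometry.

## Problem sizes used in the shipped studies

The packaged studies run at desk scale, chosen once as representative:
oracle comparisons use randomized circuits with up to 4 gates and
libraries of 5–18 gates; the recovery studies use 50 seeds at 5% CV; the
seven decoder segments are designed with the default annealing schedule;
the digit-cycle simulation covers the full 88-hour, 11-segment schedule at
0.5 h output resolution.

## Known limitations

* Sensor interference parameters are not characterized; the shipped
  defaults make sensor promoters compose additively.
* Population-level (cytometry distribution) prediction and growth-impact
  prediction are out of scope; the power module reports flux only.
* The scoring function is a conventional min-ON/max-OFF ratio, not a
  calibrated reproduction of any specific design tool's objective.
* Wash/resuspension artifacts between schedule segments and
  growth-dilution coupling are not modeled; state is simply continuous
  across boundaries.
* The synthesis gate budget is bounded by the scar set (8 gates) and the
  family count (10) in practice; functions needing more gates fail with a
  capacity error rather than a partial answer.
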
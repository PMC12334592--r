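---
title: "Modeling IKK-to-NF-kB signal transduction under pulsed cytokine stimuli"
author: "nfkbpulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling IKK-to-NF-kB signal transduction under pulsed cytokine stimuli}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfkbpulse)
```

## The problem

Cells decode time-varying cytokine inputs through the IKK--NF-kB axis.
Upstream, ligated receptors nucleate supramolecular complexes (CI,
visualized as EGFP-NEMO puncta) whose *count over time* is the effective
input signal; downstream, NF-kB (RelA) translocates to the nucleus and its
nuclear fold change is the observable output. A striking experimental
phenomenon motivates this package: splitting the same total cytokine
exposure into a train of short pulses (four 1.5-minute pulses instead of one
6-minute pulse) yields receptor-complex trajectories of *comparable area but
much longer adaptation time*, and a disproportionately larger NF-kB
response. The package implements the computational side of that study:

1. an ODE model of NF-kB translocation driven by CI-count trajectories,
   extended with cooperative NF-kB--DNA binding and a chromatin-pioneering
   positive feedback;
2. trajectory statistics -- fold-change AUC, time-to-peak and adaptation
   time, a zero- vs first-order nuclear-export classifier, and elbow-based
   fit-quality classes;
3. particle-swarm calibration with a composite objective and three post-hoc
   error criteria, including the emergent-property score;
4. the chromatin-opening equilibrium sub-model and feature-space scans;
5. two-component FRAP recovery fitting with immobile-fraction estimation;
6. a synthetic-data generator (triangular CI pulses plus paired NF-kB
   cohorts from a known ground truth) so every pipeline stage is testable
   without any experimental download.

## The model

### Base translocation module

The base translocation model this lineage builds on was published with its
rate constants outside any primary text, so we *reconstruct* a base module with
the same architecture -- two negative feedbacks around a
nucleocytoplasmic-shuttling core -- and validate it by behavioral contracts
(basal localization band, pulse responsiveness, adaptation, conservation)
rather than coefficient-level identity. All constants are ordinary entries
of the `ParameterSet` (`default_parameters()`), not hard-coded.

Species: neutral/active/inactive IKK; free NF-kB and free IkBa in cytoplasm
and nucleus; the IkBa:NF-kB complex in both compartments; IkBa mRNA; an
A20-type inhibitor; and, in the extended variant, DNA-bound nuclear NF-kB.
The reactions are:

- **IKK cycle.** CI counts activate neutral IKK bilinearly,
  $\mathrm{rate} = k_a\,\mathrm{IKKSpots}(t)\,\mathrm{IKK}_n$; active IKK
  inactivates at $k_i + k_{A20}\,[\mathrm{A20}]$ and recycles slowly. With
  the default constants, activation is near-saturating in spot number while
  inactivation is fast, so IKK activity *tracks the duration* of the CI
  signal more faithfully than its amplitude -- one of the two ingredients
  of duration sensing.
- **IkBa control.** Free IkBa is intrinsically labile and strongly
  destabilized by active IKK (catalytic degradation of free and complexed
  IkBa); its synthesis has a constitutive core plus NF-kB-inducible
  transcription with mRNA dynamics. IkBa shuttles, captures nuclear NF-kB,
  and exports it as a complex.
- **A20 feedback.** Nuclear NF-kB drives A20 accumulation, which
  accelerates IKK inactivation.
- **Conservation.** NF-kB is neither synthesized nor degraded: the
  volume-weighted total (`total_nfkb()`) is exactly conserved, which the
  test suite asserts to integrator tolerance. IKK is likewise conserved
  through its three-state cycle.

Nuclear species are tracked as nuclear-volume concentrations with the
volume ratio `vol_ratio` ($V_n/V_c$, default 0.2) entering all transport
fluxes, so amounts balance exactly.

### DNA binding and chromatin pioneering

The extended variant adds one species, DNA-bound nuclear NF-kB, with the
binding rate

$$\mathrm{rate} = k_{a1d} \cdot \mathrm{DCoop} \cdot \mathrm{NPio}, \qquad
\mathrm{DCoop} = \frac{(N/k_{dNFKB})^{h_2}}{1 + (N/k_{dNFKB})^{h_2}}, \qquad
\mathrm{NPio} = P_{s0} + P_s\,\frac{(D/K_{DNA})^{h_3}}{1 + (D/K_{DNA})^{h_3}},$$

where $N$ is free nuclear NF-kB and $D$ is DNA-bound NF-kB. DCoop captures
cooperative recruitment; NPio is chromatin permissiveness, a basal openness
$P_{s0}$ (fixed at 1) plus an inducible component that grows with bound
NF-kB -- the pioneering feedback. NF-kB leaves DNA either by direct IkBa
stripping ($k_{a2a}\,[\mathrm{IkBa}_n]\,D$, producing the nuclear complex)
or at a basal rate ($k_{d1d}\,D$).

As printed, the binding law carries no mass-action factor in $N$; DCoop
$\to 0$ as $N \to 0$ supplies the vanishing limit, and the compiled
right-hand side multiplies by the smooth guard $N/(N + 10^{-9})$ purely as
a numerical safeguard against overshoot below zero. This is a solver
protection, not a model change, and is essentially never active.

With the default (ground-truth) constants the half-saturation
$k_{dNFKB}$ sits *below* the stimulated free-nuclear level, so DCoop
saturates during activation and DNA occupancy integrates the **duration**
of nuclear residence rather than its amplitude; $K_{DNA}$ sits above the
occupancy reachable by a short pulse, so only persistent inputs ignite the
pioneering feedback. Those two thresholds are what convert "equal CI area,
longer adaptation" into a disproportionate response.

### Alternative architectures

Two variants extend the *base* model with a different inhibitor instead of
DNA binding: a constitutive IkBb (synthesis independent of NF-kB), and an
NF-kB-inducible IkBe whose transcription is gated by a Hill function of
time since stimulus onset,
$t^{n}/(t^{n} + K_{\mathrm{delay}}^{n})$ with $t$ in seconds and
$K_\mathrm{delay} = 2700$ s (45 min). The gate is evaluated in the
overflow-safe form $1/(1+(K/t)^n)$ so arbitrarily steep exponents remain
finite. Both variants reuse the IkBa interaction structure with their own
constants.

### Units, solver, initialization

Internal model time is **seconds** (the transcription-delay gate is defined
in seconds); all I/O boundaries -- trajectories, features, horizons -- are
in **minutes**. The right-hand side is compiled C called through
`deSolve::lsoda` at `rtol = 1e-8`, `atol = 1e-10`. The forcing
$\mathrm{IKKSpots}(t)$ is evaluated analytically from a sum of four
Gaussians (below), so the solver never sees interpolation kinks. Before any
stimulation the model is integrated for 10 simulated days with the forcing
off (`run_to_steady_state()`); the tests verify the resulting state is
bit-stable against doubling to 20 days. Nuclear fold change is total
nuclear NF-kB (free + complexed + DNA-bound) divided by its pre-stimulus
value, mirroring how experimental traces are normalized by the t = 0
nuclear intensity.

## Synthetic inputs and cohorts

`make_triangular_ci()` builds CI trajectories on the experimental grid (46
points, 4-minute spacing): counts rise linearly from 0 to the peak at
28 min (grid index 7 counting from zero; off-grid peak times snap to the
nearest index and record the snap), fall linearly to zero at the
adaptation time, and are smoothed by a centered rolling mean of width 3.
The window shrinks *symmetrically* at the boundaries, so the t = 0 sample
keeps its raw value of zero -- that anchors the downstream Gaussian fits at
zero, which matters because the model must start from an unstimulated
state. `make_pulse_condition_library()` provides named templates: the
equal-exposure split series (1x6, 2x3, 3x2, 4x1.5 -- constant
peak x adaptation/2 area, trading peak height for persistence), longer
single pulses (1x15, 1x30), and an all-zero control.

Raw count trajectories are converted to model forcing by
`fit_gaussian_sum()`: a least-squares fit of four Gaussians with the t = 0
residual up-weighted (default weight 1000) so the fitted curve starts at
(near) zero. The parameterization is redundant -- only the fitted curve is
meaningful -- so tests assert curve recovery, never parameter identity.

`generate_cohort()` emulates a dual-reporter experiment from a known
ground truth: per cell, the template's peak height and adaptation time are
jittered multiplicatively (lognormal, log-sd `ci_jitter`, default 0.1 --
roughly the cell-to-cell spread visible in single-cell puncta data), the
NF-kB response is simulated, and additive Gaussian noise (sd `noise_sd`,
default 0.05 fold-change units, floored at 0) is applied; t = 0 stays
exactly 1 because it is the normalization reference. The paper supplies no
noise model for synthetic stand-ins, so this simple two-component model
(feature jitter + additive measurement noise) is our own choice,
parameterized and documented here. One master seed determines everything;
per-cell substreams are derived by a counter so partial cohorts reproduce.

**What the generator does not emulate:** receptor-level stochasticity and
cell-cycle heterogeneity, oscillatory IkBa dynamics beyond what the ODE
produces, segmentation/tracking artifacts, non-Gaussian heavy-tailed noise,
and extrinsic parameter variability across cells (every cell shares the
ground-truth kinetics). Passing tests therefore certify the *pipeline* --
generator, model, features, calibration machinery -- on data whose
generating process is known; they do not certify the biological accuracy of
any particular rate constant for real cells.

## Trajectory statistics

- **AUC.** Trapezoidal integral of $\max(\mathrm{FC} - 1, 0)$: baseline
  subtracted, negative excursions clipped.
- **CI features.** `t_max` is the time of the global count maximum (first
  on ties); `t_adapt` is the first time after the peak at which counts fall
  to `adapt_fraction` x peak and stay there. The field usage never pins the
  fraction numerically; we default to 0.1 and expose it. Traces that never
  adapt are right-censored at the last timepoint, all-zero traces are
  flagged undefined.
- **Decay onset.** The global maximum of fold change (first on ties).
  The source procedure is otherwise unspecified; the global maximum is
  deterministic and matches how decay phases are read off published
  single-cell figures. Traces never exceeding baseline (within 1e-6) are
  non-responders with undefined export score.
- **Export-order score.** From onset to trace end, two models are fitted
  with time measured from onset: a line (unconstrained least squares) and
  an exponential $N_0 e^{-kt}$ with $N_0$ pinned to the onset value and
  $k \ge 0.0167\ \mathrm{min}^{-1}$ -- the floor corresponds to ~95%
  nuclear exit within 180 min, and is what forces slower-than-floor decays
  to misfit the exponential. We orient the score as
  $\mathrm{SSE}_{\mathrm{first}} - \mathrm{SSE}_{\mathrm{zero}}$ so that
  **positive = the linear (zero-order) model fits better = zero-order
  export**; this is the only orientation under which the rate floor plays
  its documented role of routing pseudo-zero-order decays to the zero-order
  class. The optimizer upper bound (10 min^-1) is a generous numerical
  limit, not a biological statement.
- **Elbow classification.** Per-cell prediction SSEs are swept as
  candidate thresholds (the sorted unique values); the curve of threshold
  vs count-above-threshold is connected first-to-last by a line and the
  candidate at maximum perpendicular distance is the elbow. Both axes are
  min--max normalized before measuring distances -- the source is silent on
  axis scaling, and normalization makes the elbow invariant to SSE units
  (the suite asserts scale invariance). "Excellent" is SSE at or below half
  the elbow, "high" up to the elbow, "low" above; boundaries are inclusive
  toward the better class; ties break toward the smaller threshold.

## Calibration

The objective equilibrates the model, simulates each training condition
from its condition-average CI input, and sums squared fold-change
residuals over all timepoints and conditions, plus a basal-localization
heuristic: 0 when the pre-stimulus nuclear/cytoplasmic ratio lies in
(0.01, 0.3), a flat 100 below, and $5R$ above (boundary points penalized;
a measure-zero convention). Crashed simulations return a finite sentinel
(1e8) so the swarm keeps moving.

Optimization is standard global-best PSO over log10-transformed parameters:
swarm 100, stall at 20 consecutive iterations without relative improvement
above 1e-6, inertia 0.729, cognitive/social coefficients 1.49445, velocity
clamped to the box range, positions clamped to bounds with the velocity
component zeroed on contact, hard cap 1000 iterations (150--300 in the
desk-scale runs). The coefficients beyond swarm size and stall length are
unstated in the source and are the standard constricted-PSO defaults; all
are arguments. Prior bounds default to +/- 1 decade around the reference
values of the free parameters -- no canonical prior table is available, so
bounds ship as editable configuration, and the
free set defaults to the constants the DNA-binding extension introduces
(plus the CI-coupling rate).

Replicates: production-scale fitting in the source repeats PSO 500 times;
the analysis scripts and tests use 2--10 replicates, which the
optimizer-adequacy tests show suffice on noiseless synthetic data to
recover trajectories within 2% RMS of signal range. Parameters themselves
are not identifiable (the acceptance surface is trajectory space), which
is why recovery is asserted on trajectories, never on rate constants.

The **emergent-property score** compares experimental and simulated
median-AUC ratios (4x1.5/1x6 and 1x15/1x6), with simulated medians taken
over per-cell predictions from each condition's single-cell CI inputs.
The three post-hoc criteria (`evaluate_criteria()`) are this score, the
mean per-condition training SSE, and the summed validation SSE. The
validation set defaults to the remaining named conditions (the source's
five validation conditions are not enumerated; ours are configuration).

## Chromatin-opening sub-model

`free_nfkb_fraction()` isolates DNA binding/unbinding: at fixed total
nuclear NF-kB and *constant* permissiveness (the scanned axis), with
nuclear IkBa frozen at its resting value, the flux balance
$k_{a1d}\,\mathrm{DCoop}(N_{\mathrm{free}})\,\mathrm{NPio}_{\mathrm{const}}\,N_{\mathrm{free}}
= (k_{d1d} + k_{a2a}\,\mathrm{IkBa}_{ss})\,(N_{\mathrm{tot}} - N_{\mathrm{free}})$
is solved by bisection on $[0, N_\mathrm{tot}]$ (the balance is monotone,
so the root is unique). Note the sub-model's binding flux carries the
mass-action factor in free NF-kB, as its defining equations do. Tests
verify strict monotonicity in permissiveness and agreement with a
long-time dynamic integration to 1e-4 relative.

## FRAP

Recovery curves are double-normalized (bleach ROI over its pre-bleach
mean, corrected by the reference trace relative to its pre-bleach mean)
and fitted to
$F(t) = y_0 + A_1(1 - e^{-t/\tau_1}) + A_2(1 - e^{-t/\tau_2})$
with nonnegative amplitudes, multi-started over a grid of $\tau$ decades
(0.1--100 s), canonicalized to $\tau_1 \le \tau_2$, and flagged when the
two components nearly coincide. Whether the original analysis constrained
parameters is unstated; we constrain amplitudes to be nonnegative because
negative components have no physical reading in a recovery curve. The
immobile fraction is $1 - (y_0 + A_1 + A_2)$, and the total immobilized
amount multiplies by the pre-bleach nuclear intensity -- the standard
operationalization of "multiplying the recovery curve by the pre-bleach
nuclear intensity". Default sampling mirrors the experiment: 10 pre-bleach
frames, 0.25-s intervals, 60 s.

## Feature-space scans

`scan_feature_space()` maps peak fold change, export-order score and
relative chromatin permissiveness over a (peak puncta x adaptation time)
grid, with the free-fraction surface on a separate
(total NF-kB x permissiveness) grid. "Relative permissiveness" has no
printed formula in the source; we use the time average of
$(\mathrm{NPio}(t) - P_{s0})/P_s$ over the horizon, with the final-value
alternative behind the `permissiveness = "final"` flag. Failed grid cells
propagate as NA, never interpolated. Trajectories whose fold-change
maximum falls on the final sample are right-censored for the export score
(fewer than 4 post-onset points) and also yield NA.

## Ground-truth parameter choice

The generator's defaults are the study conditions, so they were fixed
once, before the test suite existed, by a scripted search over the
DNA-binding and feedback constants with four requirements: basal
nuclear/cytoplasmic ratio inside the accepted (0.01, 0.3) band with closed
basal chromatin; peak fold change in the few-fold range reported for these
cells; a 4x1.5-vs-1x6 median AUC ratio of at least 2 (the magnitude of the
emergent amplification); and an increased 1x15/1x6 ratio. The selected set
realizes duration sensing through the two thresholds described above
(DCoop saturation below the stimulated level, pioneering ignition above
the short-pulse occupancy) and is frozen in `default_parameters()`.

## Numerical choices and degenerate inputs

- Hill terms evaluate `0^h = 0` for any positive exponent; negative state
  excursions are clamped to zero inside the right-hand side only.
- Simulations erroring, or producing negatives beyond 1e-6 of the NF-kB
  scale, raise errors (calibration converts them to the sentinel); nothing
  is clipped silently.
- All-zero CI traces shortcut the Gaussian fit to exact zeros; all-zero
  feature extraction flags `undefined` rather than returning numbers.
- Ties break toward the earlier index / smaller threshold everywhere.
- Equilibration stationarity is measured relative to a floor of 1e-4 of
  the NF-kB scale so empty species do not dominate the diagnostic.

## Problem sizes

The test suite and analysis scripts run at desk scale by design: cohorts
of 8--20 cells per condition, 10 PSO replicates for the recovery and
model-comparison studies (3 in the acceptance script), hard iteration caps
of 150--300, and 46-point 180-minute horizons throughout. These sizes were chosen
so the full pipeline exercises every code path in minutes; production
fitting would raise replicates (the source used 500) and cohort sizes
without touching any interface.

## Known limitations

- The base module is a behavioral reconstruction, not a coefficient-level
  copy of the published base model; quantities tied to specific published
  rate constants will differ.
- Rate constants are effective, not microscopically measured; the
  chromatin latch can hold DNA-bound NF-kB elevated beyond the 180-min
  horizon, a regime the 180-min window only partially constrains.
- The emergent-property mechanism is threshold-like, so cells jittered
  near the pioneering threshold can classify bimodally -- visible as
  heavy-tailed AUC distributions in jittered cohorts.
- Parameters are non-identifiable from trajectory data alone; all
  recovery claims are trajectory-space claims.
- No receptor-level biophysics, gene-specific promoter models, or parallel
  transcription factors.
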
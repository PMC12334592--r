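# nfkbpulse

Modeling and analysis of IKK-to-NF-kB signal transduction under pulsed
cytokine stimuli.

## The scientific problem

Cytokine-stimulated cells assemble receptor-proximal signaling complexes
(CI, visible as EGFP-NEMO puncta) whose count trajectory drives IKK
activation, IkB degradation, and nuclear translocation of NF-kB (RelA). A
central experimental observation is an *emergent* dose-timing effect:
splitting the same total cytokine exposure into a train of short pulses
(4 x 1.5 min instead of 1 x 6 min) produces CI trajectories of comparable
area but much longer adaptation time, and a disproportionately larger —
more than two-fold — nuclear NF-kB response, together with a switch of
nuclear export kinetics from first-order to pseudo-zero-order and
persistent opening of chromatin.

`nfkbpulse` implements the computational machinery of that study for
researchers in NF-kB signaling and quantitative single-cell biology:

- **ODE model** (compiled C right-hand side, `deSolve`): a two-feedback
  NF-kB translocation module (IkBa transcriptional feedback, A20-type IKK
  inactivation, nucleocytoplasmic shuttling) driven by CI-count
  trajectories through `rate = ka * IKKSpots(t) * IKKn`, extended with
  cooperative NF-kB–DNA binding and a chromatin-pioneering feedback:

  `rate = ka1d * DCoop * NPio`,
  `DCoop = (N/kdNFKB)^h2 / (1 + (N/kdNFKB)^h2)`,
  `NPio = Ps0 + Ps * (D/KDNA)^h3 / (1 + (D/KDNA)^h3)`,

  plus IkBa-stripping (`ka2a * IkBa_n * D`) and basal (`kd1d * D`)
  dissociation. Variants: base model (no DNA binding), delayed-IkBe and
  constitutive-IkBb alternatives.
- **Trajectory statistics**: fold-change AUC (`trapz(max(FC - 1, 0))`),
  CI `t_max`/`t_adapt`, four-Gaussian CI fits used as analytic model
  forcing, a zero- vs first-order export classifier with the
  `k >= 0.0167 min^-1` rate floor, and elbow-based excellent/high/low
  fit-quality classes.
- **Calibration**: global-best particle-swarm optimization (swarm 100,
  stall 20, log10 parameter space) of a composite objective (trajectory
  SSE + basal nuclear/cytoplasmic localization heuristic), with the
  emergent-property score and post-hoc error criteria.
- **Chromatin-opening sub-model**: equilibrium free-NF-kB fraction at
  fixed permissiveness, and feature-space scans over peak x adaptation.
- **FRAP**: double normalization, two-component recovery fitting,
  immobile-fraction estimation.
- **Synthetic data**: triangular CI pulse generator (46-point, 4-min grid,
  peak at 28 min) and paired NF-kB cohorts from a known ground truth, so
  the whole pipeline is testable end to end without any download.

## Worked example

The `analysis/` directory is a numbered workflow. The first two steps
generate the demo cohort and extract features:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_trajectory_features.R
```

which prints (seed 2026, 20 cells/condition, lognormal CI jitter 0.1,
fold-change noise sd 0.05):

```
Per-condition medians:
  condition auc_nfkb auc_ci t_adapt
1      1x15    278.1   7372      78
2      1x30    536.3  14684     112
3       1x6    135.2   3728      56
4       2x3    172.2   3400      66
5       3x2    240.4   3643      78
6     4x1.5    344.4   3731      98

Export-order classification (fraction zero-order):
   1x15    1x30     1x6     2x3     3x2   4x1.5
   1.00    1.00    0.00    0.45    1.00    1.00

Emergent amplification: median AUC(4x1.5)/AUC(1x6) = 2.55, AUC(1x15)/AUC(1x6) = 2.06
```

Read: the four equal-exposure conditions (1x6, 2x3, 3x2, 4x1.5) have
nearly identical CI area (`auc_ci` ~3400–3700 puncta·min) but adaptation
times rising from 56 to 98 min, and the NF-kB response (`auc_nfkb`) rises
monotonically with persistence — the 4x1.5 pulse train delivers 2.55x the
single-pulse response. Export kinetics switch from first-order (1x6, all
cells) to pseudo-zero-order (4x1.5, all cells), with the intermediate 2x3
condition split across the threshold (45% zero-order). Subsequent steps
calibrate the model by PSO (`03_calibrate.R`), compare model architectures
on the emergent-property score (`04_model_comparison.R`), scan the
CI-encoding space (`05_feature_space_scan.R`), and fit synthetic FRAP
recoveries (`06_frap.R`), each writing tables under `results/`.

In code, the core loop is three calls:

```r
library(nfkbpulse)
p   <- default_parameters("d2fc2")           # ground-truth parameter set
m   <- build_model("d2fc2", params = p)
ci  <- make_triangular_ci(peak_height = 70, adaptation_time = 103)
sim <- simulate_response(m, ci_input = ci)   # equilibrates, then simulates
max(sim$fold_change)                         # ~3.8-fold nuclear accumulation
auc_fold_change(sim_to_nfkb_trajectory(sim)) # fold-change AUC
```

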
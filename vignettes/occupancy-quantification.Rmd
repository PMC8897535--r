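---
title: "Quantifying target occupancy with an irreversible PET radioligand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying target occupancy with an irreversible PET radioligand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petocc)
```

## The quantification chain

`petocc` implements the analysis pipeline of a PET occupancy study built on
an irreversibly binding radioligand. The pipeline starts at tabular data —
regional time–activity curves (TACs), arterial blood measurements, plasma
drug concentrations, organ uptake tables — and produces influx constants,
occupancies, an EC50, and radiation-dose estimates. Image reconstruction,
coregistration and ROI delineation are upstream of the package and out of
scope.

The stages, in the order a study runs them:

1. **Input function.** The continuous whole-blood curve from an automated
   blood sampling system (ABSS, first ~3 min) is scaled to plasma units by a
   constant plasma-to-whole-blood ratio and spliced with the later discrete
   plasma samples (`merge_blood_curves`). A Hill model fitted to measured
   parent fractions (`fit_parent_fraction`) converts total plasma activity to
   the metabolite-corrected input function Cp(t) (`metabolite_correct`).
2. **Kinetics.** The irreversible two-tissue-compartment model (k4 = 0) is
   fitted to each regional TAC against Cp (`fit_2tc`), giving K1, k2, k3 and
   the influx constant Ki = K1·k3/(k2+k3). Patlak graphical analysis
   (`patlak`) provides an independent Ki estimate as the slope beyond t\*.
3. **Occupancy.** For each baseline/pretreatment scan pair, occupancy is the
   fractional Ki reduction per region, averaged across regions
   (`occupancy_from_ki`, `average_occupancy`). The drug exposure metric is
   Cave, the mean plasma drug concentration at −1 and +30 min relative to
   tracer injection (`cave`).
4. **Dose–response.** Occ = Emax·C/(EC50+C) with Emax fixed at 100% is fitted
   to the (Cave, occupancy) pairs by unweighted least squares (`fit_emax`).
5. **Dosimetry.** Whole-body organ %ID curves are integrated with physical
   decay weighting into residence times (`residence_time`), multiplied
   through a user-supplied S-value table into organ doses (`absorbed_dose`)
   and a tissue-weighted effective dose (`effective_dose`).

## Model assumptions

* **Irreversibility.** Trapping is effectively irreversible on the scan's
  time scale, so k4 = 0; the diagnostic `tissue_plasma_ratio` should rise
  continuously through the quantification window, and the optional
  4-parameter fit (`fit_2tc(..., k4 = "free")`) should not be preferred by
  AIC. The reversible fit exists for exactly this model check.
* **30-min window.** Parameter estimation uses frames with midpoints up to 30
  min (`window_end = 30`). Late-phase parent-fraction measurements are
  unreliable for rapidly metabolised ligands, and the metabolite model is
  only trusted inside the window it was fitted on.
* **Blocking acts on trapping.** Drug pretreatment reduces k3 (specific
  trapping) and leaves K1 and k2 (delivery, clearance) untouched.
* **No blood-volume term by default** (`vB = 0`): the model is the
  3-parameter configuration. A fractional blood volume is available as a fit
  option using Cp as the blood proxy.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `window_end` | 30 | min | metabolite correction trusted only to 30 min |
| `t_star` (Patlak) | 10 | min | transients with k2+k3 ≈ 1–2/min decay well before 10 min |
| `weights` | frame duration | — | counting variance shrinks with frame length |
| fit bounds | [0, 10] | 1/min | generous physiological envelope |
| `n_starts` | 5 | — | log-spaced multi-start against local minima |
| `emax` | 100 | % | full occupancy attainable for a competitive inhibitor |
| `half_life` | 20.364 | min | carbon-11 |

## Numerical choices

* **Analytic forward model.** The 2TC solution is the convolution of Cp with
  a sum of exponentials. Because the input-function contract is
  piecewise-linear, each segment's convolution integral has a closed form and
  the solution is computed by an exact O(n) recursion — no ODE step-size
  error. The test suite compares it against brute-force RK4 integration at
  dt = 0.001 min and requires agreement to 0.1%.
* **Frame averaging.** Fitted model values are the average of the solution
  over each frame (trapezoid on a sub-grid of ≤ 0.02 min, at least 21 nodes
  per frame), not the midpoint value: with 3–6-min frames and a curving TAC,
  midpoint sampling is biased. Patlak's ratio variables, by convention, use
  frame midpoints.
* **Optimisation.** Bounded Levenberg–Marquardt (`minpack.lm::nls.lm`,
  `ftol = ptol = 1e-12`) restarted from 5 log-spaced points; lowest weighted
  RSS wins, ties broken by the smaller k3. The EC50 fit is 1-D and solved by
  `optimize` on log-EC50 over [1e-6, 1e6] ng/mL, with `ec50_grid_scan`
  (10 001-point log grid) available as a brute-force cross-check.
* **Degenerate inputs.** An all-zero TAC returns a flagged zero fit rather
  than an error; constant parent-fraction samples return a constant model;
  occupancy is undefined (error) for non-positive baseline Ki; fp is clipped
  to [0, 1]; Ki with k2 = k3 = 0 is defined as 0 with a warning.
* **Residence times.** %ID curves are piecewise-linear; the decay-weighted
  integral of each segment is computed analytically, so the decay-only bound
  (T½/(ln2·60) h) is exact at any sampling. After the last pass (~5
  half-lives for C-11) the tail assumes physical decay only — conservative,
  and contributing <1% of τ. Before the first pass, fractional uptake is held
  at its first observed value. Unaccounted whole-body residence goes to a
  `remainder` source when the S-table has one.

## Design decisions that were genuinely open

* **Blood merging.** The merge procedure for ABSS + discrete samples is
  rarely published. Here the scaled continuous curve is kept over its entire
  span (it is the higher-resolution measurement); discrete samples inside
  that span serve to estimate the plasma-to-whole-blood ratio and to check
  junction consistency (warning above 5% disagreement), and samples beyond it
  extend the curve. Discarding the continuous tail in favour of a sparse
  early sample would linearise the steepest part of the curve.
* **Metabolite correction on a refined grid.** Cp = plasma × pf is evaluated
  on the plasma samples plus a 0.1-min refinement grid, so the smooth
  curvature of the parent-fraction model between sparse late samples is
  preserved instead of being linearised between plasma sample times.
* **Occupancy truth in Ki space.** In the synthetic generator, "true
  occupancy" is the fractional reduction of Ki, because that is the quantity
  the study's occupancy equation measures. The pretreatment k3 is derived by
  inverting Ki (k3′ = k2·r/(1−r), r = (1−Occ)·k3/(k2+k3)). Scaling k3 itself
  by (1−Occ) would define occupancy at the enzyme level; for an irreversible
  tracer with high baseline k3 the two differ materially (uptake is
  flow-limited at baseline), and a Ki-based pipeline cannot — and should
  not — recover a k3-space truth. The limiting cases coincide: occupancy 0
  leaves k3 unchanged, occupancy 1 forces k3′ = 0.
* **Emax fixed at 100%** with the apparent outlier pair retained and
  occupancies above 100% unclipped: the dose–response fit uses all
  information as measured. Free-Emax fitting exists (`emax = NULL`) for
  sensitivity analysis.
* **S-values are user-supplied.** Phantom S-value tables are proprietary to
  dosimetry packages; `petocc` ships only a clearly labelled synthetic toy
  table (`s_values_synthetic.csv`) for testing the chain's arithmetic.
  Published organ-dose tables for a particular phantom are therefore not
  reproduction targets of this package.

## What the synthetic generator does and does not emulate

`simulate_study` generates: a Feng-type tri-exponential plasma curve (linear
rise after a 0.5-min delay; single peak; pretreatment scans scaled 1.8× to
mimic the higher plasma peak seen under peripheral blocking), a Hill parent
fraction (floor 0.03, t50 8 min, h 2 — below 10% parent by 30 min), tissue
TACs as exact frame averages of the 2TC model for seven regions with
delivery ~0.5–0.9 mL/ccm/min and trapping ~0.7–1.3/min, ABSS + discrete
blood sampling (continuous 0–3 min at 1 s; discrete at 2, 4, 10, 20, 30, 60
min, the 2-min draw for metabolism only), and drug concentrations declining
mono-exponentially (4-h half-life from administration at −63 min) scaled so
Cave lands on the Emax curve at the scenario's true occupancy, with a
below-detection-limit flag under 0.05 ng/mL.

Frame noise is zero-mean Gaussian with standard deviation proportional to
sqrt(activity/frame duration) — the standard frame-weighting surrogate. Real
HRRT noise is Poisson-like and correlated through reconstruction; the
generator does not emulate that, nor motion, scatter, partial-volume effects,
or between-animal parameter variability. Passing recovery tests on these
simulations therefore demonstrates the correctness of the estimation chain
under its own assumptions, not robustness to every property of real scanner
data.

All stochastic draws derive from the scenario seed; identical scenarios are
reproducible byte-for-byte.

## Problem sizes used in the test suite

The tests run the "brain63" schedule (33 frames, 63 min) with the
seven-region parameter set: solver-versus-ODE comparisons on a 3×3×3 grid
spanning the regional parameter ranges; noise studies with 100–200 replicate
TACs; full-pipeline recovery at occupancies 25/50/75/95%. These sizes mirror
the scale of the emulated study (seven animals, paired scans) while keeping
the default suite fast.

## Known limitations

* No delay/dispersion correction of the ABSS segment; if the measured curve
  needs one, apply it before `merge_blood_curves`.
* The plasma-to-whole-blood ratio is a single constant; a time-varying ratio
  is not modelled.
* No reference-tissue or voxelwise (parametric image) methods: an
  irreversible ligand for a ubiquitous enzyme has no reference region.
* The dosimetry remainder rule is the simple subtraction floor-at-zero
  scheme; dynamic bladder voiding and phantom-specific remainder handling
  are not implemented.
* Occupancy via Ki underestimates enzyme-level blocking when baseline uptake
  is flow-limited (k3 ≫ k2); consequently an EC50 from Ki-based occupancies
  is an upper bound on the enzyme-level EC50. The package quantifies what
  the measurement defines; it does not correct for this bias.
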
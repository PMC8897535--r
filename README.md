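# petocc

Quantification chain for PET target-occupancy studies with **irreversibly
binding radioligands**: compartmental and graphical kinetic analysis of brain
time–activity curves (TACs) against a metabolite-corrected arterial input
function, drug-occupancy estimation from baseline/pretreatment scan pairs, an
Emax concentration–occupancy model for EC50, and MIRD-style residence-time
dosimetry from whole-body organ uptake curves.

It is written for imaging pharmacologists who start from ROI-level tabular
data (frame times, kBq/cc) rather than image volumes — for example a
non-human-primate occupancy study of an enzyme inhibitor, where each animal is
scanned at baseline and again after drug pretreatment.

## The model

Tracer kinetics follow the two-tissue-compartment (2TC) model with
irreversible trapping (k4 = 0):

    dC1/dt = K1·Cp − (k2 + k3)·C1
    dC2/dt = k3·C1
    C_T    = C1 + C2

where Cp is the metabolite-corrected arterial plasma activity, K1
(mL/ccm/min) and k2 (1/min) are delivery and clearance, and k3 (1/min) is
trapping into the specific compartment. The net influx constant

    Ki = K1·k3 / (k2 + k3)      (mL/ccm/min)

is the primary outcome; it is also estimated independently as the Patlak
slope of C_T(t)/Cp(t) versus ∫₀ᵗCp ds / Cp(t) beyond an equilibration time
t\*. Occupancy of a scan pair is

    Occ(%) = 100 · (Ki_baseline − Ki_pretreatment) / Ki_baseline

averaged over regions, and the concentration–occupancy relation is the Emax
model Occ = Emax·C/(EC50 + C) with Emax fixed at 100%. Dosimetry converts
organ %ID curves to residence times τ = ∫(%ID/100)·e^(−λt) dt and doses
D_T = Σ_S τ_S·S(T←S).

The forward 2TC solution is computed analytically (exact convolution of the
exponential kernel with the piecewise-linear input function), not by ODE
stepping; an independent brute-force ODE integration is used only in the test
suite as an oracle.

## Worked example

Everything is testable without scanner data through the synthetic-study
generator, which emulates the measurement chain (Feng-type plasma input,
Hill-shaped parent fraction, frame-averaged 2TC tissue curves, drug
concentrations on an Emax curve):

```r
library(petocc)

study <- simulate_study(study_scenario(occupancies = c(0.25, 0.75), ec50 = 1.3))
res <- analyze_scan_pair(study$baseline, study$pretreatment[[2]], method = "patlak")
round(res$occupancy, 1)
#>      cerebellum         caudate         putamen        thalamus  frontal cortex
#>            75.0            75.0            75.0            75.1            75.3
#> temporal cortex     hippocampus
#>            75.2            75.1
```

The region-averaged occupancy (75.1%) recovers the simulated truth (75%).
Fitting a single noisy regional TAC shows why Ki — not k3 — is the stable
outcome measure: individual rate constants trade off against each other under
noise while their Ki combination stays put,

```r
ifn <- simulate_input_function(feng_params(), sort(unique(c(seq(0, 3, 1/60), seq(3, 63, 0.05)))))
sch <- frame_schedule("brain63")
tac <- simulate_tissue_tac(c(0.849, 0.645, 0.750), ifn, sch, noise_level = 0.05, seed = 7)
fit_2tc(tac, ifn)        # true Ki = 0.4565
#> Irreversible 2TC fit, 28 frames, window 0 - 30 min
#>   K1 = 0.7617 mL/ccm/min, k2 = 0.3510, k3 = 0.5244, k4 = 0.0000 /min
#>   Ki = 0.4563 mL/ccm/min, WRSS = 0.2688
patlak(tac, ifn)
#> Patlak analysis (t* = 10 min, 6 points): slope 0.4571 mL/ccm/min, intercept 0.3556, R^2 0.9997
```

The packaged study table (`occ_conc_nhp.csv`: per-animal plasma drug
concentration and Patlak-derived occupancy, one pair excluded for a
below-detection-limit concentration) gives the dose–response fit:

```r
occ_tab <- read_occ_conc_table(petocc_example("occ_conc_nhp.csv"))
pairs <- occ_tab[occ_tab$method == "patlak" & !is.na(occ_tab$cave_ng_per_ml), ]
fit_emax(pairs$cave_ng_per_ml, pairs$occupancy_pct)
#> Emax occupancy model: EC50 = 1.266 ng/mL, Emax = 100% (fixed), n = 9
```

i.e. EC50 = 1.3 ng/mL at one-decimal precision: half-maximal enzyme occupancy
is reached at very low plasma drug exposure.

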
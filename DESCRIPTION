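Package: petocc
Title: PET Target-Occupancy Quantification with Irreversible Tracer Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantification chain for PET enzyme/receptor occupancy studies
    with irreversibly binding radioligands. Fits the irreversible
    two-tissue-compartment model (k4 = 0) and Patlak graphical analysis to
    regional brain time-activity curves against a metabolite-corrected
    arterial input function, derives the influx constant Ki, computes
    drug-induced target occupancy from baseline/pretreatment scan pairs,
    fits the Emax concentration-occupancy model for EC50 estimation, and
    performs MIRD-style residence-time dosimetry from whole-body organ
    uptake curves. Includes a synthetic-study generator emulating the
    statistical structure of a non-human-primate occupancy study, so the
    full pipeline is testable without raw scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm
Suggests: testthat (>= 3.0.0), deSolve, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
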
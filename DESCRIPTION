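Package: lambdahop
Title: Replica-Exchange Protocol Comparison for Alchemical Free-Energy
    Calculations on a Surrogate Torsional System
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale comparison of enhanced-sampling protocols used in
    alchemical free-energy calculations: solute-tempering Hamiltonian
    replica exchange (t-REM/ST-HREM), pure lambda-hopping, and
    lambda-hopping with a hot-zone scaling profile (FEP+ style). The
    physical stand-in is a one-dimensional torsional double well with a
    barrier of about 40 kcal/mol plus harmonic solvent coordinates, so
    every quantity of interest (E/Z free-energy gap, torsional free-energy
    profile, per-state partition-function ratios, hydration free energy)
    has an exact quadrature or closed-form oracle. Includes a Metropolis
    Monte Carlo replica-exchange engine, MBAR and BAR estimators, a
    stratified free-energy pipeline with a two-isomer mixture identity,
    and replica-exchange health diagnostics (exchange ratios, round-trip
    times, initial-condition-dependence detection).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
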
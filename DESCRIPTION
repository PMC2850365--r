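Package: endoforce
Title: Active and Passive Microrheology of Magnetic Endosomes and
    Intracellular Force Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for combined active and passive intracellular
    microrheology with chains of magnetic endosomes. Converts forced-oscillation
    records (field amplitude, chain amplitude, phase lag) into the complex shear
    modulus via the magnetic torque balance, estimates time-averaged mean-square
    displacements and anomalous exponents from particle tracks, quantifies the
    violation of the fluctuation-dissipation theorem through a lag-dependent
    effective temperature, inverts a generalized Langevin equation to obtain the
    power spectrum of active forces on endosomes, and fits a renewal step-force
    motor model (power-law distributed on-times, exponential dwells) to those
    spectra. A synthetic-data module generates Newtonian calibration tracks,
    fractional-Gaussian thermal tracks in a power-law medium, actively driven
    tracks, and oscillation records with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
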
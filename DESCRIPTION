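Package: helixspec
Title: Amide I Exciton Spectroscopy and Conformational Analysis of Helical Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the amide I vibrational spectroscopy and
    conformational dynamics of alpha-helical peptides, built around the myosin
    relay helix. Provides seeded synthetic generators for ideal and bent helix
    backbones, noisy trajectories with switchable i->i+4 hydrogen bonds, tilted
    two-dimensional Gaussian 2D-IR surfaces, bi-exponential decays, circular
    dichroism curves and analytic double-well landscapes; construction of
    per-frame exciton Hamiltonians (site frequencies, transition-dipole
    couplings, transition dipoles); linear amide I spectra by time-domain
    propagation and by stick spectra, with eigenmode delocalization diagnostics
    (inverse participation ratios, oscillator strengths, densities of states);
    purely absorptive 2D-IR spectra by numerical integration of the Schrodinger
    equation with perturbative two-quantum states; bounded tilted-Gaussian peak
    volume fitting with diagonal-volume ratio series; pump-probe isotropic
    signals with bi-exponential kinetics and fractional helicity from molar
    ellipticity at 222 nm; and hydrogen-bond, principal-component and
    well-tempered metadynamics free-energy-surface analysis of trajectories.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
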
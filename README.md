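# helixspec

Amide I exciton spectroscopy and conformational analysis of helical
peptides, built around the myosin relay helix — the long alpha-helix in the
myosin motor domain whose bent-to-straight transition couples ATP hydrolysis
to the power stroke.

The package is for spectroscopists and simulators who want to connect
backbone conformation (which i → i+4 hydrogen bonds are formed) to amide I
vibrational observables (linear FTIR, 2D-IR, pump-probe) and to free-energy
landscapes over hydrogen-bond distances, without depending on any external
simulation engine: every input the pipeline consumes can be generated
synthetically, with seeds, inside the package.

## What it computes

**Exciton model.** For a backbone trajectory, each carbonyl is an amide I
oscillator. Per frame the package builds the N × N site Hamiltonian — site
frequencies ω_n on the diagonal (a pluggable electrostatic map), couplings
J_nm off-diagonal (transition-dipole coupling,
J = k [ û_n·û_m − 3(û_n·r̂)(û_m·r̂) ] |μ|² / r³, with a constant
nearest-neighbour term) — plus per-site transition dipoles. The relay-helix
peptide (35 residues, acetyl cap, C-terminal acid) carries N = 36
oscillators.

**Linear spectra.** I(ω) = Re ∫ dt e^{−iωt} Σ_nm Σ_j μ_n^j(0) F_nm(t)
μ_m^j(t) e^{−t/2T}, with F(t) the time-ordered one-exciton propagator
(NISE), and the stick approximation I(ω) = Σ_n δ(ω − E_n) |μ_n|². Eigenmode
diagnostics are binned by frequency: density of states, oscillator strength,
squared site components and the inverse participation ratio
IPR = 1 / Σ_n φ_jn⁴ (1 = localized, N = fully delocalized).

**2D-IR.** Purely absorptive spectra (rephasing + non-rephasing) from
ground-state-bleach, stimulated-emission and excited-state-absorption
pathways evaluated by chained one-exciton propagators, with two-quantum
states treated perturbatively (site-pair basis, diagonal anharmonicity Δ).

**Peak volumes.** 2D-IR snapshots are fit by tilted 2D Gaussians (30°
diagonal peaks, 0° cross-peaks; each fundamental paired with an equal
negative lobe displaced by its anharmonicity along ω_m) under bounded
deterministic least squares; volumes are 2πAσ_τσ_m and the
high/low diagonal-volume ratio is tracked across wait times.

**Observables.** Isotropic pump-probe signal P = (S_∥ + 2S_⊥)/3 with
bi-exponential kinetics A₁e^{−B₁t} + A₂e^{−B₂t}; the μ⁴-vs-μ² consistency
check (a pump-probe peak ratio should be the square of the linear band
ratio); and fractional helicity from CD,
f_H = ([θ]₂₂₂ − θ_C)/(θ_H − θ_C), θ_C = 2220 − 53T,
θ_H = (−44000 + 250T)(1 − 3/N_r).

**Conformation.** Hydrogen-bond distance series with the 0.35 nm cutoff,
essential-dynamics PCA with pseudo-trajectories, well-tempered metadynamics
on analytic double-well landscapes (overdamped Langevin walker, shrinking
Gaussian hills), and FES analysis: minima, ΔG in kJ/mol and kT, bottleneck
barriers.

## Worked example

```r
library(helixspec)
library(dplyr)

# bent relay helix with the two hinge hydrogen bonds broken
bent <- make_bent_helix(relay_helix_peptide(), list(c(22, 26), c(23, 27)))
hbond_series(bent) |> filter(!formed)
#> # A tibble: 2 × 6
#>   frame acceptor donor distance_nm measurable formed
#>   <int>    <int> <int>       <dbl> <lgl>      <lgl>
#> 1     1       22    26       0.402 TRUE       FALSE
#> 2     1       23    27       0.373 TRUE       FALSE

# the peptide carries 36 amide I oscillators; a fully delocalized mode has
# IPR equal to that count
nrow(enumerate_oscillators(relay_helix_peptide()))
#> [1] 36
ipr(rep(1 / 6, 36))
#> [1] 36

# fractional helicity from molar ellipticity at 222 nm, 70 degrees C
helical_fraction(-14223.6, temperature_c = 70, nr = 35)$fh
#> [1] 0.56

# diagonal-volume ratios across wait times from fitted 2D-IR peak volumes
ratio_series(tibble::tibble(t_w = c(0.5, 0.7),
                            diag_low = c(8324, 6010),
                            diag_high = c(4420, 3582)))
#> # A tibble: 2 × 5
#>     t_w diag_low diag_high defined ratio
#>   <dbl>    <dbl>     <dbl> <lgl>   <dbl>
#> 1   0.5     8324      4420 TRUE    0.531
#> 2   0.7     6010      3582 TRUE    0.596
```

The broken pairs are exactly the two requested; the ratio at 0.7 ps rounds
to 0.60, the peak of the wait-time trend.

Every result type has `tidy()`/`glance()` and `autoplot()` methods, and the
whole pipeline is scriptable through JSON configs via `run_stage()` (or the
`inst/scripts/helixspec` wrapper), with provenance sidecars written next to
every artifact.

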
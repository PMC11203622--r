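---
title: "Models and methods behind helixspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind helixspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixspec)
```

helixspec models how the conformational state of an alpha-helical peptide —
concretely, the myosin relay helix — expresses itself in amide I vibrational
spectroscopy, and how free energy distributes over the hydrogen-bond
coordinates that define that state. This vignette is the package's account
of the underlying models, the conventions and defaults it fixes, and what
its synthetic data do and do not establish about real measurements.

## Synthetic structures

The chain builder constructs backbones in internal coordinates with fixed
standard geometry, one dihedral pair per residue. The constants are:

| quantity | value |
|---|---|
| N–CA, CA–C, C–N bonds | 0.1458, 0.1525, 0.1329 nm |
| C=O, N–H bonds | 0.1229, 0.1010 nm |
| N–CA–C, CA–C–N, C–N–CA angles | 111.2°, 116.2°, 121.7° |
| CA–C–O angle | 120.8° |
| omega | 180° (trans) |

Carbonyl oxygens are placed sp²-planar trans to the following amide
nitrogen; amide hydrogens sit in the peptide plane trans to the preceding
carbonyl oxygen. With the alpha-helical defaults phi/psi = −57.8°/−47.0°
this yields interior O(i)···H(i+4) distances of 0.206 nm and a rise of
0.154 nm per residue — comfortably inside the 0.35 nm hydrogen-bond cutoff
used throughout. These are idealized force-field-free geometries: they
carry no side chains (beyond the identity bookkeeping needed for residue
naming), no solvent, and no thermal anharmonicity.

Bent conformers are produced by rigid hinge rotations: for a requested
break (i, i+4), all atoms downstream of the CA of residue i+1 rotate about
an axis through that CA, and a bounded backtracking search over bend angles
(8–72°) and axis directions selects the first geometry in which exactly the
targeted O···H distances exceed the cutoff (by ≥ 0.01 nm) while every other
measurable pair stays formed (≤ cutoff − 0.01 nm). Because no experimental
bent-conformer coordinates are bundled, this construction is the package's
own artifact: it preserves ideal helical geometry exactly within each rigid
segment (piecewise RMSD to the ideal helix is zero), which is what the
structural tests exploit. What it does not emulate is the gradual curvature
of crystal-structure bends.

Multi-frame trajectories add isotropic per-atom Gaussian noise and,
optionally, two-state Markov switching of designated hydrogen bonds: each
switching pair toggles formed/broken with a per-frame probability, and the
broken geometry is the hinge construction above. This reproduces
break-and-reform *statistics* at controllable rates, not the mechanics of
bond breakage; its stationary broken fraction (1/2 for the symmetric
chain) and autocorrelation (1 − 2p per frame) are the quantities the tests
pin down. All generators are pure functions of their arguments and seed.

## The exciton Hamiltonian

Each backbone carbonyl is one amide I chromophore, ordered N→C: the acetyl
cap carbonyl, the 34 peptide-bond carbonyls, and the C-terminal acid
carbonyl — 36 for the relay-helix peptide. Counting the terminal acid
carbonyl (rather than a side-chain amide) as the 36th oscillator is a
documented convention; it reproduces the peptide's eigenstate count with
the stated caps.

Published amide I maps are parameterized against force-field
electrostatics that are out of scope here, so the default `site_map()` is
deliberately self-contained:

* site frequency = 1650 cm⁻¹ + c · (φ_O − φ_C), with φ the Coulomb
  potential of user-supplied point charges (e/nm) at the carbonyl O and C
  and c = −400 cm⁻¹ per e/nm. With no charges supplied every site sits at
  the base frequency. The map is linear in the sources by construction.
* transition dipoles of 0.37 D sit 0.0868 nm from C along C=O, tilted 20°
  toward the amide N in the O–C–N plane (the terminal acid carbonyl, which
  has no following N, keeps the C=O direction).
* couplings: transition-dipole coupling with the vacuum constant
  k = 5034.1 cm⁻¹·Å³·D⁻² for non-adjacent pairs; nearest neighbours use a
  constant −7 cm⁻¹ in place of a dihedral-indexed lookup. Both the map and
  the nearest-neighbour rule are pluggable fields, so externally
  parameterized tables drop in unchanged.

One consequence worth stating plainly: under this default map the helical
bright mode lands roughly 50 cm⁻¹ below the site frequency (the TDC sums
over i±3/i±4 contacts are negative in the ideal helix), so *absolute* band
positions are map conventions here. Everything the package's analyses rely
on — symmetry, dipole-strength conservation, delocalization, relative
structure between straight and bent conformers — is map-independent.

## Linear spectra and eigenmode diagnostics

The time-domain route propagates the three lab-axis dipole vectors with
per-frame matrix exponentials over the stored frame spacing (propagators
are unitary to 1e−9 per step; a rotating frame at the mean site frequency
keeps phases far from Nyquist), damps with exp(−t/2T), and Fourier
transforms directly onto the requested grid with a half-weighted t = 0
point. The default lifetime is T = 1 ps — a typical amide I value, exposed
as a parameter — giving a Lorentzian HWHM of 1/(4πcT) ≈ 2.65 cm⁻¹. The
default correlation window is 16 ps (truncation below 3e−4 of the signal)
with no apodization, which is what makes the static-Hamiltonian spectrum
agree with the lifetime-broadened stick spectrum to better than 0.1%; a
half-cosine window is available for noisy trajectory input. Trajectories
shorter than the window are recycled periodically, and the correlation
function can be averaged over evenly spaced start frames.

Per-frame diagonalization feeds the frequency-binned diagnostics: density
of states (sums to N per frame), oscillator strength, mean squared site
components, and IPR = 1/Σφ⁴ ∈ [1, N]. Binning is per frame followed by
time averaging.

Second derivatives of spectra use a Savitzky–Golay filter (default window
11 points, order 3) on the native uniform grid; band ratios read local
maxima within ±3 cm⁻¹ of the requested positions (a nearest-grid-point
mode exists), which is the robust reading of "peak height".

## 2D-IR

The third-order response is evaluated pathway by pathway
(bleach, stimulated emission, excited-state absorption; rephasing and
non-rephasing) with the same one-exciton propagators. Two-quantum states
are handled perturbatively in the site-pair basis: the doubly excited
wavepacket is carried as a symmetric N × N amplitude matrix whose harmonic
propagation is exactly U C Uᵀ, with the site anharmonicity Δ applied as an
extra phase on doubly occupied diagonal entries each step. Creation and
annihilation follow harmonic (bosonic) dipole scaling, so at Δ = 0 the
excited-state-absorption pathways cancel bleach plus stimulated emission
identically — the suite asserts this to 1e−10 — and uncoupled oscillators
factorize with no cross-peak pathways. The default Δ = 16 cm⁻¹ sits inside
the 10–20 cm⁻¹ range the peak fitter scans; it is flagged as an assumption
and exposed everywhere.

Lifetime damping multiplies the coherence intervals as exp(−(t₁+t₃)/2T)
and the waiting interval as exp(−T_w/T). The population-decay factor is
required for the physically expected monotone loss of signal with wait
time in a static system; a damping model confined to coherence times only
would leave static-system spectra wait-time-independent.

Spectra are cosine-apodized with half-weighted time origins and evaluated
by a direct discrete Fourier transform onto the requested frequency axes —
the infinite-zero-padding limit of padded FFTs, chosen so output grids are
arbitrary and bit-stable. Orientational averaging is the isotropic
three-axis j-sum consistent with the linear-spectrum expression; full
four-point orientational tensors and polarization-controlled signals are
out of scope. On one CPU a 36-oscillator, 2000-frame trajectory at one
wait time completes comfortably within minutes at the default 0.02 ps
frame spacing and 2 ps coherence windows.

## Tilted-Gaussian peak volumes

The fitted model is fixed by convention: each peak is a positive rotated
Gaussian plus an equal-magnitude negative lobe displaced by its
anharmonicity along ω_m, sharing widths and amplitude; tilts are 30° for
diagonal peaks and 0° for cross-peaks; the reported volume of a peak is
its positive-lobe magnitude 2πAσ_τσ_m. The "scanned" parameter ranges are
implemented as box constraints around fixed starting values — a single
deterministic bounded Levenberg–Marquardt run, not a stochastic or grid
search — with two presets (an experimental-range set and a
computational-range set) covering amplitudes, centres, widths and
anharmonicities. Cross-peak centres follow the fitted diagonal centres,
which reproduces the intended search space with fewer free parameters.
Adding cross-peaks can only lower the optimal residual (the models nest);
generate-and-refit on synthetic surfaces recovers volumes within 5% at
signal-to-noise 20. Whether tabulated volumes are signed is resolved here
as: volumes are positive-lobe magnitudes.

## Pump-probe, kinetics and CD

The isotropic signal is (S_∥ + 2S_⊥)/3 pointwise. Bi-exponential fits use
points beyond 0.5 ps with deterministic initialization (A₁ = first signal
in the window, B₁ = 1 ps⁻¹, A₂ = 0.1A₁, B₂ = 0.1 ps⁻¹), report the faster
rate first, flag effectively single-exponential solutions, and return a
flagged null fit on degenerate all-zero input. The μ⁴ consistency check is
the identity r → r²: pump-probe absorbance scales as the fourth power of
the transition dipole where linear absorbance scales as the square.

For CD, the printed form of the helicity relation is typographically
ambiguous in two places. The implemented reading is the standard Baldwin
convention f_H = (θ₂₂₂ − θ_C)/(θ_H − θ_C) — the printed denominator
(θ₂₂₂ − θ_H) would make f_H nonlinear and miss both boundary cases — and
the finite-length correction multiplies the full helix baseline,
θ_H = (−44000 + 250T)(1 − 3/N_r), with a switch (`alt_grouping`) for the
alternative grouping. Both choices are verified against the printed
values they must reproduce (θ_C(70) = −1490, θ_H(70, 35) = −24228.6,
f_H = 0.56). Out-of-range fractions are clamped to [0, 1] and flagged.

## Metadynamics and free-energy surfaces

The metadynamics stage exercises the well-tempered bias schedule at desk
scale: an overdamped Langevin walker (default diffusion 0.01 nm²/ps, step
0.01 ps, reflective domain walls) on an analytic 2D potential, hills of
initial height 1.2 kJ/mol every 500 steps, width 0.05 nm, bias factor 6.0
— and the estimate FES = −(γ/(γ−1))·V_bias on a grid, shifted to zero at
its minimum. Bias and bias gradient are accumulated on an 81-point grid
and interpolated bilinearly, so cost per step is constant. There are no
molecular degrees of freedom here by design: 200 ns solvated production
surfaces are not reproducible at desk scale, so the package establishes
*recovery* — on a calibrated double well the minima gap is recovered
within 0.5 kJ/mol in 3×10⁵ steps (about 15 s on one CPU), the test budget
used throughout.

Double-well inputs are themselves calibrated objects: two isotropic
Gaussian wells whose depths are Newton-adjusted until the measured minima
gap and saddle height match the request exactly (the example landscape
reproduces a 3.36 kJ/mol gap to 0.01). The barrier is referenced to the
global minimum, which requires barrier > |ΔG| for a saddle between two
minima to exist — slightly stricter than the naive well-formedness bound,
and validated as such.

FES analysis takes strict 8-neighbour local minima, reports gaps relative
to the global minimum in kJ/mol and in kT with kT = R·T at 298.15 K by
default (all four conversions quoted for the relay-helix surfaces — 1.4,
1.9, 1.3, 2.4 kT — are consistent with that temperature), and finds
barriers as the bottleneck level at which basins connect under a
union-find flood in order of increasing energy. Surfaces are reported
relative to their own global minimum; any published absolute offset is a
reference convention left to the caller.

## Conformational analysis

Hydrogen-bond series measure O···H (not O···N) with a configurable cutoff
(0.35 nm default); donors without an amide hydrogen are flagged absent
rather than dropped. PCA follows the two-pass essential-dynamics protocol
(superpose heavy atoms on the first frame, average, re-superpose on the
average, diagonalize the coordinate covariance); eigenvectors are
orthonormal to 1e−10 and total variance equals the covariance trace.
Pseudo-trajectories sweep the mean structure along one component between
the minimum and maximum observed projections.

## Problem sizes and limitations

The test and acceptance runs use: 36-oscillator Hamiltonians; static or
≤ 25-frame trajectories for spectra; 2–2.5 ps coherence windows at 0.02 ps
steps for 2D-IR; 91 × 91 fitting grids; 100-replicate recovery studies at
1% noise for kinetics; and 3×10⁵-step metadynamics runs. These sizes were
chosen as the smallest at which each method's convergence criteria are
comfortably met.

Passing tests establish internal consistency — exact analytic limits,
conservation laws, generate-and-refit recovery under the generators' noise
models — not agreement with measurements of the real peptide: the
generators emulate idealized geometry, Gaussian noise, Markov hydrogen-bond
kinetics and Gaussian peak shapes, whereas real data carry solvent
dynamics, spectral diffusion, non-Gaussian lineshapes and baseline
structure. Known limitations: no polarization-resolved 2D signals, no
chemical-exchange kernels, no Raman/VCD observables, no reweighting of
biased trajectories, and no force-field energetics anywhere.
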
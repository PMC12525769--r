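---
title: "Models and methods behind pbsq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pbsq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbsq)
```

`pbsq` analyses the photophysics of phycobilisomes (PBS): how excitation
energy flows through the bilin network of the antenna, and how orange
carotenoid proteins (OCP) quench it. This vignette explains the models the
package implements, why its defaults are what they are, and what its
simulations do and do not capture.

## The composition model

A PBS is described as a list of structural elements — core cylinders, rods
and auxiliary hexamer positions — each holding a stack of phycobiliprotein
(PBP) trimers. Hexamers are represented as two trimers. Bilin counts follow
from the class stoichiometry per αβ protomer: AP binds 1+1, PC 1+2 and PE
2+3 bilins, and each trimer holds three protomers.

`gvipbs_composition()` encodes the composite model of the bundle-shaped
*Gloeobacter violaceus* PBS: a pentacylindrical AP core with 14 modelled
trimers (the fourth trimer of each bottom cylinder is absent from the
deposited model, so 14 rather than 16), six rods carrying 18 PC and 14 PE
hexamers, and the two resolved auxiliary PC hexamers Rx1/Rx1′ that belt the
core. That census — 82 trimers, 864 bilins, split 84/360/420 over AP/PC/PE
— is what the tests pin down exactly.

Choices where the architecture leaves room:

* The tentatively placed Rx2/Rx3 hexamer copies are *excluded* by default;
  `include_tentative_rx = TRUE` adds them for what-if censuses.
* The PEB/PUB split inside PE subunits is not specified anywhere we can
  anchor it, so the census reports PE bilins as one class.
* Rx1/Rx1′ are reported under their own `auxiliary_hexamer` kind rather
  than being folded into "core" or "rods", since either assignment would be
  arbitrary; per-element tables (`census_by_element()`) let users regroup.

## Chromophore geometry

`harvest_chromophores()` reads PDB or mmCIF coordinates (via **bio3d**) and
collects every residue matching a user-extensible ligand map (default
`CYC→PCB, PEB→PEB, PUB→PUB`; depositions differ in their ligand codes, so
no map is assumed correct silently). Mass centers use all non-hydrogen
atoms with standard atomic masses — the choice is robust to models
deposited without hydrogens; a conjugated-system-only center would differ
by fractions of an angstrom. Energy-transfer adjacency uses mass-center
distances with an inclusive cutoff (`distance ≤ cutoff`, default 35 Å), the
geometric criterion conventionally used to chart plausible EET pathways.
Because the printed distance ranges of the real complex depend on the
deposited atomic model, the package validates this machinery by
construction instead: brute-force oracle equivalence for minimal
inter-group distances, monotonicity of edge counts in the cutoff, rigid
motion invariance, and toy structures with planted minima
(`make_toy_structure()`).

Ring coplanarity fits the B–C plane by total least squares (the smallest
eigenvector of the centred covariance of the B and C ring atoms) and
reports signed perpendicular displacements of the A and D ring centroids.
The normal is oriented so ring A's displacement is nonnegative, with +z
breaking the tie when A lies in the plane; rings B and C must each supply
at least three atoms and a two-dimensional spread, otherwise the fit
errors. Ring atom subsets are user-supplied per ligand code — atom naming
varies too much across depositions for a safe built-in default.

## The kinetic cascade and TRES simulation

Excited-state dynamics use first-order compartment kinetics, `dc/dt = K c`,
with the default unidirectional cascade PE → PC → AP → ground. Total decay
lifetimes default to 70 ps, 165 ps and 1.9 ns, so the observable decay
eigenvalues match the three components seen in global analysis of the
bundle-shaped PBS. Within each donor's total rate, 90 % is forward transfer
and 10 % loss; the split is not observable from lifetimes alone and only
rescales DAS amplitudes, so a single plausible value is fixed rather than
exposed as a fitted quantity. `propagate()` solves the system by
eigendecomposition, falling back to an adaptive integrator
(**deSolve**::lsoda) when the eigenvector matrix is ill-conditioned — e.g.
two exactly equal total rates, where the analytic solution acquires a
`t·e^{−kt}` term.

Emission is modelled per compartment as a Gaussian band; defaults place PE
at 578 nm, PC at 646 nm and AP at 663 nm. Only the PC and AP maxima are
spectroscopically anchored (the steady-state fluorescence maximum of the
complex moves from 663 nm to 646 nm under strong AP quenching); the PE
position is a nominal stand-in. The band width (fwhm 24 nm, equal
brightness) was chosen once, analytically, so that the *composite*
steady-state spectrum peaks within half a nanometre of 663 nm unquenched
and 646 nm under strong quenching despite band overlap — the overlap pulls
the composite maximum ~0.4 nm toward the neighbouring band. Steady-state
spectra are computed exactly from the rate matrix
(`∫c dt = −K⁻¹ c(0)`), and the peak is reported as the grid argmax refined
by log-quadratic interpolation, which is exact for a Gaussian; a raw
argmax on the default 2-nm grid could never report 663 nm (odd offset from
500 nm).

The TCSPC instrument model is a Gaussian IRF, channel-integrated and
unit-sum on the 4096-channel / 12.5-ns axis (≈3-ps channels), centred at
t₀ = 0.25 ns so the kernel lies fully inside the window. The width
parameter is named `fwhm_ps` (default 100); the instrument specification
this default mirrors reads "half-width at half-maximum", which is
ambiguous between HWHM and FWHM — users wanting the HWHM reading should
pass `fwhm_ps = 200`. Convolution is causal and linear (signal zero before
t = 0), computed by FFT with the kernel aligned to channel centres; with a
unit-sum kernel it preserves time-integrated intensity of any decay that
dies out inside the window, and it reproduces the closed-form
exponentially-modified Gaussian to the quadrature limit (~8×10⁻⁶ relative
at 3-ps channels, ~3×10⁻⁸ at 0.2-ps channels). A constant signal is
unchanged only beyond the kernel support: early channels see partial
kernel mass because there is no pre-trigger history.

Photon noise is pure Poisson per (time, wavelength) bin, as in
time-correlated single-photon counting; afterpulsing and dark background
are not modelled (a constant background can be added as an extra fit
column). All randomness funnels through a seed argument, making every
simulated dataset byte-reproducible.

## Quenched presets

OCP quenching is modelled as a mixture: a bound fraction of PBS particles
whose AP (terminal) lifetime is shortened, plus unbound particles. The two
quencher presets contrast a fast, efficient quencher (bound fraction 0.9,
AP lifetime ×0.15) with a slower, weaker one (0.5, ×0.35); the numbers are
invented to reproduce that qualitative contrast, since no efficiencies are
printed outside figures, and they are embedded in each dataset's metadata
so recovery tests are self-verifying. The dual-quencher preset composes
the two bound fractions independently (Bliss independence); in doubly
bound particles the stronger quencher's lifetime factor applies — the
choice does not affect the slow-component yield, which depends only on the
doubly *unbound* fraction, so the Bliss identity
`survival(dual) = survival(α) × survival(β)` holds by construction and
Jin's Q equals 1 exactly in the noiseless case.

All presets share the unquenched acquisition's counts-per-signal scale
(the quenched maxima fall below `peak_counts`), mirroring matched
measurements of one sample before and after photoactivation. Without a
common scale, per-dataset normalisation would distort cross-condition
yield ratios and the Bliss identity.

## Global reconvolution analysis

`fit_das()` implements variable projection: the nonlinear search runs over
the shared lifetimes (log-parameterised) and the IRF shift t₀ (bounded to
±3 channel widths), and at each step the per-wavelength amplitudes are
eliminated analytically by weighted linear least squares. This is
preferred over joint minimisation because the amplitude subproblem is
linear and exact, leaving a 4–6 dimensional outer problem that L-BFGS-B
handles quickly. Details that matter:

* **Weights** are 1/max(counts, 1) — Poisson-consistent and finite at
  empty bins. On full simulated surfaces most late-time/band-edge bins are
  nearly empty, and such bins contribute less than one unit each to the
  weighted sum, so the reduced χ² of a correct model sits well below 1
  (≈0.33 on the default preset). Where all fitted bins hold tens of counts
  or more the statistic recovers its textbook calibration, which is how
  the test suite checks it (χ²/ν ∈ [0.8, 1.2]).
* **DAS signs are unconstrained**: negative amplitudes are physical rise
  terms of energy transfer.
* **Degrees of freedom** count the lifetimes, t₀ and every DAS amplitude.
* **Multistart**: three starts by default — the user's initial lifetimes
  plus two ±30 % lognormal perturbations (seeded) — with the best χ²
  winning and ties broken by the smallest fast lifetime. Permuting the
  initial guesses therefore does not change the converged result.
* **Degeneracy**: if lifetimes collide during the search the normal
  equations are solved by a minimum-norm pseudo-inverse, keeping the
  objective continuous instead of erecting a penalty cliff;
  user-facing `solve_amplitudes()` still refuses exactly collinear bases
  with an informative error.
* **Fit windows** default to 10 ps–12.5 ns and 500–750 nm.
* Lifetimes are bounded below by a third of a channel width — shorter
  decays underflow to empty basis columns.
* **Non-convergence** after the iteration cap returns a result flagged
  `converged = FALSE` rather than an error.

`model_select()` fits 3- and 4-component models and keeps the larger one
only when it improves reduced χ² by more than 5 % (threshold
configurable); both fits are returned, so reporting can standardise on the
richer model while logging the decision. With a 100-ps-fwhm IRF and 3-ps
channels, a noiseless 10-ps component is recovered within 20 % — the
deconvolution resolution the instrument parameters imply.

## Quenching metrics

"Yield" of a fit component is defined as τᵢ × the wavelength-integrated
*positive* DAS amplitude — the steady-state photon contribution of that
component, with rise lobes excluded. An amplitude-only definition is
available (`weight_by_tau = FALSE`) because the convention is not uniform
across the literature. The slow component is always selected as the
largest fitted lifetime, never by matching a nominal value (the same
component is labelled ~1.8 ns or ~1.9 ns depending on context); if the
slow lifetimes of the two conditions differ by more than 3×, the
comparison warns. Efficiency is clipped to [0, 1] with a warning when
numerical noise pushes it outside.

Jin's Q classifies quencher combinations with inclusive additive-band
boundaries (0.85 ≤ Q ≤ 1.15). Exactly at 1.15 the printed rules overlap;
the package sides with the additive band. NPQ induction traces are fitted
to `F(t)/F(0) = 1 − E_max(1 − e^(−k_act·t))` (Levenberg–Marquardt, with a
bounded direct-search fallback for degenerate flat traces whose gradient
is singular), and the time of twofold fluorescence reduction is solved
analytically — it exists only when E_max > 0.5. Arrhenius fits regress
ln(1/t) on 1000/T(K) by ordinary least squares, averaging duplicate
temperatures and requiring at least three distinct ones;
Ea = −slope × R in kJ/mol. The photocycle fixture's default Ea of
60 kJ/mol is a fixture choice in the physiological range for OCP recovery,
not a measured value.

## Problem sizes and numerical checks

The test suite runs most fits on reduced grids (512–1024 channels, a dozen
wavelengths) and reserves the full 4096 × 126 surface for the end-to-end
lifetime-recovery and additivity checks; the Monte-Carlo additivity
property uses 40 seeded replicates at the reduced size. Key numerical
tolerances: propagation agrees with an adaptive ODE oracle to 1×10⁻⁸;
amplitude solving matches explicit normal equations to 1×10⁻⁸; unit-sum
convolution preserves in-window intensity to 1×10⁻⁹ relative; noiseless
lifetime recovery is exact to ~0.1 %, and seeded Poisson recovery at peak
10⁴ counts stays within 1 % of the generating 70 ps / 165 ps / 1.9 ns.

## What the simulations do not show

The synthetic layer reproduces the *statistical* structure of TCSPC data —
multiexponential kinetics under IRF convolution with Poisson counting —
not the physics beneath it. There is no Förster-rate or excitonic
calculation connecting structure to rates, no spectral relaxation within
compartments, no fourth kinetic species (scatter or a second AP pool that
real datasets sometimes demand as a 4-state model), no detector
afterpulsing, and toy structures do not mimic real bilin atom naming or
conformation. Passing recovery tests therefore demonstrates that the
estimators are correct and well-calibrated for data generated by their own
model class; they cannot certify fits of real measurements whose
deviations from that class (IRF shape error, background, photobleaching)
are not simulated.
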
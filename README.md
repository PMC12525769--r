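# pbsq — phycobilisome quenching and energy-transfer analysis

Phycobilisomes (PBS) are the megadalton light-harvesting antennas of
cyanobacteria: phycobiliprotein (PBP) trimers and hexamers — phycoerythrin
(PE), phycocyanin (PC) and allophycocyanin (AP) — carry open-chain
tetrapyrrole chromophores (bilins) that funnel excitation energy down a
PE → PC → AP cascade to the photosystems. Under excess light the orange
carotenoid protein (OCP) binds the AP core and dissipates the excitation as
heat (nonphotochemical quenching, NPQ). `pbsq` is an R toolkit for the
quantitative analyses this biology calls for:

* **Architecture censuses.** A hierarchical composition model of a PBS
  (core cylinders, rods, auxiliary hexamers) with the canonical bilin
  stoichiometry per αβ protomer (AP 1+1, PC 1+2, PE 2+3). The built-in
  model of the bundle-shaped *Gloeobacter violaceus* PBS counts 82 (αβ)₃
  trimers and 864 bilins.
* **Chromophore geometry.** Extraction of bilin ligands from PDB/mmCIF
  files, mass-center distance matrices, energy-transfer adjacency graphs at
  a distance cutoff (default 35 Å), and bilin ring-coplanarity geometry
  (signed out-of-plane displacement of the A and D rings from the B–C
  plane).
* **TCSPC simulation.** A compartmental EET cascade (`dc/dt = K c`) turned
  into time-resolved emission spectra (TRES) on a 4096-channel / 12.5-ns
  axis: Gaussian instrument-response (IRF) convolution (fwhm 100 ps),
  per-band Gaussian emission, Poisson photon noise, OCP-quenched mixtures,
  NPQ induction time courses, and Arrhenius temperature series of the OCP
  photocycle.
* **Global reconvolution analysis.** The core fit, `fit_das()`, analyses
  all wavelengths simultaneously with shared lifetimes by variable
  projection: the nonlinear search runs over {τᵢ, t₀} while the
  per-wavelength amplitudes — the decay-associated spectra (DAS) — are
  solved by weighted linear least squares at every step,

      F(t, λ) = Σᵢ DASᵢ(λ) · (e^(−t/τᵢ) ⊗ IRF),

  with Poisson weights 1/max(counts, 1), reduced-χ² and residual
  diagnostics, multistart initialisation, and 3- vs 4-component model
  comparison (`model_select()`).
* **Quenching metrics.** Component yields Yᵢ = τᵢ ∫ max(DASᵢ, 0) dλ,
  quenching efficiency E = 1 − Y_slow(quenched)/Y_slow(unquenched), the
  time of twofold fluorescence reduction from saturating-exponential NPQ
  fits, Bliss-independence additivity via Jin's statistic

      Q = E(α+β) / (Eα + Eβ − Eα·Eβ)

  (Q < 0.85 antagonism, 0.85 ≤ Q ≤ 1.15 additive, Q ≥ 1.15 synergism), and
  activation energies from Arrhenius fits of ln(1/t) against 1000/T.

## Worked example

```r
library(pbsq)

## architecture census of the bundle-shaped PBS
gvipbs_composition()
#> PBS composition model: GviPBS composite
#>   elements: 13  trimers: 82  bilins: 864
#>   bilins by class:  AP:84  PC:360  PE:420

## simulate a TCSPC measurement and refit it blind
tres <- make_tres_preset("gvipbs_unquenched", seed = 1, peak_counts = 1e4)
fit  <- fit_das(tres, n_components = 3, init_lifetimes_ns = c(0.03, 0.3, 3))
fit
#> Global reconvolution fit (3 components, 126 wavelengths)
#>   lifetimes:  69.97 ps, 166.1 ps, 1.893 ns
#>   reduced chi-square: 0.3335
#>   IRF t0: 0.2501 ns; converged ( 43 objective evaluations )
```

The three recovered lifetimes are the EET steps of the cascade: ~70 ps
(PE → PC transfer), ~165 ps (PC → AP transfer) and ~1.9 ns (AP core decay,
the component that OCP quenching removes). `plot(fit)` draws the DAS;
negative lobes mark energy-transfer rise terms.

```r
## additivity of two independently binding quenchers
jin_q(0.9, 0.5, 0.95)
#> Jin's Q = 1.000 (additive): E_alpha = 0.900, E_beta = 0.500, E_combined = 0.950

## activation energy of the OCP photocycle from a noisy temperature series
s  <- make_photocycle_preset(Ea_kJmol = 60, noise_sd = 0.01, seed = 2)
tc <- vapply(s, function(p) {
  tr <- p$trace[p$trace$A550 > 0.05, ]
  -1 / unname(coef(lm(log(tr$A550) ~ tr$t_s))[2])
}, 0)
arrhenius_fit(vapply(s, `[[`, 0, "temperature_C"), tc)
#> Arrhenius fit over 5 temperatures: Ea = 60.06 kJ/mol, lnA = 19.626, R^2 = 1.0000
```

A thin command-line front end ships in `inst/cli/pbsq`
(`pbsq census --json`, `pbsq simulate-tres`, `pbsq fit-tres`,
`pbsq structure-distances`, `pbsq jin`, `pbsq arrhenius`,
`pbsq make-fixtures`).

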
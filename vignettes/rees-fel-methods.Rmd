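---
title: "Microstate free-energy landscapes from red-edge excitation shift data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate free-energy landscapes from red-edge excitation shift data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reesfel)
```

## The physical model

A red-edge excitation shift (REES) experiment records the peak emission
wavelength of a fluorophore as the excitation wavelength moves across and
beyond the red edge of its absorption band.  A progressive red shift of the
emission reveals a static distribution of fluorophore microenvironments.
`reesfel` models a fluorescent ligand bound to a protein as a two-level
system — electronic ground state (GS) and a charge-transfer excited state
(CT) — distributed over a finite number `m` of discrete protein–ligand
*microstates* along a collective coordinate `x`.

Within each microstate `i` the GS and CT free energies are displaced
harmonic (Marcus) surfaces:

* GS: `G_i(x) = kappa (x - i x_GS)^2 / 2 + A i^b`
* CT: the same well displaced by `x_CT` along `x` and raised by a CT–GS gap
  `gap(i)` that interpolates linearly from `dg_ctgs0` (most stable state,
  `i = 0`) to `dg_ctgsn` (least stable state, `i = m - 1`).

The second GS term is the parametric free-energy landscape (FEL) `A i^b`:
`b = 1` a linear ramp, `b = 2` quadratic (harmonic), `b = 3` cubic.  The
microstates are equally spaced by `x_GS`, so the landscape needs only four
parameters (`A`, `b`, `x_GS`, `m`) regardless of the number of states.
The index convention is that `m` counts microstates `i = 0 … m − 1`; the
landscape span — the free-energy cost of moving the ligand from its most
stable to its least stable bound pose — is `A (m − 1)^b`.  This convention
makes the span of the fitted quadratic landscapes come out as
`A (m − 1)^2` (e.g. `0.00178 * 81 = 0.144` eV for ten states), consistent
with the per-state gap formula `A (2i + 1)`.

Photon energies follow from the surfaces.  Absorption from microstate `i`
at coordinate `x` is `gap(i) + kappa x_CT^2 / 2 − kappa x x_CT`;
emission occurs after vibrational relaxation in the local CT well and is
therefore independent of the excitation coordinate:
`gap(i) − kappa x_CT^2 / 2`.  Two exact identities follow and are enforced
by the test suite: absorption minus emission at the band origin equals
twice the ligand reorganization energy `kappa x_CT^2 / 2` (the Stokes
shift), and their mean recovers `gap(i)`.

Assuming thermal equilibrium in the ground state, the population of
microstate `i` at coordinate `x` is Boltzmann,
`W_i(x) ∝ exp(−G_i(x) / k_B T)`.  The observable REES curve is the pair of
Boltzmann-weighted means — ensemble absorption energy and ensemble mean
emission energy — swept over `x`.  With CT gaps decreasing along the
landscape (`dg_ctgsn < dg_ctgs0`) the emission shifts red as excitation
moves red; with the gaps reversed the model predicts a blue-shifting
("unorthodox") red-edge effect; a single microstate gives exactly zero
shift.

### Model assumptions

* The protein environment is static on the fluorescence timescale: no
  solvent or protein dipolar relaxation, and no transfer between
  microstates during the excited-state lifetime.  Systems showing
  temperature-dependent REES (dynamic averaging) are outside the model.
* The curvature `kappa` is shared by all surfaces and both electronic
  states, and the CT displacement `x_CT` and reorganization energy are the
  same for every microstate (purely inner-sphere relaxation).
* Only peak positions are modelled, not spectral band shapes; the mean
  ensemble emission energy is identified with the measured peak emission
  wavelength.

### Two absorption conventions

Subtracting the GS surface from the CT surface of microstate `i` yields a
cross-term `kappa i x_GS x_CT` that the compact per-state absorption
expression above omits.  The package implements both: the default
(`mode = "printed"`) uses the compact expression, in which every
microstate's absorption has the same slope in `x`; `mode = "strict"`
computes vertical gaps directly from the surfaces.  The default is used
everywhere unless requested, and the strict mode is provided as a
diagnostic for assessing how much the cross-term matters for a given
parameter set.  Emission is x-independent in both modes: a trailing
excitation-dependent term would contradict the single-microstate
zero-REES limit that defines the model.

## Parameters and units

| Parameter | Meaning | Units | Default |
|---|---|---|---|
| `kappa` | harmonic curvature | eV per (eV^0.5)^2 | 1 |
| `temperature_K` | temperature | K | 298 |
| `x_min`, `x_max`, `n_grid` | coordinate sweep | eV^0.5 / – | −1, 2, 1001 |
| `x_ct` | CT displacement | eV^0.5 | from calibration |
| `dg_ctgs0`, `dg_ctgsn` | CT–GS gaps | eV | from calibration |
| `a`, `b`, `x_gs`, `m` | landscape | eV / – / eV^0.5 / count | fitted |

With `kappa = 1` the collective coordinate carries eV^0.5 units and `x_CT`
matches the tabulated values directly; any other `kappa` rescales the
displacements without changing an observable.  Wavelengths convert through
`hc = 1239.84193` eV·nm and are reported to 0.1 nm.

## Calibration from spectral observables

Three ligand parameters are fixed from three measurable energies before
any landscape fitting (`ligand_from_spectra`): the absorption maximum
`abs_max`, and the blue and red asymptotic emission endpoints of the REES
curve.  Half the Stokes shift gives the reorganization energy (hence
`x_CT = sqrt(2 reorg / kappa)`), the mean of absorption and blue emission
gives `dg_ctgs0`, and the emission span gives `dg_ctgsn`.  In the full
pipeline (`analyze_rees`) the emission endpoints come from the asymptotes
of the sigmoid fit, so the calibration inherits any asymptote error of
that fit — see Limitations.

## Fitting

`fit_sigmoid` represents a dataset by the four-parameter Boltzmann sigmoid
`em(λ) = em_red + (em_blue − em_red) / (1 + exp((λ − mid)/width))`,
fitted by Levenberg–Marquardt from a multi-start grid (three mid-point
quantiles × three widths), with a Nelder–Mead fallback.  Flat data (spread
below `1e-8` nm) return a flagged degenerate fit rather than an error.

`fit_fel` fixes the ligand photophysics and the candidate `(m, b)` and
optimizes the energy scale `A` and spacing `x_GS` by bounded L-BFGS-B on
`(log10 A, x_GS)` from a 3 × 3 multi-start grid (A log-spaced in
`[1e-5, 0.2]` eV, `x_GS` in `[0.005, 0.5]` eV^0.5); with `b = "free"` the
exponent joins the search in `[0.5, 4]` with starts at 1, 2 and 3.  The
objective is the sum of squared deviations (nm²) between the theoretical
curve, resampled by monotone piecewise-linear interpolation onto the
evaluation wavelengths, and the fitting target.  During optimization the
coordinate sweep uses 401 points (its interpolation error is orders of
magnitude below the fit tolerance); the winning parameters are rescored on
the configured 1001-point grid.

Two fitting targets are supported everywhere:

* **sigmoid** — the model curve is compared with the sigmoid
  representation, evaluated at the dataset's excitation wavelengths (or at
  50 points across the sigmoid's 1–99% transition band when no dataset is
  in play).  This is the default for experimental data, where the sigmoid
  usefully smooths noise.
* **data** — the model curve is compared with the raw datapoints.

`scan_models` fits every candidate `(m, b)` and ranks them by SLSQ
(default) or AIC `= 2k + n ln(LSQ)`.  Parameter counting for AIC: `k = 2`
for `A, x_GS` with `(m, b)` fixed, `+1` when the scan varies `m`, `+1`
when `b` is free.  Ties break toward smaller `m` (parsimony).  Failed
candidates are kept as flagged entries.

### Why the recovery benchmark fits the raw points

The package's self-validation (`recovery_experiment`) simulates noiseless
datasets from known landscapes, fits the sigmoid, then refits the
landscape with `A`, `x_GS`, `m` and `b` all free.  The free fit defaults
to the **data** target.  The reason is identifiability: the theoretical
REES curve is not exactly a Boltzmann sigmoid in wavelength, so the
best-fitting sigmoid carries a small systematic shape error.  The free
inversion is ill-conditioned — many `(m, b, A, x_GS)` combinations produce
nearly indistinguishable smooth curves — and that small sigmoid error is
enough to bias it toward few-state, large-span landscapes.  Against the
raw points the generating model is the unique global minimum and the
benchmark measures what it should: the round-trip fidelity of the
simulate-and-refit machinery.  The sigmoid fit remains part of the
recovery pipeline (it is recorded in the result, and its endpoint role in
calibration is unchanged); only the least-squares target differs, and the
`target = "sigmoid"` variant remains available for studying the
compression bias itself.

## Derived thermodynamics

From a fitted landscape the package reports, per successive pair of
states: the gap `A ((i+1)^b − i^b)`; the ground-state reorganization
energy `RE = kappa x_GS^2 / 2`; and the Marcus activation barrier
`(gap + RE)^2 / (4 RE)`, which is never below `RE/4` and never below the
gap.  Because barrier values are sensitive to whether states are named
1-based or indexed 0-based, `landscape_report` always returns the full
per-state table rather than a single headline barrier.

A dissociation constant converts to a total binding free energy
`ΔG = k_B T ln(K_d / 1 M)` (1 M standard state, 298 K default).
`binding_decomposition` splits that total into a surface-association term
and an intrusion term — the free energy of moving from the least stable
(surface-proximal) bound state to the most stable interior state — where
the intrusion term is the negated landscape span in kcal/mol.

## The synthetic-data generator

`generate_rees_dataset` samples the theoretical curve at 10 excitation
wavelengths, evenly spaced across the central 2–98% band of the emission
transition (mirroring the roughly ten datapoints of a typical REES
experiment), and adds independent Gaussian noise to the emission
wavelengths only.  Seeds are mandatory whenever noise is drawn.  The
reference fixtures (`make_reference_fixtures`) are *synthetic
reconstructions* of the two kinase-complex case studies, built from their
published fitted parameters because the underlying experimental points
are not public; their filenames and metadata say so.

What the generator emulates: the shape, wavelength ranges and point count
of REES datasets, and uncorrelated emission-wavelength noise.  What it
does not: instrument response, excitation-wavelength error, correlated
drifts, band-shape effects, or an experimentally constrained excitation
window (the model-implied transition band is far wider than the
absorption band of a real ligand).  Passing tests therefore demonstrate
the internal consistency of the machinery on curves the model itself can
produce, not performance on real spectra.

## Numerical choices

* Coordinate sweep `[−1, 2]` with 1001 points; 401 during optimization.
* Boltzmann exponentials are stabilized by subtracting the minimum free
  energy before exponentiation; the Gaussian prefactor of the Boltzmann
  density cancels in the normalization and is omitted.
* Curve resampling and mid-point inversion use monotone piecewise-linear
  interpolation; the transition mid-point is defined in emission space
  (halfway between the endpoints) and mapped to excitation wavelength,
  with the slope taken by central difference there.  Flat curves return a
  flagged summary instead of an error.
* Optimizer tolerances: `factr = 1e5` (L-BFGS-B), 200 iterations, with
  the multi-start grids above; sigmoid fitting caps at 200
  Levenberg–Marquardt iterations per start.
* Problem sizes in the validation suite: 10-point fixtures, scans over
  `m = 3 … 20`, four recovery spans between 0.041 and 0.240 eV, and
  20-seed noise panels at 0.3 nm — sizes a desk analysis of one complex
  would use.

## Known limitations

* **Sigmoid compression.** The four-parameter sigmoid cannot represent
  the asymmetric model curve exactly; with sparse sampling its asymptotes
  can deviate by several nm from the true emission endpoints.  This
  propagates into the ligand calibration and biases free model selection
  (see above).  When the raw data are trustworthy, prefer
  `target = "data"`.
* **Steepness summaries fragment at wide spacing.** The mid-point slope
  increases with `x_GS` only while the spacing stays below the thermal
  coordinate width `sqrt(k_B T / kappa)` (≈ 0.16 eV^0.5 at 298 K); beyond
  that the curve becomes a staircase and the local mid-point gradient is
  no longer a monotone summary of steepness.
* **Sweep truncation.** For large `m × x_GS` the default sweep `[−1, 2]`
  does not reach the top microstates, truncating the red limb of the
  curve; widen the sweep with care, since the excitation energy must stay
  positive.
* **Model-dependence of `m`.** The recovered number of microstates counts
  spectroscopically distinguishable classes under this specific landscape
  family; it is not an absolute state count.
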
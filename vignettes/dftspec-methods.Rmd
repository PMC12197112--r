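---
title: "Simulating a switch-based digital FTS for skin Raman sensing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a switch-based digital FTS for skin Raman sensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(dftspec)
```

## The problem

Raman spectroscopy can distinguish cancerous from healthy skin without a
biopsy, but a portable instrument needs an on-chip spectrometer. A
switch-based digital Fourier-transform spectrometer (sbDFTS) encodes the
input spectrum in an interferogram: a single 2×2 interferometer whose
optical-path difference (OPD) is selected digitally by eight cascaded
switch stages, one power reading per configuration, all light landing on
one detector (the Fellgett advantage). `dftspec` simulates such a device
on a silicon-nitride platform for the 800–1800 cm⁻¹ fingerprint region of
skin (890–975 nm with 830 nm excitation), and recovers spectra from the
interferograms by Basis Pursuit Denoising (BPDN).

This vignette explains the model, its assumptions, the tunable parameters
and the design decisions taken where the design was genuinely open. All
empirical statements below are computed by the package's test-suite or the
acceptance script; none are asserted from elsewhere.

## Device geometry and the OPD grid

Each digital path-difference selector (DPDS) stage has a 35 µm top guide
and a bottom guide whose length differs by exactly $0.4 \cdot 2^{i-1}$ µm
for stage $i$ (`dpds_bank()`). A configuration is an 8-bit word $k$; the
OPD is $\Delta L = k \times 400$ nm, a uniform grid from 0 to 102 µm:

```{r opd}
config_to_opd(c(1, 1, 0, 0, 1, 1, 0, 1))  # the k = 179 configuration
range(ifts_opd_table())                   # ideal-FTS table, same set
```

The bit convention deserves a note: the first element of the configuration
vector is stage 1 (the 0.4 µm stage). This is the only decoding under
which the published anchor configuration `(1,1,0,0,1,1,0,1)` produces
71.6 µm, the per-stage length differences are binary-weighted, and the
256 arm-length combinations of the ideal reference spectrometer
(`ifts_design()`) produce exactly the same OPD set — three independent
consistency checks the constructors enforce.

Balanced phase-compensator (PC) stages (10 µm both arms) keep the
component count equal in the two arms; `calibrate_pc_phases()` performs
the one-time static phase correction (with the energy-conserving coupler
model below the optimum is phase zero, and the routine confirms it).

## Component models

* **Waveguides** (`waveguide_spec()`): 0.8 dB/cm loss and a first-order
  dispersion model $n_\mathrm{eff}(\lambda) = n_0 + n'(\lambda -
  \lambda_0)$. The slope is calibrated so the group index is
  $n_g = n_0 - \lambda_0 n' \approx 2.134$ at 935 nm, placing the Rayleigh
  resolution $\Delta\lambda = \lambda^2 / (N n_g \Delta L)$ of the
  256-channel device at 4 nm (≈ 46 cm⁻¹). The vendor index data behind
  the real device are not public; the calibration anchors the one free
  dispersion parameter to the device's stated resolution.
* **Couplers** (`coupler_spec()`): ideal mode is an exact 50:50 2×2
  coupler; parametric mode adds a wavelength-dependent split-ratio ripple
  $0.5 + \delta_0 \sin(2\pi(\lambda-\lambda_c)/\Lambda)$ with
  $\delta_0 = 0.02$, $\Lambda = 40$ nm — a stand-in for an adiabatic
  coupler at the edge of its adiabatic regime, energy-conserving and
  real-valued (no excess phase). The real coupler's S-parameters are not
  published; this reproduces the qualitative role (wavelength-dependent,
  non-uniform splitting) with three explicit knobs.
* **Phase shifters**: fixed 0.711 dB insertion loss, settable phase.
* **Amplifiers** (`amplifier_spec()`): 30 dB gain, 8.5 dB noise figure,
  ASE centred at 935 nm with a 37 nm 3-dB bandwidth. The signal gain is
  flat across the band by default — the data sheet figures specify a gain
  and a *noise* bandwidth — while the ASE spectral density
  $\rho(\lambda) = n_{sp}(G-1) h c^2/\lambda^3$ per polarization
  ($n_{sp} = 10^{NF/10}/2$) always carries the Gaussian profile. A
  `gain_shape = "gaussian"` option rolls the signal gain off with the same
  profile; we found that shape imposes ~40 dB relative attenuation at the
  band edges across two amplifiers, destroying the band-edge columns of
  the calibration matrix, and left it off by default.

The model is scalar (single polarization) and ignores thermo-optic
transients; the detector integrates power ideally with no responsivity
curve.

## Noise model and its one calibrated parameter

ASE is added as its deterministic mean plus independent Gaussian
fluctuations per wavelength bin, with standard deviation
$\rho(\lambda)/\sqrt{\Delta\nu_\mathrm{bin}\,\tau}$ — the relative
intensity noise of thermal light averaged over the bin's optical
bandwidth and an effective detector averaging time $\tau$. Beat noise
between signal and ASE is not modelled (the detector is slow, and the
subtraction protocol below removes all deterministic terms).

$\tau$ is the single free noise parameter and the device's sensitivity
hinges on it. We calibrate it once, analogously to the group index: the
documented sensitivity threshold of the instrument says a change of the
1445 cm⁻¹ band area from 0.1 to 0.5 a.u. is just distinguishable, so
$\tau$ (default 265 s) is set to make the RMS noise of a measured power
difference equal the noiseless response to that area change at the most
sensitive configuration, under the default input scale. Consequences of
this calibration are reported, not tuned: in the reconstruction domain
the 256-configuration measurement is about twice as sensitive as the
single-configuration anchor, so the 0-dB crossing of the reconstructed
difference-spectrum SNR sits at an area of ≈ 0.2–0.3 rather than 0.5.

## Phantoms

Six lesion classes (melanoma MEL, basal and squamous cell carcinoma
BCC/SCC, actinic keratosis AK, atypical nevus AN, seborrheic keratosis
SK) are modelled as ten shared Lorentzian bands (855–1745 cm⁻¹, shared
centres and widths, class-specific areas) plus a fifth-order polynomial
fluorescence baseline:

```{r phantom, fig.alt = "Melanoma phantom spectrum"}
plot(compose_skin_signal("MEL"))
```

Areas are in arbitrary units; a single input-power knob maps the peak
wavelength density of the composite spectrum to 1 nW/nm at the
spectrometer input (`scale_to_peak`), and one absolute scale factor is
shared by every measurement within a protocol — without that, the
fluorescence subtraction would be inconsistent. Spectral densities are
converted between Raman shift and wavelength with the Jacobian
$S_\lambda = y_r \cdot 10^7/\lambda^2$, preserving integrated power.

What the phantoms do *not* emulate: patient-to-patient variability, peak
position/width variation, detector shot noise, tissue heterogeneity, or
anti-Stokes scattering. Passing tests therefore show the *instrument
model* recovers *this family* of spectra; they say nothing about
classifying real tissue.

## Measurement and reconstruction

A measurement injects a spectrum, records
$P_k = \int T_k(\lambda)\,S(\lambda)\,d\lambda$ for all 256
configurations (amplifier chain applied in component mode), and follows
the two-step protocol: measure fluorescence alone, measure the full skin
signal, subtract the interferograms, then reconstruct the difference.
Subtraction also cancels the deterministic ASE floor.

The calibration matrix $A$ (256 × 171) holds the interferograms of a
0.5 nm-FWHM, 100 mW laser line swept over 890–975 nm in 0.5 nm steps,
measured on the *same* device mode as the experiment and dark-corrected;
at 100 mW the line exceeds the ASE noise by ~4 orders of magnitude, so
the columns are computed as the deterministic response.

Reconstruction solves the BPDN program
$$\hat x = \arg\min_x \tfrac12\|y - Ax\|_2^2 + w\|x\|_1,$$
by cyclic coordinate descent on the Gram matrix (compiled inner loop,
warm starts, an active-set polish step that solves the support's normal
equations with a backtracking line search, and an accelerated
proximal-gradient fallback for degenerate supports at tight tolerances;
the subgradient condition $\|A^\top(y-A\hat x)\|_\infty \le w$ is
checked on every fit). No sign
constraint is imposed; negative entries appear as a noisy baseline, as
they should. A lasso solver minimising $\frac{1}{2n}\|y-Ax\|^2 +
\lambda\|x\|_1$ computes the same solution at $\lambda = w/n$ — the
½-factor mapping is unit-tested against an independent solver.

The penalty is chosen by 10-fold cross-validation (`cv_bpdn()`) over a
49-point log grid from $10^{-6}$ to $10^{6}$: the 256 interferogram
entries are shuffled into folds of 26/26/26/26/26/26/25/25/25/25 (exactly
equal folds are impossible), the model is fitted on nine folds, and the
fold score is either the MSE of the max-normalised reconstruction against
the known ground truth (simulation mode, the default here) or the
held-out data-fidelity MSE (blind mode, for real unknowns — how penalty
selection should work on real tissue is an open question we leave to
both modes). Broad, overlapping spectra select small penalties; sharp
isolated lines select larger ones.

Numerical notes: the linear system is genuinely rank-deficient
(condition number ~10¹⁶), which is *why* the ℓ1 prior is needed; at
near-zero penalties the exact BPDN solution is spiky below the
resolution scale, so readouts at a known position average over one
resolution element (~9 bins). A related and important choice: the
reconstruction estimator is defined together with its solver budget
(tolerance 10⁻⁶, 500 coordinate sweeps, for fold fits and the reported
fit alike). On this degenerate system the set of near-minimisers is
wide, and minimisers reached at different budgets differ materially —
selecting the penalty with budgeted fits and then refitting to the exact
optimum would evaluate one estimator and report another. Exact-optimum
machinery (active-set polish with line search, accelerated proximal
gradient) is reserved for verifying solver correctness against an
independent implementation. The two outermost wavelength bins on each
side absorb whatever input light falls outside the 890–975 nm calibration
span (800–1800 cm⁻¹ maps to 889.0–975.8 nm) and should be ignored when
locating peaks.

## Evaluation statistics

* `r_squared()` — $1 - SS_{res}/SS_{tot}$ about the reference mean;
  confusion matrices (`r2_confusion()`) compare every reconstruction to
  every class model, both max-normalised on the common 800–1800 cm⁻¹
  window (the normalisation convention is ours; the reference study does
  not state one).
* `snr_horiba()` — $10\log_{10}((S_p - S_b)/N_{RMS})$.
* `sensitivity_sweep()` — sweeps the 1445 cm⁻¹ area from a 0.1 baseline;
  reports the noiseless interferogram power difference at the most
  sensitive configuration (exactly linear in the area change) and the
  reconstruction-domain SNR of the difference spectrum under noise, using
  the penalty cross-validated for the baseline lesion (the instrument's
  operating point — a CV run on the clean single-band difference would
  select a penalty that zeroes small changes entirely).
* `fsr_ttest()` — pooled two-sample, two-tailed t-test between
  max-normalised transmission curves of the switch-based and ideal
  devices at matched OPD, sampled at 17 wavelengths on 890–975 nm
  (df = 32, hence the 2.0369 critical value); Welch by flag.
* `resolution_report()` — the Rayleigh accounting above.

## Problem sizes and reproducibility

Simulations run on a 0.05 nm wavelength grid (1901 points, fine enough to
sample the 4 nm fringes of the largest OPD); a calibration matrix builds
in well under a second, a cross-validated reconstruction (490 solver
calls) in about one to three minutes on one core, and the test-suite's
end-to-end blocks use three seeds for the melanoma figure and single
seeds elsewhere. Every stochastic stage takes an explicit seed and there
is no hidden global RNG state: functions save and restore the caller's
`.Random.seed`. `run_pipeline()` writes plain-text artifacts (CSV/JSON)
plus a manifest of seeds and content hashes, and re-running a manifest
reproduces the CSVs byte for byte; calibration matrices are cached by a
content hash of the device parameters.

## Known limitations

* The coupler stand-in and the flat-gain default mean two artefacts of
  the realistic-component study are not reproduced mechanically: the
  specific AK-classified-as-SCC confusion (a hair-thin margin under
  heavier component noise) and a deterministic attenuation of the
  1745 cm⁻¹ band (which requires a vendor gain curve). Both are discussed
  above and tested honestly.
* Absolute powers (nW readings) depend on the input-power knob; only
  ratios and normalised spectra are comparable across scales.
* The fluorescence model is a fixed polynomial; real autofluorescence
  varies between patients and bleaches over time.
* Single polarization, ideal detector, no fabrication variability.
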
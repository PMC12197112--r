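# dftspec

Simulation of an on-chip **switch-based digital Fourier-transform
spectrometer** (sbDFTS) for non-invasive Raman sensing of skin lesions,
with sparse spectral reconstruction by **Basis Pursuit Denoising** (BPDN).

The package is aimed at integrated-photonics and biomedical-optics
researchers who want a desk-scale, fully reproducible model of this class
of instrument: how a digitally switched interferometer encodes a Raman
spectrum into 256 power readings, and how well an ℓ1-regularised inversion
recovers the spectrum under realistic component imperfections and
amplifier noise.

## The instrument and the method

A bank of eight binary-weighted switch stages selects the optical-path
difference (OPD) of a two-arm interferometer digitally: configuration
*k* ∈ {0, …, 255} yields ΔL = *k* × 400 nm, a uniform grid up to 102 µm.
One detected power per configuration gives the interferogram
**y** (256 values). With a calibration matrix **A** (256 × 171) measured
by sweeping a narrow laser line over 890–975 nm in 0.5 nm steps, spectrum
recovery solves the underdetermined system **y** = **A x** via

  min_x ½‖**y** − **A x**‖₂² + w‖**x**‖₁,

with the penalty *w* selected by 10-fold cross-validation over a
log-spaced grid (10⁻⁶ … 10⁶). The spectral resolution follows the
Rayleigh criterion Δλ = λ²/(N n_g ΔL): with N = 256 channels, unit OPD
400 nm and group index n_g ≈ 2.134, about 4 nm (≈ 46 cm⁻¹) at 935 nm.

Skin phantoms for six lesion classes (MEL, BCC, SCC, AK, AN, SK) are
ten-band Lorentzian mixtures over 800–1800 cm⁻¹ plus a fifth-order
fluorescence baseline; the measurement protocol records the fluorescence
alone and the combined signal, subtracts the interferograms, and
reconstructs the difference.

## Worked example

```r
library(dftspec)

# the published anchor configuration decodes to 71.6 um
config_to_opd(c(1, 1, 0, 0, 1, 1, 0, 1))
#> [1] 71.6

# Rayleigh resolution of the 8-stage device at band centre
unlist(resolution_report())
#> dlambda_nm    dnu_cm1
#>   3.999967   45.55953

# end-to-end: melanoma phantom on the component chain with amplifier
# noise, cross-validated BPDN reconstruction (~2 min on one core)
device <- dfts_device("component_chain")
cal    <- build_calibration_matrix(device)
rec    <- reconstruct_raman(device, "MEL", seed = 1, calibration = cal)
summary(rec)
#> Raman reconstruction of 'MEL' (component_chain mode)
#>   penalty 3.162e-05 (10-fold CV, ground_truth)
#>   R^2 vs noiseless Lorentzian model: 0.9434
plot(rec)   # reconstruction overlaid on the noiseless model
```

The R² of 0.94 is the self-match coefficient of determination between the
max-normalised reconstruction and the noiseless Lorentzian melanoma model
on the 800–1800 cm⁻¹ window — the quantity used to classify lesions: a
reconstruction is assigned to the class model it matches best
(`r2_confusion()`). `sensitivity_sweep()` quantifies the smallest
detectable change of the 1445 cm⁻¹ band, and `fsr_ttest()` compares the
switch-based device's transmission fringes against the ideal reference
spectrometer.

A thin command-line front end over these functions is installed at
`inst/scripts/dftspec-cli.R` (subcommands `phantom`, `calibrate`,
`measure`, `reconstruct`, `evaluate`, `run-all`, `selftest`).

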
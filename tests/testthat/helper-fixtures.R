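# Shared fixtures, built once per test run (everything is generated in
# code; the devices are cheap, reconstructions are not and are kept to the
# acceptance suite).

ideal_device <- dfts_device("ideal")
chain_device <- dfts_device("component_chain")
ideal_cal <- build_calibration_matrix(ideal_device)
chain_cal <- build_calibration_matrix(chain_device)

# A narrow Gaussian emission line as a wavelength-domain spectrum.
gaussian_line <- function(center_nm, fwhm_nm = 0.5, peak = 1,
                          grid = seq(885, 980, by = 0.05)) {
  raman_spectrum(grid, peak * exp(-4 * log(2) * ((grid - center_nm) /
                                                   fwhm_nm)^2),
                 "wavelength")
}

# Count strict interior local maxima of a vector.
n_local_maxima <- function(v) {
  sum(diff(sign(diff(v))) == -2)
}
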
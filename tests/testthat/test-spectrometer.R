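test_that("switch configurations decode to the binary-weighted OPD grid", {
  expect_equal(config_to_opd(rep(0, 8)), 0)
  expect_equal(config_to_opd(c(1, 1, 0, 0, 1, 1, 0, 1)), 71.6)
  expect_equal(config_to_opd(rep(1, 8)), 102)
  expect_equal(config_to_opd(179L), 71.6)
  # bits <-> index bijection over the whole range
  for (k in 0:255) expect_equal(config_to_opd(opd_to_config(k)), k * 0.4)
  expect_error(config_to_opd(c(1, 0, 1)), "8 bits")
  expect_error(config_to_opd(c(1, 2, 0, 0, 0, 0, 0, 0)), "0 or 1")
  expect_error(config_to_opd(300L), "0..255")
})

test_that("the DPDS bank encodes the stage weights exactly", {
  b <- dpds_bank()
  expect_equal(abs(b$bottom_um - b$top_um), 0.4 * 2^(0:7))
  expect_error(dpds_bank(bottom_um = c(34.6, 35.8, 33.4, 38.2, 28.6,
                                       47.8, 9.4, 86)), "0.4")
})

test_that("the ideal-FTS arm-length table spans the same OPD set", {
  opd <- ifts_opd_table()
  expect_length(opd, 256)
  expect_equal(opd, seq(0, 102, by = 0.4))
  expect_equal(sort(opd), sort(vapply(0:255, config_to_opd, numeric(1))))
  # largest difference comes from the extreme printed lengths
  d <- ifts_design()
  expect_equal(max(d$top_um) - min(d$bottom_um), 102)
  # transcription errors are caught
  bad <- ifts_design()
  bad$top_um[3] <- 143.3
  expect_error(ifts_opd_table(bad), "integrity")
})

test_that("balanced ideal interferometer transmits everything", {
  tr <- simulate_transmission(ideal_device, 0L)
  expect_equal(range(tr), c(1, 1))
  expect_error(simulate_transmission(ideal_device, 0L, 700), "800-1000")
  expect_error(simulate_transmission(ideal_device, opd_um = 0.3), "0.4")
})

test_that("component chain collapses to the ideal response without
           imperfections", {
  plain <- dfts_device("component_chain",
                       coupler = coupler_spec("ideal"),
                       waveguide = waveguide_spec(loss_db_cm = 0),
                       phase_shifter = phase_shifter_spec(0, 0),
                       amplifiers = FALSE)
  lam <- seq(890, 975, by = 0.25)
  for (k in c(3L, 179L)) {
    expect_equal(simulate_transmission(plain, k, lam),
                 simulate_transmission(ideal_device, k, lam),
                 tolerance = 1e-8)
  }
})

test_that("a monochromatic line yields a sinusoidal interferogram", {
  line <- gaussian_line(935, fwhm_nm = 0.1)
  ifg <- measure_interferogram(ideal_device, line)
  neff <- effective_index(ideal_device$waveguide, 935)
  model <- cos(pi * neff * ifg$opd_um * 1e3 / 935)^2
  expect_gt(cor(ifg$power_w, model), 0.999)
  # period in OPD is lambda / n_eff
  expect_equal(stats::cor(ifg$power_w,
                          cos(pi * neff * (ifg$opd_um * 1e3 +
                                             935 / neff) / 935)^2),
               cor(ifg$power_w, model), tolerance = 1e-3)
})

test_that("zero input with amplifiers off measures exactly zero", {
  dark <- raman_spectrum(seq(890, 975, 0.5), numeric(171), "wavelength")
  ifg <- measure_interferogram(ideal_device, dark, scale_to_peak = NULL)
  expect_identical(unique(ifg$power_w), 0)
  expect_error(measure_interferogram(ideal_device,
                                     gaussian_line(888, grid = seq(885, 889,
                                                                   0.05))),
               "overlap")
})

test_that("interferograms are seed-reproducible", {
  s <- compose_skin_signal("MEL")
  a <- measure_interferogram(chain_device, s, seed = 42)
  b <- measure_interferogram(chain_device, s, seed = 42)
  c <- measure_interferogram(chain_device, s, seed = 43)
  expect_identical(a$power_w, b$power_w)
  expect_false(identical(a$power_w, c$power_w))
  expect_true(all(a$power_w >= 0))   # ASE floor dominates the fluctuations
  expect_equal(a$opd_um, seq(0, 102, by = 0.4))
})

test_that("the calibration matrix has the documented geometry", {
  expect_equal(dim(ideal_cal), c(256, 171))
  expect_equal(attr(ideal_cal, "wavelengths_nm"), seq(890, 975, by = 0.5))
  expect_true(all(ideal_cal >= 0))
  # zero OPD maximises every column of the lossless ideal device
  expect_true(all(apply(ideal_cal, 2, which.max) == 1))
  # linearity in laser power
  a2 <- build_calibration_matrix(ideal_device, power_w = 0.2)
  expect_equal(unclass(a2), unclass(ideal_cal) * 2, tolerance = 1e-12)
})

test_that("phase compensation calibration lands on the transmission
           optimum", {
  dev <- calibrate_pc_phases(chain_device)
  t_cal <- simulate_transmission(dev, 0L, mean(dev$band_nm))
  shifted <- dev
  shifted$pc_phase <- dev$pc_phase + 0.5
  expect_gte(t_cal, simulate_transmission(shifted, 0L, mean(dev$band_nm)))
})
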
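test_that("fluorescence subtraction is exact and grid-checked", {
  s <- compose_skin_signal("MEL")
  a <- measure_interferogram(chain_device, s, seed = 1)
  z <- subtract_fluorescence(a, a)
  expect_identical(unique(z$power_w), 0)
  expect_equal(z$opd_um, a$opd_um)
  b <- a[1:100, ]
  class(b) <- class(a)
  expect_error(subtract_fluorescence(a, b), "OPD grids")
})

test_that("subtract-then-reconstruct equals reconstructing the Raman part
           directly on the noiseless linear device", {
  grid <- seq(800, 1800, by = 1)
  skin <- compose_skin_signal("BCC", TRUE, grid)
  fluor <- raman_spectrum(grid, fluorescence_background(grid), "shift")
  raman <- compose_skin_signal("BCC", FALSE, grid)
  sf <- dftspec:::input_density(chain_device, skin)$scale_factor
  m <- function(x) measure_interferogram(chain_device, x, noise = FALSE,
                                         scale_factor = sf)
  dark <- m(raman_spectrum(grid, numeric(length(grid)), "shift"))
  ydiff <- subtract_fluorescence(m(skin), m(fluor))
  direct <- subtract_fluorescence(m(raman), dark)
  # the deterministic ASE floor cancels in both subtractions (up to the
  # floating-point cancellation of the watt-scale ASE terms)
  expect_equal(ydiff$power_w, direct$power_w, tolerance = 1e-6)
  f1 <- bpdn(chain_cal, ydiff$power_w, 1e-3, tol = 1e-6, max_iter = 500L)
  f2 <- bpdn(chain_cal, direct$power_w, 1e-3, tol = 1e-6, max_iter = 500L)
  expect_lt(max(abs(coef(f1) - coef(f2))), 1e-2 * max(abs(coef(f2))))
})

test_that("a single Lorentzian line is recovered at the right position", {
  grid <- seq(800, 1800, by = 1)
  one <- raman_spectrum(grid,
                        lorentzian_sum(list(raman_peak(1302, 60, 100)),
                                       grid), "shift")
  ifg <- measure_interferogram(chain_device, one, noise = FALSE)
  dark <- measure_interferogram(
    chain_device, raman_spectrum(grid, numeric(length(grid)), "shift"),
    noise = FALSE, scale_to_peak = NULL)
  fit <- bpdn(chain_cal, ifg$power_w - dark$power_w, 1e-3, tol = 1e-6, max_iter = 500L)
  bins <- attr(chain_cal, "wavelengths_nm")
  # the two outermost bins on each side absorb the out-of-band Lorentzian
  # tails and are excluded from the peak search
  interior <- 3:169
  est <- bins[interior][which.max(coef(fit)[interior])]
  expect_lte(abs(est - shift_to_wavelength(1302)), 0.5)
})

test_that("noiseless end-to-end reconstruction recovers every lesion's
           sharp model and dominates its noisy counterpart", {
  for (nm in names(lesion_models())) {
    rec <- reconstruct_raman(chain_device, nm, calibration = chain_cal,
                             weight = 1e-4, noise = FALSE)
    r2 <- r_squared(rec$truth[rec$window], rec$normalized[rec$window])
    expect_gte(r2, 0.90)
  }
})

test_that("reconstruction objects carry consistent pieces", {
  rec <- reconstruct_raman(chain_device, "SK", seed = 3,
                           calibration = chain_cal, weight = 0.01)
  expect_s3_class(rec, "raman_reconstruction")
  expect_length(rec$x, 171)
  expect_equal(rec$shift_cm1,
               wavelength_to_shift(rec$wavelength_nm), tolerance = 1e-12)
  expect_equal(max(abs(rec$normalized[rec$window])), 1)
  expect_equal(max(rec$truth[rec$window]), 1)
  expect_identical(rec$fit$weight, 0.01)
  # prediction reproduces the fitted interferogram
  expect_equal(predict(rec$fit, chain_cal),
               rec$interferogram$power_w - residuals(rec$fit),
               tolerance = 1e-10)
})

test_that("reconstruction is reproducible under a fixed seed", {
  r1 <- reconstruct_raman(chain_device, "AN", seed = 9,
                          calibration = chain_cal, weight = 0.01)
  r2 <- reconstruct_raman(chain_device, "AN", seed = 9,
                          calibration = chain_cal, weight = 0.01)
  expect_identical(r1$x, r2$x)
})
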
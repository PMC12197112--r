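test_that("a single Lorentzian evaluates to its closed form", {
  # MEL 1002 cm-1 row: A = 4.5, omega = 24
  pk <- raman_peak(1002, 24, 4.5)
  expect_equal(lorentzian_sum(list(pk), 1002), 2 * 4.5 / (pi * 24),
               tolerance = 1e-12)
  # half the centre value at r0 +/- FWHM/2
  centre <- lorentzian_sum(list(pk), 1002)
  expect_equal(lorentzian_sum(list(pk), 1002 + 12), centre / 2,
               tolerance = 1e-12)
  expect_equal(lorentzian_sum(list(pk), 1002 - 12), centre / 2,
               tolerance = 1e-12)
})

test_that("Lorentzian mixture guards and degenerate inputs behave", {
  expect_warning(y <- lorentzian_sum(list(), 800:810), "empty")
  expect_identical(y, numeric(11))
  expect_error(raman_peak(1000, -3, 1), "fwhm")
  expect_error(raman_peak(1000, 3, -1), "area")
  expect_error(lorentzian_sum(list(raman_peak(1000, 5, 1)), 3500),
               "3000")
})

test_that("the integral of one Lorentzian recovers its area", {
  grid <- seq(-30000, 33000, by = 0.5)
  pk <- raman_peak(1302, 60, 155)
  y <- (2 * pk$area / pi) * pk$fwhm / (4 * (grid - pk$center)^2 + pk$fwhm^2)
  expect_equal(sum(y) * 0.5, 155, tolerance = 0.01)
})

test_that("phantom registry matches the shared-structure model", {
  models <- lesion_models()
  expect_named(models, c("MEL", "BCC", "SCC", "AK", "AN", "SK"))
  centers <- lapply(models, function(m)
    vapply(m$peaks, `[[`, numeric(1), "center"))
  widths <- lapply(models, function(m)
    vapply(m$peaks, `[[`, numeric(1), "fwhm"))
  for (m in models[-1]) {
    expect_identical(centers[[m$name]], centers$MEL)
    expect_identical(widths[[m$name]], widths$MEL)
  }
  expect_true(all(unlist(centers) >= 800 & unlist(centers) <= 1800))
  # pairwise distinct areas -> pairwise distinct spectra
  grid <- seq(800, 1800, by = 5)
  ys <- vapply(models, function(m) lorentzian_sum(m$peaks, grid),
               numeric(length(grid)))
  expect_equal(nrow(unique(t(ys))), 6)
})

test_that("MEL phantom peaks where its largest-area band sits", {
  grid <- seq(800, 1800, by = 1)
  y <- lorentzian_sum(lesion_models("MEL"), grid)
  expect_true(all(y >= 0))
  expect_lt(abs(grid[which.max(y)] - 1445), 3)
})

test_that("fluorescence polynomial matches its printed constant and a
           Horner oracle", {
  expect_equal(fluorescence_background(0), 382.2)
  # independent evaluation at r = 1000:
  # 382.2 - 906 + 1560 - 1443 + 672.1 - 124 = 141.3
  expect_equal(fluorescence_background(1000), 141.3, tolerance = 1e-12)
  expect_true(all(is.finite(fluorescence_background(seq(0, 1800)))))
  # linear in the coefficients
  p2 <- fluorescence_poly(2 * fluorescence_poly()$coefficients)
  r <- seq(800, 1800, by = 50)
  expect_equal(fluorescence_background(r, p2),
               2 * fluorescence_background(r))
})

test_that("composed skin signal is the sum of its parts", {
  grid <- seq(800, 1800, by = 2)
  for (nm in names(lesion_models())) {
    both <- compose_skin_signal(nm, TRUE, grid)
    raman <- compose_skin_signal(nm, FALSE, grid)
    expect_equal(raman$values, lorentzian_sum(lesion_models(nm), grid))
    expect_equal(both$values - fluorescence_background(grid), raman$values)
    # every lesion adds Raman signal on top of fluorescence at 1445
    expect_gt(compose_skin_signal(nm, TRUE, 1445)$values,
              fluorescence_background(1445))
  }
  expect_identical(both$grid_kind, "shift")
  expect_error(compose_skin_signal("XXX"), "MEL, BCC, SCC, AK, AN, SK")
})

test_that("shift/wavelength conversion is Stokes-consistent and involutive", {
  expect_equal(shift_to_wavelength(0), 830)
  expect_equal(shift_to_wavelength(800), 889.0317, tolerance = 1e-6)
  expect_equal(shift_to_wavelength(1800), 975.7818, tolerance = 1e-6)
  r <- seq(0, 1800, by = 7)
  expect_equal(wavelength_to_shift(shift_to_wavelength(r)), r,
               tolerance = 1e-10)
  expect_error(shift_to_wavelength(1e7 / 830), "nonphysical")
})

test_that("scale_peak replaces one area and is linear in the difference", {
  mel <- lesion_models("MEL")
  same <- scale_peak(mel, 1445, 182)
  grid <- seq(800, 1800, by = 1)
  expect_equal(lorentzian_sum(same, grid), lorentzian_sum(mel, grid))
  g0 <- scale_peak(mel, 1445, 0.1)
  gi <- scale_peak(g0, 1445, 0.7)
  dg <- lorentzian_sum(gi, grid) - lorentzian_sum(g0, grid)
  expect_equal(dg, lorentzian_sum(list(raman_peak(1445, 44, 0.6)), grid),
               tolerance = 1e-12)
  expect_error(scale_peak(mel, 1446, 1), "no peak")
})

test_that("domain conversion preserves integrated intensity", {
  s <- compose_skin_signal("AN", TRUE, seq(800, 1800, by = 0.5))
  w <- as_wavelength(s)
  # trapezoid integrals agree through the Jacobian
  tr <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  expect_equal(tr(w$grid, w$values), tr(s$grid, s$values),
               tolerance = 1e-6)
  back <- as_shift(w)
  expect_equal(back$grid, s$grid, tolerance = 1e-9)
  expect_equal(back$values, s$values, tolerance = 1e-9)
})

test_that("spectrum CSV + sidecar round-trips", {
  s <- compose_skin_signal("SK", TRUE, seq(800, 1800, by = 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(s, path)
  r <- read_spectrum_csv(path)
  expect_equal(r$grid, s$grid)
  expect_equal(r$values, s$values)
  expect_identical(r$grid_kind, "shift")
  expect_equal(r$excitation_nm, 830)
})

test_that("model registry exports readable YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  export_model_registry(path)
  reg <- yaml::read_yaml(path)
  expect_equal(reg$peaks$center_cm1[8], 1445)
  expect_equal(reg$areas$MEL[8], 182)
  expect_equal(reg$fluorescence$coefficients[1], 382.2)
})
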
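test_that("waveguide transfer has the stated loss and no-length identity", {
  wg <- waveguide_spec()
  lam <- seq(890, 975, by = 5)
  expect_equal(waveguide_transfer(wg, lam, length_um = 0),
               rep(1 + 0i, length(lam)))
  # 1 cm of guide loses 0.8 dB
  f <- waveguide_transfer(wg, 935, length_um = 1e4)
  expect_equal(20 * log10(Mod(f)), -0.8, tolerance = 1e-12)
})

test_that("MZI fringe spacing follows lambda^2 / (n_g dL)", {
  dev <- dfts_device("ideal")
  lam <- seq(900, 970, by = 0.005)
  tr <- simulate_transmission(dev, opd_um = 71.6, lambda_nm = lam)
  peaks <- which(diff(sign(diff(tr))) == -2) + 1L
  near <- peaks[abs(lam[peaks] - 935) < 15]
  fsr_sim <- mean(diff(lam[near]))
  fsr_th <- 935^2 / (group_index(dev$waveguide) * 71.6e3)
  expect_equal(fsr_sim, fsr_th, tolerance = 0.02)
})

test_that("coupler matrices conserve energy and reduce to the ideal", {
  m <- coupler_matrix(coupler_spec("ideal"), 935)
  expect_equal(Mod(m)^2, matrix(0.5, 2, 2))
  expect_equal(Conj(t(m)) %*% m, diag(2) + 0i, tolerance = 1e-10)
  # parametric with zero deviation and zero loss is the ideal coupler
  p0 <- coupler_spec("parametric", delta0 = 0)
  expect_equal(coupler_matrix(p0, 912.3), m, ignore_attr = TRUE)
  # parametric stays energy-conserving at every wavelength
  lam <- seq(800, 1000, by = 1)
  a <- dftspec:::coupler_amplitudes(coupler_spec("parametric"), lam)
  expect_equal(a$t^2 + a$k^2, rep(1, length(lam)), tolerance = 1e-12)
  expect_error(dftspec:::coupler_ratio(coupler_spec("parametric",
                                                    delta0 = 0.7), lam),
               "ratio")
})

test_that("two cascaded ideal couplers route all power to one port", {
  m <- coupler_matrix(coupler_spec("ideal"), 935)
  out <- (m %*% m) %*% c(1, 0i)
  expect_equal(as.vector(Mod(out)^2), c(0, 1), tolerance = 1e-12)
})

test_that("phase shifter transfer and interferometric port flip", {
  expect_equal(phase_shifter_transfer(phase_shifter_spec(0, 0)), 1 + 0i)
  f <- phase_shifter_transfer(phase_shifter_spec())
  expect_equal(20 * log10(Mod(f)), -0.711, tolerance = 1e-12)
  # a pi shifter inside a balanced MZI swaps the output port
  m <- coupler_matrix(coupler_spec("ideal"), 935)
  bal <- m %*% diag(c(1, 1 + 0i)) %*% m
  flip <- m %*% diag(c(1, phase_shifter_transfer(
    phase_shifter_spec(pi, 0)))) %*% m
  expect_equal(as.vector(Mod(bal %*% c(1, 0i))^2), c(0, 1),
               tolerance = 1e-12)
  expect_equal(as.vector(Mod(flip %*% c(1, 0i))^2), c(1, 0),
               tolerance = 1e-12)
})

test_that("amplifier gain, quantum-limit warning and input guard", {
  sp <- amplifier_spec()
  expect_equal(amplifier_gain(sp, 935), 1000)
  expect_equal(amplifier_gain(sp, c(900, 970)), c(1000, 1000))
  g <- amplifier_spec(gain_shape = "gaussian")
  expect_equal(amplifier_gain(g, 935), 1000)
  expect_lt(amplifier_gain(g, 890), amplifier_gain(g, 935) / 50)
  expect_warning(amplifier_spec(noise_figure_db = 2), "quantum limit")
  expect_error(amplifier_apply(c(-1, 1), sp, c(930, 940)), "non-negative")
})

test_that("ASE mean is reproduced by the seeded realizations", {
  sp <- amplifier_spec()
  lam <- seq(920, 950, by = 0.5)
  mu <- ase_mean_density(sp, lam)
  # spontaneous-emission factor at the quantum limit (NF = 10 log10 2) is 1
  nfq <- amplifier_spec(noise_figure_db = 10 * log10(2))
  expect_equal(10^(nfq$noise_figure_db / 10) / 2, 1, tolerance = 1e-12)
  # zero input -> pure ASE; average over 200 seeds recovers the mean
  outs <- vapply(1:200, function(s)
    amplifier_apply(numeric(length(lam)), sp, lam, seed = s,
                    integration_time_s = 1e-6),
    numeric(length(lam)))
  expect_equal(mean(rowMeans(outs) / mu), 1, tolerance = 0.05)
  # deterministic part: zero input, no noise -> exactly the mean
  expect_equal(amplifier_apply(numeric(length(lam)), sp, lam,
                               noise = FALSE), mu)
})

test_that("lossless chain transmission conserves energy pointwise", {
  dev <- dfts_device("component_chain",
                     waveguide = waveguide_spec(loss_db_cm = 0),
                     phase_shifter = phase_shifter_spec(0, 0),
                     amplifiers = FALSE)
  lam <- seq(890, 975, by = 0.5)
  for (k in c(0L, 7L, 179L, 255L)) {
    tr <- simulate_transmission(dev, k, lam)
    expect_true(all(tr <= 1 + 1e-12))
    expect_true(all(tr >= -1e-12))
  }
  # with losses, strictly below unity
  lossy <- dfts_device("component_chain")
  expect_true(all(simulate_transmission(lossy, 179L, lam) < 1))
})
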
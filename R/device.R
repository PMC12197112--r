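#' Digital path-difference selector (DPDS) bank
#'
#' The eight binary-weighted switch stages of the spectrometer: a fixed top
#' waveguide of 35 um per stage, and bottom waveguides whose lengths differ
#' from 35 um by exactly `0.4 * 2^(i-1)` um for stage i.  Construction
#' verifies this binary weighting.
#'
#' @param top_um Fixed top-arm length per stage, um.
#' @param bottom_um The eight bottom-arm lengths, um.
#' @return An object of class `"dpds_bank"`.
#' @export
#' @examples
#' b <- dpds_bank()
#' abs(b$bottom_um - 35)  # 0.4, 0.8, 1.6, ..., 51.2 um
dpds_bank <- function(top_um = 35,
                      bottom_um = c(34.6, 35.8, 33.4, 38.2, 28.6, 47.8,
                                    9.4, 86.2)) {
  stopifnot(length(bottom_um) == 8L)
  expected <- 0.4 * 2^(0:7)
  got <- abs(bottom_um - top_um)
  if (any(abs(got - expected) > 1e-9))
    stop("DPDS stage length differences must be 0.4 * 2^(i-1) um",
         call. = FALSE)
  structure(list(top_um = top_um, bottom_um = bottom_um,
                 stage_delta_um = got),
            class = "dpds_bank")
}

#' Decode a switch configuration into an optical-path difference
#'
#' Each selected stage i contributes `0.4 * 2^(i-1)` um, so an 8-bit
#' configuration k maps to `OPD = k * 0.4` um on a uniform 400 nm grid.
#' `config` may be an integer in 0..255 or an 8-element 0/1 vector whose
#' first element is stage 1 (the least significant, 0.4 um stage).  Note
#' this decoding reproduces the documented anchor: the displayed tuple
#' `(1,1,0,0,1,1,0,1)` is configuration k = 179 and ΔL = 71.6 um.
#'
#' @param config Integer 0..255, or an 8-bit 0/1 vector (stage 1 first).
#' @return The optical-path difference, micrometres.
#' @seealso [opd_to_config()] for the inverse.
#' @export
#' @examples
#' config_to_opd(c(1, 1, 0, 0, 1, 1, 0, 1))  # 71.6 um
#' config_to_opd(255)                        # 102 um, all stages on
config_to_opd <- function(config) {
  k <- config_to_k(config)
  round(k * 0.4, 4)   # exact decimal on the 400 nm grid
}

config_to_k <- function(config) {
  if (length(config) == 1L) {
    k <- as.integer(config)
    if (is.na(k) || k < 0L || k > 255L)
      stop("configuration index must be an integer in 0..255", call. = FALSE)
    return(k)
  }
  if (length(config) != 8L)
    stop("a switch configuration has exactly 8 bits", call. = FALSE)
  if (!all(config %in% c(0, 1)))
    stop("configuration bits must be 0 or 1", call. = FALSE)
  as.integer(sum(config * 2^(0:7)))
}

#' @rdname config_to_opd
#' @param k Configuration index 0..255.
#' @return `opd_to_config()` returns the 8-bit 0/1 vector (stage 1 first).
#' @export
opd_to_config <- function(k) {
  k <- config_to_k(k)
  as.integer(intToBits(k))[1:8]
}

#' Ideal Fourier-transform spectrometer design
#'
#' The reference single-MZI spectrometer specified by two 16-element arm
#' length vectors; combining every top length with every bottom length
#' yields the 256 interferometer configurations.
#'
#' @param top_um,bottom_um The 16 top-arm and 16 bottom-arm lengths, um.
#' @return An object of class `"ifts_design"`.
#' @export
ifts_design <- function(
    top_um = c(140, 140.8, 143.2, 144, 152.8, 153.6, 156, 156.8,
               191.2, 192, 194.4, 195.2, 204, 204.8, 207.2, 208),
    bottom_um = c(140, 139.6, 138.4, 138, 133.6, 133.2, 132, 131.6,
                  114.4, 114, 112.8, 112.4, 108, 107.6, 106.4, 106)) {
  stopifnot(length(top_um) == 16L, length(bottom_um) == 16L)
  structure(list(top_um = top_um, bottom_um = bottom_um),
            class = "ifts_design")
}

#' All 256 optical-path differences of the ideal FTS
#'
#' Forms every difference `Lt_i - Lb_j` of the design's arm-length vectors
#' and verifies, as an integrity check against transcription mistakes, that
#' each is a non-negative multiple of 0.4 um and that the set is exactly
#' `{0, 0.4, ..., 102.0}` um — the same OPD grid the switch-based device
#' reaches digitally.
#'
#' @param design An [ifts_design()].
#' @param sorted Return the OPDs sorted ascending?
#' @return Numeric vector of 256 OPDs, micrometres.
#' @export
ifts_opd_table <- function(design = ifts_design(), sorted = TRUE) {
  stopifnot(inherits(design, "ifts_design"))
  opd <- as.vector(outer(design$top_um, design$bottom_um, `-`))
  mult <- opd / 0.4
  if (any(opd < -1e-9) || any(abs(mult - round(mult)) > 1e-6))
    stop("integrity error: OPDs are not non-negative multiples of 0.4 um",
         call. = FALSE)
  opd <- round(round(mult) * 0.4, 4)
  if (!isTRUE(all.equal(sort(opd), seq(0, 102, by = 0.4))))
    stop("integrity error: OPD set is not {0, 0.4, ..., 102.0} um",
         call. = FALSE)
  if (sorted) sort(opd) else opd
}

#' Switch-based digital FTS device model
#'
#' Assembles the full spectrometer: an 8-stage DPDS/phase-compensator
#' interferometer between two 2x2 couplers, with optional booster
#' amplifiers at input and output.  Two fidelities are available:
#'
#' * `"ideal"` — lossless two-path interferometer,
#'   `T(lambda) = cos^2(pi * n_eff(lambda) * OPD / lambda)`; couplers exact
#'   50:50, no amplifiers.  This reproduces the reference (ideal-MZI)
#'   spectrometer.
#' * `"component_chain"` — cascaded transfer matrices of the parametric
#'   couplers, lossy waveguides and phase shifters; booster amplifiers with
#'   ASE noise are engaged during power measurements.
#'
#' @param mode Simulation fidelity.
#' @param excitation_nm Raman excitation wavelength, nm.
#' @param wavelength_grid_nm Simulation wavelength grid, nm.  The default
#'   spans the 890--975 nm instrument band with margin at 0.05 nm spacing
#'   (fine enough to sample the fringes of the largest, 102 um, OPD).
#' @param waveguide [waveguide_spec()] carrying loss and dispersion; the
#'   ideal mode forces zero loss.
#' @param coupler [coupler_spec()]; defaults to parametric in chain mode.
#' @param phase_shifter [phase_shifter_spec()].
#' @param input_amplifier,output_amplifier [amplifier_spec()]s.
#' @param amplifiers Engage the amplifiers in power measurements?
#' @param integration_time_s Effective detector averaging time, seconds;
#'   sets the ASE fluctuation scale (per-bin relative intensity noise
#'   `1/sqrt(bin bandwidth x time)`).  The default (265 s) is calibrated so
#'   the RMS noise of a measured power difference equals the response to an
#'   0.4 a.u. area change of the 1445 cm^-1 band at the default input power
#'   scale — the device's documented sensitivity threshold.
#' @param dpds [dpds_bank()].
#' @param pc_length_um Balanced phase-compensator arm length per stage, um.
#' @param pc_phase Compensation phase applied to the bottom arm, radians.
#' @param band_nm Instrument (calibration) band, nm.
#' @return An object of class `"dfts_device"`.
#' @export
#' @examples
#' dev <- dfts_device("ideal")
#' dev
dfts_device <- function(mode = c("component_chain", "ideal"),
                        excitation_nm = 830,
                        wavelength_grid_nm = seq(885, 980, by = 0.05),
                        waveguide = NULL,
                        coupler = NULL,
                        phase_shifter = phase_shifter_spec(),
                        input_amplifier = amplifier_spec(),
                        output_amplifier = amplifier_spec(),
                        amplifiers = NULL,
                        integration_time_s = 265,
                        dpds = dpds_bank(),
                        pc_length_um = 10,
                        pc_phase = 0,
                        band_nm = c(890, 975)) {
  mode <- match.arg(mode)
  if (is.null(waveguide))
    waveguide <- waveguide_spec(loss_db_cm = if (mode == "ideal") 0 else 0.8)
  if (mode == "ideal") waveguide$loss_db_cm <- 0
  if (is.null(coupler))
    coupler <- coupler_spec(if (mode == "ideal") "ideal" else "parametric")
  if (is.null(amplifiers)) amplifiers <- mode == "component_chain"
  stopifnot(inherits(waveguide, "waveguide_spec"),
            inherits(coupler, "coupler_spec"),
            inherits(dpds, "dpds_bank"),
            length(wavelength_grid_nm) > 1L,
            all(diff(wavelength_grid_nm) > 0))
  structure(list(mode = mode, excitation_nm = excitation_nm,
                 grid_nm = wavelength_grid_nm, waveguide = waveguide,
                 coupler = coupler, phase_shifter = phase_shifter,
                 input_amplifier = input_amplifier,
                 output_amplifier = output_amplifier,
                 amplifiers = amplifiers,
                 integration_time_s = integration_time_s,
                 dpds = dpds, pc_length_um = pc_length_um,
                 pc_phase = pc_phase, band_nm = band_nm,
                 n_stages = 8L, n_configs = 256L, opd_unit_um = 0.4),
            class = "dfts_device")
}

#' @export
print.dfts_device <- function(x, ...) {
  cat(sprintf(paste0(
    "sbDFTS device (%s mode)\n",
    "  %d stages, %d configurations, OPD grid 0..%g um step %g um\n",
    "  band %g-%g nm, excitation %g nm, group index %.4f\n",
    "  amplifiers %s, waveguide loss %g dB/cm, coupler %s\n"),
    x$mode, x$n_stages, x$n_configs, (x$n_configs - 1) * x$opd_unit_um,
    x$opd_unit_um, x$band_nm[1], x$band_nm[2], x$excitation_nm,
    group_index(x$waveguide),
    if (x$amplifiers) "on" else "off", x$waveguide$loss_db_cm,
    x$coupler$mode))
  invisible(x)
}

## Common per-arm path length outside the selectable difference: 8 DPDS
## stages (35 um top) plus 8 balanced PC stages.
device_common_arm_um <- function(device) {
  device$n_stages * (device$dpds$top_um + device$pc_length_um)
}

## Transmission matrix T[k, lambda] for configurations `ks` on grid
## `lambda`.  Chain mode cascades coupler 1 -> arms -> coupler 2 and reads
## the cross port (bright at zero OPD); amplifier gain is NOT included here.
transmission_matrix <- function(device, ks = 0:255,
                                lambda = device$grid_nm) {
  opd_nm <- ks * device$opd_unit_um * 1e3
  neff <- effective_index(device$waveguide, lambda)
  dphi <- outer(opd_nm, neff / lambda) * 2 * pi        # |ks| x |lambda|
  if (device$mode == "ideal")
    return(cos(dphi / 2)^2)
  c1 <- coupler_amplitudes(device$coupler, lambda)
  c2 <- c1   # identical coupler design at input and output
  wg <- device$waveguide
  common_um <- device_common_arm_um(device)
  ps8 <- phase_shifter_transfer(device$phase_shifter)^device$n_stages
  a_top <- waveguide_transfer(wg, lambda, common_um) * ps8
  extra_loss <- 10^(-(wg$loss_db_cm * ks * device$opd_unit_um * 1e-4) / 20)
  ## bottom arm: common path plus the selected extra length -> extra loss
  ## (per k) and the interferometric phase difference, plus compensation.
  a_bot <- outer(extra_loss, a_top * exp(1i * device$pc_phase)) *
    exp(1i * dphi)
  field <- outer(rep(1, length(ks)), c2$k * c1$t * a_top) +
    sweep(a_bot, 2, c2$t * c1$k, `*`)
  Mod(field)^2
}

#' Simulate the transmission of one configuration
#'
#' Wavelength-resolved power transmission `T(lambda)` of a single switch
#' configuration (or explicit OPD).  In ideal mode this is
#' `cos^2(pi * n_eff * OPD / lambda)`; in component-chain mode the cascaded
#' coupler/waveguide/phase-shifter matrices are used.  Amplifier gain can
#' optionally be folded in (`amplifiers = TRUE`); ASE, being additive power
#' rather than transmission, only enters power measurements
#' ([measure_interferogram()]).
#'
#' @param device A [dfts_device()].
#' @param config Configuration (integer 0..255 or 8-bit vector); ignored
#'   when `opd_um` is given.
#' @param lambda_nm Wavelength grid, nm (default: the device grid).
#' @param opd_um Optional explicit OPD, um (must be a multiple of 0.4 um).
#' @param amplifiers Multiply by the input and output amplifier gains?
#' @return Numeric vector of transmissions, one per wavelength.
#' @export
#' @examples
#' dev <- dfts_device("ideal")
#' t0 <- simulate_transmission(dev, 0)   # balanced: T = 1 everywhere
#' range(t0)
simulate_transmission <- function(device, config = 0L, lambda_nm = NULL,
                                  opd_um = NULL, amplifiers = FALSE) {
  stopifnot(inherits(device, "dfts_device"))
  if (is.null(lambda_nm)) lambda_nm <- device$grid_nm
  if (any(lambda_nm < 800 | lambda_nm > 1000))
    stop("wavelength grid must lie within 800-1000 nm", call. = FALSE)
  k <- if (is.null(opd_um)) config_to_k(config) else {
    kk <- opd_um / device$opd_unit_um
    if (abs(kk - round(kk)) > 1e-6)
      stop("'opd_um' must be a multiple of ", device$opd_unit_um, " um",
           call. = FALSE)
    as.integer(round(kk))
  }
  tr <- transmission_matrix(device, k, lambda_nm)[1L, ]
  if (amplifiers)
    tr <- tr * amplifier_gain(device$input_amplifier, lambda_nm) *
      amplifier_gain(device$output_amplifier, lambda_nm)
  tr
}

#' One-time phase-compensator calibration
#'
#' Searches for the compensation phase that maximises the band-centre
#' transmission of the balanced (zero-OPD) configuration, emulating the
#' static phase-offset correction the compensator stages perform.  Returns
#' a device with `pc_phase` set.
#'
#' @param device A [dfts_device()].
#' @param at_nm Calibration wavelength, nm (default: band centre).
#' @param n_grid Number of candidate phases searched on \[-pi, pi\).
#' @return The device with the calibrated `pc_phase`.
#' @export
calibrate_pc_phases <- function(device, at_nm = mean(device$band_nm),
                                n_grid = 721L) {
  stopifnot(inherits(device, "dfts_device"))
  phases <- seq(-pi, pi, length.out = n_grid)
  tr <- vapply(phases, function(p) {
    device$pc_phase <- p
    simulate_transmission(device, 0L, at_nm)
  }, numeric(1))
  device$pc_phase <- phases[which.max(tr)]
  device
}

## Map an input spectrum to a power density (W/nm) on the device grid.
## Shift-domain spectra are converted with the Jacobian; `scale_factor`
## (W/nm per input unit) is applied if given, else derived so the peak
## density equals `scale_to_peak`.
input_density <- function(device, input, scale_factor = NULL,
                          scale_to_peak = 1e-9) {
  stopifnot(inherits(input, "raman_spectrum"))
  w <- as_wavelength(input)
  dens <- stats::approx(w$grid, w$values, xout = device$grid_nm,
                        yleft = 0, yright = 0, rule = 1)$y
  dens[is.na(dens)] <- 0
  if (max(w$grid) < device$band_nm[1] || min(w$grid) > device$band_nm[2])
    stop("input spectrum does not overlap the instrument band",
         call. = FALSE)
  if (is.null(scale_factor)) {
    mx <- max(dens)
    scale_factor <- if (mx > 0 && !is.null(scale_to_peak))
      scale_to_peak / mx else 1
  }
  list(density = dens * scale_factor, scale_factor = scale_factor)
}

#' Measure an interferogram
#'
#' Injects a spectrum into the device and records the detected power for
#' every one of the 256 switch configurations:
#' `P_k = integral T_k(lambda) S(lambda) dlambda`, with the amplifier chain
#' (gain plus seeded ASE realization, independent per configuration)
#' applied at input and output when the device has amplifiers engaged.
#'
#' @param device A [dfts_device()].
#' @param input A [raman_spectrum] overlapping the instrument band.  Spectra
#'   in arbitrary units are scaled so their peak wavelength density equals
#'   `scale_to_peak` (default 1 nW/nm) unless an explicit `scale_factor` is
#'   supplied; pass the factor returned in the result to share one absolute
#'   scale across several measurements (required by the subtraction
#'   protocol).
#' @param seed Integer seed for the ASE noise realization.
#' @param noise Include stochastic ASE fluctuations?  The mean ASE floor is
#'   always present when amplifiers are engaged.
#' @param scale_factor,scale_to_peak Input power scaling, see above.
#' @return An object of class `"interferogram"`: a data frame with columns
#'   `opd_um` and `power_w` plus metadata attributes (`mode`, `seed`,
#'   `scale_factor`).
#' @export
measure_interferogram <- function(device, input, seed = NULL, noise = TRUE,
                                  scale_factor = NULL, scale_to_peak = 1e-9) {
  stopifnot(inherits(device, "dfts_device"))
  inp <- input_density(device, input, scale_factor, scale_to_peak)
  lam <- device$grid_nm
  dl <- mean(diff(lam))
  tr <- transmission_matrix(device, 0:255, lam)
  if (device$amplifiers) {
    g1 <- amplifier_gain(device$input_amplifier, lam)
    g2 <- amplifier_gain(device$output_amplifier, lam)
    mu1 <- ase_mean_density(device$input_amplifier, lam)
    mu2 <- ase_mean_density(device$output_amplifier, lam)
    tg <- sweep(tr, 2, g2, `*`)                      # T * G_out
    p <- as.vector(tg %*% ((g1 * inp$density + mu1) * dl)) +
      sum(mu2) * dl
    if (noise) {
      sd1 <- ase_sd_density(mu1, lam, dl, device$integration_time_s)
      sd2 <- ase_sd_density(mu2, lam, dl, device$integration_time_s)
      p <- p + with_local_seed(seed, {
        e1 <- matrix(stats::rnorm(256L * length(lam)), 256L)
        e2 <- matrix(stats::rnorm(256L * length(lam)), 256L)
        rowSums(tg * sweep(e1, 2, sd1, `*`)) * dl +
          as.vector(e2 %*% sd2) * dl
      })
    }
  } else {
    p <- as.vector(tr %*% (inp$density * dl))
  }
  out <- data.frame(opd_um = (0:255) * device$opd_unit_um, power_w = p)
  structure(out, class = c("interferogram", "data.frame"),
            mode = device$mode, seed = seed,
            scale_factor = inp$scale_factor)
}

#' @export
print.interferogram <- function(x, ...) {
  cat(sprintf("Interferogram: %d (OPD, power) pairs, OPD 0..%g um, %s mode\n",
              nrow(x), max(x$opd_um), attr(x, "mode")))
  cat(sprintf("  power range [%.4g, %.4g] W\n",
              min(x$power_w), max(x$power_w)))
  invisible(x)
}

#' @export
plot.interferogram <- function(x, ...) {
  graphics::plot(x$opd_um, x$power_w, type = "h", xlab = "OPD (um)",
                 ylab = "Detected power (W)", ...)
  invisible(x)
}

#' Build the calibration matrix
#'
#' Sweeps a narrow-line continuous-wave laser (Gaussian line, default
#' 0.5 nm FWHM, 100 mW) across the instrument band (890--975 nm in 0.5 nm
#' steps) and records one interferogram per line; the columns of the
#' resulting 256 x 171 matrix are those interferograms.  Columns are the
#' dark-corrected deterministic response: at 100 mW the line dwarfs the ASE
#' noise floor, so the calibration is computed in the strong-signal limit.
#'
#' @param device A [dfts_device()].
#' @param from_nm,to_nm,step_nm Line-centre sweep, nm.
#' @param fwhm_nm Laser line FWHM, nm.
#' @param power_w Laser power, W.
#' @return An object of class `"calibration_matrix"`: the numeric matrix
#'   with attributes `wavelengths_nm`, `opd_um` and `device_hash`.
#' @export
build_calibration_matrix <- function(device, from_nm = 890, to_nm = 975,
                                     step_nm = 0.5, fwhm_nm = 0.5,
                                     power_w = 0.1) {
  stopifnot(inherits(device, "dfts_device"))
  centers <- seq(from_nm, to_nm, by = step_nm)
  lam <- device$grid_nm
  dl <- mean(diff(lam))
  ## Gaussian lines, each integrating to power_w over wavelength
  peak <- power_w / (fwhm_nm * sqrt(pi / (4 * log(2))))
  lines <- vapply(centers, function(c0)
    peak * exp(-4 * log(2) * ((lam - c0) / fwhm_nm)^2),
    numeric(length(lam)))
  tr <- transmission_matrix(device, 0:255, lam)
  if (device$amplifiers) {
    g1 <- amplifier_gain(device$input_amplifier, lam)
    g2 <- amplifier_gain(device$output_amplifier, lam)
    tr <- sweep(tr, 2, g1 * g2, `*`)
  }
  a <- tr %*% (lines * dl)
  structure(a, class = c("calibration_matrix", class(a)),
            wavelengths_nm = centers,
            opd_um = (0:255) * device$opd_unit_um,
            device_hash = device_hash(device))
}

#' @export
print.calibration_matrix <- function(x, ...) {
  w <- attr(x, "wavelengths_nm")
  cat(sprintf("Calibration matrix: %d configurations x %d wavelength bins\n",
              nrow(x), ncol(x)))
  cat(sprintf("  bins %g-%g nm, device hash %s\n", min(w), max(w),
              attr(x, "device_hash")))
  invisible(x)
}

## FNV-1a hash (32-bit) of the device's physically relevant parameters;
## used to key calibration-matrix caching.
device_hash <- function(device) {
  key <- c(device$mode, format(device$grid_nm[1]),
           format(device$grid_nm[length(device$grid_nm)]),
           format(mean(diff(device$grid_nm))),
           format(unlist(device$waveguide)), format(unlist(device$coupler)),
           format(unlist(device$phase_shifter)),
           format(unlist(device$input_amplifier)),
           format(unlist(device$output_amplifier)),
           format(device$amplifiers), format(device$integration_time_s),
           format(device$pc_phase))
  fnv1a32(paste(key, collapse = "|"))
}

fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    ## 32-bit modular multiply in two 16-bit halves (doubles stay exact)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}
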
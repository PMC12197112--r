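## Physical constants (SI)
.h_planck <- 6.62607015e-34   # J s
.c_light  <- 2.99792458e8     # m/s

#' Waveguide specification
#'
#' SiN strip waveguide with a first-order (linear) effective-index
#' dispersion model, `n_eff(lambda) = n_eff0 + dn_dlambda * (lambda -
#' lambda0)`.  The default dispersion slope is calibrated so that the group
#' index `n_g = n_eff0 - lambda0 * dn_dlambda` is about 2.134 at 935 nm,
#' placing the Rayleigh resolution of the 8-stage device at 4 nm.
#'
#' @param length_um Physical length, micrometres.
#' @param loss_db_cm Propagation loss, dB/cm (default 0.8).
#' @param n_eff0 Effective index at the reference wavelength.
#' @param dn_dlambda Dispersion slope, 1/nm (negative for normal dispersion).
#' @param lambda0_nm Reference wavelength, nm.
#' @return An object of class `"waveguide_spec"`.
#' @export
waveguide_spec <- function(length_um = 0, loss_db_cm = 0.8, n_eff0 = 1.80,
                           dn_dlambda = -3.576e-4, lambda0_nm = 935) {
  stopifnot(length_um >= 0, loss_db_cm >= 0)
  ng <- n_eff0 - lambda0_nm * dn_dlambda
  if (ng <= 1)
    stop("group index must exceed 1; check the dispersion model",
         call. = FALSE)
  structure(list(length_um = length_um, loss_db_cm = loss_db_cm,
                 n_eff0 = n_eff0, dn_dlambda = dn_dlambda,
                 lambda0_nm = lambda0_nm),
            class = "waveguide_spec")
}

#' @rdname waveguide_spec
#' @param spec A `waveguide_spec`.
#' @export
group_index <- function(spec) {
  stopifnot(inherits(spec, "waveguide_spec"))
  spec$n_eff0 - spec$lambda0_nm * spec$dn_dlambda
}

#' Effective index at given wavelengths
#' @param spec A [waveguide_spec()].
#' @param lambda_nm Wavelengths, nm.
#' @return Numeric vector of effective indices.
#' @export
effective_index <- function(spec, lambda_nm) {
  stopifnot(inherits(spec, "waveguide_spec"))
  spec$n_eff0 + spec$dn_dlambda * (lambda_nm - spec$lambda0_nm)
}

#' Waveguide complex transfer factor
#'
#' Field transmission of a straight waveguide:
#' amplitude `10^(-loss_dB/20)` with `loss_dB = loss_db_cm * L_cm`, and
#' phase `2*pi*n_eff(lambda)*L/lambda`.
#'
#' @param spec A [waveguide_spec()].
#' @param lambda_nm Wavelength grid, nm.
#' @param length_um Optional length override, micrometres.
#' @return Complex vector of field factors, one per wavelength.
#' @export
#' @examples
#' w <- waveguide_spec(length_um = 1e4)      # 1 cm
#' 20 * log10(Mod(waveguide_transfer(w, 935)))  # -0.8 dB
waveguide_transfer <- function(spec, lambda_nm, length_um = spec$length_um) {
  stopifnot(inherits(spec, "waveguide_spec"), all(lambda_nm > 0))
  loss_db <- spec$loss_db_cm * length_um * 1e-4
  amp <- 10^(-loss_db / 20)
  phase <- 2 * pi * effective_index(spec, lambda_nm) * (length_um * 1e3) /
    lambda_nm
  amp * exp(1i * phase)
}

#' 2x2 coupler specification
#'
#' Ideal mode is an exact lossless 50:50 coupler.  Parametric mode models a
#' wavelength-dependent, non-uniform power splitting ratio
#' `0.5 + delta(lambda)` with `delta(lambda) = delta0 *
#' sin(2*pi*(lambda - center_nm)/period_nm)`, energy conserving up to the
#' insertion loss.  This is a stand-in for an adiabatic coupler operated at
#' the edge of the adiabatic regime.
#'
#' @param mode `"ideal"` or `"parametric"`.
#' @param delta0 Amplitude of the split-ratio deviation (default 0.02).
#' @param period_nm Ripple period, nm.
#' @param center_nm Ripple phase reference, nm.
#' @param insertion_loss_db Insertion loss, dB.
#' @return An object of class `"coupler_spec"`.
#' @export
coupler_spec <- function(mode = c("ideal", "parametric"), delta0 = 0.02,
                         period_nm = 40, center_nm = 935,
                         insertion_loss_db = 0) {
  mode <- match.arg(mode)
  stopifnot(insertion_loss_db >= 0, period_nm > 0)
  structure(list(mode = mode, delta0 = delta0, period_nm = period_nm,
                 center_nm = center_nm,
                 insertion_loss_db = insertion_loss_db),
            class = "coupler_spec")
}

## Cross-coupling power ratio rho(lambda) in [0, 1].
coupler_ratio <- function(spec, lambda_nm) {
  if (spec$mode == "ideal") return(rep(0.5, length(lambda_nm)))
  rho <- 0.5 + spec$delta0 *
    sin(2 * pi * (lambda_nm - spec$center_nm) / spec$period_nm)
  if (any(rho < 0 | rho > 1))
    stop("coupler power ratio outside [0, 1]; reduce 'delta0'",
         call. = FALSE)
  rho
}

## Field amplitudes (bar t, cross k) of the 2x2 coupler, vectorised over
## wavelength.  t^2 + k^2 = insertion-loss factor.
coupler_amplitudes <- function(spec, lambda_nm) {
  rho <- coupler_ratio(spec, lambda_nm)
  il <- 10^(-spec$insertion_loss_db / 20)
  list(t = il * sqrt(1 - rho), k = il * sqrt(rho))
}

#' 2x2 coupler transfer matrix
#'
#' Scattering matrix `[[t, i k], [i k, t]]` of the coupler at a single
#' wavelength, with `t = sqrt(1 - rho)`, `k = sqrt(rho)` and `rho` the power
#' cross-coupling ratio.  Lossless couplers yield a unitary matrix.
#'
#' @param spec A [coupler_spec()].
#' @param lambda_nm A single wavelength, nm.
#' @return A 2x2 complex matrix of class `"transfer_matrix"`.
#' @export
#' @examples
#' m <- coupler_matrix(coupler_spec("ideal"), 935)
#' Mod(m)^2  # 50:50 power split
coupler_matrix <- function(spec, lambda_nm) {
  stopifnot(inherits(spec, "coupler_spec"), length(lambda_nm) == 1L)
  a <- coupler_amplitudes(spec, lambda_nm)
  m <- matrix(c(a$t, 1i * a$k, 1i * a$k, a$t), 2, 2)
  structure(m, class = c("transfer_matrix", class(m)))
}

#' Phase shifter specification and transfer factor
#'
#' Broadband thermo-optic phase shifter with a settable phase and a fixed
#' insertion loss (default 0.711 dB).
#'
#' @param phase Phase, radians.
#' @param insertion_loss_db Insertion loss, dB.
#' @return `phase_shifter_spec()` returns a `"phase_shifter_spec"`;
#'   `phase_shifter_transfer()` the complex field factor
#'   `10^(-IL/20) * exp(i*phase)`.
#' @export
#' @examples
#' Mod(phase_shifter_transfer(phase_shifter_spec()))^2  # -0.711 dB
phase_shifter_spec <- function(phase = 0, insertion_loss_db = 0.711) {
  stopifnot(insertion_loss_db >= 0)
  structure(list(phase = phase, insertion_loss_db = insertion_loss_db),
            class = "phase_shifter_spec")
}

#' @rdname phase_shifter_spec
#' @param spec A `phase_shifter_spec`.
#' @export
phase_shifter_transfer <- function(spec = phase_shifter_spec()) {
  stopifnot(inherits(spec, "phase_shifter_spec"))
  10^(-spec$insertion_loss_db / 20) * exp(1i * spec$phase)
}

#' Booster optical amplifier specification
#'
#' Semiconductor booster amplifier with amplified spontaneous emission
#' (ASE).  Defaults follow a commercial 930 nm booster: 30 dB peak gain,
#' 8.5 dB noise figure, ASE centred at 935 nm with a 37 nm 3 dB bandwidth.
#' The signal gain is flat by default (the printed gain figure applies
#' across the band); `gain_shape = "gaussian"` instead rolls the gain off
#' with the same Gaussian profile as the ASE, emulating band-edge gain
#' reduction.  The ASE spectrum is always Gaussian-shaped (centre
#' `ase_center_nm`, 3 dB full width `ase_bandwidth_nm`).
#'
#' A noise figure below the 3 dB quantum limit triggers a warning but is not
#' rejected.
#'
#' @param gain_db Peak signal gain, dB.
#' @param noise_figure_db Noise figure, dB.
#' @param ase_center_nm ASE profile centre, nm.
#' @param ase_bandwidth_nm ASE 3 dB (full) bandwidth, nm.
#' @param gain_shape `"flat"` (default) or `"gaussian"`.
#' @return An object of class `"amplifier_spec"`.
#' @export
amplifier_spec <- function(gain_db = 30, noise_figure_db = 8.5,
                           ase_center_nm = 935, ase_bandwidth_nm = 37,
                           gain_shape = c("flat", "gaussian")) {
  gain_shape <- match.arg(gain_shape)
  stopifnot(gain_db >= 0, ase_bandwidth_nm > 0)
  if (noise_figure_db < 3)
    warning("noise figure below the 3 dB quantum limit")
  structure(list(gain_db = gain_db, noise_figure_db = noise_figure_db,
                 ase_center_nm = ase_center_nm,
                 ase_bandwidth_nm = ase_bandwidth_nm,
                 gain_shape = gain_shape),
            class = "amplifier_spec")
}

#' Wavelength-resolved linear power gain
#' @param spec An [amplifier_spec()].
#' @param lambda_nm Wavelengths, nm.
#' @return Linear power gain per wavelength.
#' @export
amplifier_gain <- function(spec, lambda_nm) {
  g0 <- 10^(spec$gain_db / 10)
  if (spec$gain_shape == "flat") return(rep(g0, length(lambda_nm)))
  g0 * exp(-4 * log(2) *
             ((lambda_nm - spec$ase_center_nm) / spec$ase_bandwidth_nm)^2)
}

#' Mean ASE spectral power density
#'
#' Per-polarization mean ASE density
#' \eqn{\rho(\lambda) = n_{sp} (G(\lambda) - 1) h c^2 / \lambda^3} (W/nm),
#' with spontaneous-emission factor \eqn{n_{sp} = 10^{NF/10}/2}.  The
#' Gaussian gain profile gives the ASE its 3 dB bandwidth.
#'
#' @inheritParams amplifier_gain
#' @return Mean ASE density, W/nm, per wavelength.
#' @export
ase_mean_density <- function(spec, lambda_nm) {
  nsp <- 10^(spec$noise_figure_db / 10) / 2
  ## ASE carries the amplifier's Gaussian noise profile regardless of the
  ## signal-gain shape
  g0 <- 10^(spec$gain_db / 10)
  shape <- exp(-4 * log(2) *
                 ((lambda_nm - spec$ase_center_nm) /
                    spec$ase_bandwidth_nm)^2)
  lam_m <- lambda_nm * 1e-9
  nsp * pmax(g0 * shape - 1, 0) * .h_planck * .c_light^2 / lam_m^3 * 1e-9
}

## Per-bin sd of the detected ASE density: relative intensity noise of
## thermal light averaged over the optical bandwidth of one bin and the
## detector integration time, sd = mean / sqrt(dnu_bin * tau).
ase_sd_density <- function(mean_density, lambda_nm, bin_nm,
                           integration_time_s = 1) {
  dnu <- .c_light * 1e9 * bin_nm / lambda_nm^2   # Hz per bin
  mean_density / sqrt(pmax(dnu * integration_time_s, .Machine$double.eps))
}

#' Apply an optical amplifier to a spectral power density
#'
#' Returns `G(lambda) * input + ASE`, where the ASE realization is the mean
#' density plus seeded Gaussian fluctuations per wavelength bin.  The
#' fluctuation scale models power-meter averaging of thermal light:
#' sd = mean / sqrt(bin optical bandwidth x integration time).
#'
#' @param density Input spectral power density, W/nm (non-negative).
#' @param spec An [amplifier_spec()].
#' @param lambda_nm Wavelength grid, nm (uniform spacing assumed for the
#'   bin width).
#' @param seed Optional integer seed for the fluctuation draw.
#' @param noise Include the stochastic fluctuation term?
#' @param integration_time_s Detector integration time, s.
#' @return Amplified density plus ASE, W/nm.
#' @export
amplifier_apply <- function(density, spec, lambda_nm, seed = NULL,
                            noise = TRUE, integration_time_s = 1) {
  stopifnot(inherits(spec, "amplifier_spec"),
            length(density) == length(lambda_nm))
  if (any(density < 0))
    stop("input spectral density must be non-negative", call. = FALSE)
  g <- amplifier_gain(spec, lambda_nm)
  mu <- ase_mean_density(spec, lambda_nm)
  out <- g * density + mu
  if (noise) {
    bin <- if (length(lambda_nm) > 1L) mean(diff(lambda_nm)) else 1
    sd <- ase_sd_density(mu, lambda_nm, bin, integration_time_s)
    out <- out + with_local_seed(seed, stats::rnorm(length(lambda_nm), 0, sd))
  }
  out
}

## Evaluate `expr` under a temporary RNG state when `seed` is not NULL,
## restoring the caller's stream afterwards.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
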
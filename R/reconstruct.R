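#' Subtract a fluorescence interferogram
#'
#' Entrywise power difference of two interferograms recorded on the same
#' OPD grid (the skin measurement minus the fluorescence-only measurement).
#' Negative differences — pure noise once the deterministic parts cancel —
#' are preserved, not clipped.
#'
#' @param ifg_skin Interferogram of the combined Raman + fluorescence
#'   signal.
#' @param ifg_fluor Interferogram of the fluorescence signal alone.
#' @return An `"interferogram"` of the differences.
#' @export
subtract_fluorescence <- function(ifg_skin, ifg_fluor) {
  stopifnot(inherits(ifg_skin, "interferogram"),
            inherits(ifg_fluor, "interferogram"))
  if (nrow(ifg_skin) != nrow(ifg_fluor) ||
      any(ifg_skin$opd_um != ifg_fluor$opd_um))
    stop("interferograms were recorded on different OPD grids",
         call. = FALSE)
  out <- data.frame(opd_um = ifg_skin$opd_um,
                    power_w = ifg_skin$power_w - ifg_fluor$power_w)
  structure(out, class = c("interferogram", "data.frame"),
            mode = attr(ifg_skin, "mode"), seed = attr(ifg_skin, "seed"),
            scale_factor = attr(ifg_skin, "scale_factor"))
}

#' End-to-end Raman reconstruction of a lesion phantom
#'
#' Runs the full measurement protocol for one lesion class:
#' compose the fluorescence background and the combined skin signal,
#' measure both interferograms on the device (one absolute power scale
#' shared by the pair), subtract, select the penalty by 10-fold
#' cross-validation and solve the BPDN program.  The reconstruction lives
#' on the calibration wavelength bins; it is also reported on the
#' Raman-shift axis (with the density Jacobian) and max-normalised over
#' the 800--1800 cm^-1 window, alongside the noiseless Lorentzian model
#' evaluated on the same bins for comparison.
#'
#' @param device A [dfts_device()].
#' @param lesion A [lesion_model] or lesion name.
#' @param seed Integer seed governing the ASE noise of both measurements
#'   and the CV fold shuffle.
#' @param calibration Optional precomputed [build_calibration_matrix()]
#'   for this device (built on the fly otherwise).
#' @param weights CV penalty grid, see [weight_grid()].
#' @param folds CV folds.
#' @param scoring `"ground_truth"` (simulation default) or `"blind"`; see
#'   [cv_bpdn()].
#' @param weight Optional fixed penalty; skips cross-validation.
#' @param noise Include ASE noise in the measurements?
#' @param model_grid Raman-shift grid for the phantom model, cm^-1.
#' @param solver_tol,solver_iter Solver budget used for every fit in the
#'   pipeline (see [cv_bpdn()] for why one budget is used throughout).
#' @return An object of class `"raman_reconstruction"`; see Details.
#' @details The result contains `wavelength_nm` (the 171 bins), `shift_cm1`
#'   (their Raman-shift positions), `x` (raw BPDN coefficients),
#'   `normalized` (max-normalised shift-domain reconstruction), `truth`
#'   (the normalised noiseless Lorentzian model on the same bins), the
#'   `cv` object (when CV ran) and the final `fit`.
#' @export
#' @examples
#' \donttest{
#' dev <- dfts_device("ideal")
#' rec <- reconstruct_raman(dev, "MEL", seed = 1, noise = FALSE,
#'                          weights = weight_grid(length = 13))
#' summary(rec)
#' }
reconstruct_raman <- function(device, lesion, seed = NULL,
                              calibration = NULL,
                              weights = weight_grid(), folds = 10L,
                              scoring = c("ground_truth", "blind"),
                              weight = NULL, noise = TRUE,
                              model_grid = seq(800, 1800, by = 1),
                              solver_tol = 1e-6, solver_iter = 500L) {
  stopifnot(inherits(device, "dfts_device"))
  scoring <- match.arg(scoring)
  lesion <- resolve_lesion(lesion)
  if (is.null(calibration)) calibration <- build_calibration_matrix(device)
  bins <- attr(calibration, "wavelengths_nm")
  shift <- wavelength_to_shift(bins, device$excitation_nm)

  fluor <- raman_spectrum(model_grid,
                          fluorescence_background(model_grid), "shift",
                          device$excitation_nm)
  skin <- compose_skin_signal(lesion, TRUE, model_grid)

  ## noiseless Lorentzian model on the bins, as wavelength density (the
  ## quantity the estimator recovers) — used as CV ground truth
  truth_shift <- lorentzian_sum(lesion$peaks, shift)
  truth_wl <- truth_shift * 1e7 / bins^2

  ## one absolute power scale for the pair, set by the combined spectrum
  sf <- input_density(device, skin)$scale_factor
  res <- with_local_seed(seed, {
    ifg_f <- measure_interferogram(device, fluor, noise = noise,
                                   scale_factor = sf)
    ifg_s <- measure_interferogram(device, skin, noise = noise,
                                   scale_factor = sf)
    ydiff <- subtract_fluorescence(ifg_s, ifg_f)
    cv <- NULL
    if (is.null(weight)) {
      cv <- cv_bpdn(calibration, ydiff$power_w, weights = weights,
                    folds = folds,
                    ground_truth = if (scoring == "ground_truth")
                      truth_wl else NULL,
                    tol = solver_tol, max_iter = solver_iter)
      fit <- cv$fit
    } else {
      fit <- bpdn(calibration, ydiff$power_w, weight,
                  tol = solver_tol, max_iter = solver_iter)
    }
    list(ifg_f = ifg_f, ifg_s = ifg_s, ydiff = ydiff, cv = cv, fit = fit)
  })

  xhat <- res$fit$coefficients
  xhat_shift <- xhat * bins^2 * 1e-7         # back to per-cm^-1 density
  win <- shift >= 800 & shift <= 1800
  normalized <- xhat_shift / max(abs(xhat_shift[win]))
  truth_norm <- truth_shift / max(abs(truth_shift[win]))

  structure(list(lesion = lesion$name, wavelength_nm = bins,
                 shift_cm1 = shift, x = xhat, normalized = normalized,
                 truth = truth_norm, window = win, cv = res$cv,
                 fit = res$fit, interferogram = res$ydiff,
                 seed = seed, mode = device$mode),
            class = "raman_reconstruction")
}

#' @export
print.raman_reconstruction <- function(x, ...) {
  cat(sprintf(paste0("Raman reconstruction of '%s' (%s mode)\n",
                     "  %d wavelength bins, penalty %.4g, %d nonzero\n"),
              x$lesion, x$mode, length(x$x), x$fit$weight, x$fit$nonzero))
  invisible(x)
}

#' @export
summary.raman_reconstruction <- function(object, ...) {
  r2 <- r_squared(object$truth[object$window],
                  object$normalized[object$window])
  cat(sprintf(paste0("Raman reconstruction of '%s' (%s mode)\n",
                     "  penalty %.4g (%s)\n",
                     "  R^2 vs noiseless Lorentzian model: %.4f\n"),
              object$lesion, object$mode, object$fit$weight,
              if (is.null(object$cv)) "fixed"
              else paste0("10-fold CV, ", object$cv$scoring),
              r2))
  invisible(list(r_squared = r2, weight = object$fit$weight))
}

#' @export
plot.raman_reconstruction <- function(x, ...) {
  graphics::plot(x$shift_cm1, x$truth, type = "l", col = "grey40",
                 xlab = "Raman shift (cm-1)",
                 ylab = "normalized intensity", ...)
  graphics::lines(x$shift_cm1, x$normalized, col = "firebrick")
  graphics::legend("topleft", c("model", "reconstructed"),
                   col = c("grey40", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
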
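#' Lorentzian Raman peak
#'
#' A single Raman band parameterised by its centre position, full width at
#' half maximum and the total area under the peak measured from the baseline.
#'
#' @param center Peak centre, in Raman shift units (cm^-1).
#' @param fwhm Full width at half maximum, cm^-1.  Must be positive.
#' @param area Area under the peak from the baseline, arbitrary units.
#'   Must be non-negative.
#'
#' @return An object of class `"raman_peak"`.
#' @export
#' @examples
#' raman_peak(1445, 44, 182)
raman_peak <- function(center, fwhm, area) {
  stopifnot(is.numeric(center), is.numeric(fwhm), is.numeric(area),
            length(center) == 1L, length(fwhm) == 1L, length(area) == 1L)
  if (!is.finite(fwhm) || fwhm <= 0)
    stop("'fwhm' must be a positive finite number", call. = FALSE)
  if (!is.finite(area) || area < 0)
    stop("'area' must be a non-negative finite number", call. = FALSE)
  structure(list(center = center, fwhm = fwhm, area = area),
            class = "raman_peak")
}

#' @export
print.raman_peak <- function(x, ...) {
  cat(sprintf("Raman peak: centre %g cm-1, FWHM %g cm-1, area %g a.u.\n",
              x$center, x$fwhm, x$area))
  invisible(x)
}

## Shared peak positions / widths of the six lesion phantoms, and the
## per-lesion areas.  All lesions share the same r0 and FWHM columns; only
## the areas differ.
.phantom_centers <- c(855, 936, 1002, 1075, 1125, 1271, 1302, 1445, 1655, 1745)
.phantom_fwhm    <- c(68, 62, 24, 48, 10, 20, 60, 44, 39, 39)
.phantom_areas <- list(
  MEL = c(58,   23.7, 4.5, 43, 0.2, 15,   155,   182, 78.6, 39.4),
  BCC = c(44,   35,   6.5, 39, 0.2, 16,   146,   171, 96.3, 23),
  SCC = c(53.5, 29,   7,   38, 0.2, 12,   137,   205, 92.5, 31),
  AK  = c(57,   22.3, 4,   51, 0.2, 13,   162,   205, 91.5, 27.5),
  AN  = c(58,   32.5, 1.5, 37, 0.2, 21.2, 142.3, 167, 79,   51),
  SK  = c(47,   26,   3,   35, 0.2, 16,   138,   158, 84,   52.5)
)

#' Skin-lesion phantom model
#'
#' A named set of exactly ten Lorentzian Raman peaks describing one of the
#' six modelled skin lesion classes: melanoma (MEL), basal cell carcinoma
#' (BCC), squamous cell carcinoma (SCC), actinic keratosis (AK), atypical
#' nevus (AN) and seborrheic keratosis (SK).
#'
#' @param name Lesion class label.
#' @param peaks List of ten [raman_peak()] objects.
#'
#' @return An object of class `"lesion_model"`.
#' @seealso [lesion_models()] for the built-in registry.
#' @export
lesion_model <- function(name, peaks) {
  stopifnot(is.character(name), length(name) == 1L, is.list(peaks))
  if (length(peaks) != 10L)
    stop("a lesion model holds exactly 10 Raman peaks", call. = FALSE)
  if (!all(vapply(peaks, inherits, logical(1), "raman_peak")))
    stop("'peaks' must all be raman_peak objects", call. = FALSE)
  structure(list(name = name, peaks = peaks), class = "lesion_model")
}

#' @export
print.lesion_model <- function(x, ...) {
  cat(sprintf("Lesion phantom '%s' (%d Lorentzian peaks)\n",
              x$name, length(x$peaks)))
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.lesion_model <- function(x, ...) {
  data.frame(center  = vapply(x$peaks, `[[`, numeric(1), "center"),
             fwhm    = vapply(x$peaks, `[[`, numeric(1), "fwhm"),
             area    = vapply(x$peaks, `[[`, numeric(1), "area"))
}

#' Built-in registry of the six skin-lesion phantom models
#'
#' Returns the six lesion models used throughout the package.  All classes
#' share the same peak positions (855--1745 cm^-1) and widths; the classes
#' differ only in the peak areas, which were chosen to resemble in-vivo
#' tissue spectra.
#'
#' @param name Optional lesion name; when given, the single matching model
#'   is returned instead of the full list.
#' @return A named list of [lesion_model] objects, or a single model.
#' @export
#' @examples
#' names(lesion_models())
#' lesion_models("MEL")
lesion_models <- function(name = NULL) {
  build <- function(nm) {
    peaks <- Map(raman_peak, .phantom_centers, .phantom_fwhm,
                 .phantom_areas[[nm]])
    lesion_model(nm, unname(peaks))
  }
  all <- lapply(stats::setNames(nm = names(.phantom_areas)), build)
  if (is.null(name)) return(all)
  resolve_lesion(name, all)
}

## Accept either a lesion_model or a name; error lists the valid names.
resolve_lesion <- function(lesion, registry = lesion_models()) {
  if (inherits(lesion, "lesion_model")) return(lesion)
  if (is.character(lesion) && length(lesion) == 1L) {
    if (lesion %in% names(registry)) return(registry[[lesion]])
  }
  stop("unknown lesion '", paste(lesion, collapse = ","),
       "'; valid names are: ", paste(names(.phantom_areas), collapse = ", "),
       call. = FALSE)
}

#' Fluorescence baseline polynomial
#'
#' Fifth-order polynomial in Raman shift modelling the skin autofluorescence
#' background.  The defaults are the coefficients of the built-in skin
#' fluorescence model.
#'
#' @param coefficients Numeric vector of six polynomial coefficients,
#'   constant term first.
#' @return An object of class `"fluorescence_poly"`.
#' @export
fluorescence_poly <- function(coefficients = c(382.2, -9.06e-1, 1.560e-3,
                                               -1.443e-6, 6.721e-10,
                                               -1.240e-13)) {
  stopifnot(is.numeric(coefficients), length(coefficients) == 6L,
            all(is.finite(coefficients)))
  structure(list(coefficients = coefficients), class = "fluorescence_poly")
}

#' Sum of Lorentzian Raman peaks
#'
#' Evaluates \deqn{y(r) = \sum_i \frac{2 A_i}{\pi}
#'   \frac{\omega_i}{4 (r - r_i)^2 + \omega_i^2}}{
#'   y(r) = sum_i (2 A_i / pi) w_i / (4 (r - r_i)^2 + w_i^2)}
#' on a Raman-shift grid, where \eqn{r_i} is the peak centre, \eqn{\omega_i}
#' the FWHM and \eqn{A_i} the area under the peak.
#'
#' @param peaks A list of [raman_peak()] objects, or a [lesion_model].
#' @param grid Raman-shift grid, cm^-1, within \[0, 3000\].
#' @return Numeric vector of intensities (a.u.), non-negative everywhere.
#' @export
#' @examples
#' r <- seq(800, 1800, by = 1)
#' y <- lorentzian_sum(lesion_models("MEL"), r)
#' r[which.max(y)]  # dominant CH2-bending band near 1445 cm-1
lorentzian_sum <- function(peaks, grid) {
  if (inherits(peaks, "lesion_model")) peaks <- peaks$peaks
  stopifnot(is.numeric(grid), all(is.finite(grid)))
  if (any(grid < 0 | grid > 3000))
    stop("'grid' must lie within [0, 3000] cm-1", call. = FALSE)
  if (length(peaks) == 0L) {
    warning("empty peak list; returning a zero spectrum")
    return(numeric(length(grid)))
  }
  if (!all(vapply(peaks, inherits, logical(1), "raman_peak")))
    stop("'peaks' must be raman_peak objects", call. = FALSE)
  y <- numeric(length(grid))
  for (p in peaks) {
    y <- y + (2 * p$area / pi) * p$fwhm / (4 * (grid - p$center)^2 + p$fwhm^2)
  }
  y
}

#' Fluorescence background intensity
#'
#' Evaluates the fifth-order fluorescence polynomial pointwise on a
#' Raman-shift grid (Horner scheme).
#'
#' @param grid Raman-shift grid, cm^-1.
#' @param poly A [fluorescence_poly()] object.
#' @return Numeric vector of background intensities (a.u.).
#' @export
#' @examples
#' fluorescence_background(0)  # 382.2, the constant term
fluorescence_background <- function(grid, poly = fluorescence_poly()) {
  stopifnot(is.numeric(grid), all(is.finite(grid)),
            inherits(poly, "fluorescence_poly"))
  y <- numeric(length(grid))
  for (co in rev(poly$coefficients)) y <- y * grid + co
  y
}

#' Spectrum container
#'
#' Intensity samples on a strictly increasing grid, either in Raman shift
#' (cm^-1) or absolute wavelength (nm), tied to the excitation line.
#'
#' @param grid Strictly increasing sample positions.
#' @param values Intensity per sample (a.u. or W/nm).
#' @param grid_kind `"shift"` (cm^-1) or `"wavelength"` (nm).
#' @param excitation_nm Excitation wavelength, nm.
#' @param units Free-text unit label for the values.
#' @return An object of class `"raman_spectrum"`.
#' @export
raman_spectrum <- function(grid, values, grid_kind = c("shift", "wavelength"),
                           excitation_nm = 830, units = "a.u.") {
  grid_kind <- match.arg(grid_kind)
  stopifnot(is.numeric(grid), is.numeric(values))
  if (length(grid) != length(values))
    stop("'grid' and 'values' must have the same length", call. = FALSE)
  if (length(grid) > 1L && any(diff(grid) <= 0))
    stop("'grid' must be strictly increasing", call. = FALSE)
  structure(list(grid = grid, values = values, grid_kind = grid_kind,
                 excitation_nm = excitation_nm, units = units),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("Raman spectrum: %d samples on %s grid [%g, %g] %s, units %s\n",
              length(x$grid), x$grid_kind, min(x$grid), max(x$grid),
              if (x$grid_kind == "shift") "cm-1" else "nm", x$units))
  invisible(x)
}

#' @export
plot.raman_spectrum <- function(x, ...) {
  xlab <- if (x$grid_kind == "shift") "Raman shift (cm-1)" else
    "Wavelength (nm)"
  graphics::plot(x$grid, x$values, type = "l", xlab = xlab,
                 ylab = sprintf("Intensity (%s)", x$units), ...)
  invisible(x)
}

#' Compose a synthetic skin Raman signal
#'
#' Builds the phantom spectrum of a lesion class on a Raman-shift grid:
#' the Lorentzian peak sum, optionally with the fluorescence baseline added.
#'
#' @param lesion A [lesion_model] or one of the six lesion names.
#' @param include_fluorescence Add the fluorescence polynomial background?
#' @param grid Raman-shift grid, cm^-1 (default 800--1800 at 1 cm^-1).
#' @param poly Fluorescence model, see [fluorescence_poly()].
#' @return A [raman_spectrum] on a shift grid.
#' @export
#' @examples
#' s <- compose_skin_signal("MEL")
#' plot(s)
compose_skin_signal <- function(lesion, include_fluorescence = TRUE,
                                grid = seq(800, 1800, by = 1),
                                poly = fluorescence_poly()) {
  lesion <- resolve_lesion(lesion)
  y <- lorentzian_sum(lesion$peaks, grid)
  if (include_fluorescence) y <- y + fluorescence_background(grid, poly)
  out <- raman_spectrum(grid, y, grid_kind = "shift")
  attr(out, "lesion") <- lesion$name
  out
}

#' Convert between Raman shift and absolute wavelength
#'
#' Stokes-convention conversion tied to the excitation line:
#' \eqn{\lambda = 1 / (1/\lambda_{exc} - r)} with the appropriate unit
#' handling (\eqn{\lambda} in nm, r in cm^-1).  `wavelength_to_shift()` is
#' the exact inverse.
#'
#' @param r Raman shift, cm^-1.  Must satisfy `r < 1e7 / excitation_nm`.
#' @param lambda_nm Absolute wavelength, nm (Stokes side, >= excitation).
#' @param excitation_nm Excitation wavelength, nm.
#' @return Wavelength in nm, or Raman shift in cm^-1.
#' @export
#' @examples
#' shift_to_wavelength(0)        # the excitation line, 830 nm
#' shift_to_wavelength(800)      # ~889 nm
#' wavelength_to_shift(shift_to_wavelength(1445))
shift_to_wavelength <- function(r, excitation_nm = 830) {
  stopifnot(is.numeric(r), is.numeric(excitation_nm), excitation_nm > 0)
  if (any(r >= 1e7 / excitation_nm))
    stop("Raman shift at or beyond the excitation wavenumber is nonphysical",
         call. = FALSE)
  1 / (1 / excitation_nm - r * 1e-7)
}

#' @rdname shift_to_wavelength
#' @export
wavelength_to_shift <- function(lambda_nm, excitation_nm = 830) {
  stopifnot(is.numeric(lambda_nm), all(lambda_nm > 0))
  (1 / excitation_nm - 1 / lambda_nm) * 1e7
}

#' Rescale one peak of a lesion model
#'
#' Returns a copy of the lesion model with the area of the peak centred at
#' `center` replaced; all other peaks are untouched.  Because the Lorentzian
#' mixture is linear in the areas, the difference between the modified and
#' original spectra is a single Lorentzian with area `new_area - old_area`.
#'
#' @param lesion A [lesion_model] or lesion name.
#' @param center Centre (cm^-1) of the peak to rescale; must exist.
#' @param new_area Replacement area, a.u.
#' @return A modified [lesion_model].
#' @export
#' @examples
#' g0 <- scale_peak("MEL", 1445, 0.1)  # near-baseline CH2 band
scale_peak <- function(lesion, center, new_area) {
  lesion <- resolve_lesion(lesion)
  idx <- which(vapply(lesion$peaks, `[[`, numeric(1), "center") == center)
  if (length(idx) != 1L)
    stop("no peak with centre ", center, " cm-1 in lesion '", lesion$name,
         "'", call. = FALSE)
  p <- lesion$peaks[[idx]]
  lesion$peaks[[idx]] <- raman_peak(p$center, p$fwhm, new_area)
  lesion
}

#' Convert a spectrum between shift and wavelength domains
#'
#' Converts both the grid and the spectral density.  Densities transform
#' with the Jacobian of the coordinate change
#' (\eqn{S_\lambda = y_r \, dr/d\lambda = y_r \cdot 10^7/\lambda^2}),
#' so that the integrated intensity is preserved.
#'
#' @param x A [raman_spectrum].
#' @param jacobian Apply the density Jacobian (default) or convert the grid
#'   only.
#' @return A [raman_spectrum] in the other domain.
#' @export
as_wavelength <- function(x, jacobian = TRUE) {
  stopifnot(inherits(x, "raman_spectrum"))
  if (x$grid_kind == "wavelength") return(x)
  lam <- shift_to_wavelength(x$grid, x$excitation_nm)
  val <- if (jacobian) x$values * 1e7 / lam^2 else x$values
  raman_spectrum(lam, val, "wavelength", x$excitation_nm, x$units)
}

#' @rdname as_wavelength
#' @export
as_shift <- function(x, jacobian = TRUE) {
  stopifnot(inherits(x, "raman_spectrum"))
  if (x$grid_kind == "shift") return(x)
  r <- wavelength_to_shift(x$grid, x$excitation_nm)
  val <- if (jacobian) x$values * x$grid^2 * 1e-7 else x$values
  raman_spectrum(r, val, "shift", x$excitation_nm, x$units)
}

#' Read and write spectra as CSV with a JSON sidecar
#'
#' The CSV holds two columns, `grid,intensity`; the sidecar
#' (`<path>.json`) records the grid kind, excitation wavelength and units so
#' the spectrum round-trips losslessly.
#'
#' @param x A [raman_spectrum].
#' @param path CSV file path.
#' @return `write_spectrum_csv()` returns `path` invisibly;
#'   `read_spectrum_csv()` returns a [raman_spectrum].
#' @export
write_spectrum_csv <- function(x, path) {
  stopifnot(inherits(x, "raman_spectrum"))
  df <- data.frame(grid = x$grid, intensity = x$values)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(grid_kind = x$grid_kind, excitation_nm = x$excitation_nm,
               units = x$units)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("grid", "intensity") %in% names(df)))
    stop("expected columns 'grid' and 'intensity' in ", path, call. = FALSE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else
    list(grid_kind = "shift", excitation_nm = 830, units = "a.u.")
  raman_spectrum(df$grid, df$intensity, meta$grid_kind,
                 meta$excitation_nm, meta$units)
}

#' Export the built-in phantom registry as YAML
#'
#' Writes the shared peak positions/widths, the per-lesion areas and the
#' fluorescence polynomial coefficients to a user-editable YAML file.
#'
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
export_model_registry <- function(path) {
  reg <- list(
    peaks = list(center_cm1 = .phantom_centers, fwhm_cm1 = .phantom_fwhm),
    areas = .phantom_areas,
    fluorescence = list(coefficients = fluorescence_poly()$coefficients)
  )
  yaml::write_yaml(reg, path)
  invisible(path)
}
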
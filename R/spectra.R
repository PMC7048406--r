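#' Construct a hyperspectral reflectance spectrum
#'
#' A spectrum is one quadrat's (or endmember's) per-channel reflectance on a
#' strictly increasing wavelength grid, typically the 400--1000 nm range of a
#' field imaging spectrometer. Reflectance is unitless; values slightly above
#' 1 can occur after reference-panel calibration, so the upper bound is 1.2.
#'
#' @param wavelength_nm numeric, strictly increasing channel centers in nm.
#' @param reflectance numeric, same length, finite, in \[0, 1.2\].
#' @return An object of class `spectrum`: a list with elements
#'   `wavelength_nm` and `reflectance`.
#' @export
spectrum <- function(wavelength_nm, reflectance) {
  if (!is.numeric(wavelength_nm) || !is.numeric(reflectance)) {
    stop("wavelengths and reflectance must be numeric", call. = FALSE)
  }
  if (length(wavelength_nm) != length(reflectance)) {
    stop("wavelength and reflectance lengths differ (", length(wavelength_nm),
         " vs ", length(reflectance), ")", call. = FALSE)
  }
  if (length(wavelength_nm) == 0L) stop("empty spectrum", call. = FALSE)
  if (any(diff(wavelength_nm) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(reflectance))) {
    stop("reflectance must be finite", call. = FALSE)
  }
  if (any(reflectance < 0) || any(reflectance > 1.2)) {
    stop("reflectance must lie in [0, 1.2]", call. = FALSE)
  }
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 reflectance = as.numeric(reflectance)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d channels, %.1f-%.1f nm, reflectance %.3f-%.3f\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), min(x$reflectance), max(x$reflectance)))
  invisible(x)
}

#' Broadband window definitions for NDVI
#'
#' Default windows are RED = 630--680 nm and NIR = 845--885 nm; hyperspectral
#' channels whose centers fall inside a window (endpoints inclusive) are
#' averaged to form the broadband reflectance.
#'
#' @param red,nir numeric length-2 vectors `c(low, high)` in nm, `low < high`.
#' @return A list with elements `red` and `nir`.
#' @export
ndvi_bands <- function(red = c(630, 680), nir = c(845, 885)) {
  for (b in list(red = red, nir = nir)) {
    if (!is.numeric(b) || length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2]) {
      stop("a band must be c(low, high) with low < high", call. = FALSE)
    }
  }
  list(red = as.numeric(red), nir = as.numeric(nir))
}

#' Convert raw spectrometer counts to reflectance
#'
#' Field reflectance calibration against a reference panel with dark-current
#' subtraction:
#' \deqn{\rho(\lambda) = \frac{target - dark}{panel - dark} \times \rho_{panel}.}
#' The panel reflectivity defaults to 1 (white reference). Results are
#' clipped to \[0, 1.2\]; clipping above 1.2 is reported with a warning since
#' it usually indicates a calibration problem.
#'
#' @param wavelength_nm channel centers, nm, strictly increasing.
#' @param target_counts,panel_counts,dark_counts raw per-channel counts of
#'   the target, the reference panel, and the dark-current measurement; all
#'   the same length as `wavelength_nm`.
#' @param panel_reflectivity known reflectivity of the reference panel.
#' @return A [spectrum].
#' @export
calibrate_reflectance <- function(wavelength_nm, target_counts, panel_counts,
                                  dark_counts, panel_reflectivity = 1) {
  n <- length(wavelength_nm)
  if (length(target_counts) != n || length(panel_counts) != n ||
      length(dark_counts) != n) {
    stop("count vectors must match the wavelength grid length", call. = FALSE)
  }
  bad <- which(panel_counts <= dark_counts)
  if (length(bad) > 0L) {
    stop("panel counts do not exceed dark counts at channel(s) ",
         paste(utils::head(wavelength_nm[bad], 5L), collapse = ", "),
         " nm", call. = FALSE)
  }
  refl <- (target_counts - dark_counts) / (panel_counts - dark_counts) *
    panel_reflectivity
  if (any(refl > 1.2)) {
    warning(sum(refl > 1.2), " channel(s) exceeded reflectance 1.2; clipped",
            call. = FALSE)
  }
  refl <- pmin(pmax(refl, 0), 1.2)
  spectrum(wavelength_nm, refl)
}

#' Resample a spectrum to a broadband window
#'
#' Broadband reflectance is the unweighted mean of reflectance over channels
#' whose centers lie inside the window, endpoints inclusive. With channel
#' spacing of a few nm and windows 40--50 nm wide this agrees with a proper
#' band integral to well under 1%.
#'
#' @param spec a [spectrum].
#' @param band numeric `c(low, high)` in nm.
#' @return The mean in-window reflectance (unitless scalar).
#' @export
resample_band <- function(spec, band) {
  stopifnot(inherits(spec, "spectrum"))
  if (!is.numeric(band) || length(band) != 2L || band[1] >= band[2]) {
    stop("`band` must be c(low, high) with low < high", call. = FALSE)
  }
  inside <- spec$wavelength_nm >= band[1] & spec$wavelength_nm <= band[2]
  if (!any(inside)) {
    stop(sprintf("no spectral channel inside band [%g, %g] nm", band[1],
                 band[2]), call. = FALSE)
  }
  mean(spec$reflectance[inside])
}

#' Normalized difference vegetation index
#'
#' \deqn{NDVI = (NIR - RED) / (NIR + RED)} from broadband red and
#' near-infrared reflectance. Vectorized; the result lies in \[-1, 1\].
#'
#' @param red,nir broadband reflectances (unitless, non-negative).
#' @return NDVI, same length as the inputs.
#' @export
compute_ndvi <- function(red, nir) {
  if (length(red) != length(nir)) stop("length mismatch", call. = FALSE)
  if (any(!is.finite(red)) || any(!is.finite(nir))) {
    stop("reflectances must be finite", call. = FALSE)
  }
  if (any(red < 0) || any(nir < 0)) {
    stop("reflectances must be non-negative", call. = FALSE)
  }
  if (any(red + nir == 0)) {
    stop("NDVI undefined where nir + red = 0", call. = FALSE)
  }
  (nir - red) / (nir + red)
}

#' NDVI of a quadrat from its hyperspectral measurements
#'
#' Computes NDVI for each spectrum (band means via [resample_band], then
#' [compute_ndvi]) and averages across spectra. The mean-of-NDVI convention
#' is used, not NDVI of the mean spectrum; the two differ for heterogeneous
#' quadrats and the chosen convention is applied consistently at quadrat and
#' plot level.
#'
#' @param spectra a single [spectrum] or a list of them.
#' @param bands window definitions, see [ndvi_bands()].
#' @return The quadrat NDVI (unitless scalar).
#' @export
quadrat_ndvi <- function(spectra, bands = ndvi_bands()) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  if (!is.list(spectra) || length(spectra) == 0L) {
    stop("need at least one spectrum", call. = FALSE)
  }
  vals <- vapply(spectra, function(s) {
    compute_ndvi(resample_band(s, bands$red), resample_band(s, bands$nir))
  }, numeric(1))
  mean(vals)
}

#' Plot-level mean NDVI
#'
#' Arithmetic mean of the NDVI values of the quadrats inside one plot.
#'
#' @param quadrat_ndvis numeric vector of quadrat NDVI values.
#' @return The plot mean NDVI.
#' @export
plot_mean_ndvi <- function(quadrat_ndvis) {
  if (!is.numeric(quadrat_ndvis) || length(quadrat_ndvis) == 0L) {
    stop("need at least one quadrat NDVI", call. = FALSE)
  }
  if (anyNA(quadrat_ndvis)) stop("missing NDVI values", call. = FALSE)
  mean(quadrat_ndvis)
}

#' Split a long-format spectra table into spectrum objects
#'
#' @param tbl data frame with columns `quadrat_id`, `wavelength_nm`,
#'   `reflectance` (the on-disk `spectra.csv` layout).
#' @return Named list of [spectrum] objects, one per quadrat, in first-seen
#'   quadrat order.
#' @export
spectra_from_table <- function(tbl) {
  need <- c("quadrat_id", "wavelength_nm", "reflectance")
  if (!all(need %in% names(tbl))) {
    stop("spectra table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ids <- unique(tbl$quadrat_id)
  out <- lapply(ids, function(id) {
    sub <- tbl[tbl$quadrat_id == id, , drop = FALSE]
    ord <- order(sub$wavelength_nm)
    spectrum(sub$wavelength_nm[ord], sub$reflectance[ord])
  })
  names(out) <- as.character(ids)
  out
}
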
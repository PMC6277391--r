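# Solid-state NMR spectrum utilities: region normalization and difference
# spectra, as used to compare treated and control lignin spectra.

#' NMR spectrum container
#'
#' @param ppm chemical-shift axis (strictly monotone).
#' @param intensity intensities, same length as `ppm`.
#' @param nucleus axis label (default `"13C"`).
#' @return Object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(ppm, intensity, nucleus = "13C") {
  if (length(ppm) != length(intensity))
    stop_param("'ppm' and 'intensity' must have equal length")
  if (!(is.unsorted(ppm, strictly = TRUE) == FALSE ||
        is.unsorted(rev(ppm), strictly = TRUE) == FALSE))
    stop_param("'ppm' must be strictly monotone")
  structure(list(ppm = ppm, intensity = intensity, nucleus = nucleus),
            class = "nmr_spectrum")
}

#' Normalize a spectrum to unit integral over a region
#'
#' Scales the intensities so that the trapezoidal integral over the ppm
#' region equals 1 (e.g. the aliphatic 10-60 ppm or O-aliphatic 60-110 ppm
#' carbon regions used to put lignin spectra on a common scale).
#'
#' @param spec an [nmr_spectrum()].
#' @param region numeric length-2 ppm interval.
#' @return The rescaled spectrum (idempotent; invariant to input scaling).
#' @export
normalize_spectrum_to_region <- function(spec, region) {
  stopifnot(inherits(spec, "nmr_spectrum"), length(region) == 2)
  region <- sort(region)
  ppm <- spec$ppm; y <- spec$intensity
  if (ppm[1] > ppm[length(ppm)]) { ppm <- rev(ppm); y <- rev(y) }
  sel <- ppm >= region[1] & ppm <= region[2]
  if (sum(sel) < 2) stop_param("region does not overlap the spectrum axis")
  integral <- pracma::trapz(ppm[sel], y[sel])
  if (abs(integral) < .Machine$double.eps)
    stop_param("zero integral over the normalization region")
  nmr_spectrum(spec$ppm, spec$intensity / integral, spec$nucleus)
}

#' Difference of two spectra
#'
#' Pointwise `a - b`. Both spectra must share the same axis unless
#' `interpolate = TRUE`, in which case `b` is linearly interpolated onto the
#' axis of `a`.
#'
#' @param a,b [nmr_spectrum()] objects (normalized to the same region for a
#'   meaningful comparison).
#' @param interpolate allow differing axes via linear interpolation.
#' @return An [nmr_spectrum()] on the axis of `a`.
#' @export
difference_spectrum <- function(a, b, interpolate = FALSE) {
  stopifnot(inherits(a, "nmr_spectrum"), inherits(b, "nmr_spectrum"))
  if (!isTRUE(all.equal(a$ppm, b$ppm))) {
    if (!interpolate)
      stop_param("spectra have different axes; pass interpolate = TRUE")
    b_int <- stats::approx(b$ppm, b$intensity, xout = a$ppm, rule = 2)$y
    return(nmr_spectrum(a$ppm, a$intensity - b_int, a$nucleus))
  }
  nmr_spectrum(a$ppm, a$intensity - b$intensity, a$nucleus)
}
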
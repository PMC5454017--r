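#' Emission spectrum objects
#'
#' A `Spectrum` is one emission scan from a scanning spectrofluorometer:
#' a strictly increasing emission-wavelength grid (nm) with one non-negative
#' intensity (arbitrary units) per grid point, plus acquisition metadata.
#'
#' All emission wavelengths must lie strictly above the excitation wavelength:
#' points at or below the excitation line are elastic-scatter contamination,
#' not fluorescence, and are excluded at read time (see [read_scan()]).
#'
#' @param excitation_nm Excitation wavelength in nm (scalar, > 0).
#' @param wavelengths Strictly increasing emission wavelengths in nm.
#' @param intensities Non-negative intensities, same length as `wavelengths`.
#' @param condition Condition label, typically `"AD"` or `"N"`.
#' @param replicate_id Replicate identifier (scalar, coerced to character).
#' @param bandpass_nm Monochromator slit bandpass in nm (default 2.0).
#' @param integration_s Integration time per point in seconds (default 0.2).
#' @return An object of class `"Spectrum"`.
#' @examples
#' s <- Spectrum(266, c(330, 331, 332), c(0.5, 0.6, 0.55), "AD", 1)
#' length(s$wavelengths)
#' @export
Spectrum <- function(excitation_nm, wavelengths, intensities,
                     condition = "other", replicate_id = "1",
                     bandpass_nm = 2.0, integration_s = 0.2) {
  s <- structure(
    list(
      excitation_nm = as.numeric(excitation_nm),
      wavelengths   = as.numeric(wavelengths),
      intensities   = as.numeric(intensities),
      condition     = as.character(condition),
      replicate_id  = as.character(replicate_id),
      bandpass_nm   = as.numeric(bandpass_nm),
      integration_s = as.numeric(integration_s)
    ),
    class = "Spectrum"
  )
  validate_spectrum(s)
}

validate_spectrum <- function(s) {
  stopifnot(inherits(s, "Spectrum"))
  if (length(s$excitation_nm) != 1L || !is.finite(s$excitation_nm) ||
      s$excitation_nm <= 0) {
    stop("excitation_nm must be a single positive finite number", call. = FALSE)
  }
  n <- length(s$wavelengths)
  if (n == 0L) stop("Spectrum must contain at least one point", call. = FALSE)
  if (length(s$intensities) != n) {
    stop("wavelengths and intensities must have equal length", call. = FALSE)
  }
  if (!all(is.finite(s$wavelengths)) || !all(is.finite(s$intensities))) {
    stop("wavelengths and intensities must be finite", call. = FALSE)
  }
  if (n > 1L && any(diff(s$wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(s$intensities < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (any(s$wavelengths <= s$excitation_nm)) {
    stop("all emission wavelengths must exceed the excitation wavelength",
         call. = FALSE)
  }
  s
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf(
    "<Spectrum> ex %g nm | %s | replicate %s | %d points (%g-%g nm)\n",
    x$excitation_nm, x$condition, x$replicate_id,
    length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)
  ))
  invisible(x)
}

#' @export
`==.Spectrum` <- function(e1, e2) {
  isTRUE(all.equal(unclass(e1), unclass(e2), tolerance = 1e-12))
}

#' Group of replicate spectra
#'
#' A `SpectrumGroup` collects replicate scans of one condition at one
#' excitation wavelength. All members must share the excitation wavelength,
#' the condition label, and an identical emission grid (exact to 1e-6 nm --
#' replicates from a scanning instrument are acquired on the programmed grid,
#' so any mismatch indicates mixed acquisitions, not numerical noise).
#'
#' @param spectra List of [Spectrum()] objects (at least one).
#' @return An object of class `"SpectrumGroup"` with fields `excitation_nm`,
#'   `condition`, `spectra`.
#' @examples
#' s1 <- Spectrum(266, 330:340, rep(1, 11), "AD", 1)
#' s2 <- Spectrum(266, 330:340, rep(2, 11), "AD", 2)
#' g <- SpectrumGroup(list(s1, s2))
#' length(g$spectra)
#' @export
SpectrumGroup <- function(spectra) {
  if (!is.list(spectra) || length(spectra) == 0L) {
    stop("spectra must be a non-empty list of Spectrum objects", call. = FALSE)
  }
  lapply(spectra, validate_spectrum)
  ref <- spectra[[1L]]
  for (s in spectra[-1L]) {
    if (s$excitation_nm != ref$excitation_nm) {
      stop("all group members must share one excitation wavelength",
           call. = FALSE)
    }
    if (!identical(s$condition, ref$condition)) {
      stop("all group members must share one condition label", call. = FALSE)
    }
    if (length(s$wavelengths) != length(ref$wavelengths) ||
        max(abs(s$wavelengths - ref$wavelengths)) > 1e-6) {
      stop("all group members must share an identical wavelength grid",
           call. = FALSE)
    }
  }
  structure(
    list(
      excitation_nm = ref$excitation_nm,
      condition     = ref$condition,
      spectra       = spectra
    ),
    class = "SpectrumGroup"
  )
}

#' @export
print.SpectrumGroup <- function(x, ...) {
  cat(sprintf("<SpectrumGroup> ex %g nm | %s | %d replicates | %d points\n",
              x$excitation_nm, x$condition, length(x$spectra),
              length(x$spectra[[1L]]$wavelengths)))
  invisible(x)
}

#' Intensity matrix of a group
#'
#' Rows are replicates, columns are grid points.
#' @param group A [SpectrumGroup()].
#' @return Numeric matrix of dimension n_replicates x n_wavelengths.
#' @export
group_intensity_matrix <- function(group) {
  stopifnot(inherits(group, "SpectrumGroup"))
  do.call(rbind, lapply(group$spectra, function(s) s$intensities))
}

#' Rescale every spectrum in a group by a constant
#'
#' @param group A [SpectrumGroup()].
#' @param factor Positive scalar multiplier.
#' @return A new [SpectrumGroup()] with all intensities multiplied by `factor`.
#' @export
scale_group <- function(group, factor) {
  stopifnot(inherits(group, "SpectrumGroup"), is.finite(factor), factor > 0)
  SpectrumGroup(lapply(group$spectra, function(s) {
    s$intensities <- s$intensities * factor
    s
  }))
}
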
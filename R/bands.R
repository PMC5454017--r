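#' Fluorophore emission band
#'
#' A parametric stand-in for the emission profile of one endogenous
#' fluorophore (tryptophan, NADH or FAD): a single smooth band described by a
#' peak position and a width. The default shape is Gaussian with `width_nm`
#' interpreted as the standard deviation sigma; a mildly asymmetric lognormal
#' alternative is available for users who want a red tail.
#'
#' @param name Fluorophore label (`"tryptophan"`, `"NADH"`, `"FAD"`, ...).
#' @param center_nm Emission peak position in nm, in (250, 700).
#' @param width_nm Band width parameter in nm (> 0); sigma for the Gaussian.
#' @param shape `"gaussian"` (default) or `"lognormal"`.
#' @return An object of class `"FluorophoreBand"`.
#' @export
fluorophore_band <- function(name, center_nm, width_nm, shape = "gaussian") {
  if (!is.finite(center_nm) || center_nm <= 250 || center_nm >= 700) {
    stop("center_nm must lie in (250, 700) nm", call. = FALSE)
  }
  if (!is.finite(width_nm) || width_nm <= 0) {
    stop("width_nm must be positive", call. = FALSE)
  }
  shape <- match.arg(shape, c("gaussian", "lognormal"))
  structure(
    list(name = as.character(name), center_nm = center_nm,
         width_nm = width_nm, shape = shape),
    class = "FluorophoreBand"
  )
}

#' Evaluate a band on a wavelength grid
#'
#' Returns the unit-peak band shape: values in `[0, 1]`, maximum attained at
#' the grid point nearest `center_nm` (the Gaussian evaluates to exactly 1
#' when the center lies on the grid). A center outside the grid range raises
#' a warning but the (monotone) tail is still returned.
#'
#' @param band A [fluorophore_band()].
#' @param grid Numeric vector of emission wavelengths (nm).
#' @return Numeric vector, same length as `grid`.
#' @export
band_profile <- function(band, grid) {
  stopifnot(inherits(band, "FluorophoreBand"))
  if (length(grid) == 0L || any(!is.finite(grid))) {
    stop("grid must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (band$center_nm < min(grid) || band$center_nm > max(grid)) {
    warning(sprintf("band '%s' center (%g nm) lies outside the grid [%g, %g]",
                    band$name, band$center_nm, min(grid), max(grid)))
  }
  if (band$shape == "gaussian") {
    exp(-((grid - band$center_nm)^2) / (2 * band$width_nm^2))
  } else {
    # lognormal with mode pinned to center_nm; sdlog 0.25 gives a gentle
    # red tail, scale chosen so the spread matches width_nm
    slog <- 0.25
    x0 <- band$width_nm / slog
    x <- grid - band$center_nm + x0
    out <- numeric(length(grid))
    pos <- x > 0
    mlog <- log(x0) + slog^2          # mode of lognormal = exp(mlog - slog^2)
    out[pos] <- stats::dlnorm(x[pos], meanlog = mlog, sdlog = slog)
    peak <- stats::dlnorm(x0, meanlog = mlog, sdlog = slog)
    out / peak
  }
}

#' Default band tables per excitation wavelength
#'
#' The NADH emission peak position depends on the excitation context (435 nm
#' under 266 nm excitation, 492 nm under 300 nm, 462 nm under 340 nm), so
#' bands are tabulated per excitation rather than globally. Widths are
#' calibration choices that reproduce the smooth single-peaked tissue
#' profiles: tryptophan sigma 25 nm, NADH sigma 35 nm, FAD sigma 30 nm.
#'
#' @param excitation_nm One of 266, 300, 340.
#' @return Named list of [fluorophore_band()] objects.
#' @export
default_bands <- function(excitation_nm) {
  key <- as.character(excitation_nm)
  tabs <- list(
    "266" = list(
      tryptophan = fluorophore_band("tryptophan", 331, 25),
      NADH       = fluorophore_band("NADH", 435, 35)
    ),
    "300" = list(
      tryptophan = fluorophore_band("tryptophan", 335, 25),
      NADH       = fluorophore_band("NADH", 492, 35)
    ),
    "340" = list(
      NADH = fluorophore_band("NADH", 462, 35),
      FAD  = fluorophore_band("FAD", 557, 30)
    )
  )
  if (!key %in% names(tabs)) {
    stop("no default band table for excitation ", excitation_nm,
         " nm (supported: 266, 300, 340); supply a custom band set",
         call. = FALSE)
  }
  tabs[[key]]
}
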
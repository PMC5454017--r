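# Analysis chain mirroring the published procedure: average replicate curves
# with SD, normalize both conditions to the maximum of the AD group average,
# extract fluorophore peaks in assigned windows, form peak ratios and AD/N
# fold changes.

#' Round half away from zero
#'
#' `round()` in R rounds half to even; the printed tables use conventional
#' half-away-from-zero rounding, so reproduction paths need this variant.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Average a replicate group
#'
#' Pointwise mean and sample standard deviation across replicates (SD is 0
#' for a single replicate).
#'
#' @param group A [SpectrumGroup()].
#' @return List with `mean` (a [Spectrum()] with `replicate_id = "mean"`),
#'   `sd` (numeric vector per wavelength) and `n` (replicate count).
#' @export
average_group <- function(group) {
  stopifnot(inherits(group, "SpectrumGroup"))
  m <- group_intensity_matrix(group)
  mu <- colMeans(m)
  sdv <- if (nrow(m) > 1L) apply(m, 2L, stats::sd) else numeric(ncol(m))
  ref <- group$spectra[[1L]]
  list(
    mean = Spectrum(group$excitation_nm, ref$wavelengths, mu,
                    condition = group$condition, replicate_id = "mean",
                    bandpass_nm = ref$bandpass_nm,
                    integration_s = ref$integration_s),
    sd = sdv,
    n = nrow(m)
  )
}

#' Normalize an AD/N group pair to the AD average maximum
#'
#' Every spectrum in both groups is divided by the maximum (over wavelength)
#' of the AD group's averaged spectrum, so the AD average peaks at exactly 1
#' while the N group keeps its relative level (an N average peak of ~0.5
#' stays ~0.5). Idempotent: applying it twice equals applying it once.
#'
#' @param ad_group,n_group [SpectrumGroup()]s sharing grid and excitation.
#'   `n_group` may be `NULL` (AD-only data); normalization still proceeds.
#' @return List with normalized `ad`, `n` groups and the `scale` divided out.
#' @export
normalize_to_ad_max <- function(ad_group, n_group = NULL) {
  stopifnot(inherits(ad_group, "SpectrumGroup"))
  if (!is.null(n_group)) {
    stopifnot(inherits(n_group, "SpectrumGroup"))
    if (n_group$excitation_nm != ad_group$excitation_nm) {
      stop("groups must share one excitation wavelength", call. = FALSE)
    }
    ref <- ad_group$spectra[[1L]]$wavelengths
    if (length(n_group$spectra[[1L]]$wavelengths) != length(ref) ||
        max(abs(n_group$spectra[[1L]]$wavelengths - ref)) > 1e-6) {
      stop("groups must share one wavelength grid", call. = FALSE)
    }
  }
  scale <- max(average_group(ad_group)$mean$intensities)
  if (scale <= 0) {
    stop("AD average spectrum is identically zero; cannot normalize",
         call. = FALSE)
  }
  list(
    ad = scale_group(ad_group, 1 / scale),
    n = if (!is.null(n_group)) scale_group(n_group, 1 / scale),
    scale = scale
  )
}

#' Fluorophore peak-search window
#'
#' @param fluorophore Fluorophore label.
#' @param window_nm Closed interval `c(lo, hi)` in nm, `lo < hi`.
#' @return An object of class `"PeakAssignment"`.
#' @export
peak_assignment <- function(fluorophore, window_nm) {
  if (length(window_nm) != 2L || window_nm[1] >= window_nm[2]) {
    stop("window_nm must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  structure(list(fluorophore = as.character(fluorophore),
                 window_nm = as.numeric(window_nm)),
            class = "PeakAssignment")
}

#' Default peak windows per excitation
#'
#' Search windows bracketing the published peak positions: under 266 nm
#' excitation, tryptophan (peak ~331 nm) and NADH (~435 nm); under 300 nm,
#' tryptophan (~335 nm) and NADH (~492 nm); under 340 nm, NADH (~462 nm) and
#' FAD (~557 nm). Windows at one excitation never overlap.
#'
#' @param excitation_nm One of 266, 300, 340.
#' @return Named list of two [peak_assignment()]s, ordered (peak1, peak2).
#' @export
default_peak_windows <- function(excitation_nm) {
  key <- as.character(excitation_nm)
  tabs <- list(
    "266" = list(tryptophan = peak_assignment("tryptophan", c(315, 355)),
                 NADH       = peak_assignment("NADH", c(420, 470))),
    "300" = list(tryptophan = peak_assignment("tryptophan", c(320, 360)),
                 NADH       = peak_assignment("NADH", c(430, 510))),
    "340" = list(NADH = peak_assignment("NADH", c(430, 480)),
                 FAD  = peak_assignment("FAD", c(525, 575)))
  )
  if (!key %in% names(tabs)) {
    stop("no default peak windows for excitation ", excitation_nm, " nm",
         call. = FALSE)
  }
  tabs[[key]]
}

#' Extract a fluorophore peak
#'
#' Argmax of intensity restricted to the assignment window; ties are broken
#' toward the shorter wavelength (deterministic and grid-independent).
#'
#' @param spectrum A [Spectrum()].
#' @param assignment A [peak_assignment()].
#' @return An object of class `"PeakResult"`: list with `fluorophore`,
#'   `wavelength_nm`, `intensity`.
#' @export
extract_peak <- function(spectrum, assignment) {
  validate_spectrum(spectrum)
  stopifnot(inherits(assignment, "PeakAssignment"))
  w <- assignment$window_nm
  idx <- which(spectrum$wavelengths >= w[1] & spectrum$wavelengths <= w[2])
  if (length(idx) == 0L) {
    stop(sprintf("window [%g, %g] nm does not intersect the spectrum grid",
                 w[1], w[2]), call. = FALSE)
  }
  sub <- spectrum$intensities[idx]
  best <- idx[which.max(sub)]           # which.max takes the first maximum
  structure(
    list(fluorophore = assignment$fluorophore,
         wavelength_nm = spectrum$wavelengths[best],
         intensity = spectrum$intensities[best]),
    class = "PeakResult"
  )
}

#' Per-replicate peak intensity ratios
#'
#' For each replicate, the ratio of the numerator fluorophore's peak
#' intensity to the denominator's, plus their mean and sample SD. The ratio
#' is invariant under any global rescaling of the spectra, which is what
#' makes it a useful discriminant independent of acquisition throughput.
#'
#' @param group A [SpectrumGroup()].
#' @param num,den [peak_assignment()]s for numerator and denominator.
#' @return An object of class `"RatioResult"`: `excitation_nm`, `numerator`,
#'   `denominator`, `per_replicate`, `mean`, `sd`.
#' @seealso [ratio_from_peaks()] for the reproduction mode operating on
#'   pre-extracted peak intensities (e.g. the packaged published table).
#' @export
ratio_statistic <- function(group, num, den) {
  stopifnot(inherits(group, "SpectrumGroup"))
  ratios <- vapply(group$spectra, function(s) {
    top <- extract_peak(s, num)$intensity
    bot <- extract_peak(s, den)$intensity
    if (bot <= 0) {
      stop(sprintf("replicate %s: denominator (%s) peak intensity is zero",
                   s$replicate_id, den$fluorophore), call. = FALSE)
    }
    top / bot
  }, numeric(1))
  structure(
    list(excitation_nm = group$excitation_nm,
         numerator = num$fluorophore, denominator = den$fluorophore,
         per_replicate = ratios, mean = mean(ratios),
         sd = if (length(ratios) > 1L) stats::sd(ratios) else 0),
    class = "RatioResult"
  )
}

#' Ratios from pre-extracted peak intensities
#'
#' Reproduction-mode companion of [ratio_statistic()]: takes peak-intensity
#' vectors (for instance the replicate columns of [load_table1()]) instead of
#' spectra.
#'
#' @param num_values,den_values Positive numeric vectors of equal length.
#' @param excitation_nm,numerator,denominator Labels carried into the result.
#' @return A `"RatioResult"` as in [ratio_statistic()].
#' @export
ratio_from_peaks <- function(num_values, den_values, excitation_nm = NA,
                             numerator = "peak1", denominator = "peak2") {
  stopifnot(length(num_values) == length(den_values),
            length(num_values) >= 1L)
  if (any(den_values <= 0)) {
    stop("denominator peak intensities must be positive", call. = FALSE)
  }
  ratios <- num_values / den_values
  structure(
    list(excitation_nm = excitation_nm, numerator = numerator,
         denominator = denominator, per_replicate = ratios,
         mean = mean(ratios),
         sd = if (length(ratios) > 1L) stats::sd(ratios) else 0),
    class = "RatioResult"
  )
}

#' @export
print.RatioResult <- function(x, ...) {
  cat(sprintf("<RatioResult> %s/%s @ %s nm: mean %.3f (sd %.3f, n %d)\n",
              x$numerator, x$denominator, format(x$excitation_nm),
              x$mean, x$sd, length(x$per_replicate)))
  invisible(x)
}

#' AD/N fold change of peak intensities
#'
#' `mean(ad_values) / mean(n_values)`. In `"unrounded"` mode (default) the
#' raw replicate values are averaged before dividing; in `"printed"` mode the
#' two means are first rounded half-away-from-zero to 3 decimals, matching a
#' computation done from a printed table's mean rows. The published fold
#' changes mix both conventions, which is why both are exposed.
#'
#' @param ad_values,n_values Non-empty numeric vectors of replicate peak
#'   intensities.
#' @param mode `"unrounded"` or `"printed"`.
#' @return Scalar fold change.
#' @export
fold_change <- function(ad_values, n_values, mode = c("unrounded", "printed")) {
  mode <- match.arg(mode)
  stopifnot(length(ad_values) >= 1L, length(n_values) >= 1L)
  ad <- mean(ad_values)
  n <- mean(n_values)
  if (mode == "printed") {
    ad <- round_half_up(ad, 3)
    n <- round_half_up(n, 3)
  }
  if (n <= 0) stop("N-group mean must be positive", call. = FALSE)
  ad / n
}
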
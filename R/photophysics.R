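#' Fluorescence quantum yield
#'
#' The fraction of absorbed photons re-emitted as fluorescence,
#' `Q = Kr / (Kr + Knr)`, where `Kr` and `Knr` are the radiative and
#' nonradiative decay rates of the excited state. `Knr` reflects coupling of
#' the fluorophore to its host environment: weak interaction gives a small
#' `Knr` and brighter emission; `Knr >> Kr` quenches it.
#'
#' Rates may be supplied in any consistent unit; only their ratio matters.
#'
#' @param kr Radiative rate (>= 0). Vectorized.
#' @param knr Nonradiative rate (>= 0). Vectorized.
#' @return Quantum yield in `[0, 1]`.
#' @examples
#' quantum_yield(1e8, 3e8)  # 0.25
#' @export
quantum_yield <- function(kr, knr) {
  if (any(!is.finite(kr)) || any(!is.finite(knr)) ||
      any(kr < 0) || any(knr < 0)) {
    stop("kr and knr must be finite and non-negative", call. = FALSE)
  }
  if (any(kr + knr <= 0)) {
    stop("kr + knr must be positive", call. = FALSE)
  }
  kr / (kr + knr)
}

#' Emitted intensity collected by the detector
#'
#' Photon count reaching a detector that subtends solid angle `omega` from a
#' population of `n` excited molecules with quantum yield `q`:
#' `I = (omega / 4 pi) * q * n`. Linear in each argument.
#'
#' @param omega Collection solid angle in steradians, in `(0, 4 pi]`.
#' @param q Quantum yield in `[0, 1]`.
#' @param n Number of excited molecules (>= 0).
#' @return Detected intensity (photons, arbitrary units).
#' @examples
#' emitted_intensity(4 * pi, 1, 100)  # 100: full-sphere collection
#' @export
emitted_intensity <- function(omega, q, n) {
  if (any(!is.finite(omega)) || any(omega <= 0) || any(omega > 4 * pi)) {
    stop("omega must lie in (0, 4*pi] steradians", call. = FALSE)
  }
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1)) {
    stop("q must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(n)) || any(n < 0)) {
    stop("n must be non-negative", call. = FALSE)
  }
  (omega / (4 * pi)) * q * n
}

#' Forster resonance energy transfer rate
#'
#' Rate of dipole-dipole energy transfer from an excited donor to an acceptor
#' at distance `r`: `K_DA = (1 / tau_d) * (r0 / r)^6`, where `tau_d` is the
#' donor fluorescence lifetime and `r0` the Forster radius (the distance at
#' which transfer and intrinsic decay are equally likely, set by the overlap
#' of donor emission and acceptor absorption). The characteristic sixth-power
#' distance dependence makes the rate a sensitive probe of donor-acceptor
#' separation on the nanometre scale.
#'
#' @param tau_d Donor lifetime in seconds (> 0).
#' @param r0 Forster radius in nm (> 0).
#' @param r Donor-acceptor distance in nm (> 0).
#' @return Transfer rate in s^-1.
#' @examples
#' fret_rate(3e-9, 3, 6)  # (1/3e-9) / 64
#' @export
fret_rate <- function(tau_d, r0, r) {
  if (any(!is.finite(tau_d)) || any(tau_d <= 0)) {
    stop("tau_d must be positive", call. = FALSE)
  }
  if (any(!is.finite(r0)) || any(r0 <= 0)) {
    stop("r0 must be positive", call. = FALSE)
  }
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("r must be positive", call. = FALSE)
  }
  (1 / tau_d) * (r0 / r)^6
}

#' Forster transfer efficiency
#'
#' Fraction of donor excitations lost to transfer rather than intrinsic decay:
#' `E = K_DA / (K_DA + 1/tau_d) = 1 / (1 + (r/r0)^6)`. This is the standard
#' completion of the transfer-rate law -- not itself part of the printed
#' model -- and is what the simulator uses to redistribute donor brightness
#' to the acceptor. Strictly decreasing in `r`, with `E = 1/2` at `r = r0`.
#'
#' @inheritParams fret_rate
#' @return Transfer efficiency in `[0, 1]`.
#' @examples
#' fret_efficiency(2.6e-9, 2.5, 2.5)  # 0.5 at the Forster radius
#' @export
fret_efficiency <- function(tau_d, r0, r) {
  k <- fret_rate(tau_d, r0, r)        # validates inputs; tau_d cancels below
  k / (k + 1 / tau_d)
}

#' Photophysical parameter set
#'
#' Bundles the rates and geometry used by the simulator for one fluorophore:
#' radiative/nonradiative rates, donor lifetime, Forster radius and
#' donor-acceptor distance, collection solid angle, and the number of excited
#' molecules. Units must be self-consistent (rates in s^-1, distances in nm).
#'
#' @param kr,knr Radiative and nonradiative rates (>= 0, sum > 0).
#' @param tau_d Donor lifetime in s (> 0).
#' @param r0 Forster radius in nm (> 0).
#' @param r Donor-acceptor distance in nm (> 0).
#' @param omega Collection solid angle in sr, in `(0, 4 pi]`.
#' @param n_excited Number of excited molecules (>= 0).
#' @return An object of class `"PhotophysicsParams"`.
#' @export
photophysics_params <- function(kr, knr, tau_d = 2.6e-9, r0 = 2.5, r = 4.0,
                                omega = 0.5, n_excited = 100) {
  quantum_yield(kr, knr)              # validates kr/knr
  fret_rate(tau_d, r0, r)             # validates geometry
  if (!is.finite(omega) || omega <= 0 || omega > 4 * pi) {
    stop("omega must lie in (0, 4*pi]", call. = FALSE)
  }
  if (!is.finite(n_excited) || n_excited < 0) {
    stop("n_excited must be non-negative", call. = FALSE)
  }
  structure(
    list(kr = kr, knr = knr, tau_d = tau_d, r0 = r0, r = r,
         omega = omega, n_excited = n_excited),
    class = "PhotophysicsParams"
  )
}

#' Base brightness implied by a parameter set
#'
#' Chains [quantum_yield()] and [emitted_intensity()]: the detected intensity
#' of a fluorophore population before any energy transfer.
#'
#' @param p A [photophysics_params()] object.
#' @return Scalar intensity (arbitrary units).
#' @export
base_amplitude <- function(p) {
  stopifnot(inherits(p, "PhotophysicsParams"))
  emitted_intensity(p$omega, quantum_yield(p$kr, p$knr), p$n_excited)
}
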
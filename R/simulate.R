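# Forward simulator of tissue emission scans: a sum of fluorophore bands with
# brightness set by the photophysical chain (quantum yield x collection), a
# donor->acceptor FRET redistribution for the tryptophan/NADH pair, one
# multiplicative lognormal factor per replicate (whole scans scale together,
# as the published replicate rows do), and additive i.i.d. Gaussian noise.

#' Simulation configuration
#'
#' Fully describes one simulated condition at one excitation wavelength.
#' Replicate draws are deterministic given (`seed`, `replicate_index`):
#' each (condition, excitation, replicate) triple gets its own RNG stream via
#' a stable string hash of the root seed, so adding replicates never perturbs
#' existing ones.
#'
#' @param excitation_nm Excitation wavelength (nm). Must be one of 266, 300,
#'   340 unless a custom `bands` table is supplied.
#' @param condition Condition label (`"AD"`, `"N"`, ...).
#' @param bands Named list of [fluorophore_band()]; default
#'   [default_bands()] for the excitation.
#' @param band_amplitudes Named numeric vector of base amplitudes (arbitrary
#'   units), one per band. If `NULL`, derived from `photophysics` via
#'   [base_amplitude()].
#' @param photophysics Named list of [photophysics_params()], one per band.
#'   Required when `band_amplitudes` is `NULL`.
#' @param fret `NULL` to disable donor->acceptor transfer, else a list with
#'   `tau_d`, `r0`, `r` (see [fret_efficiency()]) and transfer gain `g`
#'   (default 1) applied to the tryptophan -> NADH pair.
#' @param grid `c(start, stop, step)` of the emission grid in nm. Points at
#'   or below `excitation_nm + bandpass_nm` are excluded (scatter window).
#' @param n_replicates Number of replicate scans (>= 1, default 5).
#' @param replicate_cv Coefficient of variation of the per-replicate
#'   multiplicative lognormal scale factor (default 0.025).
#' @param noise_sd Additive Gaussian noise, as a fraction of the noiseless
#'   signal maximum (default 0.005).
#' @param bandpass_nm Slit bandpass in nm (default 2).
#' @param seed Root seed (integer).
#' @return An object of class `"SimulationConfig"`.
#' @export
simulation_config <- function(excitation_nm, condition,
                              bands = NULL, band_amplitudes = NULL,
                              photophysics = NULL, fret = NULL,
                              grid = c(300, 650, 2), n_replicates = 5,
                              replicate_cv = 0.025, noise_sd = 0.005,
                              bandpass_nm = 2, seed = 1L) {
  if (is.null(bands)) bands <- default_bands(excitation_nm)
  stopifnot(is.list(bands), length(bands) >= 1L)
  if (is.null(names(bands)) || any(!nzchar(names(bands)))) {
    names(bands) <- vapply(bands, function(b) b$name, character(1))
  }
  if (is.null(band_amplitudes)) {
    if (is.null(photophysics)) {
      stop("supply band_amplitudes or per-band photophysics", call. = FALSE)
    }
    if (!all(names(bands) %in% names(photophysics))) {
      stop("photophysics must name every band", call. = FALSE)
    }
    band_amplitudes <- vapply(names(bands),
                              function(f) base_amplitude(photophysics[[f]]),
                              numeric(1))
  }
  if (!all(names(bands) %in% names(band_amplitudes))) {
    stop("band_amplitudes must name every band", call. = FALSE)
  }
  if (any(band_amplitudes < 0)) {
    stop("band amplitudes must be non-negative", call. = FALSE)
  }
  if (!is.null(fret)) {
    if (is.null(fret$g)) fret$g <- 1
    fret_efficiency(fret$tau_d, fret$r0, fret$r)   # validates
  }
  if (length(grid) != 3L || grid[3] <= 0 || grid[2] <= grid[1]) {
    stop("grid must be c(start, stop, step) with step > 0", call. = FALSE)
  }
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  if (replicate_cv < 0) stop("replicate_cv must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(excitation_nm = excitation_nm, condition = condition, bands = bands,
         band_amplitudes = band_amplitudes[names(bands)],
         photophysics = photophysics, fret = fret, grid = as.numeric(grid),
         n_replicates = as.integer(n_replicates),
         replicate_cv = replicate_cv, noise_sd = noise_sd,
         bandpass_nm = bandpass_nm, seed = as.integer(seed)),
    class = "SimulationConfig"
  )
}

# Deterministic, platform-independent string hash into [0, 2^31 - 47).
# Polynomial rolling hash mod the Mersenne prime 2^31 - 1; all intermediates
# stay below 2^36, exactly representable in doubles.
stable_hash <- function(...) {
  s <- paste(..., sep = "/")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

rng_stream_seed <- function(config, replicate_index) {
  stable_hash(config$seed, config$condition, config$excitation_nm,
              replicate_index)
}

# Run `expr` under a private RNG stream without disturbing the caller's RNG.
with_stream <- function(stream_seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed)
  expr
}

#' Emission grid of a configuration
#'
#' The programmed grid restricted to the fluorescence region
#' (above `excitation_nm + bandpass_nm`).
#' @param config A [simulation_config()].
#' @return Numeric vector of wavelengths (nm).
#' @export
config_grid <- function(config) {
  wl <- seq(config$grid[1], config$grid[2], by = config$grid[3])
  wl <- wl[wl > config$excitation_nm + config$bandpass_nm]
  if (length(wl) == 0L) {
    stop("emission grid lies entirely inside the scatter window", call. = FALSE)
  }
  wl
}

#' Effective band amplitudes after FRET redistribution
#'
#' Applies donor quenching and acceptor enhancement to the tryptophan/NADH
#' pair when both bands are present and FRET is configured:
#' `A_trp <- A_trp (1 - E)`, `A_nadh <- A_nadh + g E A_trp`, with
#' `E = fret_efficiency(tau_d, r0, r)`.
#'
#' @param config A [simulation_config()].
#' @return Named numeric vector of effective amplitudes.
#' @export
effective_amplitudes <- function(config) {
  a <- config$band_amplitudes
  f <- config$fret
  if (!is.null(f) && all(c("tryptophan", "NADH") %in% names(a))) {
    e <- fret_efficiency(f$tau_d, f$r0, f$r)
    donor <- a[["tryptophan"]]
    a[["tryptophan"]] <- donor * (1 - e)
    a[["NADH"]] <- a[["NADH"]] + f$g * e * donor
  }
  a
}

# Noiseless mixture underlying every replicate of a configuration.
noiseless_signal <- function(config, grid = config_grid(config)) {
  a <- effective_amplitudes(config)
  sig <- numeric(length(grid))
  for (f in names(config$bands)) {
    sig <- sig + a[[f]] * band_profile(config$bands[[f]], grid)
  }
  sig
}

#' Simulate one replicate scan
#'
#' Intensities are the noiseless band mixture scaled by a per-replicate
#' lognormal factor (mean 1, coefficient of variation `replicate_cv`) plus
#' additive zero-mean Gaussian noise with standard deviation
#' `noise_sd * max(signal)`; negative values are clipped to zero.
#' Deterministic given (`config$seed`, `replicate_index`); the caller's RNG
#' state is left untouched.
#'
#' @param config A [simulation_config()].
#' @param replicate_index Positive integer replicate index.
#' @return A [Spectrum()].
#' @export
simulate_spectrum <- function(config, replicate_index = 1L) {
  stopifnot(inherits(config, "SimulationConfig"), replicate_index >= 1L)
  grid <- config_grid(config)
  sig <- noiseless_signal(config, grid)
  with_stream(rng_stream_seed(config, replicate_index), {
    fac <- 1
    if (config$replicate_cv > 0) {
      sln <- sqrt(log(1 + config$replicate_cv^2))
      fac <- stats::rlnorm(1, meanlog = -sln^2 / 2, sdlog = sln)
    }
    y <- sig * fac
    if (config$noise_sd > 0) {
      y <- y + stats::rnorm(length(grid), 0, config$noise_sd * max(sig))
    }
    Spectrum(config$excitation_nm, grid, pmax(y, 0),
             condition = config$condition, replicate_id = replicate_index,
             bandpass_nm = config$bandpass_nm)
  })
}

#' Simulate a replicate group
#'
#' @param config A [simulation_config()].
#' @return A [SpectrumGroup()] of `config$n_replicates` scans on a shared
#'   grid, replicate ids `1..n`.
#' @export
simulate_group <- function(config) {
  SpectrumGroup(lapply(seq_len(config$n_replicates),
                       function(i) simulate_spectrum(config, i)))
}
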
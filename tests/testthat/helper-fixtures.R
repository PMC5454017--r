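# Shared test fixtures, all built in code.

toy_spectrum <- function(wavelengths = seq(320, 640, by = 2),
                         intensities = NULL, excitation_nm = 266,
                         condition = "AD", replicate_id = "1") {
  if (is.null(intensities)) {
    intensities <- exp(-((wavelengths - 430)^2) / (2 * 40^2))
  }
  Spectrum(excitation_nm, wavelengths, intensities, condition, replicate_id)
}

# Triangle peaked at `apex` with value `height`, zero outside +-`halfwidth`.
triangle_spectrum <- function(apex = 440, height = 2, halfwidth = 30,
                              wavelengths = seq(320, 640, by = 2), ...) {
  y <- pmax(0, height * (1 - abs(wavelengths - apex) / halfwidth))
  toy_spectrum(wavelengths, y, ...)
}

# Random toy spectrum on a random uniform grid (for oracle-equivalence runs).
random_toy_spectrum <- function() {
  start <- runif(1, 300, 320)
  step <- sample(c(1, 2, 5), 1)
  n <- sample(5:60, 1)
  wl <- start + step * (0:(n - 1))
  toy_spectrum(wl, runif(n, 0, 10))
}

# Independent textbook Welch t-test (unequal variances, two-sided).
welch_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 /
    (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(statistic = t, p_value = 2 * stats::pt(-abs(t), df))
}

# Normalized AD/N group pair simulated from the calibrated presets.
simulated_pair <- function(excitation_nm, seed = 1, ...) {
  ad <- simulate_group(default_presets(excitation_nm, "AD", seed = seed, ...))
  nn <- simulate_group(default_presets(excitation_nm, "N", seed = seed, ...))
  norm <- normalize_to_ad_max(ad, nn)
  list(AD = norm$ad, N = norm$n)
}
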
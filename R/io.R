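#' Read one emission scan from a delimited text file
#'
#' Scan files are comma-separated with two numeric columns,
#' `wavelength_nm,intensity`. Lines starting with `#` are comments; a single
#' non-numeric header line is tolerated. Rows at or below
#' `excitation_nm + bandpass_nm` are elastic-scatter contamination and are
#' dropped, with the count reported via `message()`.
#'
#' @param path Path to the scan file.
#' @param excitation_nm Excitation wavelength of the scan (nm).
#' @param condition Condition label (`"AD"`, `"N"`, ...).
#' @param replicate_id Replicate identifier.
#' @param bandpass_nm Slit bandpass in nm (default 2.0).
#' @param integration_s Integration time in s (default 0.2).
#' @param drop_second_order If `TRUE`, additionally remove points within
#'   `2 * bandpass_nm` of the second-order grating line at twice the
#'   excitation wavelength. Off by default: deep-UV scans carry genuine
#'   signal near that line (e.g. 532 nm under 266 nm excitation).
#' @return A [Spectrum()].
#' @export
read_scan <- function(path, excitation_nm, condition = "other",
                      replicate_id = "1", bandpass_nm = 2.0,
                      integration_s = 0.2, drop_second_order = FALSE) {
  if (!file.exists(path)) stop("scan file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("scan file is empty: ", path, call. = FALSE)
  }
  parse_row <- function(line) {
    suppressWarnings(as.numeric(strsplit(line, ",", fixed = TRUE)[[1L]][1:2]))
  }
  first <- parse_row(lines[[1L]])
  header_skipped <- FALSE
  if (anyNA(first)) {                       # tolerate one header line
    lines <- lines[-1L]
    header_skipped <- TRUE
    if (length(lines) == 0L) {
      stop("scan file has a header but no data rows: ", path, call. = FALSE)
    }
  }
  vals <- vapply(lines, parse_row, numeric(2), USE.NAMES = FALSE)
  bad <- which(colSums(is.na(vals)) > 0)
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric scan row at line %d of %s",
                 bad[[1L]] + header_skipped, path), call. = FALSE)
  }
  wl <- vals[1L, ]
  it <- vals[2L, ]
  if (length(wl) > 1L && any(diff(wl) <= 0)) {
    stop(sprintf("non-monotone wavelengths at line %d of %s",
                 which(diff(wl) <= 0)[[1L]] + 1L + header_skipped, path),
         call. = FALSE)
  }
  keep <- wl > excitation_nm + bandpass_nm
  if (drop_second_order) {
    keep <- keep & abs(wl - 2 * excitation_nm) > 2 * bandpass_nm
  }
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message(sprintf("read_scan: dropped %d scatter-window row(s) from %s",
                    n_drop, basename(path)))
  }
  if (!any(keep)) {
    stop("no rows remain above the excitation scatter window in ", path,
         call. = FALSE)
  }
  Spectrum(excitation_nm, wl[keep], it[keep], condition, replicate_id,
           bandpass_nm, integration_s)
}

#' Write a scan file
#'
#' Inverse of [read_scan()]: writes `wavelength_nm,intensity` CSV with a
#' header line and `#` comment lines carrying the metadata, so the file
#' round-trips to an equal [Spectrum()].
#'
#' @param spectrum A [Spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(spectrum, path) {
  validate_spectrum(spectrum)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) {
    stop("cannot open path for writing: ", path, call. = FALSE)
  }
  on.exit(close(con))
  writeLines(c(
    sprintf("# excitation_nm=%.6g condition=%s replicate_id=%s",
            spectrum$excitation_nm, spectrum$condition, spectrum$replicate_id),
    sprintf("# bandpass_nm=%.6g integration_s=%.6g",
            spectrum$bandpass_nm, spectrum$integration_s),
    "wavelength_nm,intensity",
    sprintf("%.17g,%.17g", spectrum$wavelengths, spectrum$intensities)
  ), con)
  invisible(path)
}

#' Read a group manifest
#'
#' The manifest is a YAML map `condition -> excitation -> [scan paths]`,
#' with paths relative to the manifest's directory. Each
#' (condition, excitation) entry is loaded into one [SpectrumGroup()].
#'
#' @param path Manifest path.
#' @return Nested list: `groups[[condition]][[excitation]]` is a
#'   [SpectrumGroup()].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  man <- yaml::read_yaml(path)
  if (length(man) == 0L) stop("manifest is empty: ", path, call. = FALSE)
  base <- dirname(path)
  out <- list()
  for (cond in names(man)) {
    for (exc in names(man[[cond]])) {
      files <- unlist(man[[cond]][[exc]])
      if (length(files) == 0L) {
        stop(sprintf("manifest entry %s/%s lists no scans", cond, exc),
             call. = FALSE)
      }
      paths <- ifelse(startsWith(files, "/"), files, file.path(base, files))
      missing <- paths[!file.exists(paths)]
      if (length(missing) > 0L) {
        stop("missing scan file(s): ", paste(missing, collapse = ", "),
             call. = FALSE)
      }
      spectra <- lapply(seq_along(paths), function(i) {
        read_scan(paths[[i]], excitation_nm = as.numeric(exc),
                  condition = cond, replicate_id = i)
      })
      out[[cond]][[exc]] <- SpectrumGroup(spectra)
    }
  }
  out
}

#' Write a group manifest
#'
#' @param entries Nested list `condition -> excitation -> character vector of
#'   scan paths` (relative to `path`'s directory).
#' @param path Output manifest path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(entries, path) {
  yaml::write_yaml(entries, path)
  invisible(path)
}
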
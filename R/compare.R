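#' Welch comparison of AD vs N peak intensities
#'
#' Two-sample unequal-variance (Welch) t test, two-sided, on replicate peak
#' intensities, with group means and sample SDs. The Welch form is used
#' because the two tissue conditions have no reason to share a variance.
#'
#' @param ad_peaks,n_peaks Numeric vectors (length >= 2 each).
#' @return An object of class `"GroupComparison"`: `statistic`, `p_value`,
#'   `ad_mean`, `ad_sd`, `n_mean`, `n_sd`, `df`.
#' @export
compare_groups <- function(ad_peaks, n_peaks) {
  if (length(ad_peaks) < 2L || length(n_peaks) < 2L) {
    stop("need at least 2 replicates per group", call. = FALSE)
  }
  tt <- stats::t.test(ad_peaks, n_peaks, var.equal = FALSE,
                      alternative = "two.sided")
  structure(
    list(statistic = unname(tt$statistic), p_value = tt$p.value,
         df = unname(tt$parameter),
         ad_mean = mean(ad_peaks), ad_sd = stats::sd(ad_peaks),
         n_mean = mean(n_peaks), n_sd = stats::sd(n_peaks)),
    class = "GroupComparison"
  )
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf(
    "<GroupComparison> t = %.3f (df %.2f), p = %.4g | AD %.3f +- %.3f vs N %.3f +- %.3f\n",
    x$statistic, x$df, x$p_value, x$ad_mean, x$ad_sd, x$n_mean, x$n_sd))
  invisible(x)
}

#' Peak-table report in the published layout
#'
#' Builds the full summary table -- per-replicate peak intensities and
#' ratios, mean rows, and AD/N fold changes -- either from the packaged
#' published values ([load_table1()]) or from analyzed spectra.
#'
#' Rounding follows the printed conventions: intensities half-away-from-zero
#' to 3 decimals, ratios and folds to 2. The mean ratio is the mean of the
#' per-replicate ratio column (the published table's own column), not the
#' ratio of the mean intensities; the two differ in the third decimal for
#' some blocks.
#'
#' @param source A `"Table1Fixture"` from [load_table1()], or a named list
#'   `groups[[condition]][[excitation]]` of [SpectrumGroup()]s containing
#'   conditions `"AD"` and `"N"` (spectra are normalized to the AD average
#'   maximum and peaks extracted with [default_peak_windows()]).
#' @param digits_intensity,digits_ratio Decimal places for the rounded
#'   columns (defaults 3 and 2).
#' @return List with `rows` (data frame: `excitation_nm`, `condition`,
#'   `replicate` (`"1"`..`"n"` or `"mean"`), `peak1`, `peak2`, `ratio`,
#'   rounded) and `folds` (data frame: `excitation_nm`, `fluorophore`,
#'   `fold_unrounded`, `fold_printed`, rounded to 2 decimals).
#' @export
table1_report <- function(source, digits_intensity = 3, digits_ratio = 2) {
  if (inherits(source, "Table1Fixture")) {
    blocks <- lapply(source$blocks, function(by_cond) {
      lapply(by_cond, function(b) {
        list(peak1 = b$replicates[, 1L], peak2 = b$replicates[, 2L],
             ratio = b$replicates[, 3L])
      })
    })
    peak_names <- lapply(source$peaks, function(p) {
      c(p$peak1$fluorophore, p$peak2$fluorophore)
    })
  } else {
    blocks <- list()
    peak_names <- list()
    for (exc in names(source[["AD"]])) {
      norm <- normalize_to_ad_max(source[["AD"]][[exc]], source[["N"]][[exc]])
      wins <- default_peak_windows(as.numeric(exc))
      peak_names[[exc]] <- names(wins)
      for (cond in c("AD", "N")) {
        g <- if (cond == "AD") norm$ad else norm$n
        p1 <- vapply(g$spectra,
                     function(s) extract_peak(s, wins[[1L]])$intensity,
                     numeric(1))
        p2 <- vapply(g$spectra,
                     function(s) extract_peak(s, wins[[2L]])$intensity,
                     numeric(1))
        blocks[[exc]][[cond]] <- list(peak1 = p1, peak2 = p2,
                                      ratio = p1 / p2)
      }
    }
  }

  rows <- list()
  folds <- list()
  for (exc in names(blocks)) {
    for (cond in names(blocks[[exc]])) {
      b <- blocks[[exc]][[cond]]
      nrep <- length(b$peak1)
      rows[[length(rows) + 1L]] <- data.frame(
        excitation_nm = as.numeric(exc), condition = cond,
        replicate = c(as.character(seq_len(nrep)), "mean"),
        peak1 = round_half_up(c(b$peak1, mean(b$peak1)), digits_intensity),
        peak2 = round_half_up(c(b$peak2, mean(b$peak2)), digits_intensity),
        ratio = round_half_up(c(b$ratio, mean(b$ratio)), digits_ratio),
        stringsAsFactors = FALSE
      )
    }
    ad <- blocks[[exc]][["AD"]]
    nn <- blocks[[exc]][["N"]]
    if (!is.null(ad) && !is.null(nn)) {
      for (k in 1:2) {
        col <- paste0("peak", k)
        folds[[length(folds) + 1L]] <- data.frame(
          excitation_nm = as.numeric(exc),
          fluorophore = peak_names[[exc]][[k]],
          fold_unrounded = round_half_up(
            fold_change(ad[[col]], nn[[col]], "unrounded"), 2),
          fold_printed = round_half_up(
            fold_change(ad[[col]], nn[[col]], "printed"), 2),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  list(rows = do.call(rbind, rows), folds = do.call(rbind, folds))
}

# Frozen regression values for the reproduction path: every printed mean-row
# cell that is internally consistent with its own replicate columns, plus the
# published fold changes with the convention that reproduces each. The two
# inconsistent printed cells (AD/340 peak2 intensity, N/340 ratio) are
# excluded; see load_table1().
table1_regression_values <- function() {
  mean_rows <- data.frame(
    excitation_nm = c(266, 266, 300, 300, 340, 340),
    condition = c("AD", "N", "AD", "N", "AD", "N"),
    peak1 = c(1.000, 0.497, 1.000, 0.532, 1.000, 0.606),
    peak2 = c(0.268, 0.169, 0.161, 0.100, NA, 0.207),
    ratio = c(3.73, 2.93, 6.21, 5.33, 2.84, NA),
    stringsAsFactors = FALSE
  )
  folds <- data.frame(
    excitation_nm = c(266, 266, 300, 300, 340, 340),
    fluorophore = c("tryptophan", "NADH", "tryptophan", "NADH",
                    "NADH", "FAD"),
    fold = c(2.01, 1.58, 1.88, 1.61, 1.65, 1.70),
    mode = c("unrounded", "unrounded", "unrounded", "printed",
             "unrounded", "printed"),
    stringsAsFactors = FALSE
  )
  list(mean_rows = mean_rows, folds = folds)
}

#' Check a report against the published regression values
#'
#' Compares the mean rows and fold changes of a [table1_report()] with the
#' frozen published values (excluding the two internally inconsistent
#' printed cells).
#'
#' @param report Output of [table1_report()].
#' @return List with `ok` (logical) and `mismatches` (data frame naming each
#'   differing cell: `excitation_nm`, `condition`, `column`, `expected`,
#'   `actual`; zero rows when `ok`).
#' @export
check_table1_report <- function(report) {
  ref <- table1_regression_values()
  mism <- list()
  for (i in seq_len(nrow(ref$mean_rows))) {
    r <- ref$mean_rows[i, ]
    got <- report$rows[report$rows$excitation_nm == r$excitation_nm &
                       report$rows$condition == r$condition &
                       report$rows$replicate == "mean", ]
    for (col in c("peak1", "peak2", "ratio")) {
      if (is.na(r[[col]])) next
      if (nrow(got) != 1L || abs(got[[col]] - r[[col]]) > 1e-9) {
        mism[[length(mism) + 1L]] <- data.frame(
          excitation_nm = r$excitation_nm, condition = r$condition,
          column = col, expected = r[[col]],
          actual = if (nrow(got) == 1L) got[[col]] else NA_real_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  for (i in seq_len(nrow(ref$folds))) {
    r <- ref$folds[i, ]
    got <- report$folds[report$folds$excitation_nm == r$excitation_nm &
                        report$folds$fluorophore == r$fluorophore, ]
    col <- paste0("fold_", r$mode)
    if (nrow(got) != 1L || abs(got[[col]] - r$fold) > 1e-9) {
      mism[[length(mism) + 1L]] <- data.frame(
        excitation_nm = r$excitation_nm, condition = "AD/N",
        column = paste0("fold_", r$fluorophore),
        expected = r$fold,
        actual = if (nrow(got) == 1L) got[[col]] else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  mismatches <- if (length(mism)) {
    do.call(rbind, mism)
  } else {
    data.frame(excitation_nm = numeric(), condition = character(),
               column = character(), expected = numeric(),
               actual = numeric(), stringsAsFactors = FALSE)
  }
  list(ok = nrow(mismatches) == 0L, mismatches = mismatches)
}
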
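#' Packaged published peak table
#'
#' Loads the packaged copy of the published summary table of emission-peak
#' intensities and ratios: for each excitation wavelength (266, 300, 340 nm)
#' and condition (AD, N), five replicate rows of
#' (peak-1 normalized intensity, peak-2 normalized intensity, ratio) plus the
#' printed mean row, and the fluorophore/wavelength labels of the two peaks.
#'
#' The values are the printed ones, verbatim and immutable. Two printed mean
#' cells are internally inconsistent with their own replicate columns
#' (AD/340 nm peak-2 intensity: recomputed 0.351 vs printed 0.352;
#' N/340 nm ratio: recomputed 2.926 vs printed 2.928); these are listed in the
#' `inconsistent_mean_cells` field and excluded from reproduction regression
#' checks.
#'
#' @return An object of class `"Table1Fixture"`: a list with fields `peaks`,
#'   `blocks` (keyed `[["<excitation>"]][["<condition>"]]`, each holding a
#'   5 x 3 `replicates` matrix and a length-3 `mean` vector), and
#'   `inconsistent_mean_cells`.
#' @examples
#' fx <- load_table1()
#' fx$blocks[["266"]][["AD"]]$replicates[1, ]
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1.json", package = "fluorospec",
                      mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  cols <- raw$columns
  blocks <- lapply(raw$blocks, function(by_cond) {
    lapply(by_cond, function(b) {
      reps <- matrix(unlist(b$replicates), ncol = 3L, byrow = !is.matrix(b$replicates))
      if (is.matrix(b$replicates)) reps <- b$replicates
      colnames(reps) <- cols
      m <- as.numeric(b$mean)
      names(m) <- cols
      list(replicates = reps, mean = m)
    })
  })
  structure(
    list(
      peaks = raw$peaks,
      blocks = blocks,
      inconsistent_mean_cells = raw$inconsistent_mean_cells
    ),
    class = "Table1Fixture"
  )
}

#' @export
print.Table1Fixture <- function(x, ...) {
  cat("<Table1Fixture> published peak table:",
      length(x$blocks), "excitations x 2 conditions, 5 replicates each\n")
  invisible(x)
}
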
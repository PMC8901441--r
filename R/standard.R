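#' Calibrate the pooled intensity of a counting standard
#'
#' For each cell expressing the standard (e.g. Nup96-mEGFP nuclear pore
#' complexes), the per-cell standard intensity i_s is the mean of a single
#' Gaussian fitted to the cell's complex-intensity distribution (the maximum
#' likelihood Gaussian mean, optionally trimmed against outlier clusters);
#' the pooled standard intensity I_s is the arithmetic mean of i_s over
#' cells. At least 5 imaged cells are required for a valid calibration, each
#' with at least `min_complexes` measured complexes.
#'
#' @param cells list of numeric vectors, one per cell (complex intensities in
#'   counts), e.g. from [generate_standard_cells()] or detection on standard
#'   images.
#' @param Ms standard stoichiometry (32 for the Nup96 nuclear pore standard).
#' @param min_cells minimum number of cells (5).
#' @param min_complexes minimum complexes per cell (50).
#' @param trim trimming fraction for the per-cell mean (0 = plain Gaussian
#'   mean; robustification against outlier clusters is off by default).
#' @return list of class `standard_calibration`: `i_s` (per-cell means),
#'   `I_s` (pooled), `Ms`, `n_cells`.
#' @export
calibrate_standard <- function(cells, Ms = 32, min_cells = 5,
                               min_complexes = 50, trim = 0) {
  stopifnot(is.list(cells), Ms >= 1)
  if (length(cells) < min_cells)
    stop("calibrate_standard: ", length(cells), " cells; at least ",
         min_cells, " imaged cells are required")
  nper <- vapply(cells, length, integer(1))
  if (any(nper < min_complexes))
    stop("calibrate_standard: every cell needs >= ", min_complexes,
         " standard complexes (got ", min(nper), ")")
  i_s <- vapply(cells, function(x) mean(x, trim = trim), numeric(1))
  I_s <- mean(i_s)
  if (I_s <= 0) stop("calibrate_standard: non-positive pooled intensity")
  structure(list(i_s = i_s, I_s = I_s, Ms = Ms, n_cells = length(cells)),
            class = "standard_calibration")
}

#' @export
print.standard_calibration <- function(x, ...) {
  cat(sprintf("<standard_calibration> I_s = %.2f counts (Ms = %g, %d cells)\n",
              x$I_s, x$Ms, x$n_cells))
  invisible(x)
}

#' Ratiometric molecularity of a particle
#'
#' Converts background-corrected particle intensity to molecule number by
#' ratiometric comparison with the standard: `Mp = Ip * Ms / Is`. The map is
#' exactly linear, so a focus at standard intensity maps to Ms (32 for
#' Nup96), and one at three quarters of it to 24, the stoichiometry of the
#' ferritin cross-validation standard.
#'
#' @param Ip particle intensity (counts), vectorized.
#' @param calib a `standard_calibration`.
#' @return molecularity estimate(s), molecules.
#' @export
to_molecularity <- function(Ip, calib) {
  stopifnot(inherits(calib, "standard_calibration"))
  if (calib$I_s <= 0) stop("to_molecularity: invalid standard intensity")
  Ip * calib$Ms / calib$I_s
}
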
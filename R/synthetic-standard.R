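#' Simulate intensity sets from cells expressing a counting standard
#'
#' Emulates cells endogenously expressing a fluorescent standard of known
#' stoichiometry `Ms` (e.g. the 32-mer nucleoporin Nup96 tagged with mEGFP):
#' each cell contributes `n_complexes_per_cell` complex intensities drawn from
#' Normal(Ms * unit_intensity, cv * Ms * unit_intensity), truncated at zero.
#'
#' @param Ms standard stoichiometry (subunits per complex).
#' @param n_cells number of cells.
#' @param n_complexes_per_cell complexes measured per cell.
#' @param unit_intensity brightness of one subunit, counts.
#' @param cv relative spread of complex intensities.
#' @param seed integer seed.
#' @return list of length `n_cells`, each a numeric vector of complex
#'   intensities; attribute `Ms` records the stoichiometry.
#' @export
generate_standard_cells <- function(Ms = 32, n_cells = 5,
                                    n_complexes_per_cell = 500,
                                    unit_intensity = 100, cv = 0.1,
                                    seed = 1L) {
  stopifnot(Ms >= 1, n_cells >= 1, n_complexes_per_cell >= 1, cv >= 0)
  set.seed(as.integer(seed))
  mu <- Ms * unit_intensity
  cells <- lapply(seq_len(n_cells), function(i) {
    x <- rnorm(n_complexes_per_cell, mu, cv * mu)
    while (any(x <= 0)) x[x <= 0] <- rnorm(sum(x <= 0), mu, cv * mu)
    x
  })
  attr(cells, "Ms") <- Ms
  cells
}
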
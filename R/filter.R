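#' Quality-filter fitted particles
#'
#' Applies the three rejection rules used for brightness stoichiometry, each
#' evaluated independently on the full input sample (so the retained set does
#' not depend on rule order):
#' \enumerate{
#'   \item overlap: any pair of centers closer than
#'     `min_center_separation_px` flags both members (conservative: with
#'     overlapping background annuli neither brightness is trustworthy);
#'   \item sigma_outlier: fitted widths above the per-image
#'     `sigma_percentile`-th percentile of the sigma sample are excluded,
#'     because an inflated width indicates multiple particles in one ROI.
#'     The filter is one-sided (upper tail only). With fewer than 20 usable
#'     fits the percentile is unstable and the rule is skipped with a warning;
#'   \item edge_frame (z-stacks only): particles whose intensity peaks in the
#'     first or last plane are discarded since part of their axial profile
#'     was not sampled.
#' }
#' Fits already flagged `fit_fail` are never retained and do not enter the
#' sigma percentile.
#'
#' @param fits data.frame from [fit_particles()].
#' @param min_center_separation_px overlap distance, px; the default 7 equals
#'   ROI radius + background radius so background annuli never overlap.
#' @param sigma_percentile upper percentile for the width filter, in (50, 100).
#' @param n_planes number of z-planes when `fits` carries `argmax_frame`;
#'   `NULL` disables the edge-frame rule.
#' @param sigma_cut optional explicit width cut (counts as px); overrides the
#'   percentile computation, making repeated filtering idempotent.
#' @return list with `retained` (clean fits), `report` (all fits with logical
#'   columns `overlap`, `sigma_outlier`, `edge_frame`, `fit_fail`, updated
#'   `qc_flags` and `retained`), and `sigma_cut` (the width threshold used,
#'   `NA` if skipped).
#' @export
filter_particles <- function(fits, min_center_separation_px = 7,
                             sigma_percentile = 95, n_planes = NULL,
                             sigma_cut = NULL) {
  stopifnot(nrow(fits) >= 1,
            sigma_percentile > 50, sigma_percentile < 100)
  rep <- fits
  rep$fit_fail <- grepl("fit_fail", fits$qc_flags)
  n <- nrow(rep)

  rep$overlap <- FALSE
  if (n > 1) {
    d <- as.matrix(stats::dist(cbind(rep$row, rep$col)))
    diag(d) <- Inf
    rep$overlap <- apply(d < min_center_separation_px, 1, any)
  }

  rep$sigma_outlier <- FALSE
  sig <- rep$sigma[!rep$fit_fail]
  if (is.null(sigma_cut)) {
    if (length(sig) < 20) {
      warning("filter_particles: fewer than 20 fits, sigma filter skipped")
      sigma_cut <- NA_real_
    } else {
      sigma_cut <- quantile(sig, sigma_percentile / 100, names = FALSE)
    }
  }
  if (!is.na(sigma_cut))
    rep$sigma_outlier <- !rep$fit_fail & rep$sigma > sigma_cut

  rep$edge_frame <- FALSE
  if (!is.null(n_planes) && "argmax_frame" %in% names(rep))
    rep$edge_frame <- rep$argmax_frame %in% c(1L, as.integer(n_planes))

  flags <- c("overlap", "sigma_outlier", "edge_frame", "fit_fail")
  rep$qc_flags <- vapply(seq_len(n), function(i)
    paste(flags[unlist(rep[i, flags])], collapse = ","), character(1))
  rep$retained <- rep$qc_flags == ""
  list(retained = rep[rep$retained, names(fits), drop = FALSE],
       report = rep, sigma_cut = sigma_cut)
}
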
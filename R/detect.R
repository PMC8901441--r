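#' Detect diffraction-limited spots by difference of Gaussians
#'
#' Band-pass filters the image with a difference of Gaussians (DoG), then
#' keeps local maxima of the response above a threshold and deduplicates
#' candidates closer than about one PSF width (greedy, strongest response
#' wins). An empty result is a valid outcome on blank images.
#'
#' @param image numeric matrix (single frame or a max projection).
#' @param dog_sigma_small,dog_sigma_large band-pass sigmas in px
#'   (small < large); the small sigma should match the PSF sigma.
#' @param threshold absolute threshold on the DoG response, counts. If `NULL`,
#'   a noise-based default of `threshold_sd` robust SDs (MAD) of the response
#'   is used; the value actually applied is returned as an attribute.
#' @param threshold_sd multiplier for the noise-quantile default threshold.
#' @param min_distance_px deduplication radius; default one PSF FWHM
#'   (2.355 * dog_sigma_small).
#' @return data.frame with `row`, `col` (pixel coordinates of candidate
#'   maxima) and `response` (DoG value), ordered by decreasing response;
#'   attribute `threshold` records the cut applied.
#' @export
detect_spots <- function(image, dog_sigma_small = 1.3, dog_sigma_large = 2.6,
                         threshold = NULL, threshold_sd = 5,
                         min_distance_px = NULL) {
  stopifnot(is.matrix(image), dog_sigma_small < dog_sigma_large)
  if (is.null(min_distance_px)) min_distance_px <- 2.355 * dog_sigma_small
  dog <- as.matrix(EBImage::gblur(image, dog_sigma_small, boundary = "replicate")) -
    as.matrix(EBImage::gblur(image, dog_sigma_large, boundary = "replicate"))
  if (is.null(threshold)) threshold <- threshold_sd * mad(dog)

  nr <- nrow(dog); nc <- ncol(dog)
  # strict local maxima over the 8-neighbourhood, borders excluded
  core <- dog[2:(nr - 1), 2:(nc - 1)]
  ismax <- core > threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ismax <- ismax & (core > dog[2:(nr - 1) + dr, 2:(nc - 1) + dc])
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(structure(data.frame(row = numeric(0), col = numeric(0),
                                response = numeric(0)),
                     threshold = threshold))
  cand <- data.frame(row = idx[, 1] + 1, col = idx[, 2] + 1,
                     response = core[idx])
  cand <- cand[order(-cand$response), , drop = FALSE]

  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (cand$row[keep] - cand$row[i])^2 + (cand$col[keep] - cand$col[i])^2
    keep[i] <- all(d2 >= min_distance_px^2)
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, threshold = threshold)
}
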
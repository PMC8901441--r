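#' Expression level per unit mitochondrial area
#'
#' Measures a cell's fluorescent-protein expression as total GFP intensity
#' normalized to the area of its mitochondrial network. The network is
#' segmented from a mitochondrial marker channel (e.g. Smac-mCherry imaged
#' before apoptosis induction) by automatic thresholding (Otsu's method on
#' the marker histogram), and the metric is
#' `sum(gfp) / number of mask pixels`.
#'
#' @param gfp_image numeric matrix, GFP channel of one cell.
#' @param marker_image numeric matrix of identical shape, mitochondrial
#'   marker channel (co-registered).
#' @param threshold marker threshold in counts; `NULL` selects it by Otsu's
#'   method.
#' @return list: `expression` (counts per mask pixel), `mask` (logical
#'   matrix), `threshold` used.
#' @export
expression_level <- function(gfp_image, marker_image, threshold = NULL) {
  stopifnot(is.matrix(gfp_image), is.matrix(marker_image),
            all(dim(gfp_image) == dim(marker_image)))
  if (is.null(threshold)) {
    rng <- range(marker_image)
    if (diff(rng) <= 0) stop("expression_level: constant marker image")
    norm <- (marker_image - rng[1]) / diff(rng)
    threshold <- rng[1] + diff(rng) *
      EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  }
  mask <- marker_image > threshold
  area <- sum(mask)
  if (area == 0) stop("expression_level: empty mitochondrial mask")
  list(expression = sum(gfp_image) / area, mask = mask, threshold = threshold)
}
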
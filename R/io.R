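#' Read an image stack from a TIFF file
#'
#' Reads a single- or multi-page TIFF as an [image_stack()]. Pixel values are
#' returned as raw integer counts (no rescaling). Multi-sample (e.g. RGB)
#' pages are rejected unless a `channel` index selects one sample.
#'
#' @param path TIFF file path.
#' @param pixel_size_nm pixel size recorded in the stack metadata (TIFF tags
#'   rarely carry it; supplied by configuration).
#' @param channel sample index for multi-sample TIFFs; `NULL` expects
#'   single-channel data.
#' @param ... further metadata passed to [image_stack()].
#' @return an [image_stack()].
#' @export
read_stack <- function(path, pixel_size_nm = 100, channel = NULL, ...) {
  if (!file.exists(path)) stop("read_stack: no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("read_stack: cannot read '", path, "': ",
                           conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(pg) {
    if (length(dim(pg)) == 3L) {
      if (is.null(channel))
        stop("read_stack: multi-channel TIFF '", path,
             "'; select one with channel =")
      pg <- pg[, , channel]
    }
    pg
  })
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  image_stack(arr, pixel_size_nm = pixel_size_nm, ...)
}

#' Write an image stack as a 16-bit multi-page TIFF
#'
#' Counts are rounded and stored as 16-bit integers; values outside
#' [0, 65535] raise an error rather than clip silently.
#'
#' @param stack an [image_stack()] (or matrix/array of counts).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_stack <- function(stack, path) {
  arr <- if (inherits(stack, "image_stack")) stack$data else stack
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  arr <- round(arr)
  if (any(arr < 0) || any(arr > 65535))
    stop("write_stack: counts outside the 16-bit range")
  pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a particle table as CSV
#'
#' One row per fitted particle. Columns: `row`, `col` (subpixel center, px),
#' `sigma` (fitted Gaussian SD, px), `amplitude` (counts), `background`
#' (counts/px), `brightness` (integrated background-corrected intensity,
#' counts), `residual` (RMS fit residual), `qc_flags` (comma-separated;
#' empty = retained), plus `argmax_frame` for z-projections.
#'
#' @param fits particle data.frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_particles <- function(fits, path) {
  write.csv(fits, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_particles
#' @export
read_particles <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("row", "col", "brightness", "qc_flags") %in% names(df)))
    stop("read_particles: '", path, "' is not a particle table")
  df$qc_flags[is.na(df$qc_flags)] <- ""
  df
}
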
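#' Image stack container
#'
#' A light container for single-channel fluorescence stacks: a numeric array
#' with dimensions rows x cols x frames plus acquisition metadata. Frames may
#' be time points (TIRF movies) or z-planes (confocal z-stacks); `z_interval_nm`
#' marks the latter.
#'
#' @param data numeric matrix (single frame) or 3D array (rows x cols x frames);
#'   intensities in detector counts, non-negative.
#' @param pixel_size_nm lateral pixel size in nanometres (100 nm for the TIRF
#'   acquisition geometry emulated by the simulator).
#' @param frame_interval time between frames, any unit, recorded as-is.
#' @param channel free-text channel label.
#' @param z_interval_nm spacing between z-planes in nanometres, or `NA` for
#'   time series.
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size_nm = 100, frame_interval = NA_real_,
                        channel = "green", z_interval_nm = NA_real_) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (any(data < 0)) stop("image_stack: negative intensities")
  if (dim(data)[3] < 1L) stop("image_stack: at least one frame required")
  structure(
    list(data = data, pixel_size_nm = pixel_size_nm,
         frame_interval = frame_interval, channel = channel,
         z_interval_nm = z_interval_nm),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d px, %d frame(s), %.0f nm/px, channel '%s'\n",
              d[1], d[2], d[3], x$pixel_size_nm, x$channel))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' Number of frames in a stack
#' @param stack an [image_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$data)[3]

#' Extract one frame as a matrix
#' @param stack an [image_stack()].
#' @param i frame index.
#' @return numeric matrix.
#' @export
get_frame <- function(stack, i) stack$data[, , i]

#' Maximum-intensity z-projection
#'
#' Collapses a z-stack to a single image by taking, per pixel, the maximum
#' over planes, and records the plane index attaining that maximum (ties
#' resolve to the lowest plane index). The argmax map feeds the edge-frame
#' filter: particles brightest in the first or last plane are discarded
#' downstream because part of their axial intensity profile was not sampled.
#'
#' @param stack an [image_stack()] with at least 2 planes; a single-plane
#'   stack is returned unchanged with a warning.
#' @return list with `image` (matrix of per-pixel maxima) and `argmax`
#'   (integer matrix of plane indices, 1-based).
#' @export
max_z_project <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- n_frames(stack)
  if (nz < 2L) {
    warning("max_z_project: single-plane stack, returning identity")
    return(list(image = stack$data[, , 1],
                argmax = matrix(1L, nrow(stack$data), ncol(stack$data))))
  }
  img <- stack$data[, , 1]
  arg <- matrix(1L, nrow(img), ncol(img))
  for (k in 2:nz) {
    frm <- stack$data[, , k]
    upd <- frm > img   # strict: ties keep the lower plane index
    img[upd] <- frm[upd]
    arg[upd] <- k
  }
  list(image = img, argmax = arg)
}
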
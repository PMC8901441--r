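#' Fit a 2D Gaussian to one candidate spot
#'
#' Extracts a circular region of interest of radius `roi_radius_px` around the
#' candidate center, estimates the local background as the mean of the annulus
#' between `roi_radius_px` and `bg_radius_px`, and fits an isotropic 2D
#' Gaussian `A * exp(-((r-r0)^2+(c-c0)^2)/(2 sigma^2))` to the
#' background-subtracted ROI pixels by nonlinear least squares. Because the
#' PSF tail leaks into the annulus, the background estimate is refined
#' iteratively by subtracting the fitted model's annulus mean (exact on
#' noiseless spots). The particle brightness is the fitted Gaussian volume
#' `Ip = 2 pi A sigma^2`, clipped at zero.
#'
#' A fit is flagged `fit_fail` when the background annulus does not fit inside
#' the image, the optimizer does not converge, or the fitted sigma exceeds the
#' ROI radius; flagged particles are excluded downstream.
#'
#' @param image numeric matrix.
#' @param center numeric length-2 (row, col) candidate center, px.
#' @param roi_radius_px fitting disc radius, px (in vitro TIRF analyses use 3,
#'   in-cell z-projections 2).
#' @param bg_radius_px outer radius of the background annulus, px (4 in vitro,
#'   3 in cells).
#' @param psf_sigma_guess starting value for sigma, px.
#' @param sigma_fixed when given, sigma is not fitted but held at this value
#'   (used for the consensus-width brightness pass of [fit_particles()],
#'   which stabilizes the fitted volume on dim spots).
#' @return one-row data.frame: `row`, `col` (subpixel refined center), `sigma`,
#'   `amplitude`, `background`, `brightness`, `residual` (RMS of fit
#'   residuals), `qc_flags` (comma-separated string, empty when clean).
#' @export
fit_particle <- function(image, center, roi_radius_px = 3, bg_radius_px = 4,
                         psf_sigma_guess = 1.3, sigma_fixed = NULL) {
  stopifnot(is.matrix(image), length(center) == 2, bg_radius_px > roi_radius_px)
  r0 <- round(center[1]); c0 <- round(center[2])
  nr <- nrow(image); nc <- ncol(image)
  fail <- function(flag) data.frame(
    row = center[1], col = center[2], sigma = NA_real_, amplitude = NA_real_,
    background = NA_real_, brightness = NA_real_, residual = NA_real_,
    qc_flags = flag, stringsAsFactors = FALSE)

  if (r0 - bg_radius_px < 1 || r0 + bg_radius_px > nr ||
      c0 - bg_radius_px < 1 || c0 + bg_radius_px > nc)
    return(fail("fit_fail"))

  rs <- (r0 - bg_radius_px):(r0 + bg_radius_px)
  cs <- (c0 - bg_radius_px):(c0 + bg_radius_px)
  patch <- image[rs, cs]
  dr <- outer(rs - r0, rep(1, length(cs)))
  dc <- outer(rep(1, length(rs)), cs - c0)
  rad <- sqrt(dr^2 + dc^2)
  roi <- rad <= roi_radius_px
  ann <- rad > roi_radius_px & rad <= bg_radius_px
  b <- mean(patch[ann])

  rroi <- (dr + r0)[roi]; croi <- (dc + c0)[roi]
  rann <- (dr + r0)[ann]; cann <- (dc + c0)[ann]
  a0 <- max(patch[roi]) - b
  if (!is.finite(a0)) return(fail("fit_fail"))
  if (a0 <= 0)   # nothing above background: a zero-brightness particle
    return(data.frame(row = center[1], col = center[2],
                      sigma = psf_sigma_guess, amplitude = 0, background = b,
                      brightness = 0, residual = sd(patch[roi]), qc_flags = "",
                      stringsAsFactors = FALSE))
  # the PSF tail leaks into the annulus and biases the raw background mean
  # high; subtract the fitted model's annulus mean and refit (converges in
  # a couple of rounds, exactly on noiseless spots)
  b_eff <- b
  fit <- NULL
  for (round in 1:3) {
    df <- data.frame(y = patch[roi] - b_eff, r = rroi, c = croi)
    fit <- tryCatch(
      if (is.null(sigma_fixed)) {
        minpack.lm::nlsLM(
          y ~ A * exp(-((r - rr)^2 + (c - cc)^2) / (2 * s^2)), data = df,
          start = list(A = max(a0, 1e-6), rr = r0, cc = c0,
                       s = psf_sigma_guess),
          lower = c(A = 0, rr = r0 - roi_radius_px, cc = c0 - roi_radius_px,
                    s = 0.3),
          upper = c(A = Inf, rr = r0 + roi_radius_px, cc = c0 + roi_radius_px,
                    s = 2 * roi_radius_px),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          y ~ A * exp(-((r - rr)^2 + (c - cc)^2) / (2 * sigma_fixed^2)),
          data = df,
          start = list(A = max(a0, 1e-6), rr = r0, cc = c0),
          lower = c(A = 0, rr = r0 - roi_radius_px, cc = c0 - roi_radius_px),
          upper = c(A = Inf, rr = r0 + roi_radius_px, cc = c0 + roi_radius_px),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      },
      error = function(e) NULL)
    if (is.null(fit)) return(fail("fit_fail"))
    p <- coef(fit)
    s_cur <- if (is.null(sigma_fixed)) p[["s"]] else sigma_fixed
    tail_leak <- mean(p[["A"]] *
      exp(-((rann - p[["rr"]])^2 + (cann - p[["cc"]])^2) / (2 * s_cur^2)))
    b_eff <- b - tail_leak
  }
  p <- coef(fit)
  s_fit <- if (is.null(sigma_fixed)) p[["s"]] else sigma_fixed
  if (s_fit > roi_radius_px) return(fail("fit_fail"))
  ip <- max(2 * pi * p[["A"]] * s_fit^2, 0)
  data.frame(row = p[["rr"]], col = p[["cc"]], sigma = s_fit,
             amplitude = p[["A"]], background = b_eff,
             brightness = ip,
             residual = sqrt(mean(resid(fit)^2)), qc_flags = "",
             stringsAsFactors = FALSE)
}

#' Fit all candidate spots of an image
#'
#' Applies [fit_particle()] to every row of a candidate table (as returned by
#' [detect_spots()]) and optionally annotates each particle with the z-plane
#' of maximum intensity at its center (for the edge-frame filter applied to
#' max projections of z-stacks).
#'
#' Brightness uses a two-pass scheme: the first pass fits every spot with a
#' free width (the per-spot `sigma` kept for the width filter); the second
#' pass refits amplitude and center with the width held at the image
#' consensus (median of clean first-pass widths -- the PSF is one optical
#' property of the image, so per-spot width scatter on dim spots is noise,
#' and letting it into the volume `2 pi A sigma^2` would inflate brightness
#' variance). Disable with `refine_brightness = FALSE` to report pure
#' single-pass fits.
#'
#' @param image numeric matrix.
#' @param centers data.frame with `row` and `col` columns.
#' @param argmax optional integer matrix from [max_z_project()].
#' @param refine_brightness apply the consensus-width second pass (needs at
#'   least 5 clean fits, otherwise skipped).
#' @inheritParams fit_particle
#' @return data.frame of particle fits, one row per candidate, with an
#'   additional `argmax_frame` column when `argmax` is supplied.
#' @export
fit_particles <- function(image, centers, roi_radius_px = 3, bg_radius_px = 4,
                          psf_sigma_guess = 1.3, argmax = NULL,
                          refine_brightness = TRUE) {
  fits <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    fit_particle(image, c(centers$row[i], centers$col[i]),
                 roi_radius_px, bg_radius_px, psf_sigma_guess)))
  if (is.null(fits))
    fits <- fit_particle(image, c(-1, -1))[0, ]
  clean <- fits$qc_flags == ""
  if (refine_brightness && sum(clean) >= 5) {
    sigma_ref <- median(fits$sigma[clean])
    for (i in which(clean)) {
      rf <- fit_particle(image, c(centers$row[i], centers$col[i]),
                         roi_radius_px, bg_radius_px, psf_sigma_guess,
                         sigma_fixed = sigma_ref)
      if (rf$qc_flags == "") {
        fits$row[i] <- rf$row; fits$col[i] <- rf$col
        fits$amplitude[i] <- rf$amplitude
        fits$background[i] <- rf$background
        fits$brightness[i] <- rf$brightness
        fits$residual[i] <- rf$residual
      }
    }
  }
  if (!is.null(argmax)) {
    fits$argmax_frame <- vapply(seq_len(nrow(fits)), function(i) {
      r <- round(if (is.na(fits$row[i])) centers$row[i] else fits$row[i])
      c <- round(if (is.na(fits$col[i])) centers$col[i] else fits$col[i])
      argmax[max(1, min(nrow(argmax), r)), max(1, min(ncol(argmax), c))]
    }, integer(1))
  }
  rownames(fits) <- NULL
  fits
}
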
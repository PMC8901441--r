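#' Radial intensity profile around a vesicle center
#'
#' Azimuthally averages pixel intensities into concentric annular bins around
#' a given center. The local background is the mean intensity beyond
#' `background_factor * r_vesicle` (still within `r_max`); the corrected
#' profile is background-subtracted and normalized to its peak. Raw bin means
#' and pixel counts are returned as well, so that total intensity within
#' `r_max` is exactly conserved by the binning.
#'
#' @param image numeric matrix.
#' @param center length-2 (row, col) vesicle center, px; must lie inside the
#'   image and the circle of radius `r_max` fully within it.
#' @param r_max outer profile radius, px.
#' @param n_bins number of radial bins (>= 10).
#' @param r_vesicle nominal vesicle radius, px, used for the background zone;
#'   defaults to `r_max / background_factor` (background from the outermost
#'   annuli).
#' @param background_factor multiple of `r_vesicle` beyond which pixels count
#'   as background.
#' @return list of class `radial_profile`: `r_mid` (bin mid-radii), `raw_mean`,
#'   `count`, `background`, `profile` (corrected, peak-normalized), `center`,
#'   `r_max`.
#' @export
radial_profile <- function(image, center, r_max, n_bins = 50,
                           r_vesicle = NULL, background_factor = 1.2) {
  stopifnot(is.matrix(image), length(center) == 2, r_max > 0, n_bins >= 10)
  nr <- nrow(image); nc <- ncol(image)
  if (center[1] < 1 || center[1] > nr || center[2] < 1 || center[2] > nc)
    stop("radial_profile: center outside image")
  if (center[1] - r_max < 1 || center[1] + r_max > nr ||
      center[2] - r_max < 1 || center[2] + r_max > nc)
    stop("radial_profile: circle of radius r_max not fully inside image")
  if (is.null(r_vesicle)) r_vesicle <- r_max / background_factor

  rr <- outer(seq_len(nr) - center[1], rep(1, nc))
  cc <- outer(rep(1, nr), seq_len(nc) - center[2])
  rad <- sqrt(rr^2 + cc^2)
  inside <- rad <= r_max
  width <- r_max / n_bins
  bin <- pmin(pmax(ceiling(rad[inside] / width), 1L), n_bins)
  vals <- image[inside]

  count <- tabulate(bin, n_bins)
  sums <- vapply(seq_len(n_bins), function(b) sum(vals[bin == b]), numeric(1))
  raw_mean <- ifelse(count > 0, sums / count, NA_real_)

  bg_zone <- rad > background_factor * r_vesicle & inside
  background <- if (any(bg_zone)) mean(image[bg_zone]) else 0
  corr <- raw_mean - background
  peak <- max(corr, na.rm = TRUE)
  profile <- if (peak > 0) corr / peak else corr

  structure(list(r_mid = (seq_len(n_bins) - 0.5) * width, raw_mean = raw_mean,
                 count = count, background = background, profile = profile,
                 center = center, r_max = r_max),
            class = "radial_profile")
}

#' Locate the vesicle rim by a Gaussian fit to the radial profile
#'
#' Fits `A * exp(-(r - mu)^2 / (2 w^2)) + c` to the background-corrected
#' radial profile. A profile without an interior local maximum (flat, or
#' peaking at the first/last bin) is flagged `unbound`: no protein ring at
#' the membrane.
#'
#' @param profile a `radial_profile`, or a numeric profile vector (then
#'   `r` gives the radii).
#' @param r radii for a plain numeric profile.
#' @return list: `center`, `amplitude`, `width` (px), `unbound` (logical);
#'   fit fields are `NA` when unbound.
#' @export
fit_rim_peak <- function(profile, r = NULL) {
  if (inherits(profile, "radial_profile")) {
    y <- profile$profile; r <- profile$r_mid
  } else {
    y <- as.numeric(profile)
    if (is.null(r)) r <- seq_along(y)
  }
  ok <- is.finite(y)
  y <- y[ok]; r <- r[ok]
  unbound <- list(center = NA_real_, amplitude = NA_real_, width = NA_real_,
                  unbound = TRUE)
  if (length(y) < 5) return(unbound)
  imax <- which.max(y)
  if (imax == 1 || imax == length(y)) return(unbound)
  if (diff(range(y)) <= .Machine$double.eps * (abs(max(y)) + 1)) return(unbound)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(r - mu)^2 / (2 * w^2)) + c0,
                      data = data.frame(r = r, y = y),
                      start = list(A = y[imax] - min(y), mu = r[imax],
                                   w = diff(range(r)) / 10, c0 = min(y)),
                      lower = c(A = 0, mu = min(r), w = .Machine$double.eps,
                                c0 = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(unbound)
  p <- coef(fit)
  if (p[["A"]] <= 0) return(unbound)
  list(center = p[["mu"]], amplitude = p[["A"]], width = abs(p[["w"]]),
       unbound = FALSE)
}

#' Fraction of permeabilized vesicles
#'
#' A vesicle counts as permeabilized when the ratio of its internal to
#' external probe intensity reaches `threshold` (default 0.5: the lumen has
#' equilibrated at least half-way with the bulk). Vesicles with near-zero
#' outside intensity are excluded (ratio undefined). The percentage is
#' invariant under any global rescaling of the probe channel.
#'
#' @param vesicles data.frame with columns `inside` and `outside` (mean probe
#'   intensities per vesicle).
#' @param threshold inside/outside ratio defining permeabilization.
#' @param eps relative floor below which the outside intensity counts as zero.
#' @return list: `percent` permeabilized, `n_used`, `n_excluded`, `ratio`
#'   (per-vesicle, NA where excluded).
#' @export
permeabilization_fraction <- function(vesicles, threshold = 0.5, eps = 1e-9) {
  stopifnot(is.data.frame(vesicles), nrow(vesicles) >= 1,
            all(c("inside", "outside") %in% names(vesicles)))
  scale <- max(abs(vesicles$outside), na.rm = TRUE)
  bad <- !is.finite(vesicles$outside) | vesicles$outside <= eps * max(scale, 1)
  ratio <- ifelse(bad, NA_real_, vesicles$inside / vesicles$outside)
  if (all(bad)) stop("permeabilization_fraction: no vesicle with usable outside intensity")
  list(percent = 100 * mean(ratio[!bad] >= threshold),
       n_used = sum(!bad), n_excluded = sum(bad), ratio = ratio)
}
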
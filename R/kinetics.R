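#' Average molecularity from an exponential fit of cumulative counts
#'
#' Fits `C(M) = A * exp(-M / mean)` to the complementary cumulative count
#' C(M) = number of foci with molecularity >= M, evaluated at the sorted
#' sample values, by nonlinear least squares. For exponentially distributed
#' molecularities the decay constant is the mean molecularity of the foci
#' population; the estimator is exactly scale-equivariant. With fewer than
#' `min_foci` values, or a degenerate (constant) sample, the sample mean is
#' returned with `fallback = TRUE`.
#'
#' @param m numeric vector of foci molecularities (>= 0).
#' @param min_foci minimum sample size for the fit.
#' @return list: `mean` (average molecularity), `A` (fitted amplitude, `NA`
#'   on fallback), `fallback`, `n`.
#' @export
fit_cumulative_decay <- function(m, min_foci = 10) {
  m <- m[is.finite(m)]
  n <- length(m)
  if (n == 0) return(list(mean = NA_real_, A = NA_real_, fallback = TRUE, n = 0L))
  if (n < min_foci || sd(m) == 0)
    return(list(mean = mean(m), A = NA_real_, fallback = TRUE, n = n))
  x <- sort(m)
  C <- n - seq_len(n) + 1  # number of foci >= x_i
  fit <- tryCatch(
    minpack.lm::nlsLM(C ~ A * exp(-x / mb),
                      data = data.frame(x = x, C = C),
                      start = list(A = n, mb = mean(m)),
                      lower = c(A = 0, mb = .Machine$double.eps),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(mean = mean(m), A = NA_real_, fallback = TRUE, n = n))
  p <- coef(fit)
  list(mean = p[["mb"]], A = p[["A"]], fallback = FALSE, n = n)
}

#' Kinetic summary of a MOMP-aligned foci time series
#'
#' Per timepoint: the average molecularity from the exponential-survival fit
#' ([fit_cumulative_decay()]), the foci density per mitochondrial area, and
#' the fraction of foci whose molecularity exceeds each threshold (strict
#' inequality; 200 and 400 molecules by default). Timepoints without foci
#' report zero density and fractions and an undefined average.
#'
#' @param series a [foci_time_series()].
#' @param thresholds molecularity thresholds for the large-focus fractions.
#' @param min_foci passed to [fit_cumulative_decay()].
#' @return data.frame: `time`, `n_foci`, `density`, `mean_molecularity`,
#'   `fallback`, and one `frac_gt_<T>` column per threshold.
#' @export
summarize_timeseries <- function(series, thresholds = c(200, 400),
                                 min_foci = 10) {
  stopifnot(inherits(series, "foci_time_series"))
  if (series$mito_area <= 0) stop("summarize_timeseries: zero mitochondrial area")
  out <- data.frame(time = series$timepoints,
                    n_foci = series$foci_count,
                    density = series$foci_count / series$mito_area,
                    mean_molecularity = NA_real_, fallback = NA)
  for (th in thresholds) out[[paste0("frac_gt_", th)]] <- 0
  for (k in seq_along(series$timepoints)) {
    m <- series$molecularity[[k]]
    if (length(m) == 0) { out$fallback[k] <- TRUE; next }
    fit <- fit_cumulative_decay(m, min_foci)
    out$mean_molecularity[k] <- fit$mean
    out$fallback[k] <- fit$fallback
    for (th in thresholds)
      out[[paste0("frac_gt_", th)]][k] <- mean(m > th)
  }
  out
}

#' Align acquisition times to MOMP
#'
#' Re-expresses acquisition timestamps relative to the moment of MOMP (Smac
#' release), the temporal reference that synchronizes kinetics across cells.
#' Pre-MOMP frames are flagged and, for time series, excluded from kinetics.
#'
#' @param x numeric timepoints, or a [foci_time_series()] whose clock is the
#'   raw acquisition clock.
#' @param momp_time MOMP time on the same clock; must be finite and within
#'   the acquisition window.
#' @param ... unused.
#' @return For numeric input, a data.frame `time`, `rel_time`, `pre_momp`;
#'   for a time series, a new [foci_time_series()] on the MOMP clock with
#'   pre-MOMP timepoints dropped (warning if none remain, returning `NULL`).
#' @export
align_to_momp <- function(x, momp_time, ...) UseMethod("align_to_momp")

#' @export
align_to_momp.numeric <- function(x, momp_time, ...) {
  if (is.null(momp_time) || !is.finite(momp_time))
    stop("align_to_momp: momp_time undefined")
  if (momp_time < min(x) || momp_time > max(x))
    warning("align_to_momp: momp_time outside the acquisition window")
  data.frame(time = x, rel_time = x - momp_time, pre_momp = x < momp_time)
}

#' @export
align_to_momp.foci_time_series <- function(x, momp_time, ...) {
  al <- align_to_momp(x$timepoints, momp_time)
  keep <- !al$pre_momp
  if (!any(keep)) {
    warning("align_to_momp: all frames precede MOMP; empty kinetics")
    return(NULL)
  }
  foci_time_series(al$rel_time[keep], x$molecularity[keep], x$mito_area,
                   truth_mean = if (!is.null(x$truth_mean)) x$truth_mean[keep])
}
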
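#' Count photobleaching steps in an intensity trace
#'
#' Smooths the trace with a running median, then segments it into
#' piecewise-constant plateaus by binary segmentation: the split that most
#' reduces the residual sum of squares is accepted while the reduction
#' exceeds a BIC-style penalty proportional to the noise variance (estimated
#' robustly from first differences). Steps are the boundaries at which the
#' plateau level decreases; a level increase larger than the noise tolerance
#' (re-brightening) marks the trace as rejected, since bleaching is
#' irreversible.
#'
#' @param trace numeric vector of intensities per frame.
#' @param median_window running-median window, frames (odd; even values are
#'   promoted). The trace must be longer than 3 windows.
#' @param penalty RSS-reduction required per accepted changepoint; the default
#'   `8 * sigma^2 * log(n)` was validated on simulated staircase traces.
#' @param min_segment minimum plateau length, frames.
#' @return list: `n_steps` (downward steps), `levels` (plateau means),
#'   `changepoints` (last frame of each plateau but the final one),
#'   `rejected` (logical, re-brightening detected).
#' @export
count_bleach_steps <- function(trace, median_window = 5, penalty = NULL,
                               min_segment = 3) {
  stopifnot(is.numeric(trace), length(trace) > 3 * median_window)
  k <- median_window
  if (k %% 2 == 0) k <- k + 1
  sm <- if (k >= 3) runmed(trace, k, endrule = "median") else trace
  n <- length(sm)
  sigma <- mad(diff(trace)) / sqrt(2)
  if (is.null(penalty))
    penalty <- max(8 * sigma^2 * log(n), 1e-9 * (diff(range(sm))^2 + 1))

  # binary segmentation on plateau means
  best_split <- function(lo, hi) {
    seg <- sm[lo:hi]; m <- length(seg)
    if (m < 2 * min_segment) return(NULL)
    cs <- cumsum(seg); tot <- cs[m]
    i <- min_segment:(m - min_segment)
    gain <- cs[i]^2 / i + (tot - cs[i])^2 / (m - i) - tot^2 / m
    j <- which.max(gain)
    list(pos = lo + i[j] - 1L, gain = gain[j])
  }
  bounds <- integer(0)
  queue <- list(c(1L, n))
  while (length(queue) > 0) {
    seg <- queue[[1]]; queue <- queue[-1]
    sp <- best_split(seg[1], seg[2])
    if (is.null(sp) || sp$gain <= penalty) next
    bounds <- c(bounds, sp$pos)
    queue <- c(queue, list(c(seg[1], sp$pos)), list(c(sp$pos + 1L, seg[2])))
  }
  bounds <- sort(bounds)
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  levels <- vapply(seq_along(starts), function(i)
    mean(sm[starts[i]:ends[i]]), numeric(1))

  dl <- diff(levels)
  tol <- if (sigma > 0) 3 * sigma else 1e-8 * (abs(mean(levels)) + 1)
  rejected <- any(dl > tol)
  list(n_steps = sum(dl < 0), levels = levels,
       changepoints = bounds, rejected = rejected)
}

#' Calibrate the monomer brightness unit
#'
#' Estimates the mean brightness of a single fluorophore (mu1) and its spread
#' (sigma1), either from photobleaching traces -- keeping only traces showing
#' exactly one downward step and no re-brightening, and measuring the initial
#' plateau height above the final baseline -- or directly from the fitted
#' brightnesses of a single-molecule sample.
#'
#' @param x either a matrix of traces (rows = traces, as from
#'   [generate_bleach_traces()]) or a numeric vector of single-molecule
#'   brightness values.
#' @param median_window,penalty passed to [count_bleach_steps()] for traces.
#' @param min_traces minimum number of accepted single-step candidates; below
#'   it the calibration is considered unreliable and an error is raised.
#' @return list of class `monomer_calibration`: `mu1`, `sigma1`, `n_used`.
#' @export
calibrate_monomer <- function(x, median_window = 5, penalty = NULL,
                              min_traces = 50) {
  if (is.matrix(x)) {
    heights <- numeric(0)
    for (i in seq_len(nrow(x))) {
      st <- count_bleach_steps(x[i, ], median_window, penalty)
      if (st$n_steps == 1 && !st$rejected)
        heights <- c(heights, st$levels[1] - st$levels[length(st$levels)])
    }
  } else {
    heights <- as.numeric(x)
    heights <- heights[is.finite(heights) & heights > 0]
  }
  if (length(heights) < min_traces)
    stop("calibrate_monomer: only ", length(heights),
         " single-step candidates (need >= ", min_traces, ")")
  structure(list(mu1 = mean(heights), sigma1 = sd(heights),
                 n_used = length(heights)),
            class = "monomer_calibration")
}

#' @export
print.monomer_calibration <- function(x, ...) {
  cat(sprintf("<monomer_calibration> mu1 = %.2f, sigma1 = %.2f counts (n = %d)\n",
              x$mu1, x$sigma1, x$n_used))
  invisible(x)
}
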
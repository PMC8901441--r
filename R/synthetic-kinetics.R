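#' Kinetic model of focus growth after MOMP
#'
#' Two idealized growth regimes for mitochondrial BAX/BAK-type foci, with time
#' measured in minutes after MOMP (Smac release):
#' \describe{
#'   \item{saturating}{mean molecularity M(t) = plateau * (1 - exp(-t'/tau))
#'     with t' = max(0, t - onset_lag) and tau = plateau / rate (so `rate` is
#'     the initial growth speed). Emulates fast-assembling oligomers that
#'     stabilize at a fixed size of a few hundred molecules; the number of
#'     foci stays roughly constant after an initial nucleation burst.}
#'   \item{linear}{mean molecularity M(t) = rate * t', unbounded, with a focus
#'     count that keeps increasing over the acquisition. Emulates slower
#'     continuously growing oligomers.}
#' }
#' These functional forms are the simplest ones producing a stable size versus
#' unbounded growth; real foci trajectories are reported only graphically.
#'
#' @param mode `"saturating"` or `"linear"`.
#' @param plateau asymptotic molecularity (saturating mode), molecules.
#' @param rate growth rate, molecules/min.
#' @param onset_lag delay between MOMP and growth onset, min.
#' @param noise_cv coefficient of variation of the per-timepoint lognormal
#'   factor applied to the mean trajectory (cell/measurement variability).
#' @param foci_birth_rate foci per (px^2 * min); sets the focus count scale.
#' @return list of class `kinetic_model`.
#' @export
kinetic_model <- function(mode = c("saturating", "linear"),
                          plateau = 200, rate = 80, onset_lag = 0,
                          noise_cv = 0.1, foci_birth_rate = 2e-5) {
  mode <- match.arg(mode)
  if (mode == "saturating" && plateau <= 0) stop("kinetic_model: plateau must be > 0")
  if (rate <= 0) stop("kinetic_model: rate must be > 0")
  structure(list(mode = mode, plateau = plateau, rate = rate,
                 onset_lag = onset_lag, noise_cv = noise_cv,
                 foci_birth_rate = foci_birth_rate),
            class = "kinetic_model")
}

#' Mean molecularity trajectory of a kinetic model
#' @param model a [kinetic_model()].
#' @param t time(s) after MOMP, min.
#' @return numeric vector of mean molecularities.
#' @export
mean_trajectory <- function(model, t) {
  te <- pmax(0, t - model$onset_lag)
  if (model$mode == "saturating") {
    tau <- model$plateau / model$rate
    model$plateau * (1 - exp(-te / tau))
  } else {
    model$rate * te
  }
}

#' Foci time-series container
#'
#' Per-timepoint lists of foci molecularities on a MOMP-aligned clock.
#'
#' @param timepoints strictly increasing times, min after MOMP.
#' @param molecularity list (one element per timepoint) of numeric vectors of
#'   per-focus molecularities (>= 0).
#' @param mito_area mitochondrial network area, px^2 (or um^2; any consistent
#'   unit for the density summary).
#' @param truth_mean optional ground-truth mean trajectory (generator only).
#' @return list of class `foci_time_series`.
#' @export
foci_time_series <- function(timepoints, molecularity, mito_area,
                             truth_mean = NULL) {
  stopifnot(length(timepoints) == length(molecularity))
  if (length(timepoints) == 0) stop("foci_time_series: empty timepoints")
  if (is.unsorted(timepoints, strictly = TRUE))
    stop("foci_time_series: timepoints must be strictly increasing")
  if (any(unlist(molecularity) < 0))
    stop("foci_time_series: negative molecularity")
  if (mito_area <= 0) stop("foci_time_series: mito_area must be > 0")
  structure(list(timepoints = timepoints, molecularity = molecularity,
                 mito_area = mito_area,
                 foci_count = vapply(molecularity, length, integer(1)),
                 truth_mean = truth_mean),
            class = "foci_time_series")
}

#' @export
print.foci_time_series <- function(x, ...) {
  cat(sprintf("<foci_time_series> %d timepoints (%g..%g min), %d foci total, area %g\n",
              length(x$timepoints), min(x$timepoints), max(x$timepoints),
              sum(x$foci_count), x$mito_area))
  invisible(x)
}

#' Simulate a MOMP-aligned foci time series with known mean trajectory
#'
#' At each timepoint the focus count is Poisson with mean
#' `foci_birth_rate * mito_area * min(t, 5)` (saturating mode: nucleation
#' completes within the first acquisition interval, constant count afterwards)
#' or `foci_birth_rate * mito_area * t` (linear mode: count grows with time).
#' Per-focus molecularity is drawn Exponential with mean M(t) * eta_t, where
#' eta_t is a lognormal factor of CV `noise_cv` shared by all foci of a
#' timepoint. The exponential dispersion matches the decaying shape of
#' per-cell foci intensity distributions, for which an exponential-survival
#' fit is the natural mean estimator.
#'
#' @param model a [kinetic_model()].
#' @param timepoints sorted times >= 0, min after MOMP (0 = Smac release).
#' @param mito_area mitochondrial area, px^2.
#' @param seed integer seed.
#' @return a [foci_time_series()] with `truth_mean` set to M(t).
#' @export
generate_foci_timeseries <- function(model, timepoints, mito_area,
                                     seed = 1L) {
  stopifnot(inherits(model, "kinetic_model"))
  if (length(timepoints) == 0) stop("generate_foci_timeseries: empty timepoints")
  stopifnot(!is.unsorted(timepoints, strictly = TRUE), min(timepoints) >= 0)
  set.seed(as.integer(seed))
  mtru <- mean_trajectory(model, timepoints)
  slog <- sqrt(log(1 + model$noise_cv^2))
  mol <- vector("list", length(timepoints))
  for (k in seq_along(timepoints)) {
    t <- timepoints[k]
    lam <- model$foci_birth_rate * mito_area *
      (if (model$mode == "saturating") min(t, 5) else t)
    nf <- rpois(1, lam)
    if (nf == 0 || mtru[k] <= 0) { mol[[k]] <- numeric(0); next }
    eta <- exp(rnorm(1, -slog^2 / 2, slog))
    mol[[k]] <- rexp(nf, rate = 1 / (mtru[k] * eta))
  }
  foci_time_series(timepoints, mol, mito_area, truth_mean = mtru)
}
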
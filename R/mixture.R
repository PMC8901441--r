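#' Decompose a brightness distribution into labeled n-mer fractions
#'
#' Fits the probability density of particle brightnesses with a linear
#' combination of Gaussians whose means and variances are fixed by the
#' monomer calibration: component j (particles carrying j labeled
#' fluorophores) has mean `j * mu1` and variance `j * sigma1^2`, the variance
#' of a sum of j independent emitters. Only the mixing weights are free,
#' constrained to the simplex, and are estimated by maximum likelihood on the
#' raw brightness values (weight-only EM), avoiding histogram bin-width
#' sensitivity.
#'
#' @param brightness numeric vector of background-corrected particle
#'   brightnesses (Ip). Non-positive values are dropped with a warning.
#'   Fewer than 200 values triggers a warning (stoichiometry experiments
#'   typically pool >= 600-1500 particles).
#' @param calib a `monomer_calibration` (or list with `mu1`, `sigma1`).
#' @param max_n highest labeled order fitted (10 covers oligomers up to
#'   10-mer labeled units).
#' @param labeling_efficiency optional p; when given, the labeling-corrected
#'   true n-mer weights are computed via [correct_labeling()] and included.
#' @param tol,max_iter EM convergence controls (relative log-likelihood).
#' @return list of class `mixture_result`: `weights` (named w_1..w_max_n,
#'   observed labeled-unit fractions, summing to 1), `corrected` (true n-mer
#'   fractions, `NULL` unless p given), `mu1`, `sigma1`, `max_n`, `loglik`,
#'   `n`, `labeling_efficiency`.
#' @export
fit_gaussian_mixture <- function(brightness, calib, max_n = 10,
                                 labeling_efficiency = NULL,
                                 tol = 1e-8, max_iter = 1000) {
  mu1 <- calib$mu1; s1 <- calib$sigma1
  stopifnot(mu1 > 0, s1 >= 0, max_n >= 1)
  x <- brightness[is.finite(brightness)]
  if (any(x <= 0)) {
    warning("fit_gaussian_mixture: dropping ", sum(x <= 0),
            " non-positive brightness values")
    x <- x[x > 0]
  }
  if (length(x) < 200)
    warning("fit_gaussian_mixture: only ", length(x),
            " particles; weight estimates may be unstable")
  if (length(x) < 10) stop("fit_gaussian_mixture: too few particles")

  j <- seq_len(max_n)
  mu_j <- j * mu1
  sd_j <- pmax(sqrt(j) * s1, 0.05 * mu1)  # floor guards degenerate sigma1 = 0
  dens <- vapply(j, function(k) dnorm(x, mu_j[k], sd_j[k]), numeric(length(x)))

  w <- rep(1 / max_n, max_n)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    num <- sweep(dens, 2, w, `*`)
    tot <- rowSums(num)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    w <- colMeans(num / tot)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  w <- w / sum(w)
  names(w) <- paste0("w", j)

  corrected <- NULL
  if (!is.null(labeling_efficiency))
    corrected <- correct_labeling(w, labeling_efficiency)
  structure(list(weights = w, corrected = corrected, mu1 = mu1, sigma1 = s1,
                 max_n = max_n, loglik = ll, n = length(x),
                 labeling_efficiency = labeling_efficiency),
            class = "mixture_result")
}

#' @export
print.mixture_result <- function(x, ...) {
  cat(sprintf("<mixture_result> n = %d particles, mu1 = %.2f, logLik = %.1f\n",
              x$n, x$mu1, x$loglik))
  cat("  observed labeled-unit weights (%):\n  ")
  cat(paste(sprintf("%d:%.1f", seq_len(x$max_n), 100 * x$weights),
            collapse = "  "), "\n")
  if (!is.null(x$corrected)) {
    cat(sprintf("  corrected n-mer weights (p = %.2f) (%%):\n  ",
                x$labeling_efficiency))
    cat(paste(sprintf("%d:%.1f", seq_along(x$corrected), 100 * x$corrected),
              collapse = "  "), "\n")
  }
  invisible(x)
}
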
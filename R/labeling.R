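#' Binomial labeling operator on visible classes
#'
#' With labeling efficiency p, a true n-mer shows j labeled subunits with
#' probability `C(n, j) p^j (1-p)^(n-j)`. Particles with j = 0 carry no dye
#' and are never detected, so the observable operator maps true n-mer
#' fractions v_n to visible labeled-class fractions w_j (j >= 1). With
#' `renormalize_invisible = TRUE` (default) each column is conditioned on
#' visibility, i.e. divided by `1 - (1-p)^n`, which is the operator whose
#' inverse recovers the composition of the detected population.
#'
#' @param max_n largest order (matrix is max_n x max_n, rows j, cols n).
#' @param p labeling efficiency in (0, 1].
#' @param renormalize_invisible condition on j >= 1 per column.
#' @return max_n x max_n numeric matrix B with B[j, n] = P(j labels | n-mer).
#' @export
labeling_matrix <- function(max_n, p, renormalize_invisible = TRUE) {
  stopifnot(max_n >= 1)
  if (p <= 0 || p > 1) stop("labeling_matrix: p must be in (0, 1]")
  B <- outer(seq_len(max_n), seq_len(max_n),
             function(j, n) ifelse(j <= n, choose(n, j) * p^j * (1 - p)^(n - j), 0))
  if (renormalize_invisible) {
    vis <- 1 - (1 - p)^seq_len(max_n)
    B <- sweep(B, 2, vis, `/`)
  }
  B
}

#' Forward-project true n-mer weights through partial labeling
#'
#' @param v simplex of true n-mer fractions (length defines max_n).
#' @param p labeling efficiency.
#' @inheritParams labeling_matrix
#' @return visible labeled-class fractions w_j, renormalized to sum to 1.
#' @export
project_labeling <- function(v, p, renormalize_invisible = TRUE) {
  w <- as.vector(labeling_matrix(length(v), p, renormalize_invisible) %*% v)
  w / sum(w)
}

#' Correct observed labeled-unit weights for partial labeling
#'
#' Inverts the binomial labeling operator: solves `w = B v` for the true
#' n-mer fractions v by non-negative least squares and renormalizes to the
#' simplex. At p = 1 the operator is the identity and v = w. Labeling
#' efficiencies outside the (0.75, 1] range accepted for stoichiometry
#' experiments trigger a warning but are processed.
#'
#' @param w observed weights over labeled classes j = 1..max_n (as from
#'   [fit_gaussian_mixture()]); renormalized internally.
#' @param p labeling efficiency in (0, 1].
#' @param renormalize_invisible see [labeling_matrix()]; the default inverts
#'   the visible-conditioned operator (the detected population excludes
#'   unlabeled particles).
#' @return named numeric vector v_1..v_max_n of corrected n-mer fractions.
#' @export
correct_labeling <- function(w, p, renormalize_invisible = TRUE) {
  if (p <= 0 || p > 1) stop("correct_labeling: p must be in (0, 1]")
  if (p <= 0.75)
    warning("correct_labeling: labeling efficiency below the 75% acceptance ",
            "threshold for stoichiometry experiments")
  if (any(w < 0)) stop("correct_labeling: negative weights")
  w <- w / sum(w)
  max_n <- length(w)
  B <- labeling_matrix(max_n, p, renormalize_invisible)
  v <- pracma::lsqnonneg(B, as.numeric(w))$x
  if (sum(v) <= 0) stop("correct_labeling: degenerate solution")
  v <- v / sum(v)
  names(v) <- paste0("v", seq_len(max_n))
  v
}

#' Summarize n-mer occurrence across experiments
#'
#' Per-order mean and standard deviation of occurrence, in percent, across
#' repeated experiments (each contributing one weight vector, observed or
#' corrected). Vectors shorter than the longest are padded with zeros:
#' orders beyond an experiment's maximum observed order occurred 0% of the
#' time.
#'
#' @param results list of `mixture_result` objects or of numeric weight
#'   vectors.
#' @param use when given `mixture_result`s, take `"weights"` (observed) or
#'   `"corrected"` fractions.
#' @return data.frame: `order`, `mean_pct`, `sd_pct` (SD 0 for one
#'   experiment).
#' @export
occurrence_summary <- function(results, use = c("weights", "corrected")) {
  use <- match.arg(use)
  stopifnot(length(results) >= 1)
  ws <- lapply(results, function(r) {
    v <- if (inherits(r, "mixture_result")) r[[use]] else r
    if (is.null(v)) stop("occurrence_summary: missing '", use, "' component")
    as.numeric(v)
  })
  kmax <- max(vapply(ws, length, integer(1)))
  m <- t(vapply(ws, function(v) c(v, rep(0, kmax - length(v))), numeric(kmax)))
  data.frame(order = seq_len(kmax),
             mean_pct = 100 * colMeans(m),
             sd_pct = if (nrow(m) > 1) 100 * apply(m, 2, sd) else rep(0, kmax))
}
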
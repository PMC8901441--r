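#' Simulate a field of diffraction-limited particles with known ground truth
#'
#' Places `n_particles` oligomers at random subpixel positions, draws the
#' oligomer order n from `nmer_weights`, the number of labeled protomers
#' j ~ Binomial(n, p), and the emitted brightness as the sum of j independent
#' monomer draws Normal(mu1, cv*mu1) truncated at zero. Each particle is
#' rendered as an isotropic 2D Gaussian sampled at pixel centers with total
#' volume equal to its brightness, on top of a uniform background. Poisson
#' shot noise and Gaussian read noise are then applied if enabled.
#'
#' Particles with j = 0 carry no dye and are invisible; they stay in the truth
#' table flagged `visible = FALSE` so that labeling-correction tests can
#' account for the unobservable class.
#'
#' @param config a [sim_config()].
#' @return list with `stack` (an [image_stack()] of one frame) and `truth`
#'   (data.frame: `particle`, `row`, `col` subpixel centers, `n` true order,
#'   `j` labeled count, `brightness` emitted counts, `visible`).
#'   A warning is raised when the particle density implies a mean
#'   nearest-neighbour distance below 4 PSF sigma (crowded field).
#' @export
generate_particle_field <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  nr <- config$field_size_px[1]; nc <- config$field_size_px[2]
  np <- config$n_particles
  sig <- config$psf_sigma_px

  dens <- np / (nr * nc)
  if (np > 1 && 0.5 / sqrt(dens) < 4 * sig)
    warning("generate_particle_field: particle density implies mean ",
            "nearest-neighbour distance < 4 PSF sigma; expect overlaps")

  m <- config$edge_margin_px
  if (nr - 2 * m <= 1 || nc - 2 * m <= 1)
    stop("generate_particle_field: edge margin leaves no room for particles")

  sep2 <- config$min_separation_px^2
  ctr <- cbind(runif(np, 1 + m, nr - m), runif(np, 1 + m, nc - m))
  if (np > 1 && sep2 > 0) {
    # sequential dart throwing: each center is redrawn until it clears all
    # previously accepted ones (hard-core process)
    crowded <- FALSE
    for (i in 2:np) {
      for (attempt in 1:1000) {
        d2 <- (ctr[1:(i - 1), 1] - ctr[i, 1])^2 +
          (ctr[1:(i - 1), 2] - ctr[i, 2])^2
        if (min(d2) >= sep2) break
        ctr[i, ] <- c(runif(1, 1 + m, nr - m), runif(1, 1 + m, nc - m))
      }
      if (attempt == 1000) crowded <- TRUE
    }
    if (crowded)
      warning("generate_particle_field: min_separation_px unachievable at ",
              "this density; some particles placed closer")
  }

  orders <- as.integer(names(config$nmer_weights))
  n_true <- if (np > 0)
    orders[sample.int(length(orders), np, replace = TRUE,
                      prob = config$nmer_weights)] else integer(0)
  j_lab <- rbinom(np, n_true, config$labeling_efficiency)
  mu1 <- config$monomer_intensity
  s1 <- config$monomer_cv * mu1
  brightness <- vapply(j_lab, function(j) {
    if (j == 0) return(0)
    sum(pmax(rnorm(j, mu1, s1), 0))
  }, numeric(1))

  img <- matrix(config$background_level, nr, nc)
  if (np > 0) {
    w <- ceiling(6 * sig)
    for (i in seq_len(np)) {
      if (brightness[i] <= 0) next
      r0 <- ctr[i, 1]; c0 <- ctr[i, 2]
      rs <- max(1L, floor(r0 - w)):min(nr, ceiling(r0 + w))
      cs <- max(1L, floor(c0 - w)):min(nc, ceiling(c0 + w))
      gr <- exp(-((rs - r0)^2) / (2 * sig^2))
      gc <- exp(-((cs - c0)^2) / (2 * sig^2))
      amp <- brightness[i] / (2 * pi * sig^2)
      img[rs, cs] <- img[rs, cs] + amp * outer(gr, gc)
    }
  }

  if (config$shot_noise)
    img <- matrix(rpois(length(img), img), nr, nc)
  if (config$read_noise_sd > 0)
    img <- pmax(img + matrix(rnorm(length(img), 0, config$read_noise_sd), nr, nc), 0)

  truth <- data.frame(
    particle = seq_len(np),
    row = if (np > 0) ctr[, 1] else numeric(0),
    col = if (np > 0) ctr[, 2] else numeric(0),
    n = n_true, j = j_lab, brightness = brightness,
    visible = j_lab > 0)

  list(stack = image_stack(img, pixel_size_nm = config$pixel_size_nm),
       truth = truth)
}
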
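#' Simulation configuration for synthetic particle fields
#'
#' Bundles the acquisition and sample parameters of the single-molecule
#' simulator. Defaults emulate the TIRF regime used for in vitro brightness
#' stoichiometry: 100 nm pixels, a diffraction-limited PSF of about 1.3 px
#' standard deviation, and partial fluorophore labeling in the 75-84% range
#' typical of maleimide dye coupling to single-cysteine protein.
#'
#' @param field_size_px integer pair, image size (rows, cols).
#' @param pixel_size_nm pixel size in nm.
#' @param psf_sigma_px PSF standard deviation in pixels (isotropic 2D Gaussian).
#' @param monomer_intensity mean integrated brightness of one labeled
#'   fluorophore, in counts (the monomer unit mu1).
#' @param monomer_cv coefficient of variation of single-fluorophore brightness
#'   (sigma1/mu1). The emitter-to-emitter variance of single fluorophores is a
#'   free parameter of the simulator.
#' @param background_level uniform background, counts/pixel.
#' @param read_noise_sd additive Gaussian read noise, counts.
#' @param labeling_efficiency probability p in (0, 1] that a protomer carries a
#'   functional fluorophore.
#' @param nmer_weights named numeric vector mapping oligomer order n (names)
#'   to probability; must sum to 1.
#' @param n_particles number of particles to place.
#' @param seed integer seed; every random draw in the generator flows from it.
#' @param shot_noise logical; apply Poisson shot noise to the expected image.
#'   Disable together with `read_noise_sd = 0` for noiseless oracle images.
#' @param min_separation_px optional minimum center-to-center distance enforced
#'   by rejection sampling (0 = none).
#' @param edge_margin_px margin kept free of particle centers; the default
#'   (6 sigma, rounded up) keeps essentially the whole PSF volume inside the
#'   field so photon-conservation checks hold to float precision.
#'
#' @return list of class `sim_config`.
#' @export
sim_config <- function(field_size_px = c(150L, 150L),
                       pixel_size_nm = 100,
                       psf_sigma_px = 1.3,
                       monomer_intensity = 500,
                       monomer_cv = 0.15,
                       background_level = 100,
                       read_noise_sd = 5,
                       labeling_efficiency = 0.84,
                       nmer_weights = c("1" = 1),
                       n_particles = 100L,
                       seed = 1L,
                       shot_noise = TRUE,
                       min_separation_px = 0,
                       edge_margin_px = NULL) {
  if (is.null(edge_margin_px)) edge_margin_px <- ceiling(6 * psf_sigma_px)
  cfg <- structure(
    list(field_size_px = as.integer(field_size_px),
         pixel_size_nm = pixel_size_nm, psf_sigma_px = psf_sigma_px,
         monomer_intensity = monomer_intensity, monomer_cv = monomer_cv,
         background_level = background_level, read_noise_sd = read_noise_sd,
         labeling_efficiency = labeling_efficiency,
         nmer_weights = nmer_weights, n_particles = as.integer(n_particles),
         seed = as.integer(seed), shot_noise = isTRUE(shot_noise),
         min_separation_px = min_separation_px,
         edge_margin_px = edge_margin_px),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$field_size_px) == 2L, all(cfg$field_size_px >= 8L))
  if (abs(sum(cfg$nmer_weights) - 1) > 1e-9)
    stop("sim_config: nmer_weights must sum to 1")
  if (any(cfg$nmer_weights < 0)) stop("sim_config: negative nmer_weights")
  if (is.null(names(cfg$nmer_weights)) ||
      anyNA(suppressWarnings(as.integer(names(cfg$nmer_weights)))))
    stop("sim_config: nmer_weights must be named by integer oligomer order")
  p <- cfg$labeling_efficiency
  if (!(p > 0 && p <= 1)) stop("sim_config: labeling_efficiency must be in (0, 1]")
  if (cfg$monomer_intensity < 0 || cfg$background_level < 0 ||
      cfg$read_noise_sd < 0 || cfg$monomer_cv < 0)
    stop("sim_config: intensities and noise levels must be >= 0")
  if (cfg$psf_sigma_px <= 0) stop("sim_config: psf_sigma_px must be > 0")
  if (cfg$n_particles < 0) stop("sim_config: n_particles must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> %dx%d px @ %.0f nm/px | PSF sigma %.2f px\n",
    "  mu1 = %.1f counts (CV %.2f), bg %.1f, read noise %.1f\n",
    "  labeling p = %.2f, %d particles, orders {%s}, seed %d\n"),
    x$field_size_px[1], x$field_size_px[2], x$pixel_size_nm, x$psf_sigma_px,
    x$monomer_intensity, x$monomer_cv, x$background_level, x$read_noise_sd,
    x$labeling_efficiency, x$n_particles,
    paste(names(x$nmer_weights), collapse = ","), x$seed))
  invisible(x)
}

#' Write / read a simulation configuration as a flat key-value file
#'
#' @param cfg a [sim_config()].
#' @param path file path (YAML).
#' @return `read_sim_config` returns a validated [sim_config()].
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  lst <- unclass(cfg)
  lst$nmer_weights <- as.list(cfg$nmer_weights)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$nmer_weights <- unlist(lst$nmer_weights)
  do.call(sim_config, lst)
}
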
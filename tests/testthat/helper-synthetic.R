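# shared fixtures, all generated in code

# render one sampled 2D Gaussian + flat background on an empty frame
render_spot <- function(nr = 21, nc = 21, A = 500, r0 = 11, c0 = 11,
                        sigma = 1.3, b = 100) {
  rr <- outer(seq_len(nr) - r0, rep(1, nc))
  cc <- outer(rep(1, nr), seq_len(nc) - c0)
  b + A * exp(-(rr^2 + cc^2) / (2 * sigma^2))
}

# field configuration at a given peak signal-to-noise ratio
snr_field_config <- function(snr, n_particles, field = c(200L, 200L),
                             background = 100, read_noise = 5,
                             sigma = 1.3, seed = 1L) {
  noise_sd <- sqrt(background + read_noise^2)
  brightness <- snr * noise_sd * 2 * pi * sigma^2
  sim_config(field_size_px = field, psf_sigma_px = sigma,
             monomer_intensity = brightness, monomer_cv = 0.05,
             background_level = background, read_noise_sd = read_noise,
             labeling_efficiency = 1, nmer_weights = c("1" = 1),
             n_particles = n_particles, min_separation_px = 4 * sigma,
             seed = seed)
}

# greedy matching of detections to ground-truth centers within a radius
match_detections <- function(cand, truth, radius = 2) {
  if (nrow(cand) == 0 || nrow(truth) == 0)
    return(list(precision = NA_real_, recall = NA_real_))
  d2 <- outer(cand$row, truth$row, "-")^2 + outer(cand$col, truth$col, "-")^2
  list(precision = mean(apply(d2, 1, min) <= radius^2),
       recall = mean(apply(d2, 2, min) <= radius^2))
}

# random point on the simplex of dimension k (fixed RNG stream of the caller)
random_simplex <- function(k) {
  x <- rexp(k)
  x / sum(x)
}

total_variation <- function(a, b) 0.5 * sum(abs(a - b))
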
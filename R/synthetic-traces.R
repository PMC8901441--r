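#' Simulate stepwise photobleaching traces
#'
#' Each trace carries `j_fluors` fluorophores with fixed individual
#' brightnesses Normal(mu1, cv*mu1); every fluorophore bleaches irreversibly
#' and independently with probability `bleach_prob_per_frame` per frame
#' (geometric bleaching times), so the noiseless trace is a staircase that
#' decreases by one monomer unit per bleaching event and ends at baseline.
#' Gaussian noise of SD `noise_sd` is added per frame. Blinking is not
#' modeled: at the tens-of-millisecond exposures these traces emulate,
#' step counting is insensitive to it.
#'
#' @param j_fluors number of fluorophores per trace (>= 1).
#' @param n_traces number of traces.
#' @param bleach_prob_per_frame per-frame, per-fluorophore bleach probability.
#' @param frames trace length in frames (>= 10).
#' @param noise_sd additive Gaussian noise SD, counts.
#' @param seed integer seed.
#' @param monomer_intensity mean single-fluorophore brightness (mu1), counts.
#' @param monomer_cv brightness CV across fluorophores.
#' @param baseline constant offset (local background), counts.
#'
#' @return list with `traces` (matrix n_traces x frames) and `truth`
#'   (data.frame: `trace`, `j` fluorophore count, `n_steps` distinct bleaching
#'   epochs actually present, `start_level` noiseless initial intensity,
#'   `bleach_frames` comma-joined frame indices of the bleaching events).
#' @export
generate_bleach_traces <- function(j_fluors, n_traces, bleach_prob_per_frame,
                                   frames, noise_sd, seed = 1L,
                                   monomer_intensity = 100, monomer_cv = 0.1,
                                   baseline = 0) {
  stopifnot(j_fluors >= 1, frames >= 10, n_traces >= 1,
            bleach_prob_per_frame > 0, bleach_prob_per_frame <= 1)
  set.seed(as.integer(seed))
  mu1 <- monomer_intensity
  s1 <- monomer_cv * mu1
  traces <- matrix(0, n_traces, frames)
  truth <- data.frame(trace = seq_len(n_traces), j = j_fluors,
                      n_steps = 0L, start_level = 0,
                      bleach_frames = "", stringsAsFactors = FALSE)
  fr <- seq_len(frames)
  for (i in seq_len(n_traces)) {
    u <- pmax(rnorm(j_fluors, mu1, s1), 0)
    # rgeom counts pre-bleach frames: fluorophore k is emissive in frames 1..g_k
    g <- rgeom(j_fluors, bleach_prob_per_frame)
    clean <- baseline + vapply(fr, function(f) sum(u[g >= f]), numeric(1))
    traces[i, ] <- clean + rnorm(frames, 0, noise_sd)
    # a visible step needs the fluorophore alive at frame 1 and dead before the end
    truth$n_steps[i] <- length(unique(g[g >= 1 & g < frames]))
    truth$start_level[i] <- clean[1]
    truth$bleach_frames[i] <- paste(sort(unique(g[g >= 1 & g < frames])),
                                    collapse = ",")
  }
  list(traces = traces, truth = truth)
}
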
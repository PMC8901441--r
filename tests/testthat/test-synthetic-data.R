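test_that("empty particle field is pure background with an empty truth table", {
  cfg <- sim_config(n_particles = 0L, shot_noise = FALSE, read_noise_sd = 0)
  f <- generate_particle_field(cfg)
  expect_equal(nrow(f$truth), 0)
  expect_true(all(f$stack$data == cfg$background_level))
})

test_that("fully labeled noiseless monomers each carry exactly mu1 counts", {
  cfg <- sim_config(n_particles = 25L, monomer_cv = 0, monomer_intensity = 700,
                    labeling_efficiency = 1, shot_noise = FALSE,
                    read_noise_sd = 0, min_separation_px = 12, seed = 4L)
  f <- generate_particle_field(cfg)
  expect_true(all(abs(f$truth$brightness - 700) < 1e-9))
  img <- get_frame(f$stack, 1) - cfg$background_level
  # integrated signal in a generous window around each center equals mu1
  for (i in seq_len(nrow(f$truth))) {
    r <- round(f$truth$row[i]); c <- round(f$truth$col[i])
    s <- sum(img[(r - 6):(r + 6), (c - 6):(c + 6)])
    expect_lt(abs(s - 700) / 700, 1e-4)
  }
})

test_that("binomial labeling of dimers matches the binomial pmf", {
  cfg <- sim_config(field_size_px = c(400L, 400L), n_particles = 10000L,
                    labeling_efficiency = 0.8, nmer_weights = c("2" = 1),
                    shot_noise = FALSE, read_noise_sd = 0, seed = 11L)
  f <- suppressWarnings(generate_particle_field(cfg))
  emp <- table(factor(f$truth$j, levels = 0:2)) / nrow(f$truth)
  expect_equal(as.numeric(emp), c(0.04, 0.32, 0.64), tolerance = 0.05)
  chi <- chisq.test(table(factor(f$truth$j, levels = 0:2)),
                    p = dbinom(0:2, 2, 0.8))
  expect_gt(chi$p.value, 0.01)
})

test_that("noiseless images conserve emitted photons", {
  cfg <- sim_config(n_particles = 40L, nmer_weights = c("1" = 0.5, "3" = 0.5),
                    shot_noise = FALSE, read_noise_sd = 0, seed = 8L)
  f <- generate_particle_field(cfg)
  emitted <- sum(f$stack$data) - prod(cfg$field_size_px) * cfg$background_level
  expect_lt(abs(emitted - sum(f$truth$brightness)) /
              max(sum(f$truth$brightness), 1), 1e-6)
})

test_that("identical configuration and seed reproduce the truth table bit for bit", {
  cfg <- sim_config(n_particles = 50L, seed = 123L)
  f1 <- generate_particle_field(cfg)
  f2 <- generate_particle_field(cfg)
  expect_identical(f1$truth, f2$truth)
  expect_identical(f1$stack$data, f2$stack$data)
})

test_that("crowded fields trigger a density warning", {
  cfg <- sim_config(field_size_px = c(64L, 64L), n_particles = 300L,
                    edge_margin_px = 4, seed = 1L)
  expect_warning(generate_particle_field(cfg), "nearest-neighbour")
})

test_that("bleach traces are staircases with the recorded truth", {
  # single fluorophore, no noise: one downward step to baseline
  tr <- generate_bleach_traces(1, 5, 0.05, 60, 0, seed = 2L, monomer_cv = 0)
  for (i in 1:5) {
    x <- tr$traces[i, ]
    lev <- unique(x)
    expect_lte(length(lev), 2)
    expect_equal(x[length(x)], 0)
    expect_true(all(diff(x) <= 0))
  }
  # three fluorophores start near 3*mu1 and end at baseline
  tr3 <- generate_bleach_traces(3, 20, 0.02, 200, 0, seed = 3L,
                                monomer_intensity = 100, monomer_cv = 0.1)
  full <- tr3$truth$n_steps == 3   # all three fluorophores alive at frame 1
  expect_true(any(full))
  expect_true(all(abs(tr3$truth$start_level[full] - 300) < 5 * sqrt(3) * 10))
  expect_true(all(tr3$traces[full, 200] == 0))
  # certain bleaching: everything gone from the first frame
  tr1 <- generate_bleach_traces(2, 5, 1, 20, 0, seed = 4L)
  expect_true(all(tr1$traces == 0))
  expect_true(all(tr1$truth$n_steps == 0))
})

test_that("standard cells reproduce the configured stoichiometry scale", {
  # zero spread: every complex at exactly Ms * unit
  cells0 <- generate_standard_cells(32, 5, 50, 100, cv = 0, seed = 1L)
  expect_true(all(unlist(cells0) == 3200))
  # law of large numbers at cv = 0.1
  cells <- generate_standard_cells(32, 5, 500, 100, cv = 0.1, seed = 2L)
  sems <- vapply(cells, function(x) sd(x) / sqrt(length(x)), numeric(1))
  for (k in 1:5) expect_lt(abs(mean(cells[[k]]) - 3200), 3 * sems[k])
  # 24-mer versus 32-mer at the same unit intensity: mean ratio 0.75
  c24 <- generate_standard_cells(24, 5, 2000, 100, cv = 0.1, seed = 3L)
  ratio <- mean(unlist(c24)) / mean(unlist(cells))
  expect_equal(ratio, 0.75, tolerance = 0.02)
})

test_that("foci time series follow the configured kinetics", {
  sat <- kinetic_model("saturating", plateau = 200, rate = 80, noise_cv = 0.1)
  ser <- generate_foci_timeseries(sat, seq(0, 60, 5), 4e6, seed = 5L)
  expect_equal(length(ser$molecularity[[1]]), 0)     # nothing at MOMP itself
  expect_true(!is.unsorted(ser$truth_mean))          # non-decreasing mean
  expect_true(all(ser$truth_mean <= 200 + 1e-9))
  late <- unlist(ser$molecularity[ser$timepoints >= 20])
  expect_equal(mean(late), 200, tolerance = 3 * sat$noise_cv)
  lin <- kinetic_model("linear", rate = 10, noise_cv = 0.1,
                       foci_birth_rate = 2e-6)
  ser2 <- generate_foci_timeseries(lin, seq(0, 60, 5), 4e6, seed = 6L)
  m60 <- ser2$molecularity[[13]]
  expect_equal(mean(m60), 600, tolerance = 0.35)
  expect_true(!is.unsorted(ser2$truth_mean))
  expect_true(ser2$foci_count[13] > ser2$foci_count[2])
  expect_error(generate_foci_timeseries(lin, numeric(0), 4e6), "empty")
})
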
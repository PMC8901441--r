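test_that("max projection picks per-pixel maxima with lowest-plane tie-break", {
  # constant stack: ties resolve to plane 1
  const <- image_stack(array(7, c(5, 5, 3)))
  pr <- max_z_project(const)
  expect_true(all(pr$image == 7))
  expect_true(all(pr$argmax == 1L))
  # one bright plane wins everywhere
  arr <- array(1, c(5, 5, 4)); arr[, , 3] <- 9
  pr2 <- max_z_project(image_stack(arr))
  expect_true(all(pr2$image == 9) && all(pr2$argmax == 3L))
  # random stack: elementwise >= every plane (brute-force oracle)
  set.seed(1)
  arr3 <- array(runif(5 * 4 * 6), c(5, 4, 6))
  pr3 <- max_z_project(image_stack(arr3))
  expect_equal(pr3$image, apply(arr3, c(1, 2), max))
  for (k in 1:6) expect_true(all(pr3$image >= arr3[, , k]))
  # single plane: identity with warning
  expect_warning(max_z_project(image_stack(matrix(1, 4, 4))), "single-plane")
})

test_that("DoG detection finds isolated spots and nothing in blank noise", {
  set.seed(42)
  blank <- matrix(100 + rnorm(150 * 150, 0, 10), 150, 150)
  cand <- detect_spots(blank, threshold_sd = 5)
  expect_equal(nrow(cand), 0)

  one <- blank + render_spot(150, 150, A = 100, r0 = 70, c0 = 80, b = 0)
  c1 <- detect_spots(one)
  expect_equal(nrow(c1), 1)
  expect_lt(sqrt((c1$row - 70)^2 + (c1$col - 80)^2), 1.5)

  two <- one + render_spot(150, 150, A = 100, r0 = 70, c0 = 90, b = 0)
  c2 <- detect_spots(two)
  expect_equal(nrow(c2), 2)
})

test_that("2D Gaussian fit recovers noiseless parameters and the volume identity", {
  img <- render_spot(21, 21, A = 500, r0 = 11.3, c0 = 10.6, sigma = 1.3, b = 100)
  ft <- fit_particle(img, c(11, 11))
  expect_equal(ft$qc_flags, "")
  expect_equal(ft$amplitude, 500, tolerance = 0.01)
  expect_equal(ft$sigma, 1.3, tolerance = 0.01)
  expect_equal(ft$row, 11.3, tolerance = 0.01)
  expect_equal(ft$col, 10.6, tolerance = 0.01)
  expect_equal(ft$brightness, 2 * pi * 500 * 1.3^2, tolerance = 0.02)
  # model-free oracle: background-subtracted pixel sum over the full PSF
  ps <- sum(img - 100)
  expect_equal(ft$brightness, ps, tolerance = 0.05)
})

test_that("flat images fit to zero brightness", {
  ft <- fit_particle(matrix(100, 15, 15), c(8, 8))
  expect_lt(abs(ft$brightness), 1)
  expect_lt(abs(ft$amplitude), 1)
})

test_that("fits near the border are flagged fit_fail", {
  img <- render_spot(15, 15, r0 = 2, c0 = 2)
  ft <- fit_particle(img, c(2, 2))
  expect_match(ft$qc_flags, "fit_fail")
})

test_that("sigma filter retains about 95% and overlap/edge rules flag as specified", {
  set.seed(7)
  n <- 10000
  fits <- data.frame(row = runif(n, 10, 990), col = runif(n, 10, 990),
                     sigma = rnorm(n, 1.3, 0.15), amplitude = 50,
                     background = 100, brightness = 500, residual = 1,
                     qc_flags = "", stringsAsFactors = FALSE)
  flt <- filter_particles(fits, min_center_separation_px = 0.001)
  kept <- mean(!flt$report$sigma_outlier)
  expect_equal(kept, 0.95, tolerance = 0.005)

  # close pair: both flagged overlap
  pair <- fits[1:2, ]; pair$row <- c(50, 51.5); pair$col <- c(50, 50.5)
  fp <- suppressWarnings(filter_particles(pair, min_center_separation_px = 7))
  expect_true(all(fp$report$overlap))
  expect_equal(nrow(fp$retained), 0)

  # z-stack particle brightest in an outer plane is discarded
  zf <- fits[1:30, ]
  zf$argmax_frame <- c(1L, 8L, rep(4L, 28))
  fz <- filter_particles(zf, min_center_separation_px = 0.001, n_planes = 8)
  expect_true(all(fz$report$edge_frame[1:2]))
  expect_false(any(fz$report$edge_frame[3:30]))

  # small samples skip the width rule with a warning
  expect_warning(filter_particles(fits[1:10, ], min_center_separation_px = 0.001),
                 "sigma filter skipped")
})

test_that("filtering is idempotent given its width cut and order-independent", {
  set.seed(8)
  n <- 500
  fits <- data.frame(row = runif(n, 10, 490), col = runif(n, 10, 490),
                     sigma = rnorm(n, 1.3, 0.15), amplitude = 50,
                     background = 100, brightness = 500, residual = 1,
                     qc_flags = "", stringsAsFactors = FALSE)
  f1 <- filter_particles(fits)
  f2 <- suppressWarnings(
    filter_particles(f1$retained, sigma_cut = f1$sigma_cut))
  expect_equal(f1$retained, f2$retained, ignore_attr = TRUE)
  # shuffling the input changes nothing about the retained set
  perm <- sample(n)
  f3 <- filter_particles(fits[perm, ])
  expect_equal(sort(rownames(f1$retained)), sort(rownames(fits[perm, ][f3$report$retained, ])),
               ignore_attr = TRUE)
  expect_setequal(f3$retained$row, f1$retained$row)
})

test_that("fitted brightness is linear in true brightness", {
  base <- snr_field_config(20, 80, seed = 21L)
  cfg1 <- base; cfg1$shot_noise <- FALSE; cfg1$read_noise_sd <- 0
  cfg2 <- cfg1; cfg2$monomer_intensity <- 2 * cfg1$monomer_intensity
  med_ip <- function(cfg) {
    f <- generate_particle_field(cfg)
    img <- get_frame(f$stack, 1)
    fits <- fit_particles(img, detect_spots(img))
    median(filter_particles(fits)$retained$brightness)
  }
  expect_equal(med_ip(cfg2) / med_ip(cfg1), 2, tolerance = 0.02)
})

test_that("end-to-end brightness error stays within the noise-dependent bounds", {
  run_field <- function(cfg) {
    f <- generate_particle_field(cfg)
    img <- get_frame(f$stack, 1)
    fits <- fit_particles(img, detect_spots(img))
    ret <- filter_particles(fits)$retained
    tru <- f$truth
    d2 <- outer(ret$row, tru$row, "-")^2 + outer(ret$col, tru$col, "-")^2
    idx <- apply(d2, 1, which.min)
    ok <- sqrt(d2[cbind(seq_len(nrow(ret)), idx)]) <= 2
    abs(ret$brightness[ok] - tru$brightness[idx[ok]]) / tru$brightness[idx[ok]]
  }
  noiseless <- snr_field_config(10, 60, seed = 31L)
  noiseless$shot_noise <- FALSE; noiseless$read_noise_sd <- 0
  expect_lt(median(run_field(noiseless)), 0.05)
  expect_lt(median(run_field(snr_field_config(5, 60, seed = 32L))), 0.15)
})
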
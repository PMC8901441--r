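test_that("step counting handles clean, constant and re-brightening traces", {
  # noiseless single step
  x <- c(rep(100, 30), rep(0, 30))
  st <- count_bleach_steps(x)
  expect_equal(st$n_steps, 1)
  expect_equal(st$levels, c(100, 0), tolerance = 1e-6)
  expect_false(st$rejected)
  # constant trace: no steps, not a monomer candidate
  st0 <- count_bleach_steps(rep(50, 60))
  expect_equal(st0$n_steps, 0)
  # re-brightening marks the trace as rejected
  up <- c(rep(100, 20), rep(0, 20), rep(100, 20))
  expect_true(count_bleach_steps(up)$rejected)
})

test_that("three-step traces are counted correctly in at least 95% of cases", {
  tr <- generate_bleach_traces(3, 700, 0.004, 1000, 10, seed = 42L,
                               monomer_intensity = 100, monomer_cv = 0.1)
  # condition on ground-truth resolvability: three distinct bleaching events
  # separated by at least 15 frames (the counter's documented resolution)
  resolvable <- vapply(seq_len(nrow(tr$traces)), function(i) {
    if (tr$truth$n_steps[i] != 3) return(FALSE)
    g <- as.numeric(strsplit(tr$truth$bleach_frames[i], ",")[[1]])
    all(diff(c(0, g)) >= 15) && (1000 - max(g)) >= 15
  }, logical(1))
  sel <- head(which(resolvable), 200)
  expect_gte(length(sel), 200)
  detected <- vapply(sel, function(i)
    count_bleach_steps(tr$traces[i, ])$n_steps, numeric(1))
  expect_gte(mean(detected == 3), 0.95)
})

test_that("monomer calibration recovers mu1 and selects only single-step traces", {
  tr <- generate_bleach_traces(1, 300, 0.02, 200, 8, seed = 7L,
                               monomer_intensity = 100, monomer_cv = 0.15)
  cal <- calibrate_monomer(tr$traces)
  sem <- cal$sigma1 / sqrt(cal$n_used)
  expect_lt(abs(cal$mu1 - 100), 3 * sem + 2)
  expect_equal(cal$sigma1, 15, tolerance = 0.25)

  # identical plateau heights: mu1 = h, sigma1 = 0
  flat <- t(replicate(60, c(rep(80, 50), rep(0, 50))))
  cal0 <- calibrate_monomer(flat, min_traces = 50)
  expect_equal(cal0$mu1, 80, tolerance = 1e-6)
  expect_equal(cal0$sigma1, 0, tolerance = 1e-6)

  # two-step traces never enter the monomer pool
  tr2 <- generate_bleach_traces(2, 150, 0.01, 300, 5, seed = 8L,
                                monomer_intensity = 100, monomer_cv = 0.1)
  mix <- rbind(tr$traces[1:120, 1:200], tr2$traces[, 1:200])
  calm <- calibrate_monomer(mix)
  expect_lt(abs(calm$mu1 - 100), 15)   # near mu1, not 2*mu1

  expect_error(calibrate_monomer(tr$traces[1:20, ]), "single-step")
})

test_that("mixture fit recovers known compositions with calibrated components", {
  calib <- list(mu1 = 100, sigma1 = 10)
  set.seed(5)
  mono <- rnorm(2000, 100, 10)
  m1 <- fit_gaussian_mixture(mono, calib, max_n = 6)
  expect_gt(m1$weights[1], 0.95)

  dimer_tetramer <- c(rnorm(2000, 200, sqrt(2) * 10),
                      rnorm(2000, 400, 2 * 10))
  m2 <- fit_gaussian_mixture(dimer_tetramer, calib, max_n = 10)
  expect_equal(unname(m2$weights[2]), 0.5, tolerance = 0.1)
  expect_equal(unname(m2$weights[4]), 0.5, tolerance = 0.1)
  expect_true(all(m2$weights[-c(2, 4)] < 0.03))

  # dimer-dominated versus high-order samples separate by mean fitted order
  bak_like <- c(rnorm(1500, 200, sqrt(2) * 10), rnorm(500, 100, 10))
  bax_like <- as.vector(vapply(1:10, function(j) rnorm(200, j * 100, sqrt(j) * 10),
                               numeric(200)))
  wb <- fit_gaussian_mixture(bak_like, calib)$weights
  wx <- fit_gaussian_mixture(bax_like, calib)$weights
  mean_order <- function(w) sum(seq_along(w) * w)
  expect_lt(mean_order(wb), 2.5)
  expect_gt(mean_order(wx), 4)
})

test_that("fitted mean brightness matches the sample mean within 2%", {
  calib <- list(mu1 = 100, sigma1 = 12)
  set.seed(6)
  x <- c(rnorm(1500, 100, 12), rnorm(1500, 300, sqrt(3) * 12),
         rnorm(1000, 500, sqrt(5) * 12))
  w <- fit_gaussian_mixture(x, calib)$weights
  expect_equal(sum(seq_along(w) * w * 100), mean(x), tolerance = 0.02)
})

test_that("weights are invariant under joint intensity rescaling", {
  calib <- list(mu1 = 100, sigma1 = 10)
  set.seed(9)
  x <- c(rnorm(1000, 100, 10), rnorm(1000, 300, sqrt(3) * 10))
  w1 <- fit_gaussian_mixture(x, calib)$weights
  w2 <- fit_gaussian_mixture(3.7 * x, list(mu1 = 370, sigma1 = 37))$weights
  expect_equal(w1, w2, tolerance = 1e-6)
})

test_that("labeling correction inverts the binomial mixing operator", {
  # identity at full labeling
  w <- c(0.2, 0.5, 0.3, 0, 0, 0)
  expect_equal(unname(correct_labeling(w, 1)), w, tolerance = 1e-10)

  # pure dimers at p = 0.8: visible classes are 1/3 and 2/3
  wd <- project_labeling(c(0, 1, 0, 0, 0, 0), 0.8)
  expect_equal(wd[1:2], c(1, 2) / 3, tolerance = 1e-12)
  vd <- correct_labeling(wd, 0.8)
  expect_gt(vd[2], 0.99)

  # tetramers at the 84% efficiency used for BAX
  wt <- project_labeling(c(0, 0, 0, 1, 0, 0), 0.84)
  expect_gte(correct_labeling(wt, 0.84)[4], 0.9)

  # explicit pseudo-inverse residual check
  B <- labeling_matrix(6, 0.8)
  set.seed(10)
  v <- random_simplex(6)
  w_fwd <- as.vector(B %*% v); w_fwd <- w_fwd / sum(w_fwd)
  v_rec <- correct_labeling(w_fwd, 0.8)
  expect_lt(sqrt(sum((B %*% v_rec / sum(B %*% v_rec) - w_fwd)^2)), 1e-8)

  expect_error(correct_labeling(w, 0), "p must be")
  expect_error(correct_labeling(w, 1.2), "p must be")
  expect_warning(correct_labeling(w, 0.6), "75%")
})

test_that("round-trip identifiability holds across the simplex for p >= 0.8", {
  set.seed(11)
  for (p in c(0.8, 0.84, 1.0)) {
    for (rep in 1:20) {
      v <- random_simplex(6)
      w <- project_labeling(v, p)
      v_rec <- correct_labeling(w, p)
      expect_lt(total_variation(v, v_rec), 0.05)
    }
  }
})

test_that("occurrence summaries average experiments in percent", {
  one <- occurrence_summary(list(c(0.4, 0.6)))
  expect_equal(one$sd_pct, c(0, 0))
  two <- occurrence_summary(list(c(0.4, 0.6), c(0.3, 0.7)))
  expect_equal(two$mean_pct, c(35, 65))
  expect_equal(two$sd_pct[2], 7.07, tolerance = 0.01)
  # orders beyond an experiment's maximum are 0%
  padded <- occurrence_summary(list(c(1), c(0.5, 0.5)))
  expect_equal(padded$mean_pct, c(75, 25))
})
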
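test_that("SNR masking keeps tissue, drops flat pixels, and is monotone", {
  sim <- vm_movie(rows = 10, cols = 10, noise_sd = 0.04, tissue_margin = 2,
                  seed = 8)
  w <- segment_beats(sim$movie)
  mask <- mask_pixels(sim$movie, snr_threshold = 3, windows = w)
  expect_true(all(mask[sim$truth$mask]))
  expect_false(any(mask[!sim$truth$mask]))
  # raising the threshold never adds pixels
  m5 <- mask_pixels(sim$movie, snr_threshold = 5, windows = w)
  expect_true(all(!m5 | mask))
  expect_error(mask_pixels(sim$movie, snr_threshold = Inf, windows = w),
               "threshold")
  # noiseless movie: every tissue pixel valid
  sim0 <- vm_movie(rows = 8, cols = 8, tissue_margin = 1)
  m0 <- mask_pixels(sim0$movie, windows = segment_beats(sim0$movie))
  expect_true(all(m0[sim0$truth$mask]))
})

test_that("baseline removal strips drift without touching beat morphology", {
  # pure linear drift, no beats: residual fluctuation tiny vs drift range
  d <- array(0, c(500, 3, 3))
  t <- (0:499) * 2
  for (f in 1:500) d[f, , ] <- 1000 + 0.5 * t[f]
  mv <- mapping_movie(d, 2, 0.1, stimulus_times = c(100, 400, 700),
                      cycle_length = 300)
  out <- remove_baseline(mv)
  rng <- diff(range(d))
  expect_lt(diff(range(out$data)), 1e-6 * rng)
  # zero drift: identity up to machine tolerance
  sim <- vm_movie(rows = 6, cols = 6)
  out2 <- remove_baseline(sim$movie)
  expect_equal(out2$data, sim$movie$data, tolerance = 1e-9)
  # exp+linear bleach on a real movie: APD recovery within 2 ms of truth
  simb <- vm_movie(rows = 10, cols = 10, noise_sd = 0,
                   bleach = list(b1 = -0.08, b2 = 150, tau = 1500))
  s <- analyze_vm(simb$movie, baseline_method = "exp_linear")$summary
  expect_lt(abs(s$apd30_mean - 134), 2)
  expect_lt(abs(s$apd80_mean - 220), 2)
})

test_that("masked spatial filtering conserves mass and respects the mask", {
  sim <- vm_movie(rows = 8, cols = 8, n_beats = 2)
  expect_identical(spatial_filter(sim$movie, 1)$data, sim$movie$data)
  expect_error(spatial_filter(sim$movie, 4), "odd")
  # uniform frame unchanged
  d <- array(5, c(3, 6, 6))
  mv <- mapping_movie(d, 2, 0.1)
  expect_equal(spatial_filter(mv, 3)$data, d, tolerance = 1e-12)
  # checkerboard moves toward the mean; direct convolution oracle agrees
  chk <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
  d2 <- array(rep(chk, each = 2), c(2, 6, 6))
  mv2 <- mapping_movie(d2, 2, 0.1)
  sm <- spatial_filter(mv2, 3)
  k1 <- exp(-(-1:1)^2 / (2 * 1^2)); kern <- outer(k1, k1)
  oracle <- matrix(0, 6, 6)
  for (r in 1:6) for (cc in 1:6) {
    acc <- 0; wsum <- 0
    for (dr in -1:1) for (dc in -1:1) {
      r2 <- r + dr; c2 <- cc + dc
      if (r2 >= 1 && r2 <= 6 && c2 >= 1 && c2 <= 6) {
        wgt <- kern[dr + 2, dc + 2]
        acc <- acc + wgt * chk[r2, c2]; wsum <- wsum + wgt
      }
    }
    oracle[r, cc] <- acc / wsum
  }
  expect_equal(sm$data[1, , ], oracle, tolerance = 1e-12)
  # invalid pixels never leak in
  mask <- matrix(TRUE, 6, 6); mask[3, 3] <- FALSE
  d3 <- d2; d3[, 3, 3] <- 1e6
  sm3 <- spatial_filter(mapping_movie(d3, 2, 0.1), 3, mask = mask)
  expect_lt(max(sm3$data[, 2, 2]), 2)
})

test_that("beat segmentation windows are disjoint and bounded by the cycle", {
  sim <- vm_movie(rows = 4, cols = 4, n_beats = 3, cycle_length = 1000)
  w <- segment_beats(sim$movie)
  expect_equal(nrow(w), 2)   # first beat discarded
  w3 <- segment_beats(sim$movie, discard_first = FALSE)
  expect_equal(nrow(w3), 3)
  expect_true(all(w3$end - w3$start <= 1000))
  expect_true(all(diff(w3$start) >= (w3$end - w3$start)[-3]))
  sim7 <- vm_movie(rows = 4, cols = 4, cycle_length = 700, n_beats = 3,
                   apd30 = 100, apd80 = 160)
  w7 <- segment_beats(sim7$movie)
  expect_true(all(w7$end - w7$start <= 700))
  mv <- sim$movie; mv$stimulus_times <- numeric(0)
  expect_error(segment_beats(mv), "stimulus")
})

test_that("per-beat normalization pins diastole to 0 and peak to 1", {
  sim <- vm_movie(rows = 6, cols = 6)
  w <- segment_beats(sim$movie)
  nb <- normalize_beats(sim$movie, w, sim$truth$mask)
  for (b in nb$beats) {
    expect_equal(max(b$Y[, 15]), 1)
    pre <- b$t < 0
    expect_equal(mean(b$Y[pre, 15]), 0, tolerance = 1e-12)
  }
  # scale invariance: amplitude-rescaled raw signal, identical normalization
  mv2 <- sim$movie
  mv2$data <- mv2$data * 3.7 + 250
  nb2 <- normalize_beats(mv2, w, sim$truth$mask)
  expect_equal(nb2$beats[[1]]$Y, nb$beats[[1]]$Y, tolerance = 1e-9)
  # idempotence: renormalizing a normalized beat changes nothing
  b <- nb$beats[[1]]
  yn <- b$Y[, 20]
  pre <- b$t < 0
  y2 <- (yn - mean(yn[pre])) / max(yn - mean(yn[pre]))
  expect_equal(y2, yn, tolerance = 1e-9)
})

test_that("noisy normalized diastole stays centered near zero", {
  sim <- vm_movie(rows = 8, cols = 8, noise_sd = 0.05, seed = 12)
  w <- segment_beats(sim$movie)
  nb <- normalize_beats(remove_baseline(sim$movie), w, sim$truth$mask)
  dia <- unlist(lapply(nb$beats, function(b) colMeans(b$Y[b$t < 0, ])))
  expect_lt(max(abs(dia)), 0.02)
})

test_that("spontaneous beats are detected at the simulated period", {
  cfg <- sim_config(ap_template(134, 220), rows = 8, cols = 8,
                    spontaneous_period = 1000, duration = 8000,
                    first_stimulus = 200, noise_sd = 0.03, seed = 5)
  sim <- simulate_movie(cfg)
  times <- detect_beats(sim$movie)
  expect_gte(length(times), 7)
  expect_lt(max(abs(diff(times) - 1000)), sim$movie$frame_interval)
  flat <- mapping_movie(array(1000, c(300, 4, 4)), 2, 0.1)
  expect_error(detect_beats(flat), "flat|beats")
})
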
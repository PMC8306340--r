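test_that("APD crossings of sampled templates are recovered to sub-frame precision", {
  for (p in list(c(134, 220), c(227, 365))) {
    tb <- template_beat(ap_template(p[1], p[2], 5), dt = 1)
    t_rel <- tb$time - tb$onset
    expect_equal(apd(tb$y, t_rel, 0.3, activation = 0), p[1], tolerance = 0.5)
    expect_equal(apd(tb$y, t_rel, 0.8, activation = 0), p[2], tolerance = 0.5)
    # onset-referenced default agrees without an explicit activation
    expect_equal(apd(tb$y, t_rel, 0.3), p[1], tolerance = 0.5)
  }
  tb <- template_beat(ap_template(134, 220, 5), dt = 1)
  expect_error(apd(tb$y, tb$time - tb$onset, 0.05), "level")
  expect_error(apd(tb$y, tb$time - tb$onset, 0.99), "level")
})

test_that("activation time tracks the upstroke and flags flat traces", {
  tb <- template_beat(ap_template(134, 220, 4), dt = 1, onset = 15)
  act <- activation_time(tb$y, tb$time)
  # max-dF/dt activation sits inside the upstroke starting at 15 ms
  expect_lt(abs(act - 17), 1.5)
  expect_true(is.na(activation_time(rep(0, 100), 0:99)))
  expect_true(is.na(upstroke_velocity(rep(0.5, 100), 0:99)))
})

test_that("upstroke velocity equals the rise slope and is amplitude invariant", {
  tb5 <- template_beat(ap_template(134, 220, 5), dt = 1)
  expect_equal(upstroke_velocity(tb5$y, tb5$time), 0.2, tolerance = 0.01)
  tb10 <- template_beat(ap_template(134, 220, 10), dt = 1)
  expect_equal(upstroke_velocity(tb10$y, tb10$time), 0.1, tolerance = 0.005)
  # doubling the raw amplitude before normalization changes nothing:
  # normalization divides it away
  y2 <- tb10$y * 2
  y2 <- y2 / max(y2)
  expect_equal(upstroke_velocity(y2, tb10$time),
               upstroke_velocity(tb10$y, tb10$time), tolerance = 1e-9)
})

test_that("APD is monotone in level on valid traces", {
  set.seed(31)
  for (i in 1:8) {
    a30 <- runif(1, 90, 240); a80 <- a30 + runif(1, 50, 150)
    tb <- template_beat(ap_template(a30, a80, 8), dt = 2,
                        noise_sd = 0.03, seed = i)
    v30 <- apd(tb$y, tb$time - tb$onset, 0.3)
    v80 <- apd(tb$y, tb$time - tb$onset, 0.8)
    expect_lt(v30, v80)
  }
})

test_that("heterogeneity RSD matches a two-pass sd/mean oracle", {
  m <- matrix(c(8, 12, 8, 12, 8, 12, 8, 12, 8, 12, 8, 12), 3, 4)
  expect_equal(heterogeneity_rsd(m, min_pixels = 2),
               sd(as.numeric(m)) / mean(m), tolerance = 1e-12)
  expect_equal(heterogeneity_rsd(matrix(c(8, 12), 1, 2), min_pixels = 2),
               0.2828, tolerance = 1e-3)
  expect_equal(heterogeneity_rsd(matrix(5, 4, 4)), 0)
  set.seed(9)
  vals <- matrix(rlnorm(400, 0, 0.3), 20, 20)
  oracle <- sqrt(sum((vals - mean(vals))^2) / (length(vals) - 1)) / mean(vals)
  expect_equal(heterogeneity_rsd(vals), oracle, tolerance = 1e-12)
  expect_error(heterogeneity_rsd(matrix(-1, 5, 5)), "positive")
  expect_error(heterogeneity_rsd(matrix(1, 2, 2)), "valid pixels")
})

test_that("beating rate converts mean inter-beat intervals", {
  expect_equal(beating_rate(c(0, 1000, 2000, 3000)), 60)
  expect_equal(beating_rate(cumsum(c(0, rep(887.6, 5)))), 67.5980622,
               tolerance = 1e-6)
  expect_equal(beating_rate(c(0, 900, 2000)), 60)  # mean interval 1000
  expect_error(beating_rate(c(0, 1000)), "3 beats")
})

test_that("metric maps recover a noiseless movie pixel for pixel", {
  sim <- vm_movie(rows = 10, cols = 10)
  w <- segment_beats(sim$movie)
  nb <- normalize_beats(sim$movie, w, sim$truth$mask)
  ap <- map_ap_metrics(nb)
  expect_equal(ap$summary$n_valid_pixels, 100)
  dtms <- sim$movie$frame_interval
  expect_lt(max(abs(ap$apd30 - 134)), dtms)
  expect_lt(max(abs(ap$apd80 - 220)), dtms)
  # measured activation ramps along the wave like the truth
  act <- ap$activation_time
  expect_equal(act[, 8] - act[, 2], sim$truth$activation_offset[, 8] -
                 sim$truth$activation_offset[, 2], tolerance = dtms / 2)
})
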
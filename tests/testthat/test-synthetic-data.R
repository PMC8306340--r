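test_that("AP template crosses its repolarization levels analytically", {
  for (p in list(c(134, 220), c(213, 311), c(227, 365))) {
    tpl <- ap_template(p[1], p[2], upstroke_duration = 5)
    expect_equal(template_value(tpl, p[1]), 0.7, tolerance = 1e-12)
    expect_equal(template_value(tpl, p[2]), 0.2, tolerance = 1e-12)
  }
  tpl <- ap_template(100, 200, upstroke_duration = 2)
  expect_identical(template_value(tpl, -1), 0)
  expect_identical(template_value(tpl, 2), 1)          # peak exactly 1
  expect_identical(template_value(tpl, 200 * 1.15), 0) # fully repolarized
  tr <- sample_template(tpl, 0.5)
  expect_equal(max(tr$value), 1)
})

test_that("template parameter ordering is enforced", {
  expect_error(ap_template(220, 134), "upstroke_duration < apd30 < apd80")
  expect_error(ap_template(100, 200, upstroke_duration = 150), "apd30")
  expect_error(ca_template(-1, 400), "must be > 0")
  expect_error(ca_template(98, 0), "must be > 0")
  expect_error(sample_template(ap_template(100, 200), 0), "frame_interval")
})

test_that("Ca template peaks exactly at time_to_peak and decays monoexponentially", {
  tpl <- ca_template(98, 400)
  expect_identical(template_value(tpl, 98), 1)
  expect_lt(template_value(tpl, 97), 1)
  expect_equal(template_value(tpl, 98 + 400), exp(-1), tolerance = 1e-12)
  tpl2 <- ca_template(170, 400)
  tt <- seq(0, 600, by = 0.25)
  expect_equal(tt[which.max(template_value(tpl2, tt))], 170)
  # near-infinite tau: decay segment flat at 1 to machine tolerance
  flat <- ca_template(50, 1e12)
  expect_equal(template_value(flat, c(60, 500, 5000)), rep(1, 3),
               tolerance = 1e-8)
})

test_that("planar-wave activation offsets follow distance / speed exactly", {
  sim <- vm_movie(rows = 8, cols = 8, planar_wave_speed = 0.02,
                  pixel_pitch = 0.1, cycle_length = 700)
  off <- sim$truth$activation_offset
  # 0.1 mm / 0.02 mm/ms = 5 ms per column from the left edge
  expect_equal(diff(off[4, ]), rep(5, 7))
  expect_equal(off[, 3], rep(10, 8))
  expect_identical(sim$truth$true_cv, 0.02)
})

test_that("fixed seed makes simulated movies bit-reproducible", {
  a <- vm_movie(noise_sd = 0.05, seed = 42, rows = 6, cols = 6)
  b <- vm_movie(noise_sd = 0.05, seed = 42, rows = 6, cols = 6)
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$truth$upstroke_duration, b$truth$upstroke_duration)
  c_ <- vm_movie(noise_sd = 0.05, seed = 43, rows = 6, cols = 6)
  expect_false(identical(a$movie$data, c_$movie$data))
})

test_that("noiseless movies never exceed baseline + amplitude", {
  sim <- vm_movie(rows = 6, cols = 6, baseline_offset = 1000,
                  amplitude_counts = 2000)
  expect_lte(max(sim$movie$data), 3000 + 1e-9)
  expect_gte(min(sim$movie$data), 1000 - 1e-9)
})

test_that("spontaneous beat count follows floor(duration / period) + 1", {
  cfg <- sim_config(ap_template(134, 220), rows = 4, cols = 4,
                    spontaneous_period = 887.6, duration = 30000,
                    first_stimulus = 0, planar_wave_speed = 1)
  sim <- simulate_movie(cfg)
  expect_length(sim$truth$beat_times, floor(30000 / 887.6) + 1)
  expect_length(sim$movie$stimulus_times, 0)
})

test_that("a movie too short for its pacing schedule is rejected", {
  cfg <- sim_config(ap_template(134, 220), rows = 4, cols = 4,
                    cycle_length = 1000, n_beats = 3, duration = 1500)
  expect_error(simulate_movie(cfg), "too short")
})

test_that("ground-truth upstroke RSD matches the drawn lognormal field", {
  sigma <- upstroke_sigma_for_rsd(0.27)
  cfg <- sim_config(ap_template(134, 220), rows = 100, cols = 100,
                    cycle_length = 600, n_beats = 1,
                    pixel_heterogeneity = sigma, seed = 7)
  sim <- simulate_movie(cfg)
  v <- 1 / as.numeric(sim$truth$upstroke_duration)
  expect_identical(sim$truth$true_upstroke_rsd, sd(v) / mean(v))
  # at n = 1e4 the sample RSD sits within 2% of the tuned value
  expect_lt(abs(sim$truth$true_upstroke_rsd - 0.27) / 0.27, 0.02)
})

test_that("synthetic Cq tables encode fold changes in cycles", {
  # fold change 0.5, E = 2: exactly +1 cycle
  tab <- simulate_cq_table(dsg2_qpcr_design(0.5))
  cq_mut <- mean(tab$cq[tab$gene == "DSG2" & tab$group == "Mut"])
  cq_ctl <- mean(tab$cq[tab$gene == "DSG2" & tab$group == "Ctrl1"])
  expect_equal(cq_mut - cq_ctl, 1)
  # fold change 0.648: -log2(0.648) cycles
  tab <- simulate_cq_table(dsg2_qpcr_design(0.648))
  cq_mut <- mean(tab$cq[tab$gene == "DSG2" & tab$group == "Mut"])
  cq_ctl <- mean(tab$cq[tab$gene == "DSG2" & tab$group == "Ctrl1"])
  expect_equal(cq_mut - cq_ctl, -log2(0.648))
  # all fold changes 1, no noise: constant Cq per gene
  tab <- simulate_cq_table(dsg2_qpcr_design(1))
  expect_equal(length(unique(tab$cq[tab$gene == "DSG2"])), 1L)
  # reference genes flat everywhere
  expect_equal(length(unique(tab$cq[tab$gene == "GAPDH"])), 1L)
})

test_that("zline generator records drawn lengths exactly and rejects overlap", {
  segs <- data.frame(row = c(30, 70), col = c(30, 70), angle = c(0, 90),
                     length_um = c(0.76, 1.1))
  sim <- simulate_zline_image(zline_sim_config(100, 0.05, segs,
                                               background_sd = 0))
  expect_identical(sim$lengths_um, c(0.76, 1.1))
  expect_equal(max(sim$image), 1, tolerance = 1e-9)
  # zero segments: pure-noise image, empty truth
  blank <- simulate_zline_image(zline_sim_config(60, 0.05, NULL,
                                                 background_sd = 0.05,
                                                 seed = 2))
  expect_length(blank$lengths_um, 0)
  # overlapping strokes rejected
  bad <- data.frame(row = c(50, 50), col = c(48, 52), angle = c(0, 0),
                    length_um = c(1, 1))
  expect_error(simulate_zline_image(zline_sim_config(100, 0.05, bad)),
               "overlap")
  # random placement reproduces the drawn sample mean exactly
  rs <- random_zline_segments(10, 400, 0.05, 1.17, 0.1, seed = 11)
  sim2 <- simulate_zline_image(zline_sim_config(400, 0.05, rs,
                                                background_sd = 0))
  expect_identical(mean(sim2$lengths_um), mean(rs$length_um))
})
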
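test_that("ROI selection is seeded, disjoint, and handles the degenerate case", {
  img <- matrix(0, 400, 400)
  # image exactly ROI-sized: the single ROI is the full image
  r1 <- select_rois(img, pixel_size_um = 0.05, roi_size_um = 20, n_rois = 1)
  expect_equal(r1$row0, 1)
  expect_equal(r1$col0, 1)
  expect_equal(r1$size_px, 400)
  big <- matrix(0, 900, 900)
  a <- select_rois(big, 0.05, 20, n_rois = 2, seed = 7)
  b <- select_rois(big, 0.05, 20, n_rois = 2, seed = 7)
  expect_identical(a, b)
  expect_true(abs(a$row0[1] - a$row0[2]) >= 400 ||
                abs(a$col0[1] - a$col0[2]) >= 400)
  expect_error(select_rois(matrix(0, 100, 100), 0.05, 20), "smaller")
})

test_that("a single drawn segment is measured near its true length", {
  segs <- data.frame(row = 60, col = 60, angle = 25, length_um = 0.76)
  sim <- simulate_zline_image(zline_sim_config(120, 0.05, segs,
                                               background_sd = 0.05,
                                               seed = 5))
  l <- detect_zlines(sim$image, 0.05)
  expect_length(l, 1)
  expect_lt(abs(l - 0.76), 3.5 * 0.05)
  # blank noise ROI: empty result
  blank <- simulate_zline_image(zline_sim_config(120, 0.05, NULL,
                                                 background_sd = 0.05,
                                                 seed = 6))
  expect_length(detect_zlines(blank$image, 0.05), 0)
})

test_that("known segments are counted exactly and measured within tolerance", {
  segs <- random_zline_segments(10, 500, 0.05, length_mean_um = 1.0,
                                length_sd_um = 0.15, seed = 13)
  sim <- simulate_zline_image(zline_sim_config(500, 0.05, segs,
                                               background_sd = 0.05,
                                               seed = 14))
  l <- sort(detect_zlines(sim$image, 0.05))
  truth <- sort(sim$lengths_um)
  expect_length(l, 10)
  err_px <- abs(l - truth) / 0.05
  expect_lt(median(err_px), 1)
  expect_gte(sum(err_px < 2), 7)
  expect_lt(max(err_px), 4)
})

test_that("measured lengths are robust to a 90-degree rotation", {
  segs <- random_zline_segments(6, 300, 0.05, length_mean_um = 1.0,
                                length_sd_um = 0.1, seed = 23)
  sim <- simulate_zline_image(zline_sim_config(300, 0.05, segs,
                                               background_sd = 0.04,
                                               seed = 24))
  l0 <- sort(detect_zlines(sim$image, 0.05))
  rot <- t(sim$image)[ncol(sim$image):1, ]
  l90 <- sort(detect_zlines(rot, 0.05))
  expect_length(l90, length(l0))
  expect_lt(max(abs(l0 - l90)), 1 * 0.05)
})

test_that("seeded determinism covers ROI choice and measured lengths", {
  segs <- random_zline_segments(8, 600, 0.05, 1.17, 0.1, seed = 31)
  sim <- simulate_zline_image(zline_sim_config(600, 0.05, segs,
                                               background_sd = 0.06,
                                               seed = 32))
  run <- function() {
    rois <- select_rois(sim$image, 0.05, 10, n_rois = 2, seed = 33)
    unlist(lapply(seq_len(nrow(rois)), function(i)
      detect_zlines(sim$image[rois$row0[i]:(rois$row0[i] + rois$size_px[i] - 1),
                              rois$col0[i]:(rois$col0[i] + rois$size_px[i] - 1)],
                    0.05)))
  }
  expect_identical(run(), run())
})

test_that("group summaries pool lengths with a t-interval", {
  s <- summarize_lengths(list(ctrl = rep(1, 5)))
  expect_equal(s$mean_um, 1)
  expect_equal(s$ci95_um, 0)
  s2 <- summarize_lengths(list(g = c(1, 3)))
  expect_equal(s2$mean_um, 2)
  expect_error(summarize_lengths(list(g = 1)), "fewer than 2")
  # generator set to the Ctrl1 morphology: pooled mean within 0.05 um
  set.seed(45)
  all_l <- c()
  for (i in 1:3) {
    segs <- random_zline_segments(20, 600, 0.05, 1.17, 0.1, seed = 40 + i)
    sim <- simulate_zline_image(zline_sim_config(600, 0.05, segs,
                                                 background_sd = 0.05,
                                                 seed = 50 + i))
    rois <- select_rois(sim$image, 0.05, 10, n_rois = 3, seed = 60 + i)
    for (k in 1:3)
      all_l <- c(all_l, detect_zlines(
        sim$image[rois$row0[k]:(rois$row0[k] + rois$size_px[k] - 1),
                  rois$col0[k]:(rois$col0[k] + rois$size_px[k] - 1)], 0.05))
  }
  s3 <- summarize_lengths(list(Ctrl1 = all_l))
  expect_gt(s3$n, 10)
  expect_lt(abs(s3$mean_um - 1.17), 0.08)
})
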
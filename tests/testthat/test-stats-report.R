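# from-scratch oracles, independent of stats::t.test / stats::p.adjust
welch_oracle <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[o[i]]))
    adj[o[i]] <- running
  }
  adj
}

test_that("Welch t equals the textbook formula on random samples", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  w <- welch_t(c(10, 11, 12, 13), c(20, 21, 22, 23))
  o <- welch_oracle(c(10, 11, 12, 13), c(20, 21, 22, 23))
  expect_equal(w$t, o$t, tolerance = 1e-10)
  expect_equal(w$df, o$df, tolerance = 1e-10)
  expect_equal(w$p, o$p, tolerance = 1e-10)
  set.seed(55)
  for (i in 1:100) {
    a <- rnorm(sample(2:9, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:9, 1), mean = runif(1, -1, 1))
    w <- welch_t(a, b); o <- welch_oracle(a, b)
    expect_equal(w$t, o$t, tolerance = 1e-10)
    expect_equal(w$df, o$df, tolerance = 1e-10)
    expect_equal(w$p, o$p, tolerance = 1e-10)
  }
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("Holm adjustment matches the step-down oracle and is order invariant", {
  expect_equal(holm_bonferroni(0.03), 0.03)
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_bonferroni(rep(1, 5)), rep(1, 5))
  expect_error(holm_bonferroni(c(0.2, 1.4)), "\\[0, 1\\]")
  set.seed(66)
  for (i in 1:50) {
    p <- runif(sample(1:8, 1))
    adj <- holm_bonferroni(p)
    expect_equal(adj, holm_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    perm <- sample(length(p))
    expect_equal(holm_bonferroni(p[perm]), adj[perm], tolerance = 1e-12)
  }
})

test_that("95% confidence intervals use the t quantile", {
  expect_equal(ci95(c(5, 5, 5, 5))$half_width, 0)
  ci <- ci95(1:5)
  expect_equal(ci$mean, 3)
  expect_equal(ci$half_width, qt(0.975, 4) * sd(1:5) / sqrt(5),
               tolerance = 1e-12)
  expect_error(ci95(3), "n >= 2")
})

test_that("group comparisons form families and adjust within them", {
  set.seed(70)
  d <- data.frame(group = rep(c("A", "B", "C"), each = 6),
                  metric = "apd80",
                  value = rnorm(18, mean = 100, sd = 5))
  rep3 <- compare_groups(d)
  expect_equal(nrow(rep3$comparisons), 3)
  expect_equal(unique(rep3$comparisons$m), 3)
  expect_false(any(rep3$comparisons$significant))
  # two groups, one metric: adjusted p equals the raw p
  d2 <- d[d$group != "C", ]
  rep2 <- compare_groups(d2)
  expect_equal(rep2$comparisons$p_adjusted, rep2$comparisons$p)
  # summaries carry n, mean, and CI
  expect_equal(sort(unique(rep3$summaries$group)), c("A", "B", "C"))
  expect_equal(rep3$summaries$n, rep(6, 3))
})

test_that("the study's APD80 group separation is detected with high power", {
  set.seed(81)
  hits <- replicate(200, {
    d <- data.frame(
      group = c(rep("DSG2Mut", 9), rep("Ctrl1", 8), rep("Ctrl2", 13)),
      metric = "apd80",
      value = c(rnorm(9, 220, 24), rnorm(8, 311, 27), rnorm(13, 365, 26)))
    cmp <- compare_groups(d)$comparisons
    mut <- cmp$group_a == "DSG2Mut" | cmp$group_b == "DSG2Mut"
    all(cmp$significant[mut])
  })
  expect_gte(mean(hits), 0.95)
})
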
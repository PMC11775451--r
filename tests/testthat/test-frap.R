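# FRAP recovery quantification and group comparison.

mk_trace <- function(pre = 1, post = 0.1, end = 0.1, dt = 0.1) {
  # 10 s plateau, drop at 10 s, 20 s linear rise, then flat at `end`
  times <- seq(0, 70, by = dt)
  bi <- as.integer(10 / dt)
  f <- rep(end, length(times))
  f[seq_len(bi)] <- pre
  rise <- bi + seq_len(as.integer(20 / dt))
  f[rise] <- seq(post, end, length.out = length(rise))
  frap_trace(times, f, bi)
}

test_that("recovery endpoints behave as defined", {
  expect_equal(frap_recovery(mk_trace(end = 0.1)), 0)
  expect_equal(frap_recovery(mk_trace(end = 1.0)), 1, tolerance = 1e-9)
  expect_error(frap_recovery(mk_trace(pre = 0.1, post = 0.5, end = 0.5)),
               "no bleach")
})

test_that("recovery is invariant to affine rescaling", {
  tr <- generate_frap(0.4, tau = 15, config = synth_config(seed = 8),
                      noise_sd = 0.03, duration = 90)
  r1 <- frap_recovery(tr)
  tr2 <- frap_trace(tr$times, 37 * tr$intensities + 5, tr$bleach_index)
  expect_equal(frap_recovery(tr2), r1, tolerance = 1e-12)
})

test_that("noise-free generator traces recover the mobile fraction", {
  cfg <- synth_config(seed = 1)
  for (mf in c(0, 0.35, 0.8)) {
    tr <- generate_frap(mf, tau = 20, config = cfg, noise_sd = 0,
                        duration = 130)
    expect_equal(frap_recovery(tr), mf, tolerance = 0.02)
  }
})

test_that("pooled t from summaries agrees with t.test on raw values", {
  set.seed(5)
  x <- rnorm(12, 0.11, 0.10)
  y <- rnorm(5, 0.07, 0.03)
  ours <- two_sample_t(group_stats(x), group_stats(y))
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  # Welch variant against its oracle
  ours_w <- two_sample_t(group_stats(x), group_stats(y),
                         var_equal = FALSE)
  ref_w <- t.test(x, y)
  expect_equal(ours_w$t, unname(ref_w$statistic), tolerance = 1e-12)
  expect_equal(ours_w$p, ref_w$p.value, tolerance = 1e-12)
})

test_that("t statistic degenerates and flips sign correctly", {
  g <- list(mean = 0.2, sd = 0, n = 5)
  out <- two_sample_t(g, g)
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  a <- group_stats(c(0.1, 0.2, 0.3)); b <- group_stats(c(0.2, 0.4, 0.6))
  expect_equal(two_sample_t(a, b)$t, -two_sample_t(b, a)$t)
  expect_error(two_sample_t(group_stats(0.5), a), "n >= 2")
})

test_that("simulated FRAP groups reproduce the design summaries", {
  sim <- simulate_frap_groups(config = synth_config(seed = 2), seed = 2)
  expect_named(sim$groups, c("control", "cbx", "gap27"))
  expect_identical(sim$groups$control$n, 12L)
  expect_identical(sim$groups$cbx$n, 5L)
  # recoveries track the drawn true mobile fractions
  for (g in names(sim$groups)) {
    expect_lt(max(abs(sim$groups[[g]]$values - sim$truth[[g]])), 0.1)
  }
  expect_true(all(c("t", "p") %in% names(sim$tests$cbx)))
})
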
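# Baseline estimation, spike detection and spike-train utilities.

test_that("baseline of a constant trace is that constant", {
  b <- estimate_baseline(rep(5, 400), 0.1, window = 10)
  expect_equal(b, rep(5, 400), tolerance = 1e-12)
})

test_that("baseline tracks a linear drift", {
  drift <- seq(100, 150, length.out = 3000)
  b <- estimate_baseline(drift, 0.1, window = 30, percentile = 0.2)
  # a rolling percentile of a ramp sits below the ramp by a bounded
  # offset; it must follow the slope everywhere
  expect_true(all(abs(diff(b) - diff(drift)[1]) < 0.05))
  # away from the clamped window edges it stays at or below the ramp
  interior <- 151:2850
  expect_true(all(b[interior] <= drift[interior] + 1e-9))
})

test_that("baseline ignores sparse transients on a flat floor", {
  floor_level <- 200
  f <- fluorescence_from_spikes(c(300, 900, 1500, 2100), 3000,
                                amplitude = 0.5, f0 = floor_level,
                                noise_sd = 0)
  b <- estimate_baseline(f, 0.1, window = 30)
  expect_true(all(abs(b - floor_level) / floor_level < 0.01))
})

test_that("baseline window validation", {
  expect_error(estimate_baseline(rep(1, 50), 0.1, window = 10),
               "longer than the trace")
  expect_error(estimate_baseline(rep(1, 50), 0.1, window = 0.5),
               "at least 10 frames")
  expect_error(estimate_baseline(c(1, NA, 3), 0.1, window = 0.3),
               "non-finite")
})

test_that("flat traces yield empty spike trains", {
  st <- detect_spikes(rep(100, 600), 0.1)
  expect_identical(st$frames, integer(0))
})

test_that("noise-free transients are detected at their rise frames", {
  f <- fluorescence_from_spikes(c(100, 200, 300), 500, noise_sd = 0)
  st <- detect_spikes(f, 0.1)
  expect_identical(st$frames, c(100L, 200L, 300L))
})

test_that("detection is invariant to positive rescaling", {
  f <- fluorescence_from_spikes(c(50, 130, 260, 390), 600,
                                noise_sd = 0.02, f0 = 1000)
  a <- detect_spikes(f, 0.1)$frames
  b <- detect_spikes(3.7 * f, 0.1)$frames
  expect_identical(a, b)
})

test_that("detection is translation-equivariant away from boundaries", {
  spikes <- c(400, 700, 1100)
  f1 <- fluorescence_from_spikes(spikes, 2000, noise_sd = 0)
  f2 <- fluorescence_from_spikes(spikes + 50, 2000, noise_sd = 0)
  expect_identical(detect_spikes(f2, 0.1)$frames,
                   detect_spikes(f1, 0.1)$frames + 50L)
})

test_that("noise-free generator output is recovered exactly", {
  cfg <- synth_config(n_slices = 1, cells_per_slice = 8,
                      n_frames = 6000, noise_sd = 0, seed = 6)
  out <- generate_recording(cfg)
  trains <- detect_session(out$session)
  for (id in names(trains)) {
    expect_identical(trains[[id]]$frames,
                     out$truth$spike_frames[[id]])
  }
})

test_that("detection achieves high per-cell sensitivity and precision at
           peak SNR 10", {
  cfg <- synth_config(n_slices = 1, cells_per_slice = 20,
                      coupling_prob = 0, n_frames = 12000, seed = 18)
  out <- generate_recording(cfg)
  trains <- detect_session(out$session)
  st <- vapply(names(trains), function(id) {
    match_counts(trains[[id]]$frames, out$truth$spike_frames[[id]],
                 tol = 1)
  }, numeric(3))
  sens <- st["tp", ] / st["n_true", ]
  prec <- st["tp", ] / st["n_det", ]
  expect_true(all(sens >= 0.95))
  expect_true(all(prec >= 0.95))
})

test_that("binarize and its inverse round-trip", {
  expect_identical(binarize(spike_train("c", integer(0), 5)),
                   rep(0L, 5))
  expect_identical(binarize(spike_train("c", c(0, 4), 5)),
                   c(1L, 0L, 0L, 0L, 1L))
  tr <- spike_train("c", c(2, 9, 31), 40)
  expect_identical(spike_frames_from_binary(binarize(tr)), tr$frames)
})

test_that("epoch restriction re-indexes and discards the lead-in", {
  tr <- spike_train("c", c(10, 700), 1200, 0.1)
  r <- restrict_to_epoch(tr, c(0, 1200), discard_lead = 60)
  expect_identical(r$frames, 100L)
  expect_identical(r$n_frames, 600L)
  # identity when nothing is discarded
  r0 <- restrict_to_epoch(tr, c(0, 1200), discard_lead = 0)
  expect_identical(r0$frames, tr$frames)
  expect_identical(r0$n_frames, tr$n_frames)
  # all spikes inside the discarded lead
  r2 <- restrict_to_epoch(spike_train("c", c(5, 50), 1200, 0.1),
                          c(0, 1200), discard_lead = 60)
  expect_identical(r2$frames, integer(0))
  expect_error(restrict_to_epoch(tr, c(0, 300), discard_lead = 60),
               "consumes the whole epoch")
})

test_that("spike_train validates its invariants", {
  expect_error(spike_train("c", c(3, 3), 10), "duplicate")
  expect_error(spike_train("c", c(-1), 10), "n_frames")
  expect_error(spike_train("c", c(10), 10), "n_frames")
})
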
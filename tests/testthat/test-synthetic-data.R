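# Synthetic-data generator: determinism, rate fidelity, coupling and
# geometry structure, FRAP traces.

test_that("generator is bit-reproducible for a fixed config and seed", {
  cfg <- small_protocol_config(seed = 7, n_frames = 3000)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$session$traces, b$session$traces)
  expect_identical(a$truth$spike_frames, b$truth$spike_frames)
  expect_identical(a$session$geometry, b$session$geometry)
})

test_that("coupling_prob = 0 produces no coupled pairs", {
  cfg <- synth_config(n_slices = 1, cells_per_slice = 12,
                      coupling_prob = 0, n_frames = 2000, seed = 3)
  out <- generate_recording(cfg)
  expect_identical(nrow(out$truth$coupled_pairs), 0L)
})

test_that("a 14-cell, 27,000-frame config reproduces the example scale", {
  cfg <- synth_config(n_slices = 1, cells_per_slice = 14,
                      n_frames = 27000, frame_interval = 0.1, seed = 2)
  out <- generate_recording(cfg)
  expect_identical(dim(out$session$traces), c(27000L, 14L))
  # 45 min at 10 frames/s
  expect_equal(nrow(out$session$traces) * cfg$frame_interval / 60, 45)
})

test_that("ground-truth spike rate converges to base_rate", {
  # ~ 186 * 2700 s * 0.43 expected spikes >> 1e4: law of large numbers
  cfg <- synth_config(n_slices = 2, cells_per_slice = 40,
                      coupling_prob = 0, n_frames = 27000, seed = 8)
  out <- generate_recording(cfg)
  rate <- sum(lengths(out$truth$spike_frames)) /
    (80 * 27000 * cfg$frame_interval)
  expect_lt(abs(rate - cfg$base_rate) / cfg$base_rate, 0.05)
})

test_that("generated spike trains respect the minimum inter-spike interval", {
  cfg <- synth_config(n_slices = 1, cells_per_slice = 10,
                      coupling_prob = 0, n_frames = 20000, seed = 12)
  out <- generate_recording(cfg)
  gaps <- unlist(lapply(out$truth$spike_frames, diff))
  expect_gte(min(gaps), round(cfg$min_isi / cfg$frame_interval))
})

test_that("ground-truth JI of coupled pairs grows with coupling_strength", {
  mean_ji <- function(s) {
    cfg <- synth_config(n_slices = 1, cells_per_slice = 20,
                        rosette_size = 2, coupling_prob = 1,
                        coupling_strength = s, n_frames = 20000,
                        seed = 31)
    out <- generate_recording(cfg)
    gt <- ground_truth_trains(out$truth)
    cp <- out$truth$coupled_pairs
    mean(mapply(function(a, b) jaccard_index(gt[[a]], gt[[b]]),
                cp$cell_a, cp$cell_b))
  }
  jis <- vapply(c(0.3, 0.6, 0.9), mean_ji, numeric(1))
  expect_true(all(diff(jis) > 0))
  # expected pair JI is s / (2 - s); allow simulation noise
  expect_equal(jis[2], 0.6 / 1.4, tolerance = 0.1)
})

test_that("uncoupled pairs show only chance-level synchrony", {
  cfg <- synth_config(n_slices = 1, cells_per_slice = 30,
                      coupling_prob = 0, n_frames = 20000, seed = 14)
  out <- generate_recording(cfg)
  res <- pairwise_ji(ground_truth_trains(out$truth), out$session$slices)
  vals <- res$ji[upper.tri(res$ji)]
  expect_true(all(vals < 0.1, na.rm = TRUE))
})

test_that("rosette geometry places neighbours at cell_spacing and keeps
           rosettes apart", {
  cfg <- synth_config(n_slices = 1, cells_per_slice = 21,
                      rosette_size = 7, n_frames = 100, seed = 4)
  out <- generate_recording(cfg)
  d <- pair_distances(out$session$geometry, out$session$pixel_size)
  # ring neighbours within one rosette: cells 1-2, 2-3, ... of each group
  ids <- rownames(d)
  grp <- rep(1:3, each = 7)
  for (g in 1:3) {
    members <- ids[grp == g]
    ring <- cbind(members, c(members[-1], members[1]))
    expect_equal(unname(d[ring]), rep(cfg$cell_spacing, 7),
                 tolerance = 1e-6)
    # every cross-rosette distance exceeds every within-rosette one
    within <- max(d[members, members])
    across <- min(d[members, ids[grp != g]])
    expect_gt(across, within)
  }
})

test_that("drug epochs suppress the generated spike rate", {
  cfg <- small_protocol_config(seed = 9, n_frames = 18000)
  out <- generate_recording(cfg)
  gt <- ground_truth_trains(out$truth)
  rates <- session_epoch_rates(gt, out$session$epochs, discard_lead = 60)
  rb <- mean(rates$rate_hz[rates$epoch == "baseline"])
  rd <- mean(rates$rate_hz[rates$epoch == "drug"])
  expect_lt(rd, rb * 0.3)
})

test_that("FRAP generator obeys its closed form", {
  cfg <- synth_config(seed = 5)
  # immobile: post-bleach trace flat at bleach_depth
  tr0 <- generate_frap(0, tau = 10, bleach_depth = 0.1, config = cfg,
                       noise_sd = 0)
  post <- tr0$intensities[(tr0$bleach_index + 1L):length(tr0$times)]
  expect_equal(post, rep(0.1, length(post)), tolerance = 1e-12)
  # fully mobile, window >> tau: returns to the pre-bleach level
  tr1 <- generate_frap(1, tau = 5, config = cfg, noise_sd = 0,
                       duration = 130)
  expect_equal(tail(tr1$intensities, 1), 1, tolerance = 1e-3)
  # seed determinism with noise
  a <- generate_frap(0.4, tau = 20, config = cfg)
  b <- generate_frap(0.4, tau = 20, config = cfg)
  expect_identical(a$intensities, b$intensities)
})

test_that("configuration errors are caught", {
  expect_error(synth_config(n_frames = 0), "n_frames")
  expect_error(synth_config(coupling_prob = 1.2), "coupling_prob")
  expect_error(synth_config(base_rate = 2, intraburst_freq = 1),
               "occupancy")
  expect_error(generate_frap(1.5, tau = 10), "mobile_fraction")
  expect_error(generate_frap(0.5, tau = -1), "tau")
})
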
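# Baseline vs drug epoch comparison of rates and synchrony.

test_that("epoch spike rate is count over duration", {
  expect_equal(epoch_spike_rate(spike_train("c", integer(0), 600, 0.1)), 0)
  tr <- spike_train("c", seq(0, 580, by = 20), 600, 0.1)  # 30 in 60 s
  expect_equal(epoch_spike_rate(tr), 0.5)
})

test_that("identical epochs give zero JI change", {
  n <- 400
  trains <- list(a = spike_train("a", c(1, 2, 3, 9), n),
                 b = spike_train("b", c(1, 2, 3, 7), n),
                 c = spike_train("c", c(100, 200), n))
  res <- pairwise_ji(trains)
  cmp <- ji_change(res, res, n_resamples = 200, seed = 1)
  expect_equal(cmp$connections$change_abs,
               rep(0, nrow(cmp$connections)))
  expect_equal(cmp$summary_relative$mean, 0)
  expect_equal(cmp$summary_absolute$mean, 0)
})

test_that("JI change arithmetic: 0.4 -> 0.2 is -0.2 absolute, -50% relative", {
  n <- 100
  base <- pairwise_ji(list(a = spike_train("a", c(1, 2, 3, 4), n),
                           b = spike_train("b", c(1, 2, 7, 8), n)))
  stopifnot(abs(base$ji["a", "b"] - 1 / 3) < 1e-12)
  drug <- pairwise_ji(list(a = spike_train("a", c(1, 2, 3, 4, 5, 6), n),
                           b = spike_train("b", c(1, 9, 10, 11, 12), n)))
  expect_equal(drug$ji["a", "b"], 0.1)
  cmp <- ji_change(base, drug, n_resamples = 200, seed = 1)
  expect_equal(cmp$connections$change_abs, 0.1 - 1 / 3)
  expect_equal(cmp$connections$change_rel_pct, 100 * (0.1 - 1 / 3) * 3)
})

test_that("drug-epoch connections with undefined JI are excluded", {
  n <- 200
  base <- pairwise_ji(list(a = spike_train("a", 1:4, n),
                           b = spike_train("b", 1:4, n)))
  drug <- pairwise_ji(list(a = spike_train("a", integer(0), n),
                           b = spike_train("b", integer(0), n)))
  cmp <- ji_change(base, drug, n_resamples = 100, seed = 1)
  expect_identical(nrow(cmp$connections), 0L)
  expect_identical(cmp$n_excluded, 1L)
})

test_that("compare_groups flags CI overlap symmetrically", {
  n <- 400
  trains <- list(a = spike_train("a", c(1, 2, 3, 9), n),
                 b = spike_train("b", c(1, 2, 3, 7), n))
  res <- pairwise_ji(trains)
  cmp <- ji_change(res, res, n_resamples = 200, seed = 1)
  out <- compare_groups(cmp, cmp)
  expect_true(out$ci_overlap)
  expect_equal(out$table$mean[1], out$table$mean[2])
})

test_that("a null drug effect yields overlapping treated/control CIs", {
  mk <- function(seed) {
    cfg <- synth_config(
      n_slices = 2, cells_per_slice = 10, rosette_size = 5,
      coupling_prob = 0.8, coupling_strength = 0.7,
      drug_rate_factor = 1, drug_coupling_factor = 1,
      n_frames = 15000, epochs = protocol_epochs(15000), seed = seed
    )
    out <- generate_recording(cfg)
    gt <- ground_truth_trains(out$truth)
    ep <- out$session$epochs
    base <- pairwise_ji(lapply(gt, restrict_to_epoch, epoch = ep[1, ]),
                        out$session$slices)
    drug <- pairwise_ji(lapply(gt, restrict_to_epoch, epoch = ep[2, ]),
                        out$session$slices)
    ji_change(base, drug, n_resamples = 500, seed = seed)
  }
  out <- compare_groups(mk(1), mk(2))
  expect_true(out$ci_overlap)
})

test_that("session_epoch_rates covers every cell and epoch", {
  cfg <- small_protocol_config(seed = 2, n_frames = 6000)
  out <- generate_recording(cfg)
  gt <- ground_truth_trains(out$truth)
  rates <- session_epoch_rates(gt, out$session$epochs, discard_lead = 10)
  expect_identical(nrow(rates), length(gt) * nrow(out$session$epochs))
  expect_true(all(rates$rate_hz >= 0))
})
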
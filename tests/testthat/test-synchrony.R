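# Jaccard-index synchrony, coupling classification, shift null and
# bootstrap machinery.

test_that("jaccard_index matches hand-enumerated instances", {
  n <- 20
  t_ <- function(f) spike_train("x", f, n)
  expect_equal(jaccard_index(t_(c(1, 5, 9)), t_(c(1, 5, 9))), 1)
  expect_equal(jaccard_index(t_(c(1, 5, 9)), t_(c(2, 6, 10))), 0)
  expect_equal(jaccard_index(t_(c(1, 5, 9)), t_(c(1, 5, 12))), 0.5)
  # tolerance 1: matches {1<->2, 5<->5}; JI = 2 / (3 + 3 - 2)
  expect_equal(jaccard_index(t_(c(1, 5, 9)), t_(c(2, 5, 12)),
                             tolerance = 1), 0.5)
  expect_true(is.na(jaccard_index(t_(integer(0)), t_(integer(0)))))
  expect_equal(jaccard_index(t_(integer(0)), t_(c(3))), 0)
  expect_error(jaccard_index(t_(1), spike_train("y", 1, 30)),
               "frame grids")
})

test_that("tolerance-0 JI equals the brute-force set computation and
           respects symmetry, bounds and tolerance monotonicity", {
  set.seed(42)
  for (i in 1:300) {
    p <- random_train_pair()
    ji <- jaccard_index(p$a, p$b)
    expect_identical(ji, ji_bruteforce(p$a$frames, p$b$frames))
    expect_identical(ji, jaccard_index(p$b, p$a))
    if (!is.na(ji)) {
      expect_gte(ji, 0); expect_lte(ji, 1)
      tols <- vapply(0:3, function(t) jaccard_index(p$a, p$b, t),
                     numeric(1))
      expect_true(all(diff(tols) >= -1e-12))
    }
  }
})

test_that("JI = 1 iff non-empty trains are identical at tolerance 0", {
  set.seed(7)
  for (i in 1:50) {
    p <- random_train_pair()
    ji <- jaccard_index(p$a, p$b)
    if (!is.na(ji)) {
      expect_identical(ji == 1, identical(p$a$frames, p$b$frames))
    }
  }
})

test_that("pairwise_ji computes all within-slice pairs", {
  n <- 40
  trains <- list(
    a = spike_train("a", c(1, 7, 20), n),
    b = spike_train("b", c(1, 7, 20), n),
    c = spike_train("c", c(3, 15), n),
    d = spike_train("d", c(9), n)
  )
  res <- pairwise_ji(trains)
  expect_equal(sum(!is.na(res$ji[upper.tri(res$ji)])), 4 * 3 / 2)
  expect_equal(res$ji["a", "b"], 1)
  expect_true(isSymmetric(unname(res$ji)))
  # cross-slice pairs are never formed
  slices <- c(a = "s1", b = "s1", c = "s2", d = "s2")
  res2 <- pairwise_ji(trains, slices)
  expect_true(is.na(res2$ji["a", "c"]))
  expect_false(is.na(res2$ji["a", "b"]))
  expect_equal(sum(!is.na(res2$ji[upper.tri(res2$ji)])), 2)
})

test_that("coupling classification uses a strict threshold", {
  n <- 100
  trains <- list(
    c1 = spike_train("c1", c(1, 2, 3, 4), n),
    c2 = spike_train("c2", c(1, 2, 5, 6), n),   # JI = 2/6 = 1/3
    c3 = spike_train("c3", c(50, 60), n)
  )
  res <- pairwise_ji(trains, threshold = 0.1)
  expect_identical(res$coupled_cells, c("c1", "c2"))
  expect_equal(nrow(res$coupled_pairs), 1L)
  # strict inequality: a pair sitting exactly at the cutoff is not coupled
  res_at <- classify_coupled(res, threshold = 1 / 3)
  expect_identical(length(res_at$coupled_cells), 0L)
  # all-zero matrix
  res0 <- pairwise_ji(list(a = spike_train("a", 1, n),
                           b = spike_train("b", 50, n)))
  expect_identical(length(res0$coupled_cells), 0L)
})

test_that("shift null collapses identical trains and respects periodicity", {
  n <- 1000
  f <- sort(sample(0:(n - 1), 40))
  trains <- list(a = spike_train("a", f, n), b = spike_train("b", f, n))
  sn <- shift_null(trains, max_shift = 3)
  expect_equal(sn$summary$mean_ji[1], 1)
  expect_lt(sn$summary$mean_ji[2], 1)
  # periodic train shifted by its period is unchanged
  per <- spike_train("p", seq(0, 995, by = 5), 1000)
  per2 <- spike_train("q", seq(0, 995, by = 5), 1000)
  snp <- shift_null(list(p = per, q = per2), max_shift = 5)
  expect_equal(snp$summary$mean_ji[snp$summary$shift == 5], 1)
  expect_error(shift_null(trains, max_shift = 1000), "smaller")
})

test_that("shift 0 reproduces the plain pairwise result", {
  set.seed(11)
  n <- 600
  trains <- lapply(1:5, function(i) {
    spike_train(paste0("c", i), sort(sample(0:(n - 1), 25)), n)
  })
  names(trains) <- vapply(trains, `[[`, "", "cell_id")
  sn <- shift_null(trains, max_shift = 2)
  direct <- pairwise_ji(trains)
  expect_identical(sn$observed$ji, direct$ji)
})

test_that("bootstrap CI is degenerate on constant input and contains the
           sample mean", {
  ci <- bootstrap_ci(rep(2.5, 20), n_resamples = 500, seed = 1)
  expect_identical(c(ci$lower, ci$upper), c(2.5, 2.5))
  set.seed(3)
  x <- rnorm(40, 5, 2)
  ci2 <- bootstrap_ci(x, n_resamples = 2000, seed = 9)
  expect_lte(ci2$lower, mean(x))
  expect_gte(ci2$upper, mean(x))
  # seed determinism
  ci3 <- bootstrap_ci(x, n_resamples = 2000, seed = 9)
  expect_identical(c(ci2$lower, ci2$upper), c(ci3$lower, ci3$upper))
  expect_error(bootstrap_ci(numeric(0)), "finite")
})

test_that("coupled-JI summary averages connections above threshold", {
  n <- 100
  trains <- list(
    a = spike_train("a", c(1, 2, 3, 4, 5), n),
    b = spike_train("b", c(1, 2, 3, 4, 5), n),   # JI 1 with a
    c = spike_train("c", c(90, 95), n)
  )
  res <- pairwise_ji(trains)
  s <- summarize_coupled_ji(res, n_resamples = 200, seed = 2)
  expect_equal(s$mean, 1)
  expect_equal(c(s$ci$lower, s$ci$upper), c(1, 1))
  # arithmetic on two connections
  expect_equal(mean(c(0.2, 0.4)), 0.3)
  res$coupled_pairs <- data.frame(cell_a = c("a", "a"),
                                  cell_b = c("b", "c"),
                                  ji = c(0.2, 0.4))
  s2 <- summarize_coupled_ji(res, n_resamples = 200, seed = 2)
  expect_equal(s2$mean, 0.3)
  # no coupled pairs -> flagged empty
  res0 <- pairwise_ji(list(a = spike_train("a", 1, n),
                           b = spike_train("b", 50, n)))
  expect_true(summarize_coupled_ji(res0)$empty)
})

test_that("undefined pairs are excluded from summaries, not zeroed", {
  n <- 200
  trains <- list(
    a = spike_train("a", c(1, 5), n),
    b = spike_train("b", c(1, 5), n),
    c = spike_train("c", integer(0), n),
    d = spike_train("d", integer(0), n)
  )
  res <- pairwise_ji(trains)
  expect_true(res$undefined["c", "d"])
  sn <- shift_null(trains, max_shift = 2)
  # mean over defined pairs only: five defined pairs, one of JI 1
  expect_equal(sn$summary$n_pairs[1], 5)
  expect_equal(sn$summary$mean_ji[1], 1 / 5)
})
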
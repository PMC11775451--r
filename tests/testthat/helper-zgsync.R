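# Shared fixtures and independent oracles for the test suite.

# Small, fast session config with a three-epoch protocol.
small_protocol_config <- function(seed = 1, n_frames = 9000, ...) {
  synth_config(
    n_slices = 2, cells_per_slice = 8, rosette_size = 4,
    n_frames = n_frames, epochs = protocol_epochs(n_frames),
    seed = seed, ...
  )
}

# Brute-force Jaccard index on frame-index sets (independent oracle for
# the tolerance-0 implementation).
ji_bruteforce <- function(fa, fb) {
  if (!length(fa) && !length(fb)) return(NA_real_)
  length(intersect(fa, fb)) / length(union(fa, fb))
}

# Random spike-train pair on a shared grid.
random_train_pair <- function(n_frames = 120, max_spikes = 30) {
  na <- sample(0:max_spikes, 1)
  nb <- sample(0:max_spikes, 1)
  fa <- sort(sample(0:(n_frames - 1), na))
  fb <- sort(sample(0:(n_frames - 1), nb))
  list(a = spike_train("a", fa, n_frames),
       b = spike_train("b", fb, n_frames))
}

# Greedy one-to-one matching of detected vs true spikes within a frame
# tolerance; returns true positives and the two counts.
match_counts <- function(det, tru, tol = 1) {
  m <- 0L; i <- 1L; j <- 1L
  while (i <= length(det) && j <= length(tru)) {
    d <- det[i] - tru[j]
    if (abs(d) <= tol) {
      m <- m + 1L; i <- i + 1L; j <- j + 1L
    } else if (d < 0) i <- i + 1L else j <- j + 1L
  }
  c(tp = m, n_det = length(det), n_true = length(tru))
}
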
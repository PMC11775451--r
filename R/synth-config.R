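#' Configuration for the synthetic ZG recording generator
#'
#' Bundles and validates every parameter of the synthetic-data model. The
#' defaults reproduce the statistical structure of acute adrenal slice
#' recordings: ~23 cells per slice across 8 slices (186 cells), 27,000
#' frames at 10 frames/s (45 min), a mean baseline activity of 0.43
#' spikes/s clustered into bursts of ~1 Hz intra-burst spiking, synchrony
#' confined to near-neighbour pairs within rosettes, strong drug-epoch
#' rate suppression and a mild drug-epoch synchrony reduction.
#'
#' @param n_slices Number of slices (independent fields of view).
#' @param cells_per_slice Cells per slice; either a single count or a
#'   vector of length `n_slices`.
#' @param rosette_size Cells per rosette (glomerulus); slices are
#'   partitioned into rosettes of this size (last rosette may be smaller).
#' @param frame_interval Seconds between frames (default 0.1 s).
#' @param n_frames Total frames per recording (default 27,000 = 45 min).
#' @param base_rate Mean baseline spike rate, spikes/s (default 0.43).
#' @param burst_rate Burst initiations per minute at baseline (default 5);
#'   together with the burst-state occupancy this sets the mean burst
#'   length.
#' @param intraburst_freq Spike frequency within bursts, Hz (default 1.0).
#' @param min_isi Minimum inter-spike interval, seconds (default 0.4);
#'   emulates the finite width of calcium spikes.
#' @param coupling_prob Probability that an adjacent (ring-neighbour)
#'   within-rosette pair is directly coupled (default 0.2). Coupled
#'   components are the connected components of these edges.
#' @param coupling_strength Per-spike inclusion probability with which a
#'   coupled cell copies its component's shared parent train (default
#'   0.55). The expected pair Jaccard index is
#'   \code{s / (2 - s)} for strength \code{s}.
#' @param coupling_jitter Timing noise on shared spikes, in frames
#'   (uniform on \code{-j..j}; default 0).
#' @param drug_rate_factor Multiplicative spike-rate suppression during
#'   epochs whose solution is `"cbx"` (default 0.06/0.43).
#' @param drug_coupling_factor Multiplicative suppression of the expected
#'   pair Jaccard index during `"cbx"` epochs (default 1 - 0.156).
#' @param washout_rate_factor Rate multiplier for `"washout"` epochs
#'   (default 0.5; recovery after washout is slow and partial).
#' @param amplitude Fluorescence transient amplitude, dF/F per spike
#'   (default 0.2).
#' @param decay_tau Indicator decay time constant, seconds (default 0.5).
#' @param noise_sd Additive Gaussian noise SD in dF/F units (default
#'   0.02, i.e. peak SNR 10 at the default amplitude).
#' @param bleach_slope Photobleaching rate, fraction per minute applied as
#'   exponential multiplicative drift (default 0.005).
#' @param baseline_f0 Resting fluorescence level, a.u. (default 1000).
#' @param pixel_size Calibration, micrometers per pixel (default 0.4).
#' @param cell_spacing Center-to-center distance of adjacent rosette
#'   cells, micrometers (default 5.6).
#' @param epochs Optional epoch table (`data.frame` with columns `name`,
#'   `start_frame`, `end_frame`, `solution`); `NULL` means one baseline
#'   epoch spanning the recording. See [protocol_epochs()].
#' @param seed Integer seed; the generator is bit-reproducible for a
#'   fixed config + seed.
#'
#' @return An object of class `synth_config` (a validated list).
#' @seealso [generate_recording()], [generate_frap()], [protocol_epochs()]
#' @export
#' @examples
#' cfg <- synth_config(n_slices = 1, cells_per_slice = 8, n_frames = 3000)
#' cfg$base_rate
synth_config <- function(n_slices = 8,
                         cells_per_slice = c(rep(23, 6), 24, 24),
                         rosette_size = 7,
                         frame_interval = 0.1,
                         n_frames = 27000,
                         base_rate = 0.43,
                         burst_rate = 5,
                         intraburst_freq = 1.0,
                         min_isi = 0.4,
                         coupling_prob = 0.2,
                         coupling_strength = 0.55,
                         coupling_jitter = 0,
                         drug_rate_factor = 0.06 / 0.43,
                         drug_coupling_factor = 1 - 0.156,
                         washout_rate_factor = 0.5,
                         amplitude = 0.2,
                         decay_tau = 0.5,
                         noise_sd = 0.02,
                         bleach_slope = 0.005,
                         baseline_f0 = 1000,
                         pixel_size = 0.4,
                         cell_spacing = 5.6,
                         epochs = NULL,
                         seed = 1L) {
  check_number(n_slices, "n_slices", lower = 1)
  if (n_slices != round(n_slices)) stop_config("'n_slices' must be integer")
  if (!is.numeric(cells_per_slice) || any(!is.finite(cells_per_slice)) ||
      any(cells_per_slice < 1) ||
      any(cells_per_slice != round(cells_per_slice))) {
    stop_config("'cells_per_slice' must be positive integer count(s)")
  }
  if (!length(cells_per_slice) %in% c(1L, n_slices)) {
    stop_config("'cells_per_slice' must have length 1 or n_slices")
  }
  if (length(cells_per_slice) == 1L) {
    cells_per_slice <- rep(cells_per_slice, n_slices)
  }
  check_number(rosette_size, "rosette_size", lower = 1)
  check_number(frame_interval, "frame_interval", lower = 1e-6)
  check_number(n_frames, "n_frames", lower = 1)
  check_number(base_rate, "base_rate", lower = 0)
  check_number(burst_rate, "burst_rate", lower = 1e-9)
  check_number(intraburst_freq, "intraburst_freq", lower = 1e-9)
  check_number(min_isi, "min_isi", lower = 0)
  check_number(coupling_prob, "coupling_prob", lower = 0, upper = 1)
  check_number(coupling_strength, "coupling_strength", lower = 0, upper = 1)
  check_number(coupling_jitter, "coupling_jitter", lower = 0)
  check_number(drug_rate_factor, "drug_rate_factor", lower = 0)
  check_number(drug_coupling_factor, "drug_coupling_factor", lower = 0)
  check_number(washout_rate_factor, "washout_rate_factor", lower = 0)
  check_number(amplitude, "amplitude", lower = 0)
  check_number(decay_tau, "decay_tau", lower = 1e-6)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(bleach_slope, "bleach_slope", lower = 0)
  check_number(baseline_f0, "baseline_f0", lower = 1e-9)
  check_number(pixel_size, "pixel_size", lower = 1e-9)
  check_number(cell_spacing, "cell_spacing", lower = 1e-9)
  check_number(seed, "seed", allow_null = TRUE)

  if (base_rate > intraburst_freq) {
    stop_config(
      "base_rate (%g) cannot exceed intraburst_freq (%g): burst-state %s",
      base_rate, intraburst_freq, "occupancy would exceed 1"
    )
  }
  min_gap <- max(1L, as.integer(round(min_isi / frame_interval)))
  if (intraburst_freq * frame_interval * min_gap > 1) {
    stop_config(
      "min_isi (%g s) is incompatible with intraburst_freq (%g Hz)",
      min_isi, intraburst_freq
    )
  }
  # The shared parent train runs at base_rate / strength; make sure the
  # refractory structure can sustain that rate in every epoch.
  if (coupling_prob > 0 && coupling_strength > 0) {
    s_min <- min(coupling_strength,
                 adjust_strength(coupling_strength, drug_coupling_factor))
    parent_rate <- base_rate / s_min
    f_parent <- max(intraburst_freq, parent_rate)
    if (f_parent * frame_interval * min_gap > 1) {
      stop_config(
        "coupling_strength %g too small: parent rate %.3g Hz violates %s",
        coupling_strength, parent_rate, "the minimum inter-spike interval"
      )
    }
  }
  if (!is.null(epochs)) epochs <- validate_epochs(epochs, n_frames)

  structure(
    list(
      n_slices = as.integer(n_slices),
      cells_per_slice = as.integer(cells_per_slice),
      rosette_size = as.integer(rosette_size),
      frame_interval = frame_interval,
      n_frames = as.integer(n_frames),
      base_rate = base_rate,
      burst_rate = burst_rate,
      intraburst_freq = intraburst_freq,
      min_isi = min_isi,
      coupling_prob = coupling_prob,
      coupling_strength = coupling_strength,
      coupling_jitter = as.integer(round(coupling_jitter)),
      drug_rate_factor = drug_rate_factor,
      drug_coupling_factor = drug_coupling_factor,
      washout_rate_factor = washout_rate_factor,
      amplitude = amplitude,
      decay_tau = decay_tau,
      noise_sd = noise_sd,
      bleach_slope = bleach_slope,
      baseline_f0 = baseline_f0,
      pixel_size = pixel_size,
      cell_spacing = cell_spacing,
      epochs = epochs,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  %d slice(s), %d cells total, %d frames @ %g s/frame\n",
              x$n_slices, sum(x$cells_per_slice), x$n_frames,
              x$frame_interval))
  cat(sprintf("  base rate %g Hz, intraburst %g Hz, %g bursts/min\n",
              x$base_rate, x$intraburst_freq, x$burst_rate))
  cat(sprintf("  coupling: prob %g, strength %g, jitter %d frame(s)\n",
              x$coupling_prob, x$coupling_strength, x$coupling_jitter))
  cat(sprintf("  drug factors: rate %.3g, coupling %.3g\n",
              x$drug_rate_factor, x$drug_coupling_factor))
  invisible(x)
}

#' Standard three-epoch perfusion protocol
#'
#' Splits a recording into consecutive baseline / drug / washout epochs of
#' equal length. The solution label of the middle epoch controls the drug
#' effect applied by the generator (`"cbx"` applies the drug factors;
#' `"control"` leaves rates and coupling untouched, for time-matched
#' control cohorts).
#'
#' @param n_frames Total number of frames.
#' @param drug_solution Solution label of the middle epoch
#'   (default `"cbx"`).
#' @param names Epoch names (length 3).
#' @return A `data.frame` with columns `name`, `start_frame`, `end_frame`
#'   (half-open, 0-based) and `solution`.
#' @export
#' @examples
#' protocol_epochs(27000)
protocol_epochs <- function(n_frames, drug_solution = "cbx",
                            names = c("baseline", "drug", "washout")) {
  check_number(n_frames, "n_frames", lower = 3)
  stopifnot(length(names) == 3L)
  cuts <- round(seq(0, n_frames, length.out = 4))
  data.frame(
    name = as.character(names),
    start_frame = as.integer(cuts[1:3]),
    end_frame = as.integer(cuts[2:4]),
    solution = c("control", drug_solution, "washout"),
    stringsAsFactors = FALSE
  )
}

#' @noRd
validate_epochs <- function(epochs, n_frames) {
  need <- c("name", "start_frame", "end_frame", "solution")
  if (!is.data.frame(epochs) || !all(need %in% names(epochs))) {
    stop_config("'epochs' must be a data.frame with columns %s",
                paste(need, collapse = ", "))
  }
  epochs <- epochs[order(epochs$start_frame), need, drop = FALSE]
  if (any(epochs$start_frame < 0) || any(epochs$end_frame > n_frames) ||
      any(epochs$end_frame <= epochs$start_frame)) {
    stop_config("epochs must be non-empty intervals within [0, n_frames)")
  }
  if (nrow(epochs) > 1 &&
      any(epochs$start_frame[-1] < epochs$end_frame[-nrow(epochs)])) {
    stop_config("epochs must not overlap")
  }
  epochs$name <- as.character(epochs$name)
  epochs$solution <- as.character(epochs$solution)
  epochs$start_frame <- as.integer(epochs$start_frame)
  epochs$end_frame <- as.integer(epochs$end_frame)
  rownames(epochs) <- NULL
  epochs
}

# Map a solution label to (rate multiplier, coupling factor).
#' @noRd
epoch_factors <- function(solution, config) {
  sol <- tolower(solution)
  if (grepl("cbx|carbenoxolone", sol)) {
    c(rate = config$drug_rate_factor, coupling = config$drug_coupling_factor)
  } else if (grepl("washout", sol)) {
    c(rate = config$washout_rate_factor, coupling = 1)
  } else {
    c(rate = 1, coupling = 1)
  }
}

# Thinning probability that scales the expected pair Jaccard index
# JI(s) = s/(2-s) by a factor g: solve JI(s') = g * JI(s).
#' @noRd
adjust_strength <- function(s, g) {
  if (g == 1 || s == 0) return(s)
  s2 <- 2 * g * s / (2 - s + g * s)
  if (s2 > 1 || s2 < 0) {
    stop_config("drug_coupling_factor %g is unreachable for strength %g",
                g, s)
  }
  s2
}
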
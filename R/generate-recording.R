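# Synthetic recording generator: burst-modulated spiking point process,
# shared-parent coupling within rosettes, rectangle geometry and a
# fluorescence forward model.

#' Generate a synthetic ZG calcium-imaging session with ground truth
#'
#' Simulates per-cell spike trains, fluorescence traces, rosette geometry
#' and epoch structure according to a [synth_config()], and returns the
#' recording together with the generating ground truth.
#'
#' The spike process of every stream is a two-state (burst/quiescent)
#' Markov modulation; within bursts, spikes follow a discrete renewal
#' process with a hard minimum inter-spike interval and a geometric tail,
#' started from the equilibrium residual so that the expected per-cell
#' rate equals the configured rate exactly. Coupling is generated by a
#' shared parent train per coupled component (parent rate
#' `rate / coupling_strength`), which each member cell copies with
#' per-spike inclusion probability `coupling_strength`; the marginal rate
#' of every cell therefore stays at the configured rate while coupled
#' pairs share spikes. During `"cbx"` epochs the rate multiplier and the
#' coupling factor of the config are applied.
#'
#' Fluorescence is `F0 * bleach(t) * (1 + dF/F(t) + noise)` with an
#' instantaneous-rise, exponential-decay transient of amplitude
#' `amplitude` per spike and additive Gaussian noise in dF/F units.
#'
#' @param config A [synth_config()].
#' @return A list with elements
#'   \describe{
#'     \item{session}{`recording_session`: `traces` (frames x cells
#'       matrix, colnames = cell ids), `geometry` (rectangle table in
#'       pixels), `epochs`, `slices` (cell -> slice id), `frame_interval`,
#'       `pixel_size`, `metadata`.}
#'     \item{truth}{`synth_ground_truth`: per-cell 0-based
#'       `spike_frames`, `coupled_pairs` (all pairs sharing a parent
#'       train), sampled `edges`, `components`, and the per-epoch rate
#'       multipliers / coupling factors actually applied.}
#'   }
#' @export
#' @examples
#' out <- generate_recording(synth_config(n_slices = 1,
#'                                        cells_per_slice = 6,
#'                                        n_frames = 2000, seed = 7))
#' dim(out$session$traces)
#' length(out$truth$spike_frames)
generate_recording <- function(config) {
  if (!inherits(config, "synth_config")) {
    stop_config("'config' must be a synth_config object")
  }
  with_seed(config$seed, generate_recording_impl(config))
}

#' @noRd
generate_recording_impl <- function(config) {
  dt <- config$frame_interval
  n_frames <- config$n_frames
  epochs <- config$epochs
  if (is.null(epochs)) {
    epochs <- data.frame(
      name = "baseline", start_frame = 0L,
      end_frame = as.integer(n_frames), solution = "control",
      stringsAsFactors = FALSE
    )
  }
  # Frames not covered by any epoch still need spikes; extend coverage by
  # carrying the preceding epoch's condition into gaps.
  segs <- epoch_segments(epochs, n_frames)
  factors <- t(vapply(segs$solution, epoch_factors, numeric(2),
                      config = config))

  min_gap <- max(1L, as.integer(round(config$min_isi / dt)))
  burst_len_s <- 60 * (config$base_rate / config$intraburst_freq) /
    config$burst_rate

  layout <- build_layout(config)
  ids <- layout$geometry$cell_id
  n_cells <- length(ids)

  spikes <- stats::setNames(vector("list", n_cells), ids)
  for (i in seq_len(n_cells)) spikes[[i]] <- integer(0)

  for (grp in layout$groups) {
    members <- grp$members
    coupled <- length(members) > 1L
    for (k in seq_along(segs$start)) {
      seg_len <- segs$end[k] - segs$start[k]
      rate <- config$base_rate * factors[k, "rate"]
      if (rate <= 0 || seg_len <= 0) next
      if (coupled) {
        s_eff <- adjust_strength(config$coupling_strength,
                                 factors[k, "coupling"])
        if (s_eff <= 0) { # fall back to independent streams
          for (id in members) {
            fr <- sim_burst_stream(seg_len, rate, config$intraburst_freq,
                                   burst_len_s, dt, min_gap)
            spikes[[id]] <- c(spikes[[id]], fr + segs$start[k])
          }
          next
        }
        parent_rate <- rate / s_eff
        parent <- sim_burst_stream(
          seg_len, parent_rate,
          max(config$intraburst_freq, parent_rate),
          burst_len_s, dt, min_gap
        )
        for (id in members) {
          keep <- parent[stats::runif(length(parent)) < s_eff]
          if (config$coupling_jitter > 0 && length(keep)) {
            j <- config$coupling_jitter
            keep <- keep + sample.int(2L * j + 1L, length(keep),
                                      replace = TRUE) - j - 1L
            keep <- sort(unique(pmin(pmax(keep, 0L), seg_len - 1L)))
          }
          spikes[[id]] <- c(spikes[[id]], keep + segs$start[k])
        }
      } else {
        for (id in members) {
          fr <- sim_burst_stream(seg_len, rate, config$intraburst_freq,
                                 burst_len_s, dt, min_gap)
          spikes[[id]] <- c(spikes[[id]], fr + segs$start[k])
        }
      }
    }
  }
  spikes <- lapply(spikes, function(x) sort(unique(as.integer(x))))

  traces <- matrix(0, nrow = n_frames, ncol = n_cells,
                   dimnames = list(NULL, ids))
  bleach <- exp(-config$bleach_slope * (seq_len(n_frames) - 1) * dt / 60)
  for (i in seq_len(n_cells)) {
    traces[, i] <- fluorescence_from_spikes(
      spikes[[i]], n_frames,
      amplitude = config$amplitude, decay_tau = config$decay_tau,
      frame_interval = dt, f0 = config$baseline_f0,
      noise_sd = config$noise_sd, bleach = bleach
    )
  }

  session <- structure(
    list(
      traces = traces,
      geometry = layout$geometry,
      epochs = epochs,
      slices = layout$slices,
      frame_interval = dt,
      pixel_size = config$pixel_size,
      metadata = list(config = config)
    ),
    class = "recording_session"
  )
  truth <- structure(
    list(
      spike_frames = spikes,
      coupled_pairs = layout$coupled_pairs,
      edges = layout$edges,
      components = layout$components,
      epoch_conditions = data.frame(
        name = segs$name, start_frame = segs$start, end_frame = segs$end,
        solution = segs$solution,
        rate_multiplier = factors[, "rate"],
        coupling_factor = factors[, "coupling"],
        stringsAsFactors = FALSE
      ),
      frame_interval = dt,
      n_frames = as.integer(n_frames)
    ),
    class = "synth_ground_truth"
  )
  list(session = session, truth = truth)
}

#' @export
print.recording_session <- function(x, ...) {
  cat("<recording_session>\n")
  cat(sprintf("  %d cells, %d frames @ %g s, %d slice(s)\n",
              ncol(x$traces), nrow(x$traces), x$frame_interval,
              length(unique(x$slices))))
  cat(sprintf("  epochs: %s\n",
              paste(sprintf("%s[%d,%d)", x$epochs$name,
                            x$epochs$start_frame, x$epochs$end_frame),
                    collapse = " ")))
  invisible(x)
}

#' @export
print.synth_ground_truth <- function(x, ...) {
  cat("<synth_ground_truth>\n")
  cat(sprintf("  %d cells, %d true spikes, %d coupled pair(s)\n",
              length(x$spike_frames),
              sum(lengths(x$spike_frames)),
              nrow(x$coupled_pairs)))
  invisible(x)
}

# ---- point process -------------------------------------------------------

# Cover [0, n_frames) with condition segments; frames between annotated
# epochs inherit the previous epoch's solution (or the first one's).
#' @noRd
epoch_segments <- function(epochs, n_frames) {
  starts <- integer(0); ends <- integer(0)
  names_ <- character(0); sols <- character(0)
  cursor <- 0L
  for (i in seq_len(nrow(epochs))) {
    if (epochs$start_frame[i] > cursor) {
      starts <- c(starts, cursor); ends <- c(ends, epochs$start_frame[i])
      names_ <- c(names_, paste0("gap_", i))
      sols <- c(sols, if (i == 1) epochs$solution[1] else
        epochs$solution[i - 1])
    }
    starts <- c(starts, epochs$start_frame[i])
    ends <- c(ends, epochs$end_frame[i])
    names_ <- c(names_, epochs$name[i])
    sols <- c(sols, epochs$solution[i])
    cursor <- epochs$end_frame[i]
  }
  if (cursor < n_frames) {
    starts <- c(starts, cursor); ends <- c(ends, as.integer(n_frames))
    names_ <- c(names_, "tail")
    sols <- c(sols, epochs$solution[nrow(epochs)])
  }
  list(start = starts, end = ends, name = names_, solution = sols)
}

#' Simulate one burst-modulated spike stream
#'
#' Internal point-process core: a stationary two-state Markov chain
#' (burst/quiescent) gates a discrete renewal process with minimum gap
#' `min_gap` frames and geometric tail, started at the equilibrium
#' residual inside each burst. Expected overall rate equals `rate_hz`.
#'
#' @return 0-based spike frames within `[0, n_frames)`.
#' @noRd
sim_burst_stream <- function(n_frames, rate_hz, intraburst_hz,
                             burst_len_s, dt, min_gap) {
  if (n_frames < 1L || rate_hz <= 0) return(integer(0))
  f_burst <- rate_hz / intraburst_hz
  if (f_burst > 1) { # saturate: continuous renewal at the target rate
    intraburst_hz <- rate_hz
    f_burst <- 1
  }
  m <- 1 / (intraburst_hz * dt)            # mean ISI in frames
  d <- min_gap - 1L                        # ISI support is d+1, d+2, ...
  if (m < min_gap) {
    stop_config("intraburst rate %g Hz violates the minimum ISI", intraburst_hz)
  }
  p <- if (m - d <= 1) 1 else 1 / (m - d)  # geometric tail parameter

  if (f_burst >= 1) {
    runs <- data.frame(start = 0L, end = as.integer(n_frames))
  } else {
    lb <- max(1, burst_len_s / dt)
    lq <- max(1, lb * (1 - f_burst) / f_burst)
    runs <- burst_runs(n_frames, lb, lq, f_burst)
    if (nrow(runs) == 0L) return(integer(0))
  }

  out <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    a <- runs$start[i]; b <- runs$end[i]
    len <- b - a
    first <- eq_residual(1L, p, d)           # equilibrium start
    if (first > len) next
    n_max <- ceiling(len / min_gap) + 8L
    isis <- d + 1L + stats::rgeom(n_max, p)
    t_loc <- first + c(0L, cumsum(isis))
    t_loc <- t_loc[t_loc <= len]
    out[[i]] <- a + t_loc - 1L               # 0-based frames
  }
  as.integer(sort(unlist(out)))
}

# Alternating geometric run lengths for the burst gate; returns half-open
# 0-based [start, end) burst intervals covering [0, n_frames).
#' @noRd
burst_runs <- function(n_frames, mean_burst, mean_quiet, f_burst) {
  state <- stats::runif(1) < f_burst
  starts <- integer(0); ends <- integer(0)
  pos <- 0L
  pb <- 1 / mean_burst
  pq <- 1 / mean_quiet
  while (pos < n_frames) {
    len <- 1L + stats::rgeom(1L, if (state) pb else pq)
    if (state) {
      starts <- c(starts, pos)
      ends <- c(ends, min(pos + len, n_frames))
    }
    pos <- pos + len
    state <- !state
  }
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

# Equilibrium residual of the discrete renewal ISI (d + 1 + Geom(p)):
# P(R = r) = P(ISI >= r) / E[ISI], sampled by closed-form inverse CDF.
#' @noRd
eq_residual <- function(n, p, d) {
  m <- d + 1 / p
  q <- 1 - p
  x <- stats::runif(n) * m
  r <- ceiling(x)
  if (q > 0) {
    idx <- x > d + 1
    if (any(idx)) {
      arg <- pmax(1 - p * (x[idx] - d - 1) / q, .Machine$double.xmin)
      r[idx] <- d + 1 + ceiling(log(arg) / log(q))
    }
  }
  pmax(as.integer(r), 1L)
}

# ---- forward model -------------------------------------------------------

#' Fluorescence forward model
#'
#' Converts a spike train into a fluorescence trace: each spike adds an
#' instantaneous rise of `amplitude` (dF/F units) that decays
#' exponentially with `decay_tau`; the resulting dF/F is scaled onto a
#' resting level `f0`, multiplied by a bleaching drift, and Gaussian
#' noise (SD `noise_sd` in dF/F units) is added.
#'
#' @param spike_frames 0-based spike frames.
#' @param n_frames Trace length.
#' @param amplitude dF/F per spike.
#' @param decay_tau Decay time constant, seconds.
#' @param frame_interval Seconds per frame.
#' @param f0 Resting fluorescence, a.u.
#' @param noise_sd Gaussian noise SD in dF/F units (0 for noise-free).
#' @param bleach Either a scalar bleaching rate in fraction/min (applied
#'   as `exp(-rate * t_min)`) or a precomputed length-`n_frames`
#'   multiplicative drift vector.
#' @return Numeric vector of fluorescence intensities (a.u.).
#' @export
#' @examples
#' f <- fluorescence_from_spikes(c(100, 200, 300), 500, noise_sd = 0)
#' which(diff(f) > 50) # rise frames
fluorescence_from_spikes <- function(spike_frames, n_frames,
                                     amplitude = 0.2, decay_tau = 0.5,
                                     frame_interval = 0.1, f0 = 1000,
                                     noise_sd = 0, bleach = 0) {
  n_frames <- as.integer(n_frames)
  stopifnot(n_frames >= 1L)
  if (length(spike_frames) &&
      (min(spike_frames) < 0 || max(spike_frames) >= n_frames)) {
    stop_config("spike frames must lie within [0, n_frames)")
  }
  impulse <- numeric(n_frames)
  if (length(spike_frames)) {
    tab <- table(spike_frames + 1L)
    impulse[as.integer(names(tab))] <- amplitude * as.integer(tab)
  }
  alpha <- exp(-frame_interval / decay_tau)
  dff <- as.numeric(stats::filter(impulse, alpha, method = "recursive"))
  if (length(bleach) == 1L) {
    bleach <- exp(-bleach * (seq_len(n_frames) - 1) * frame_interval / 60)
  } else if (length(bleach) != n_frames) {
    stop_config("'bleach' must be a scalar rate or length n_frames")
  }
  noise <- if (noise_sd > 0) stats::rnorm(n_frames, 0, noise_sd) else 0
  f0 * bleach * (1 + dff + noise)
}

# ---- geometry / coupling layout -----------------------------------------

# Rosette ring layout per slice plus sampled coupling graph.
#' @noRd
build_layout <- function(config) {
  spacing <- config$cell_spacing
  px <- config$pixel_size
  half_um <- 0.45 * spacing                # cells nearly touching
  pitch <- 12 * spacing                    # rosette grid pitch, um

  geometry <- NULL
  slices <- character(0)
  groups <- list()
  edges_a <- character(0); edges_b <- character(0)
  comp_list <- list()
  pair_a <- character(0); pair_b <- character(0)

  for (s in seq_len(config$n_slices)) {
    n_cells <- config$cells_per_slice[s]
    sizes <- rep(config$rosette_size,
                 n_cells %/% config$rosette_size)
    if (n_cells %% config$rosette_size > 0) {
      sizes <- c(sizes, n_cells %% config$rosette_size)
    }
    n_ros <- length(sizes)
    cols <- ceiling(sqrt(n_ros))
    cell_idx <- 0L
    for (r in seq_len(n_ros)) {
      k <- sizes[r]
      cx0 <- ((r - 1) %% cols) * pitch + pitch / 2
      cy0 <- ((r - 1) %/% cols) * pitch + pitch / 2
      if (k == 1L) {
        cx <- cx0; cy <- cy0
      } else {
        radius <- spacing / (2 * sin(pi / k))
        ang <- 2 * pi * (seq_len(k) - 1) / k
        cx <- cx0 + radius * cos(ang)
        cy <- cy0 + radius * sin(ang)
      }
      ids <- sprintf("s%02d_c%03d", s, cell_idx + seq_len(k))
      cell_idx <- cell_idx + k
      geometry <- rbind(geometry, data.frame(
        cell_id = ids,
        x_min = cx / px - half_um / px, y_min = cy / px - half_um / px,
        x_max = cx / px + half_um / px, y_max = cy / px + half_um / px,
        stringsAsFactors = FALSE
      ))
      slices <- c(slices, stats::setNames(rep(sprintf("slice%02d", s), k),
                                          ids))

      # ring-neighbour candidate edges, each kept with coupling_prob
      if (k >= 2L && config$coupling_prob > 0) {
        ea <- seq_len(k)
        eb <- c(seq_len(k)[-1], 1L)
        if (k == 2L) { ea <- 1L; eb <- 2L }
        keep <- stats::runif(length(ea)) < config$coupling_prob
        ea <- ea[keep]; eb <- eb[keep]
      } else {
        ea <- integer(0); eb <- integer(0)
      }
      comp <- union_find(k, ea, eb)
      for (cmp in split(seq_len(k), comp)) {
        groups[[length(groups) + 1L]] <- list(members = ids[cmp])
        if (length(cmp) > 1L) {
          comp_list[[length(comp_list) + 1L]] <- ids[cmp]
          prs <- utils::combn(sort(ids[cmp]), 2)
          pair_a <- c(pair_a, prs[1, ]); pair_b <- c(pair_b, prs[2, ])
        }
      }
      if (length(ea)) {
        edges_a <- c(edges_a, pmin(ids[ea], ids[eb]))
        edges_b <- c(edges_b, pmax(ids[ea], ids[eb]))
      }
    }
  }
  rownames(geometry) <- NULL
  list(
    geometry = geometry,
    slices = slices,
    groups = groups,
    edges = data.frame(cell_a = edges_a, cell_b = edges_b,
                       stringsAsFactors = FALSE),
    components = comp_list,
    coupled_pairs = data.frame(cell_a = pair_a, cell_b = pair_b,
                               stringsAsFactors = FALSE)
  )
}

#' @noRd
union_find <- function(n, ea, eb) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (j in seq_along(ea)) {
    ra <- find(ea[j]); rb <- find(eb[j])
    if (ra != rb) parent[rb] <- ra
  }
  vapply(seq_len(n), find, integer(1))
}

#' Ground-truth spike trains as `spike_train` objects
#'
#' Convenience accessor converting a generator ground truth into the
#' spike-train representation used by the synchrony module.
#'
#' @param truth A `synth_ground_truth` from [generate_recording()].
#' @return Named list of [spike_train()] objects.
#' @export
ground_truth_trains <- function(truth) {
  if (!inherits(truth, "synth_ground_truth")) {
    stop_config("'truth' must be a synth_ground_truth")
  }
  out <- lapply(names(truth$spike_frames), function(id) {
    spike_train(id, truth$spike_frames[[id]], truth$n_frames,
                truth$frame_interval)
  })
  stats::setNames(out, names(truth$spike_frames))
}
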
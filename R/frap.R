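# FRAP: fluorescence recovery after photobleaching. Recovery of a
# bleached cell's signal reports dye influx from coupled neighbours.

#' Construct a FRAP trace
#'
#' @param times Time stamps, seconds (strictly increasing).
#' @param intensities Fluorescence values, a.u.
#' @param bleach_index 0-based index of the bleach frame (the first
#'   post-bleach sample); must be interior to the trace.
#' @return A `frap_trace` list.
#' @export
frap_trace <- function(times, intensities, bleach_index) {
  if (length(times) != length(intensities) || length(times) < 4L) {
    stop_config("times and intensities must match and hold >= 4 samples")
  }
  if (any(!is.finite(times)) || any(!is.finite(intensities)) ||
      any(diff(times) <= 0)) {
    stop_config("times must be finite and strictly increasing")
  }
  check_number(bleach_index, "bleach_index",
               lower = 1, upper = length(times) - 2)
  structure(
    list(times = as.numeric(times), intensities = as.numeric(intensities),
         bleach_index = as.integer(bleach_index)),
    class = "frap_trace"
  )
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("<frap_trace: %d samples over %.1f s, bleach at %.1f s>\n",
              length(x$times), diff(range(x$times)),
              x$times[x$bleach_index + 1L]))
  invisible(x)
}

#' Generate a synthetic FRAP trace
#'
#' Pre-bleach plateau at 1, instantaneous drop to `bleach_depth` at the
#' bleach frame, single-exponential recovery toward
#' `bleach_depth + mobile_fraction * (1 - bleach_depth)`, plus Gaussian
#' noise. Seed-deterministic via `config$seed`.
#'
#' @param mobile_fraction Fraction of the bleached signal that recovers
#'   (in `[0, 1]`).
#' @param tau Recovery time constant, seconds (> 0).
#' @param bleach_depth Post-bleach floor as a fraction of the pre-bleach
#'   level (default 0.1: the signal drops to ~10%).
#' @param config A [synth_config()] supplying `frame_interval` and
#'   `seed`.
#' @param noise_sd Gaussian noise SD relative to the pre-bleach level
#'   (default 0.05, i.e. SNR 20; 0 for noise-free).
#' @param pre_duration Seconds recorded before the bleach (default 10).
#' @param duration Total trace length, seconds (default 80).
#' @return A [frap_trace()].
#' @export
#' @examples
#' tr <- generate_frap(0.35, tau = 20, config = synth_config(seed = 3),
#'                     noise_sd = 0)
#' frap_recovery(tr)
generate_frap <- function(mobile_fraction, tau, bleach_depth = 0.1,
                          config = synth_config(), noise_sd = 0.05,
                          pre_duration = 10, duration = 80) {
  check_number(mobile_fraction, "mobile_fraction", lower = 0, upper = 1)
  check_number(tau, "tau", lower = 1e-9)
  check_number(bleach_depth, "bleach_depth", lower = 0, upper = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(pre_duration, "pre_duration", lower = 1e-9)
  check_number(duration, "duration", lower = 2 * pre_duration)
  dt <- config$frame_interval
  times <- seq(0, duration, by = dt)
  n <- length(times)
  bleach_index <- as.integer(ceiling(pre_duration / dt))
  plateau <- bleach_depth + mobile_fraction * (1 - bleach_depth)
  f <- numeric(n)
  pre <- seq_len(bleach_index)
  f[pre] <- 1
  post <- (bleach_index + 1L):n
  t_post <- times[post] - times[bleach_index + 1L]
  f[post] <- plateau - (plateau - bleach_depth) * exp(-t_post / tau)
  if (noise_sd > 0) {
    f <- f + with_seed(config$seed, stats::rnorm(n, 0, noise_sd))
  }
  frap_trace(times, f, bleach_index)
}

#' Fractional fluorescence recovery of a FRAP trace
#'
#' `F_pre` is the mean over `pre_window` seconds before the bleach;
#' `F_post` is the minimum of a lightly smoothed segment within
#' `post_search` seconds after the bleach (smoothing keeps shot noise
#' from deflating the floor); `F_end` is the mean over the final
#' `end_window` seconds. Recovery is
#' `(F_end - F_post) / (F_pre - F_post)` -- 0 for no recovery, 1 for a
#' return to the pre-bleach level. The value is reported unclipped and
#' is invariant to affine rescaling of the whole trace.
#'
#' @param trace A [frap_trace()].
#' @param pre_window Pre-bleach averaging window, seconds (default 5).
#' @param post_search Post-bleach window searched for the floor,
#'   seconds (default 1).
#' @param end_window End-of-trace averaging window, seconds (default 10).
#' @param smooth Boxcar width in samples for the floor search (default
#'   7, i.e. 0.7 s at 10 frames/s; 1 disables smoothing). Smoothing
#'   keeps shot noise from biasing the minimum-based floor downward.
#' @return Recovery fraction.
#' @export
frap_recovery <- function(trace, pre_window = 5, post_search = 1,
                          end_window = 10, smooth = 7) {
  stopifnot(inherits(trace, "frap_trace"))
  check_number(pre_window, "pre_window", lower = 1e-9)
  check_number(post_search, "post_search", lower = 1e-9)
  check_number(end_window, "end_window", lower = 1e-9)
  t <- trace$times; f <- trace$intensities
  bi <- trace$bleach_index + 1L  # 1-based index of first post-bleach frame
  t_bleach <- t[bi]
  pre_idx <- which(t < t_bleach & t >= t_bleach - pre_window)
  if (!length(pre_idx)) stop_config("pre_window holds no samples")
  f_pre <- mean(f[pre_idx])
  post_idx <- which(t >= t_bleach & t < t_bleach + post_search)
  if (!length(post_idx)) stop_config("post_search holds no samples")
  seg <- f[post_idx]
  if (smooth > 1 && length(seg) >= smooth) {
    seg <- as.numeric(stats::filter(seg, rep(1 / smooth, smooth),
                                    sides = 2))
    seg <- seg[!is.na(seg)]
  }
  f_post <- min(seg)
  end_idx <- which(t > max(t) - end_window)
  f_end <- mean(f[end_idx])
  if (f_pre <= f_post) {
    stop_config("no bleach detected: pre-bleach level <= post-bleach floor")
  }
  (f_end - f_post) / (f_pre - f_post)
}

#' Group summary of FRAP recoveries
#'
#' @param values Recovery fractions of a treatment group.
#' @param label Group label.
#' @return A `group_stats` list: `label`, `values`, `mean`, `sd`, `n`.
#' @export
group_stats <- function(values, label = "group") {
  values <- as.numeric(values)
  if (!length(values) || any(!is.finite(values))) {
    stop_config("group values must be finite and non-empty")
  }
  structure(
    list(label = as.character(label), values = values,
         mean = mean(values),
         sd = if (length(values) > 1L) stats::sd(values) else 0,
         n = length(values)),
    class = "group_stats"
  )
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("<group_stats %s: mean %.3g, sd %.3g, n %d>\n",
              x$label, x$mean, x$sd, x$n))
  invisible(x)
}

#' Two-sample Student's t-test from group summaries
#'
#' Pooled-variance (equal-variance) Student's t by default, computable
#' directly from `(mean, sd, n)` summaries -- so printed group tables
#' can be tested without raw values. Welch's unequal-variance form is
#' available via `var_equal = FALSE`.
#'
#' @param a,b [group_stats()] objects (or lists with `mean`, `sd`, `n`).
#' @param var_equal Use the pooled-variance Student's t (default TRUE).
#' @return A list `t`, `df`, `p` (two-sided), `method`.
#' @export
#' @examples
#' two_sample_t(group_stats(c(1, 2, 3)), group_stats(c(2, 3, 4)))
two_sample_t <- function(a, b, var_equal = TRUE) {
  for (g in list(a, b)) {
    if (!all(c("mean", "sd", "n") %in% names(g))) {
      stop_config("groups need mean, sd and n")
    }
    if (g$n < 2L) stop_config("each group needs n >= 2")
  }
  if (var_equal) {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    method <- "Student's t (pooled variance)"
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
    method <- "Welch's t"
  }
  if (se == 0) {
    tt <- if (a$mean == b$mean) 0 else sign(a$mean - b$mean) * Inf
  } else {
    tt <- (a$mean - b$mean) / se
  }
  p <- if (is.infinite(tt)) 0 else 2 * stats::pt(-abs(tt), df)
  list(t = tt, df = df, p = p, method = method)
}
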
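# Before/during drug comparison of spiking and synchrony.

#' Per-connection JI change between baseline and drug epochs
#'
#' Restricted to connections that were coupled at baseline (baseline JI
#' strictly above the threshold), computes per-connection absolute
#' (`JI_drug - JI_baseline`) and relative
#' (`100 * (JI_drug - JI_baseline) / JI_baseline`) changes, with mean
#' and bootstrap CI over connections for both modes. Connections whose
#' drug-epoch JI is undefined (both trains empty) are excluded and
#' counted in `n_excluded`.
#'
#' @param baseline,drug `synchrony_result`s for the two epochs, computed
#'   over the same cells.
#' @param mode Primary change mode, `"relative"` (percent, default) or
#'   `"absolute"`; both are always computed, `mode` selects which one
#'   `summary` refers to.
#' @param threshold Baseline coupling cutoff (default: baseline result's
#'   threshold).
#' @param n_resamples,confidence,seed Bootstrap settings.
#' @param breaks Histogram breaks for the absolute-change table.
#' @return An `epoch_comparison`: `connections` (per-connection table),
#'   `summary` (mean + CI of the selected mode), `summary_absolute`,
#'   `summary_relative`, `histogram` (absolute changes), `mode`,
#'   `threshold`, `n_excluded`.
#' @export
ji_change <- function(baseline, drug, mode = c("relative", "absolute"),
                      threshold = baseline$threshold,
                      n_resamples = 10000, confidence = 0.95,
                      seed = NULL, breaks = seq(-1, 1, by = 0.05)) {
  stopifnot(inherits(baseline, "synchrony_result"),
            inherits(drug, "synchrony_result"))
  mode <- match.arg(mode)
  if (!identical(sort(baseline$cell_ids), sort(drug$cell_ids))) {
    stop_config("baseline and drug results cover different cells")
  }
  base <- classify_coupled(baseline, threshold)
  pairs <- base$coupled_pairs
  if (!nrow(pairs)) stop_config("no coupled connections at baseline")
  ji_d <- drug$ji[cbind(pairs$cell_a, pairs$cell_b)]
  ok <- !is.na(ji_d)
  con <- data.frame(
    cell_a = pairs$cell_a[ok], cell_b = pairs$cell_b[ok],
    ji_baseline = pairs$ji[ok], ji_drug = ji_d[ok],
    stringsAsFactors = FALSE
  )
  con$change_abs <- con$ji_drug - con$ji_baseline
  con$change_rel_pct <- 100 * con$change_abs / con$ji_baseline

  mk_summary <- function(v) {
    list(mean = mean(v),
         ci = if (length(v)) bootstrap_ci(v, n_resamples, confidence, seed)
              else NULL,
         n = length(v))
  }
  s_abs <- mk_summary(con$change_abs)
  s_rel <- mk_summary(con$change_rel_pct)
  h <- graphics::hist(pmin(pmax(con$change_abs, min(breaks)), max(breaks)),
                      breaks = breaks, plot = FALSE)
  structure(
    list(
      connections = con,
      summary = if (mode == "relative") s_rel else s_abs,
      summary_absolute = s_abs,
      summary_relative = s_rel,
      histogram = data.frame(mid = h$mids, count = h$counts),
      mode = mode, threshold = threshold,
      n_excluded = sum(!ok)
    ),
    class = "epoch_comparison"
  )
}

#' @export
print.epoch_comparison <- function(x, ...) {
  cat("<epoch_comparison>\n")
  cat(sprintf("  %d baseline-coupled connection(s) (threshold %g), %d excluded\n",
              nrow(x$connections), x$threshold, x$n_excluded))
  unit <- if (x$mode == "relative") "%" else ""
  cat(sprintf("  mean %s change: %.3g%s", x$mode, x$summary$mean, unit))
  if (!is.null(x$summary$ci)) {
    cat(sprintf(" (95%% CI %.3g to %.3g)", x$summary$ci$lower,
                x$summary$ci$upper))
  }
  cat("\n")
  invisible(x)
}

#' Side-by-side comparison of treated and control JI changes
#'
#' @param treated,control `epoch_comparison` objects computed with the
#'   same mode and threshold.
#' @return A list with a `table` (`data.frame` of group, mean, CI, n)
#'   and `ci_overlap` (TRUE when the two confidence intervals overlap).
#' @export
compare_groups <- function(treated, control) {
  stopifnot(inherits(treated, "epoch_comparison"),
            inherits(control, "epoch_comparison"))
  if (!identical(treated$mode, control$mode) ||
      !isTRUE(all.equal(treated$threshold, control$threshold))) {
    stop_config("groups must use the same change mode and threshold")
  }
  row <- function(label, x) {
    data.frame(group = label, mean = x$summary$mean,
               ci_lower = if (is.null(x$summary$ci)) NA_real_
                          else x$summary$ci$lower,
               ci_upper = if (is.null(x$summary$ci)) NA_real_
                          else x$summary$ci$upper,
               n = x$summary$n, stringsAsFactors = FALSE)
  }
  tab <- rbind(row("treated", treated), row("control", control))
  overlap <- !(tab$ci_upper[1] < tab$ci_lower[2] ||
                 tab$ci_upper[2] < tab$ci_lower[1])
  list(table = tab, ci_overlap = isTRUE(overlap), mode = treated$mode)
}

#' Per-cell spike rates for every epoch of a session
#'
#' @param trains Named list of [spike_train()] objects (full recording).
#' @param epochs Epoch table (`name`, `start_frame`, `end_frame`, ...).
#' @param discard_lead Seconds discarded after each solution change
#'   (default 60).
#' @return A `data.frame` with one row per cell x epoch: `cell_id`,
#'   `epoch`, `rate_hz`.
#' @export
session_epoch_rates <- function(trains, epochs, discard_lead = 60) {
  out <- lapply(seq_len(nrow(epochs)), function(k) {
    ep <- epochs[k, ]
    rates <- vapply(trains, function(tr) {
      epoch_spike_rate(tr, ep, discard_lead)
    }, numeric(1))
    data.frame(cell_id = names(rates), epoch = ep$name, rate_hz = rates,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
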
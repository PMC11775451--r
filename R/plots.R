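# Quick-look base-graphics plots for interactive QC.

#' Raster plot of spike trains
#'
#' One row per cell, a tick per spike; epoch boundaries are drawn as
#' dashed vertical lines when an epoch table is supplied.
#'
#' @param trains Named list of [spike_train()] objects.
#' @param epochs Optional epoch `data.frame`.
#' @param max_cells Plot at most this many cells (default 30).
#' @export
plot_raster <- function(trains, epochs = NULL, max_cells = 30) {
  trains <- trains[seq_len(min(length(trains), max_cells))]
  n <- length(trains)
  dt <- trains[[1]]$frame_interval
  t_max <- trains[[1]]$n_frames * dt
  graphics::plot(NA, xlim = c(0, t_max), ylim = c(0.5, n + 0.5),
                 xlab = "time (s)", ylab = "cell", yaxt = "n")
  graphics::axis(2, at = seq_len(n),
                 labels = vapply(trains, `[[`, "", "cell_id"),
                 las = 2, cex.axis = 0.6)
  for (i in seq_len(n)) {
    tt <- trains[[i]]$frames * dt
    if (length(tt)) {
      graphics::segments(tt, i - 0.4, tt, i + 0.4)
    }
  }
  if (!is.null(epochs)) {
    graphics::abline(v = epochs$start_frame * dt, lty = 2,
                     col = "grey50")
  }
  invisible(NULL)
}

#' JI against inter-cell distance
#'
#' Scatter of every within-slice connection's Jaccard index against its
#' center-to-center distance, with the coupling threshold drawn as a
#' horizontal line.
#'
#' @param result A `synchrony_result` carrying distances.
#' @export
plot_ji_distance <- function(result) {
  stopifnot(inherits(result, "synchrony_result"))
  if (is.null(result$distances)) {
    stop_config("result carries no distances")
  }
  ut <- upper.tri(result$ji)
  ok <- ut & !is.na(result$ji)
  graphics::plot(result$distances[ok], result$ji[ok],
                 xlab = "distance (um)", ylab = "Jaccard index",
                 pch = 16, cex = 0.6,
                 col = grDevices::adjustcolor("black", 0.4))
  graphics::abline(h = result$threshold, col = "red")
  invisible(NULL)
}
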
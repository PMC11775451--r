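# Spike-train container and frame-grid utilities. Frames are 0-based and
# epochs half-open [start, end) throughout.

#' Construct a spike train
#'
#' @param cell_id Cell identifier.
#' @param frames 0-based spike frame indices (any order; duplicates are
#'   an error).
#' @param n_frames Length of the underlying frame grid.
#' @param frame_interval Seconds per frame.
#' @return Object of class `spike_train` with sorted `frames`.
#' @export
#' @examples
#' spike_train("c1", c(3, 10, 42), n_frames = 100, frame_interval = 0.1)
spike_train <- function(cell_id, frames, n_frames, frame_interval = 0.1) {
  check_number(n_frames, "n_frames", lower = 1)
  check_number(frame_interval, "frame_interval", lower = 1e-9)
  frames <- as.integer(frames)
  if (anyNA(frames)) stop_config("spike frames must be finite")
  if (length(frames)) {
    if (min(frames) < 0 || max(frames) >= n_frames) {
      stop_config("spike frames must lie in [0, n_frames)")
    }
    if (anyDuplicated(frames)) stop_config("duplicate spike frames")
    frames <- sort(frames)
  }
  structure(
    list(cell_id = as.character(cell_id), frames = frames,
         n_frames = as.integer(n_frames),
         frame_interval = frame_interval),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train %s: %d spikes / %d frames (%.1f s)>\n",
              x$cell_id, length(x$frames), x$n_frames,
              x$n_frames * x$frame_interval))
  invisible(x)
}

#' Binary per-frame representation of a spike train
#'
#' @param train A [spike_train()].
#' @return Integer vector of length `n_frames` with 1 at spike frames.
#' @export
#' @examples
#' binarize(spike_train("c", c(0, 4), 5))
binarize <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  v <- integer(train$n_frames)
  v[train$frames + 1L] <- 1L
  v
}

#' Recover spike frames from a binary vector
#'
#' Inverse of [binarize()].
#' @param x Binary (0/1) vector.
#' @return 0-based frame indices of the nonzero entries.
#' @export
spike_frames_from_binary <- function(x) {
  which(x != 0) - 1L
}

#' Restrict a spike train to an epoch, discarding the solution-exchange
#' lead-in
#'
#' Keeps spikes in `[start + discard_lead, end)` and re-indexes them to
#' epoch-local frames. The first `discard_lead` seconds after a solution
#' change are excluded so that analysis only sees fully exchanged bath
#' solution.
#'
#' @param train A [spike_train()].
#' @param epoch Either a length-2 numeric `c(start_frame, end_frame)`
#'   (half-open, 0-based) or a one-row epoch `data.frame` with
#'   `start_frame` / `end_frame` columns.
#' @param discard_lead Seconds discarded at the epoch start (default 60).
#' @return A `spike_train` on the retained local frame grid.
#' @export
#' @examples
#' tr <- spike_train("c", c(10, 700), 1200, 0.1)
#' restrict_to_epoch(tr, c(0, 1200))$frames  # 700 - 600 = 100
restrict_to_epoch <- function(train, epoch, discard_lead = 60) {
  stopifnot(inherits(train, "spike_train"))
  check_number(discard_lead, "discard_lead", lower = 0)
  if (is.data.frame(epoch)) {
    stopifnot(nrow(epoch) == 1L)
    epoch <- c(epoch$start_frame, epoch$end_frame)
  }
  stopifnot(length(epoch) == 2L)
  start <- as.integer(epoch[1]); end <- as.integer(epoch[2])
  if (start < 0 || end > train$n_frames || end <= start) {
    stop_config("epoch [%d, %d) outside recording of %d frames",
                start, end, train$n_frames)
  }
  lead <- as.integer(round(discard_lead / train$frame_interval))
  lo <- start + lead
  if (lo >= end) {
    stop_config("discard_lead (%g s) consumes the whole epoch", discard_lead)
  }
  keep <- train$frames[train$frames >= lo & train$frames < end]
  spike_train(train$cell_id, keep - lo, end - lo, train$frame_interval)
}

#' Spike rate of a train within an epoch
#'
#' Spike count divided by epoch duration in seconds, after
#' [restrict_to_epoch()] (pass `epoch = NULL` to rate the train as-is).
#'
#' @param train A [spike_train()].
#' @param epoch Optional epoch (see [restrict_to_epoch()]).
#' @param discard_lead Seconds discarded at the epoch start (default 60;
#'   ignored when `epoch` is `NULL`).
#' @return Spikes per second.
#' @export
#' @examples
#' tr <- spike_train("c", seq(0, 590, by = 20), 600, 0.1)
#' epoch_spike_rate(tr, NULL)
epoch_spike_rate <- function(train, epoch = NULL, discard_lead = 60) {
  stopifnot(inherits(train, "spike_train"))
  if (!is.null(epoch)) {
    train <- restrict_to_epoch(train, epoch, discard_lead)
  }
  dur <- train$n_frames * train$frame_interval
  if (dur <= 0) stop_config("zero-duration epoch")
  length(train$frames) / dur
}
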
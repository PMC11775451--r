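# Plain-text interchange: traces / geometry / spikes as CSV, epochs and
# reports as JSON, configs as YAML. All files are language-agnostic.

#' Write / read a traces table (frames x cells)
#'
#' CSV layout: one row per frame, one column per cell, header row of
#' cell ids.
#' @param traces Numeric matrix, colnames = cell ids.
#' @param path File path.
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(is.matrix(traces), !is.null(colnames(traces)))
  utils::write.csv(as.data.frame(traces), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  as.matrix(df)
}

#' Write / read a spike table (`cell_id, spike_frame`)
#'
#' @param trains Named list of [spike_train()] objects.
#' @param path File path.
#' @export
write_spikes_csv <- function(trains, path) {
  rows <- lapply(trains, function(tr) {
    if (!length(tr$frames)) return(NULL)
    data.frame(cell_id = tr$cell_id, spike_frame = tr$frames,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(
    data.frame(cell_id = character(0), spike_frame = integer(0))
  )))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @param n_frames,frame_interval Frame grid of the recording the spikes
#'   came from.
#' @param cell_ids Cell ids to materialise (cells without spikes are
#'   returned as empty trains); default: ids present in the file.
#' @export
read_spikes_csv <- function(path, n_frames, frame_interval = 0.1,
                            cell_ids = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(cell_ids)) cell_ids <- unique(df$cell_id)
  out <- lapply(cell_ids, function(id) {
    spike_train(id, df$spike_frame[df$cell_id == id], n_frames,
                frame_interval)
  })
  stats::setNames(out, cell_ids)
}

#' Write / read a rectangle geometry table
#'
#' CSV columns: `cell_id, x_min, y_min, x_max, y_max` (pixels).
#' @param geometry Geometry `data.frame`.
#' @param path File path.
#' @export
write_geometry_csv <- function(geometry, path) {
  utils::write.csv(
    geometry[, c("cell_id", "x_min", "y_min", "x_max", "y_max")],
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_geometry_csv
#' @export
read_geometry_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read an epoch table as JSON
#'
#' JSON array of objects `{name, start_frame, end_frame, solution}`.
#' @param epochs Epoch `data.frame`.
#' @param path File path.
#' @export
write_epochs_json <- function(epochs, path) {
  jsonlite::write_json(epochs, path, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_epochs_json
#' @param n_frames Recording length used to validate the epochs.
#' @export
read_epochs_json <- function(path, n_frames = Inf) {
  df <- jsonlite::fromJSON(path)
  validate_epochs(df, n_frames)
}

#' Write / read a generator or pipeline configuration as YAML
#'
#' @param config A [synth_config()] (epoch tables are stored as plain
#'   lists and rebuilt on read).
#' @param path File path.
#' @export
write_config_yaml <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$epochs)) x$epochs <- as.list(x$epochs)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$epochs)) {
    x$epochs <- as.data.frame(x$epochs, stringsAsFactors = FALSE)
  }
  do.call(synth_config, x)
}

#' Assemble a recording session from plain-text inputs
#'
#' @param traces_path Traces CSV (frames x cells).
#' @param geometry_path Geometry CSV.
#' @param epochs_path Epochs JSON.
#' @param frame_interval Seconds per frame.
#' @param pixel_size Micrometers per pixel.
#' @param slices Optional cell -> slice map; default: one slice.
#' @return A `recording_session`.
#' @export
read_session <- function(traces_path, geometry_path, epochs_path,
                         frame_interval = 0.1, pixel_size = 1,
                         slices = NULL) {
  traces <- read_traces_csv(traces_path)
  geometry <- read_geometry_csv(geometry_path)
  epochs <- read_epochs_json(epochs_path, nrow(traces))
  ids <- colnames(traces)
  if (!setequal(ids, geometry$cell_id)) {
    stop_config("geometry ids do not match trace ids")
  }
  if (is.null(slices)) {
    slices <- stats::setNames(rep("slice01", length(ids)), ids)
  }
  structure(
    list(traces = traces, geometry = geometry, epochs = epochs,
         slices = slices, frame_interval = frame_interval,
         pixel_size = pixel_size, metadata = list()),
    class = "recording_session"
  )
}

#' Write a session to a directory of plain-text files
#'
#' Writes `traces.csv`, `geometry.csv`, `epochs.json` and, when given,
#' ground truth as `truth.json`.
#' @param session A `recording_session`.
#' @param dir Output directory (created if missing).
#' @param truth Optional `synth_ground_truth`.
#' @export
write_session <- function(session, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_traces_csv(session$traces, file.path(dir, "traces.csv"))
  write_geometry_csv(session$geometry, file.path(dir, "geometry.csv"))
  write_epochs_json(session$epochs, file.path(dir, "epochs.json"))
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(
        spike_frames = truth$spike_frames,
        coupled_pairs = truth$coupled_pairs,
        epoch_conditions = truth$epoch_conditions,
        n_frames = truth$n_frames,
        frame_interval = truth$frame_interval
      ),
      file.path(dir, "truth.json"), pretty = TRUE, auto_unbox = TRUE,
      dataframe = "rows", digits = NA
    )
  }
  invisible(dir)
}
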
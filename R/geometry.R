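# Cell geometry: fitted rectangles, centers and micrometer distances.

#' Fit a rectangle around an ROI and take its center
#'
#' ZG cells are irregular but mostly rectangular-to-oval; the cell
#' position is defined as the center of the axis-aligned bounding
#' rectangle of the ROI pixel set.
#'
#' @param pixels ROI pixels: a two-column matrix/data.frame of `(x, y)`
#'   pixel coordinates.
#' @param cell_id Identifier for the returned geometry.
#' @return A `cell_geometry` list: `cell_id`, `x_min`, `y_min`, `x_max`,
#'   `y_max`, `center` (`c(x, y)` in pixels).
#' @export
#' @examples
#' fit_rectangle(cbind(x = c(0, 9, 3), y = c(0, 5, 2)))$center
fit_rectangle <- function(pixels, cell_id = "cell") {
  pixels <- as.matrix(pixels)
  if (!nrow(pixels)) stop_config("empty ROI: no pixels to fit")
  if (ncol(pixels) < 2L || any(!is.finite(pixels[, 1:2]))) {
    stop_config("ROI pixels must be finite (x, y) coordinates")
  }
  x <- pixels[, 1]; y <- pixels[, 2]
  geo <- list(
    cell_id = as.character(cell_id),
    x_min = min(x), y_min = min(y), x_max = max(x), y_max = max(y)
  )
  geo$center <- c(x = (geo$x_min + geo$x_max) / 2,
                  y = (geo$y_min + geo$y_max) / 2)
  structure(geo, class = "cell_geometry")
}

#' Center-to-center distance matrix in micrometers
#'
#' @param geometry A `data.frame` with columns `cell_id`, `x_min`,
#'   `y_min`, `x_max`, `y_max` (pixel units), e.g. the geometry table of
#'   a generated session.
#' @param pixel_size Micrometers per pixel (single value shared by the
#'   slice; a vector of per-cell values must be constant).
#' @return Symmetric matrix of Euclidean distances (um) with zero
#'   diagonal, dimnames = cell ids.
#' @export
#' @examples
#' g <- data.frame(cell_id = c("a", "b"), x_min = c(0, 3), y_min = c(0, 4),
#'                 x_max = c(0, 3), y_max = c(0, 4))
#' pair_distances(g, 1)["a", "b"]   # 5
pair_distances <- function(geometry, pixel_size) {
  need <- c("cell_id", "x_min", "y_min", "x_max", "y_max")
  if (!is.data.frame(geometry) || !all(need %in% names(geometry))) {
    stop_config("'geometry' must have columns %s",
                paste(need, collapse = ", "))
  }
  if (length(unique(pixel_size)) != 1L) {
    stop_config("mismatched pixel_size within one slice")
  }
  pixel_size <- pixel_size[1]
  check_number(pixel_size, "pixel_size", lower = 1e-12)
  cx <- (geometry$x_min + geometry$x_max) / 2
  cy <- (geometry$y_min + geometry$y_max) / 2
  d <- as.matrix(stats::dist(cbind(cx, cy))) * pixel_size
  dimnames(d) <- list(geometry$cell_id, geometry$cell_id)
  d
}

#' Distance summary of coupled connections
#'
#' Mean and standard error of the center-to-center distances of all
#' connections above the coupling threshold.
#'
#' @param result A `synchrony_result` carrying distances (build it with
#'   `pairwise_ji(..., geometry = , pixel_size = )`).
#' @return A list `mean_um`, `sem_um`, `n`; flagged empty when there are
#'   no coupled pairs.
#' @export
coupled_distance_summary <- function(result) {
  stopifnot(inherits(result, "synchrony_result"))
  if (is.null(result$distances)) {
    stop_config("result carries no distances; supply geometry to pairwise_ji()")
  }
  d <- result$coupled_pairs$distance_um
  if (!length(d)) {
    return(list(mean_um = NA_real_, sem_um = NA_real_, n = 0L,
                empty = TRUE))
  }
  sem <- if (length(d) > 1L) stats::sd(d) / sqrt(length(d)) else 0
  list(mean_um = mean(d), sem_um = sem, n = length(d), empty = FALSE)
}
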
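# Pairwise spike-train synchrony: Jaccard index, coupling classification,
# frame-shift surrogate null, bootstrap confidence intervals.

#' Jaccard index between two spike trains
#'
#' With `tolerance = 0`, the index is `|A intersect B| / |A union B|`
#' over binarized frames: the fraction of temporally synchronized spikes
#' among all spikes across the two cells. With `tolerance = t > 0`,
#' synchronized spikes are counted by greedy one-to-one matching of
#' spikes within `t` frames of each other (each spike matched at most
#' once), and `JI = matched / (|A| + |B| - matched)`.
#'
#' If both trains are empty the index is undefined and `NA` is returned
#' (such pairs are excluded from all summaries rather than counted as 0).
#'
#' @param a,b [spike_train()] objects on the same frame grid.
#' @param tolerance Matching tolerance in frames (default 0).
#' @return A value in `[0, 1]`, or `NA` if undefined.
#' @export
#' @examples
#' t1 <- spike_train("a", c(1, 5, 9), 20)
#' t2 <- spike_train("b", c(1, 5, 12), 20)
#' jaccard_index(t1, t2)            # 2 shared / 4 total = 0.5
jaccard_index <- function(a, b, tolerance = 0) {
  stopifnot(inherits(a, "spike_train"), inherits(b, "spike_train"))
  if (a$n_frames != b$n_frames ||
      !isTRUE(all.equal(a$frame_interval, b$frame_interval))) {
    stop_config("spike trains live on different frame grids")
  }
  check_number(tolerance, "tolerance", lower = 0)
  ji_frames(a$frames, b$frames, as.integer(round(tolerance)))
}

# Core JI on 0-based frame vectors (assumed sorted, unique).
#' @noRd
ji_frames <- function(fa, fb, tol = 0L) {
  na <- length(fa); nb <- length(fb)
  if (na == 0L && nb == 0L) return(NA_real_)
  if (na == 0L || nb == 0L) return(0)
  if (tol == 0L) {
    m <- length(intersect(fa, fb))
  } else {
    # greedy earliest-first one-to-one matching; optimal for interval
    # matching of points on a line
    m <- 0L; i <- 1L; j <- 1L
    while (i <= na && j <= nb) {
      d <- fa[i] - fb[j]
      if (abs(d) <= tol) {
        m <- m + 1L; i <- i + 1L; j <- j + 1L
      } else if (d < 0) {
        i <- i + 1L
      } else {
        j <- j + 1L
      }
    }
  }
  m / (na + nb - m)
}

#' Pairwise Jaccard-index matrix for a cohort of spike trains
#'
#' Computes the JI for every unordered pair of cells within a slice;
#' pairs spanning different slices are never formed (their geometry is
#' unrelated). Optionally attaches center-to-center distances from a
#' rectangle geometry table.
#'
#' @param trains Named list of [spike_train()] objects.
#' @param slices Named character vector mapping cell id to slice id;
#'   `NULL` treats all cells as one slice.
#' @param tolerance Matching tolerance in frames (default 0).
#' @param threshold JI cutoff used by [classify_coupled()] (default 0.1,
#'   strict `>`).
#' @param geometry Optional geometry `data.frame`
#'   (`cell_id, x_min, y_min, x_max, y_max` in pixels).
#' @param pixel_size Micrometers per pixel (required with `geometry`).
#' @return A `synchrony_result`: `cell_ids`, symmetric `ji` matrix (`NA`
#'   on the diagonal, for cross-slice pairs and for undefined pairs),
#'   `undefined` logical matrix flagging both-empty pairs, `distances`
#'   (um, or `NULL`), `tolerance`, `threshold`, `slices`, plus the
#'   coupled sets filled in by [classify_coupled()].
#' @export
pairwise_ji <- function(trains, slices = NULL, tolerance = 0,
                        threshold = 0.1, geometry = NULL,
                        pixel_size = NULL) {
  if (length(trains) < 2L) stop_config("need at least 2 spike trains")
  ids <- vapply(trains, function(t) t$cell_id, character(1))
  if (is.null(names(trains))) names(trains) <- ids
  if (is.null(slices)) {
    slices <- stats::setNames(rep("slice01", length(ids)), ids)
  }
  if (!all(ids %in% names(slices))) {
    stop_config("every cell id needs a slice assignment")
  }
  slices <- slices[ids]
  n <- length(ids)
  ji <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  undef <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  tol <- as.integer(round(tolerance))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (slices[i] != slices[j]) next
      v <- jaccard_index(trains[[i]], trains[[j]], tol)
      ji[i, j] <- ji[j, i] <- v
      if (is.na(v)) undef[i, j] <- undef[j, i] <- TRUE
    }
  }
  distances <- NULL
  if (!is.null(geometry)) {
    if (is.null(pixel_size)) {
      stop_config("'pixel_size' is required with 'geometry'")
    }
    distances <- pair_distances(geometry, pixel_size)[ids, ids]
  }
  res <- structure(
    list(cell_ids = ids, ji = ji, undefined = undef,
         distances = distances, tolerance = tol, threshold = threshold,
         slices = slices, coupled_pairs = NULL, coupled_cells = NULL),
    class = "synchrony_result"
  )
  classify_coupled(res, threshold)
}

#' Classify coupled pairs and cells from a JI matrix
#'
#' A connection is coupled when its JI strictly exceeds `threshold`; a
#' cell is coupled when it has at least one coupled connection.
#'
#' @param result A `synchrony_result` from [pairwise_ji()].
#' @param threshold JI cutoff (default: the result's stored threshold).
#' @return The result with `threshold`, `coupled_pairs` (a `data.frame`
#'   `cell_a, cell_b, ji` and, when distances are present,
#'   `distance_um`) and `coupled_cells` updated.
#' @export
classify_coupled <- function(result, threshold = result$threshold) {
  stopifnot(inherits(result, "synchrony_result"))
  check_number(threshold, "threshold", lower = 0)
  ids <- result$cell_ids
  n <- length(ids)
  ia <- integer(0); ib <- integer(0)
  if (n >= 2L) {
    ut <- upper.tri(result$ji)
    hit <- which(ut & !is.na(result$ji) & result$ji > threshold,
                 arr.ind = TRUE)
    ia <- hit[, 1]; ib <- hit[, 2]
  }
  pairs <- data.frame(
    cell_a = ids[ia], cell_b = ids[ib],
    ji = result$ji[cbind(ia, ib)],
    stringsAsFactors = FALSE
  )
  if (!is.null(result$distances) && nrow(pairs)) {
    pairs$distance_um <- result$distances[cbind(ia, ib)]
  } else if (!is.null(result$distances)) {
    pairs$distance_um <- numeric(0)
  }
  result$threshold <- threshold
  result$coupled_pairs <- pairs
  result$coupled_cells <- sort(unique(c(pairs$cell_a, pairs$cell_b)))
  result
}

#' @export
print.synchrony_result <- function(x, ...) {
  n_pairs <- sum(!is.na(x$ji[upper.tri(x$ji)]))
  cat("<synchrony_result>\n")
  cat(sprintf("  %d cells, %d within-slice pair(s), tolerance %d frame(s)\n",
              length(x$cell_ids), n_pairs, x$tolerance))
  cat(sprintf("  threshold %g: %d coupled pair(s), %d coupled cell(s)\n",
              x$threshold, nrow(x$coupled_pairs),
              length(x$coupled_cells)))
  invisible(x)
}

#' Frame-shift surrogate null for pairwise synchrony
#'
#' Re-computes the full JI matrix after circularly shifting one train of
#' each pair by `i` frames, for `i = 1..max_shift`. If observed
#' synchrony were a chance product of the camera's frame binning,
#' shifted recordings would show similar JI distributions; genuinely
#' coupled activity collapses under shifting.
#'
#' @param trains Named list of [spike_train()] objects.
#' @param slices Optional cell -> slice map (see [pairwise_ji()]).
#' @param max_shift Largest shift in frames (default 10).
#' @param tolerance JI matching tolerance in frames.
#' @param threshold JI cutoff used for the per-shift exceedance fraction.
#' @return A `shift_null_result`: `shifts` (0..max_shift), the observed
#'   result at shift 0, per-shift JI matrices, and a `summary`
#'   `data.frame` (`shift`, `mean_ji`, `frac_above`, `n_pairs`).
#' @export
shift_null <- function(trains, slices = NULL, max_shift = 10,
                       tolerance = 0, threshold = 0.1) {
  check_number(max_shift, "max_shift", lower = 1)
  n_frames <- trains[[1]]$n_frames
  if (max_shift >= n_frames) {
    stop_config("max_shift must be smaller than the recording length")
  }
  observed <- pairwise_ji(trains, slices, tolerance, threshold)
  matrices <- vector("list", max_shift)
  rows <- vector("list", max_shift + 1L)
  ut <- upper.tri(observed$ji)
  obs_vals <- observed$ji[ut]
  rows[[1]] <- data.frame(
    shift = 0L,
    mean_ji = mean(obs_vals, na.rm = TRUE),
    frac_above = mean(obs_vals > threshold, na.rm = TRUE),
    n_pairs = sum(!is.na(obs_vals))
  )
  for (s in seq_len(max_shift)) {
    shifted <- lapply(trains, function(t) {
      spike_train(t$cell_id, (t$frames + s) %% t$n_frames, t$n_frames,
                  t$frame_interval)
    })
    ids <- observed$cell_ids
    m <- matrix(NA_real_, length(ids), length(ids),
                dimnames = list(ids, ids))
    tol <- as.integer(round(tolerance))
    for (i in seq_along(ids)[-length(ids)]) {
      for (j in (i + 1L):length(ids)) {
        if (observed$slices[i] != observed$slices[j]) next
        m[i, j] <- m[j, i] <- jaccard_index(trains[[i]], shifted[[j]], tol)
      }
    }
    matrices[[s]] <- m
    vals <- m[ut]
    rows[[s + 1L]] <- data.frame(
      shift = s,
      mean_ji = mean(vals, na.rm = TRUE),
      frac_above = mean(vals > threshold, na.rm = TRUE),
      n_pairs = sum(!is.na(vals))
    )
  }
  structure(
    list(observed = observed, shift_matrices = matrices,
         summary = do.call(rbind, rows), max_shift = as.integer(max_shift),
         tolerance = as.integer(round(tolerance)), threshold = threshold),
    class = "shift_null_result"
  )
}

#' @export
print.shift_null_result <- function(x, ...) {
  cat("<shift_null_result>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Percentile bootstrap confidence interval of the mean
#'
#' Resamples the values with replacement `n_resamples` times, computes
#' the mean of each resample and reports the
#' `(1 - confidence) / 2` and `(1 + confidence) / 2` quantiles.
#'
#' @param values Numeric vector (at least one finite value; `NA`s are
#'   dropped).
#' @param n_resamples Number of bootstrap resamples (default 10,000).
#' @param confidence Confidence level (default 0.95).
#' @param seed Optional seed for reproducible resampling.
#' @return A `bootstrap_ci`: `statistic` (the sample mean), `lower`,
#'   `upper`, `n`, `n_resamples`, `confidence`, `seed`.
#' @export
#' @examples
#' bootstrap_ci(c(1, 2, 3, 4), n_resamples = 500, seed = 1)
bootstrap_ci <- function(values, n_resamples = 10000, confidence = 0.95,
                         seed = NULL) {
  values <- values[is.finite(values)]
  if (!length(values)) stop_config("no finite values to bootstrap")
  check_number(n_resamples, "n_resamples", lower = 1)
  check_number(confidence, "confidence", lower = 1e-6, upper = 1 - 1e-6)
  n <- length(values)
  means <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      mean(values[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
  })
  alpha <- (1 - confidence) / 2
  qs <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(
    list(statistic = mean(values), lower = qs[1], upper = qs[2],
         n = n, n_resamples = as.integer(n_resamples),
         confidence = confidence, seed = seed),
    class = "bootstrap_ci"
  )
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("mean %.4g, %g%% CI [%.4g, %.4g] (n = %d, %d resamples)\n",
              x$statistic, 100 * x$confidence, x$lower, x$upper, x$n,
              x$n_resamples))
  invisible(x)
}

#' Mean JI of coupled connections with a bootstrap CI
#'
#' Averages the JI of all connections above the coupling threshold
#' (resampling unit: connections).
#'
#' @param result A `synchrony_result`.
#' @param n_resamples,confidence,seed Passed to [bootstrap_ci()].
#' @return A list `mean`, `ci` ([bootstrap_ci()]), `n_connections`; if
#'   no connection exceeds the threshold, a flagged empty summary
#'   (`n_connections = 0`, `mean = NA`).
#' @export
summarize_coupled_ji <- function(result, n_resamples = 10000,
                                 confidence = 0.95, seed = NULL) {
  stopifnot(inherits(result, "synchrony_result"))
  vals <- result$coupled_pairs$ji
  if (!length(vals)) {
    return(list(mean = NA_real_, ci = NULL, n_connections = 0L,
                empty = TRUE))
  }
  ci <- bootstrap_ci(vals, n_resamples, confidence, seed)
  list(mean = mean(vals), ci = ci, n_connections = length(vals),
       empty = FALSE)
}
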
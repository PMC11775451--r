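# End-to-end orchestration: simulate (or load) -> detect -> synchrony ->
# shift null -> perturbation -> FRAP -> machine-readable report.

#' FRAP experiment design for the pipeline
#'
#' One row per treatment group: number of recordings and the mean / SD
#' of the per-recording true mobile fraction. The defaults reproduce the
#' study conditions (control n = 12, CBX n = 5, GAP-27 n = 4 with group
#' means 0.11 / 0.07 / 0.11 and SDs 0.10 / 0.03 / 0.05).
#'
#' @param group Group labels.
#' @param n Recordings per group.
#' @param mobile_mean,mobile_sd Mean and SD of the true mobile fraction
#'   (draws are truncated to `[0, 1]`).
#' @return A `data.frame` design table.
#' @export
frap_group_design <- function(group = c("control", "cbx", "gap27"),
                              n = c(12L, 5L, 4L),
                              mobile_mean = c(0.11, 0.07, 0.11),
                              mobile_sd = c(0.10, 0.03, 0.05)) {
  stopifnot(length(group) == length(n),
            length(group) == length(mobile_mean),
            length(group) == length(mobile_sd))
  data.frame(group = as.character(group), n = as.integer(n),
             mobile_mean = mobile_mean, mobile_sd = mobile_sd,
             stringsAsFactors = FALSE)
}

#' Simulate and quantify a set of FRAP experiment groups
#'
#' Draws a true mobile fraction per recording, generates the trace with
#' [generate_frap()], recovers it with [frap_recovery()], and compares
#' every group against the first (reference) group with a pooled
#' Student's t-test.
#'
#' @param design A [frap_group_design()] table.
#' @param config A [synth_config()] (frame interval; the FRAP stage
#'   derives per-recording seeds from `seed`).
#' @param tau,bleach_depth,noise_sd,duration Passed to
#'   [generate_frap()].
#' @param seed Integer seed for the whole FRAP stage.
#' @return A list with `groups` (named [group_stats()] list), `tests`
#'   (t-test vs reference per non-reference group) and `truth`
#'   (per-group true mobile fractions).
#' @export
simulate_frap_groups <- function(design = frap_group_design(),
                                 config = synth_config(),
                                 tau = 20, bleach_depth = 0.1,
                                 noise_sd = 0.05, duration = 80,
                                 seed = 1L) {
  groups <- list()
  truth <- list()
  counter <- 0L
  for (g in seq_len(nrow(design))) {
    mobile <- with_seed(seed + 7L * g, {
      m <- stats::rnorm(design$n[g], design$mobile_mean[g],
                        design$mobile_sd[g])
      pmin(pmax(m, 0), 1)
    })
    rec <- vapply(seq_along(mobile), function(i) {
      counter <<- counter + 1L
      cfg_i <- config
      cfg_i$seed <- as.integer(seed + 1000L + counter)
      tr <- generate_frap(mobile[i], tau = tau,
                          bleach_depth = bleach_depth, config = cfg_i,
                          noise_sd = noise_sd, duration = duration)
      frap_recovery(tr)
    }, numeric(1))
    groups[[design$group[g]]] <- group_stats(rec, design$group[g])
    truth[[design$group[g]]] <- mobile
  }
  ref <- groups[[1]]
  tests <- lapply(groups[-1], function(g) two_sample_t(ref, g))
  list(groups = groups, tests = tests, truth = truth,
       reference = design$group[1])
}

# Detect + per-epoch synchrony for one cohort.
#' @noRd
analyze_cohort <- function(session, detect = detect_params(),
                           tolerance = 0, threshold = 0.1,
                           discard_lead = 60) {
  trains <- detect_session(session, detect)
  epochs <- session$epochs
  per_epoch <- lapply(seq_len(nrow(epochs)), function(k) {
    restricted <- lapply(trains, restrict_to_epoch,
                         epoch = epochs[k, ], discard_lead = discard_lead)
    pairwise_ji(restricted, session$slices, tolerance, threshold,
                geometry = session$geometry,
                pixel_size = session$pixel_size)
  })
  names(per_epoch) <- epochs$name
  rates <- session_epoch_rates(trains, epochs, discard_lead)
  list(trains = trains, per_epoch = per_epoch, rates = rates,
       epochs = epochs)
}

#' Run the full analysis pipeline and build a reproduction report
#'
#' Simulates a treated cohort (and a time-matched control cohort),
#' detects spikes, quantifies baseline synchrony, distances and the
#' frame-shift null, compares baseline vs drug epochs, simulates and
#' quantifies the FRAP groups, and collects every statistic into a
#' machine-readable report. Identical config + seed give an identical
#' report.
#'
#' @param config Treated-cohort [synth_config()]; it should carry a
#'   multi-epoch protocol (see [protocol_epochs()]). Defaults to the
#'   study conditions (8 slices / 186 cells, 45 min, CBX middle epoch).
#' @param control_config Control-cohort config; `NULL` (default) builds
#'   one from `config` with 11 slices / 205 cells and control solution
#'   throughout. Pass `NA` to skip the control cohort.
#' @param detect [detect_params()] used for spike detection.
#' @param tolerance,threshold JI matching tolerance (frames) and
#'   coupling cutoff.
#' @param max_shift Largest surrogate shift (frames).
#' @param discard_lead Seconds discarded after each solution change.
#' @param n_resamples,confidence Bootstrap settings.
#' @param frap_design [frap_group_design()] table (`NULL` skips FRAP).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Optional directory: writes `report.json`, spike,
#'   JI-matrix and connection CSVs there.
#' @return A `pipeline_report` list: `entries` (named statistics, each
#'   `value` / `n` / `description` and optional `ci`), `provenance`
#'   (seeds, parameters, config echo) plus the underlying stage objects
#'   (`treated`, `control`, `shiftnull`, `comparison`, `frap`).
#' @export
run_pipeline <- function(config = synth_config(epochs = protocol_epochs(27000)),
                         control_config = NULL,
                         detect = detect_params(),
                         tolerance = 0, threshold = 0.1,
                         max_shift = 10, discard_lead = 60,
                         n_resamples = 10000, confidence = 0.95,
                         frap_design = frap_group_design(),
                         seed = config$seed,
                         out_dir = NULL) {
  if (is.null(seed)) seed <- 1L
  seed <- as.integer(seed)
  config$seed <- seed
  if (is.null(control_config)) {
    control_config <- config
    control_config$n_slices <- 11L
    control_config$cells_per_slice <- as.integer(c(rep(19, 7), rep(18, 4)))
    control_config$seed <- seed + 101L
    if (!is.null(config$epochs)) {
      ctrl_epochs <- config$epochs
      ctrl_epochs$solution <- rep("control", nrow(ctrl_epochs))
      control_config$epochs <- ctrl_epochs
    }
  } else if (length(control_config) == 1L && is.na(control_config)) {
    control_config <- NULL
  }

  sim <- generate_recording(config)
  treated <- analyze_cohort(sim$session, detect, tolerance, threshold,
                            discard_lead)
  baseline_name <- treated$epochs$name[1]
  base_res <- treated$per_epoch[[baseline_name]]
  coupled_sum <- summarize_coupled_ji(base_res, n_resamples, confidence,
                                      seed = seed + 303L)
  dist_sum <- coupled_distance_summary(base_res)
  shiftnull <- shift_null(
    lapply(treated$trains, restrict_to_epoch,
           epoch = treated$epochs[1, ], discard_lead = discard_lead),
    sim$session$slices, max_shift, tolerance, threshold
  )

  entries <- list()
  add <- function(name, value, n, description, ci = NULL) {
    entries[[name]] <<- c(
      list(value = unname(value), n = unname(n),
           description = description),
      if (!is.null(ci)) list(ci = c(ci$lower, ci$upper))
    )
  }

  ids <- base_res$cell_ids
  n_pairs <- sum(!is.na(base_res$ji[upper.tri(base_res$ji)]) |
                   base_res$undefined[upper.tri(base_res$undefined)])
  add("analyzed_cells", length(ids), length(ids),
      "cells entering the synchrony analysis (treated cohort)")
  add("within_slice_pairs", n_pairs, n_pairs,
      "within-slice cell pairs with a computed baseline JI")
  add("synchronized_cells", length(base_res$coupled_cells), length(ids),
      sprintf("cells with >= 1 baseline connection with JI > %g",
              threshold))
  add("coupled_connections", nrow(base_res$coupled_pairs), n_pairs,
      "baseline connections above the coupling threshold")
  add("mean_coupled_ji", coupled_sum$mean, coupled_sum$n_connections,
      "mean baseline JI of connections above threshold",
      ci = coupled_sum$ci)
  add("coupled_distance_um", dist_sum$mean_um, dist_sum$n,
      "mean center-to-center distance of coupled connections (um)")
  add("coupled_distance_sem_um", dist_sum$sem_um, dist_sum$n,
      "s.e.m. of the coupled-connection distance (um)")
  add("shift0_mean_ji", shiftnull$summary$mean_ji[1],
      shiftnull$summary$n_pairs[1],
      "mean baseline JI at shift 0")
  add("shifted_mean_ji", mean(shiftnull$summary$mean_ji[-1]),
      sum(shiftnull$summary$n_pairs[-1]),
      sprintf("mean JI over surrogate shifts 1..%d", max_shift))

  # epoch rates
  for (ep in unique(treated$rates$epoch)) {
    v <- treated$rates$rate_hz[treated$rates$epoch == ep]
    add(paste0("rate_", ep, "_hz"), mean(v), length(v),
        sprintf("mean spike rate during '%s' (spikes/s)", ep))
  }

  comparison <- NULL
  control <- NULL
  if (nrow(treated$epochs) >= 2L) {
    drug_name <- treated$epochs$name[2]
    comparison <- ji_change(
      base_res, treated$per_epoch[[drug_name]],
      mode = "relative", threshold = threshold,
      n_resamples = n_resamples, confidence = confidence,
      seed = seed + 404L
    )
    add("drug_ji_change_pct", comparison$summary_relative$mean,
        comparison$summary_relative$n,
        "mean relative JI change, drug vs baseline (%)",
        ci = comparison$summary_relative$ci)
    add("drug_ji_change_abs", comparison$summary_absolute$mean,
        comparison$summary_absolute$n,
        "mean absolute JI change, drug vs baseline",
        ci = comparison$summary_absolute$ci)

    if (!is.null(control_config)) {
      csim <- generate_recording(control_config)
      cohort <- analyze_cohort(csim$session, detect, tolerance,
                               threshold, discard_lead)
      cmp_ctrl <- ji_change(
        cohort$per_epoch[[cohort$epochs$name[1]]],
        cohort$per_epoch[[cohort$epochs$name[2]]],
        mode = "relative", threshold = threshold,
        n_resamples = n_resamples, confidence = confidence,
        seed = seed + 505L
      )
      control <- list(session = csim$session, truth = csim$truth,
                      cohort = cohort, comparison = cmp_ctrl)
      add("control_cells", length(cohort$per_epoch[[1]]$cell_ids),
          length(cohort$per_epoch[[1]]$cell_ids),
          "cells in the no-drug control cohort")
      add("control_ji_change_pct", cmp_ctrl$summary_relative$mean,
          cmp_ctrl$summary_relative$n,
          "mean relative JI change in controls without drug (%)",
          ci = cmp_ctrl$summary_relative$ci)
      side <- compare_groups(comparison, cmp_ctrl)
      add("drug_vs_control_ci_overlap", as.numeric(side$ci_overlap), 2,
          "1 if the drug and control change CIs overlap, else 0")
    }
  }

  frap <- NULL
  if (!is.null(frap_design)) {
    frap <- simulate_frap_groups(frap_design, config, seed = seed + 606L)
    for (nm in names(frap$groups)) {
      g <- frap$groups[[nm]]
      add(paste0("frap_recovery_", nm), g$mean, g$n,
          sprintf("mean FRAP recovery fraction, %s group", nm))
      add(paste0("frap_recovery_sd_", nm), g$sd, g$n,
          sprintf("SD of FRAP recovery, %s group", nm))
    }
    for (nm in names(frap$tests)) {
      tt <- frap$tests[[nm]]
      n_tot <- frap$groups[[frap$reference]]$n + frap$groups[[nm]]$n
      add(paste0("frap_t_", nm, "_vs_", frap$reference), tt$t, n_tot,
          sprintf("Student's t, %s vs %s FRAP recovery", nm,
                  frap$reference))
      add(paste0("frap_p_", nm, "_vs_", frap$reference), tt$p, n_tot,
          "two-sided p value of the above")
    }
  }

  report <- structure(
    list(
      entries = entries,
      provenance = list(
        seed = seed,
        stage_seeds = c(treated = seed, control = seed + 101L,
                        coupled_ci = seed + 303L, drug_ci = seed + 404L,
                        control_ci = seed + 505L, frap = seed + 606L),
        detect = unclass(detect),
        tolerance = tolerance, threshold = threshold,
        max_shift = max_shift, discard_lead = discard_lead,
        n_resamples = n_resamples, confidence = confidence,
        config = unclass(config)[setdiff(names(config), "epochs")]
      ),
      treated = list(session = sim$session, truth = sim$truth,
                     cohort = treated, baseline = base_res,
                     coupled_summary = coupled_sum,
                     distance_summary = dist_sum),
      control = control,
      shiftnull = shiftnull,
      comparison = comparison,
      frap = frap
    ),
    class = "pipeline_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_json(report, file.path(out_dir, "report.json"))
    write_spikes_csv(treated$trains, file.path(out_dir, "spikes.csv"))
    utils::write.csv(as.data.frame(base_res$ji),
                     file.path(out_dir, "ji_baseline.csv"))
    utils::write.csv(base_res$coupled_pairs,
                     file.path(out_dir, "coupled_pairs.csv"),
                     row.names = FALSE)
    utils::write.csv(shiftnull$summary,
                     file.path(out_dir, "shift_null_summary.csv"),
                     row.names = FALSE)
    if (!is.null(comparison)) {
      utils::write.csv(comparison$connections,
                       file.path(out_dir, "ji_change_connections.csv"),
                       row.names = FALSE)
    }
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (nm in names(x$entries)) {
    e <- x$entries[[nm]]
    cat(sprintf("  %-28s %10.4g  (n = %s)\n", nm, e$value,
                format(e$n)))
  }
  invisible(x)
}

#' Write the statistics of a pipeline report as JSON
#'
#' Serialises the `entries` and `provenance` of a [run_pipeline()]
#' report (no timestamps; identical runs give identical files).
#'
#' @param report A `pipeline_report`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  jsonlite::write_json(
    list(entries = report$entries, provenance = report$provenance),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
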
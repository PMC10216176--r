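#' Run manifest for the end-to-end workflow
#'
#' Bundles everything one scenario run needs: the simulator
#' configuration, the slicing/ROI geometry, the metric configuration,
#' the classification thresholds, and the sampling cadence.
#'
#' @param scenario `"NT"`, `"LD"`, `"HD"`, `"HDV"` or `"custom"`.
#' @param config A [sim_config()]; defaults to
#'   [scenario_config()] of `scenario` at test scale (required when
#'   `scenario = "custom"`).
#' @param sampling_interval Days between metric samples (default 3 —
#'   frequent enough to resolve the metric trends at a desk-scale cost).
#' @param roi_width,roi_height ROI size in micrometers (default the
#'   1 x 1 mm tile), center-cropped from the mid-plane slide.
#' @param slice_thickness Slab thickness of the 2-D slice in micrometers
#'   (default 20, one voxel layer).
#' @param metric_cfg A [metric_config()].
#' @param change_thr A [change_thresholds()].
#' @param bivariate_thr A [bivariate_thresholds()] or `NULL` to skip
#'   bivariate labeling.
#' @param seed Overrides `config$random_seed` when given.
#' @param output_dir If non-`NULL`, tables are also written there as
#'   tab-separated text.
#' @return A `run_manifest` object.
#' @export
run_manifest <- function(scenario = c("HD", "LD", "NT", "HDV", "custom"),
                         config = NULL, sampling_interval = 3,
                         roi_width = 1000, roi_height = 1000,
                         slice_thickness = 20,
                         metric_cfg = metric_config(),
                         change_thr = change_thresholds(),
                         bivariate_thr = bivariate_thresholds(),
                         seed = NULL, output_dir = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(config)) {
    if (scenario == "custom")
      stop("scenario \"custom\" requires an explicit config", call. = FALSE)
    config <- scenario_config(scenario)
  }
  if (!is.null(seed)) config$random_seed <- as.integer(seed)
  if (sampling_interval <= 0) stop("sampling_interval must be > 0",
                                   call. = FALSE)
  structure(list(scenario = scenario, config = config,
                 sampling_interval = sampling_interval,
                 roi_width = roi_width, roi_height = roi_height,
                 slice_thickness = slice_thickness,
                 metric_cfg = metric_cfg, change_thr = change_thr,
                 bivariate_thr = bivariate_thr, output_dir = output_dir),
            class = "run_manifest")
}

metric_names <- c("mixing_score", "avg_neighbor_frequency",
                  "shannon_entropy", "gcross_auc")

#' Run a full scenario: simulate, slice, crop, score, classify
#'
#' Executes the whole workflow for one manifest: runs all replicates of
#' the simulator; at every sampling time slices the mid-plane of the 3-D
#' box, center-crops the ROI and computes the five metrics; then derives
#' the replicate mean +/- SD time courses, the time-averaged metric
#' table, bivariate labels over time, and before/after-treatment (BT/AT)
#' percent-change labels. BT is the last sample strictly before the dose
#' day, AT the final sample.
#'
#' @param manifest A [run_manifest()].
#' @return A `scenario_result` list:
#'   `series` (per replicate x time metric rows),
#'   `series_summary` (mean and SD over replicates per time),
#'   `time_averaged` (per metric: grand/replicate mean, SD),
#'   `bt_at` (per replicate and metric: BT, AT, percent change, direction,
#'     change label; plus the consensus label per replicate),
#'   `bivariate` (per replicate x time x metric label, if thresholds
#'     given), `sim` (the [run_simulation()] result) and the manifest.
#' @export
run_scenario <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  cfg <- manifest$config
  rows <- list()
  on_sample <- function(cm, t, rep_i) {
    slide <- slice_2d(cm, thickness = manifest$slice_thickness)
    tile <- crop_roi(slide, center_roi(slide, manifest$roi_width,
                                       manifest$roi_height))
    rec <- suppressWarnings(
      compute_metrics(tile, manifest$metric_cfg, time = t))
    rows[[length(rows) + 1L]] <<- data.frame(replicate = rep_i, rec)
  }
  sim <- run_simulation(cfg, sample_interval = manifest$sampling_interval,
                        on_sample = on_sample)
  series <- do.call(rbind, rows)
  series <- series[order(series$replicate, series$time), ]
  rownames(series) <- NULL

  agg <- function(fun) {
    out <- stats::aggregate(
      series[c(metric_names, "cell_ratio")],
      by = list(time = series$time),
      FUN = function(v) if (any(is.finite(v))) fun(v[is.finite(v)])
            else NA_real_)
    out
  }
  mean_tab <- agg(mean)
  sd_tab <- agg(stats::sd)
  names(sd_tab)[-1] <- paste0(names(sd_tab)[-1], "_sd")
  series_summary <- merge(mean_tab, sd_tab, by = "time")

  time_averaged <- do.call(rbind, lapply(
    c(metric_names, "cell_ratio"), function(m) {
      ta <- suppressWarnings(time_average(series, m))
      data.frame(metric = m, mean = ta$mean,
                 replicate_mean = ta$replicate_mean,
                 replicate_sd = ta$replicate_sd,
                 n_defined = ta$n_defined)
    }))

  times <- sort(unique(series$time))
  bt_time <- max(times[times < cfg$dose_day])
  at_time <- max(times)
  bt_at <- do.call(rbind, lapply(unique(series$replicate), function(r) {
    sub <- series[series$replicate == r, ]
    bt <- sub[sub$time == bt_time, ]
    at <- sub[sub$time == at_time, ]
    recs <- lapply(c(metric_names, "cell_ratio"), function(m) {
      pc <- suppressWarnings(percent_change(bt[[m]], at[[m]]))
      data.frame(replicate = r, metric = m, bt = bt[[m]], at = at[[m]],
                 percent = pc$percent,
                 direction = pc$direction %||% NA_character_)
    })
    out <- do.call(rbind, recs)
    ch <- setNames(out$percent, out$metric)[metric_names]
    lab <- suppressWarnings(classify_by_change(ch, manifest$change_thr))
    out$change_label <- unname(lab$per_metric[match(out$metric,
                                                    names(lab$per_metric))])
    out$consensus <- lab$consensus
    out
  }))
  bt_at$bt_time <- bt_time
  bt_at$at_time <- at_time

  bivariate <- NULL
  if (!is.null(manifest$bivariate_thr)) {
    bl <- lapply(metric_names, function(m) {
      lab <- mapply(function(v, rt) classify_bivariate(m, v, rt,
                                                       manifest$bivariate_thr),
                    series[[m]], series$cell_ratio)
      data.frame(replicate = series$replicate, time = series$time,
                 metric = m, value = series[[m]],
                 cell_ratio = series$cell_ratio, label = unname(lab))
    })
    bivariate <- do.call(rbind, bl)
  }

  result <- structure(list(scenario = manifest$scenario, series = series,
                           series_summary = series_summary,
                           time_averaged = time_averaged, bt_at = bt_at,
                           bivariate = bivariate, sim = sim,
                           manifest = manifest),
                      class = "scenario_result")
  if (!is.null(manifest$output_dir)) write_scenario(result,
                                                    manifest$output_dir)
  result
}

#' Write the tables of a scenario result
#'
#' @param result A `scenario_result`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
write_scenario <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in c("series", "series_summary", "time_averaged", "bt_at",
               "bivariate")) {
    tab <- result[[nm]]
    if (is.null(tab)) next
    p <- file.path(dir, paste0(nm, ".tsv"))
    data.table::fwrite(tab, p, sep = "\t")
    paths <- c(paths, p)
  }
  p <- file.path(dir, "cancer_counts.tsv")
  data.table::fwrite(result$sim$summary, p, sep = "\t")
  invisible(c(paths, p))
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s | %d replicates | %d sample times\n",
              x$scenario, length(unique(x$series$replicate)),
              length(unique(x$series$time))))
  cons <- unique(x$bt_at[, c("replicate", "consensus")])
  cat("  BT/AT consensus labels:",
      paste(cons$consensus, collapse = ", "), "\n")
  invisible(x)
}

#' Bundled virtual-patient cohort table
#'
#' Loads the packaged reference cohort of five responder (R) and five
#' non-responder (NR) virtual patients: the cancer:immune cell ratio
#' before (BT) and after (AT) a 3 mg/kg anti-PD-1 course, the published
#' ratio-reduction column, and the absolute percent changes of the four
#' spatial metrics over treatment. Used as the worked input for the
#' percent-change classifier.
#'
#' @return A `data.frame` with one row per case.
#' @export
virtual_cohort <- function() {
  path <- system.file("extdata", "virtual_cohort.csv", package = "tmearch",
                      mustWork = TRUE)
  data.table::fread(path, data.table = FALSE)
}
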
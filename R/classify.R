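#' Immunoarchitecture labels
#'
#' The closed set of tumor-microenvironment archetype labels.
#' @format Character vector `c("COLD", "MIXED", "COMPARTMENTALIZED")`.
#' @export
TME_LABELS <- c("COLD", "MIXED", "COMPARTMENTALIZED")

#' Percent-change classification thresholds
#'
#' Band edges (in percent) for [classify_by_change()]: a metric change
#' below `cold_below` indicates a TME that stayed cold, a change above
#' `compartmentalized_above` indicates conversion to a compartmentalized
#' pattern, and everything between is mixed. Boundary values (exactly 1
#' or exactly 10 with the defaults) fall in the mixed band.
#'
#' @param cold_below Percent, default 1.
#' @param compartmentalized_above Percent, default 10.
#' @return A `change_thresholds` object.
#' @export
change_thresholds <- function(cold_below = 1, compartmentalized_above = 10) {
  if (!(0 < cold_below && cold_below < compartmentalized_above))
    stop("need 0 < cold_below < compartmentalized_above", call. = FALSE)
  structure(list(cold_below = cold_below,
                 compartmentalized_above = compartmentalized_above),
            class = "change_thresholds")
}

#' Absolute percent change between two measurements
#'
#' `100 * |after - before| / before`, with the direction of the change
#' reported separately so that metrics that respond by increasing (the
#' spatial entropy) and by decreasing (the other three) share one scale.
#'
#' @param before,after Metric values before/after treatment; `before`
#'   must be nonzero.
#' @return A list with `percent` (non-negative), and `direction`
#'   (`"increase"`, `"decrease"` or `"none"`). `before = 0` yields
#'   `percent = NA` with a warning.
#' @examples
#' percent_change(3.19, 2.84)  # 10.97 % reduction
#' @export
percent_change <- function(before, after) {
  if (!is.finite(before) || !is.finite(after)) {
    warning("percent change undefined for non-finite inputs", call. = FALSE)
    return(list(percent = NA_real_, direction = NA_character_))
  }
  if (before == 0) {
    warning("percent change undefined for before = 0", call. = FALSE)
    return(list(percent = NA_real_, direction = NA_character_))
  }
  list(percent = 100 * abs(after - before) / before,
       direction = if (after > before) "increase"
                   else if (after < before) "decrease" else "none")
}

label_one_change <- function(pct, th) {
  if (!is.finite(pct)) return(NA_character_)
  if (pct < th$cold_below) "COLD"
  else if (pct <= th$compartmentalized_above) "MIXED"
  else "COMPARTMENTALIZED"
}

#' Classify the TME from metric percent changes
#'
#' Applies the change bands to each supplied metric change and derives a
#' consensus label from the median change across the supplied metrics.
#' The rationale: cold microenvironments barely remodel under treatment
#' (sub-percent metric changes), mixed ones shift modestly, and conversion
#' to a compartmentalized pattern moves the spatial metrics by more than
#' 10 percent.
#'
#' @param changes Named numeric vector of absolute percent changes, one
#'   per metric (NA entries are ignored for the consensus).
#' @param thresholds A [change_thresholds()].
#' @return List with `per_metric` (named character vector of labels) and
#'   `consensus` (single label, the label of the median defined change).
#'   All-NA input yields `consensus = NA` with a warning.
#' @examples
#' classify_by_change(c(mixing_score = 64.03, gcross_auc = 34.71))
#' @export
classify_by_change <- function(changes, thresholds = change_thresholds()) {
  stopifnot(is.numeric(changes))
  per <- vapply(changes, label_one_change, character(1),
                th = thresholds)
  ok <- is.finite(changes)
  if (!any(ok)) {
    warning("all metric changes undefined; consensus label is NA",
            call. = FALSE)
    return(list(per_metric = per, consensus = NA_character_))
  }
  list(per_metric = per,
       consensus = label_one_change(stats::median(changes[ok]), thresholds))
}

#' Bivariate classification thresholds
#'
#' Split values for [classify_bivariate()]. The direction of each split is
#' fixed by the biology: low mixing score, low average neighbor frequency
#' and low G-cross AUC, or high spatial entropy, indicate a
#' compartmentalized architecture; a high cancer:immune ratio indicates a
#' cold one regardless of the spatial metric. The numeric split values are
#' not canonical — the defaults here are round numbers chosen for the
#' simulator's test-scale output, and [calibrate_bivariate_thresholds()]
#' derives them from a pair of reference runs instead. Always overridable.
#'
#' @param ratio_cold_above Cancer:immune ratio at or above which the TME is
#'   labeled cold (default 10).
#' @param splits Named numeric vector of per-metric split values with
#'   defaults `mixing_score = 0.5`, `avg_neighbor_frequency = 0.3`,
#'   `shannon_entropy = 0.5`, `gcross_auc = 25`.
#' @return A `bivariate_thresholds` object.
#' @export
bivariate_thresholds <- function(ratio_cold_above = 10,
                                 splits = c(mixing_score = 0.5,
                                            avg_neighbor_frequency = 0.3,
                                            shannon_entropy = 0.5,
                                            gcross_auc = 25)) {
  defaults <- c(mixing_score = 0.5, avg_neighbor_frequency = 0.3,
                shannon_entropy = 0.5, gcross_auc = 25)
  defaults[names(splits)] <- splits
  structure(list(ratio_cold_above = ratio_cold_above, splits = defaults),
            class = "bivariate_thresholds")
}

# which side of the split means COMPARTMENTALIZED, per metric
.comp_side_low <- c(mixing_score = TRUE, avg_neighbor_frequency = TRUE,
                    gcross_auc = TRUE, shannon_entropy = FALSE)

#' Calibrate bivariate split values from two reference runs
#'
#' Sets each metric's split to the midpoint between its time-averaged
#' value under an effective-treatment run (expected compartmentalized
#' side) and an ineffective-treatment run (expected mixed side).
#'
#' @param avg_effective,avg_ineffective Named numeric vectors of
#'   time-averaged metric values from the two reference runs (names as in
#'   [bivariate_thresholds()]).
#' @param ratio_cold_above Passed through.
#' @return A [bivariate_thresholds()].
#' @export
calibrate_bivariate_thresholds <- function(avg_effective, avg_ineffective,
                                           ratio_cold_above = 10) {
  common <- intersect(names(avg_effective), names(avg_ineffective))
  common <- intersect(common, names(.comp_side_low))
  if (!length(common)) stop("no shared metric names", call. = FALSE)
  bivariate_thresholds(
    ratio_cold_above = ratio_cold_above,
    splits = (avg_effective[common] + avg_ineffective[common]) / 2)
}

#' Bivariate metric-by-ratio classification
#'
#' Labels one observation from a spatial metric value together with the
#' cancer:immune cell ratio. A high ratio (immune-scarce tissue) is cold
#' no matter what the spatial metric says; otherwise the metric decides
#' between compartmentalized and mixed, with the direction fixed per
#' metric (see [bivariate_thresholds()]).
#'
#' @param metric_name One of `"mixing_score"`, `"avg_neighbor_frequency"`,
#'   `"shannon_entropy"`, `"gcross_auc"`.
#' @param metric_value Metric value.
#' @param ratio Cancer:immune cell ratio.
#' @param thresholds A [bivariate_thresholds()].
#' @return One of [TME_LABELS], or `NA` if either input is `NA`.
#' @export
classify_bivariate <- function(metric_name, metric_value, ratio,
                               thresholds = bivariate_thresholds()) {
  if (!metric_name %in% names(.comp_side_low))
    stop("unknown metric name: ", metric_name, call. = FALSE)
  if (!is.finite(metric_value) || !is.finite(ratio)) return(NA_character_)
  if (ratio >= thresholds$ratio_cold_above) return("COLD")
  split <- thresholds$splits[[metric_name]]
  low_is_comp <- .comp_side_low[[metric_name]]
  comp <- if (low_is_comp) metric_value < split else metric_value > split
  if (comp) "COMPARTMENTALIZED" else "MIXED"
}

#' Time average of a metric series
#'
#' Arithmetic mean of the defined values of one metric over the full
#' simulated interval, with the replicate spread when replicate ids are
#' present. Undefined (NA) samples — e.g. immune-dependent metrics before
#' the first recruitment — are skipped, not imputed.
#'
#' @param series `data.frame` with columns `time`, the metric column, and
#'   optionally `replicate`.
#' @param metric_name Column to average.
#' @return List with `mean` (grand mean over defined values),
#'   `replicate_mean` and `replicate_sd` (across per-replicate averages;
#'   `NA` sd for a single replicate), and `n_defined`.
#' @export
time_average <- function(series, metric_name) {
  if (!metric_name %in% names(series))
    stop("series has no column ", metric_name, call. = FALSE)
  v <- series[[metric_name]]
  ok <- is.finite(v)
  if (!any(ok)) {
    warning("no defined values to average", call. = FALSE)
    return(list(mean = NA_real_, replicate_mean = NA_real_,
                replicate_sd = NA_real_, n_defined = 0L))
  }
  per_rep <- if ("replicate" %in% names(series)) {
    tapply(v[ok], series$replicate[ok], mean)
  } else mean(v[ok])
  list(mean = mean(v[ok]),
       replicate_mean = mean(per_rep),
       replicate_sd = if (length(per_rep) > 1) stats::sd(per_rep)
                      else NA_real_,
       n_defined = sum(ok))
}
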
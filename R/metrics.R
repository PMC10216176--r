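#' Configuration for the spatial heterogeneity metrics
#'
#' @param neighbor_radius Neighborhood radius in micrometers for the mixing
#'   score and average neighbor frequency. Default 50; values between 30
#'   and 50 are customary for cell-contact neighborhoods in multiplexed
#'   pathology. The default sits at the upper end so a single length scale
#'   is shared with the G-cross radius.
#' @param gcross_radius Integration radius `r` in micrometers for the
#'   G-cross AUC (default 50).
#' @param quadrature_points Number of fixed nodes for the trapezoidal
#'   integration of the G-cross function (default 200, >= 2).
#' @param grouping A [type_grouping()] mapping cell types to metric classes.
#' @param max_class_cells Per-class cap for the all-pairs distance averages
#'   in the spatial entropy; beyond it the class is subsampled with a fixed
#'   internal seed (see [shannon_entropy()]). Default 2000.
#' @param exact_distances If `TRUE`, never subsample (exact all-pairs means
#'   regardless of size).
#' @return A `metric_config` object.
#' @export
metric_config <- function(neighbor_radius = 50, gcross_radius = 50,
                          quadrature_points = 200,
                          grouping = type_grouping(),
                          max_class_cells = 2000,
                          exact_distances = FALSE) {
  if (neighbor_radius <= 0 || gcross_radius <= 0)
    stop("radii must be > 0", call. = FALSE)
  if (quadrature_points < 2) stop("quadrature_points must be >= 2",
                                  call. = FALSE)
  structure(list(neighbor_radius = neighbor_radius,
                 gcross_radius = gcross_radius,
                 quadrature_points = as.integer(quadrature_points),
                 grouping = grouping,
                 max_class_cells = as.integer(max_class_cells),
                 exact_distances = isTRUE(exact_distances)),
            class = "metric_config")
}

# Shared "metric undefined" signal: warn once and return NA, so an
# undefined value is never confused with a true 0 (early simulation times
# have no immune cells at all).
undefined_metric <- function(what) {
  warning(what, " is undefined on this input (no immune cells); returning NA",
          call. = FALSE)
  NA_real_
}

#' Mixing score
#'
#' Fraction of immune cells in the map that have at least one cancer cell
#' within the neighborhood radius. High values indicate immune cells
#' intermingled with (or confined to the margin of) the tumor mass; on a
#' cold pattern, where the few immune cells all sit against the tumor, the
#' score is 1. Lower scores accompany compartmentalized architectures.
#'
#' @param cells A 2-D [cell_map()], typically an ROI crop.
#' @param cfg A [metric_config()].
#' @return Fraction in `[0, 1]`, or `NA` (with a warning) when the map
#'   contains no immune cells.
#' @export
mixing_score <- function(cells, cfg = metric_config()) {
  cl <- split_classes(cells, cfg$grouping)
  if (nrow(cl$immune) == 0L) return(undefined_metric("mixing_score"))
  if (nrow(cl$cancer) == 0L) return(0)
  k <- count_within_radius(cl$immune$x, cl$immune$y,
                           cl$cancer$x, cl$cancer$y, cfg$neighbor_radius)
  mean(k > 0L)
}

#' Average neighbor frequency
#'
#' A localized refinement of the mixing score: for each immune cell the
#' fraction of its neighbors (all cells within the neighborhood radius,
#' excluding itself) that are cancer cells, averaged over immune cells.
#' An immune cell with an empty neighborhood contributes 0. Because the
#' per-cell fraction never exceeds the per-cell at-least-one indicator,
#' this metric is bounded above by the mixing score on the same input.
#'
#' @inheritParams mixing_score
#' @return Fraction in `[0, 1]`, or `NA` when there are no immune cells.
#' @export
avg_neighbor_frequency <- function(cells, cfg = metric_config()) {
  cl <- split_classes(cells, cfg$grouping)
  n_imm <- nrow(cl$immune)
  if (n_imm == 0L) return(undefined_metric("avg_neighbor_frequency"))
  allx <- c(cl$cancer$x, cl$immune$x)
  ally <- c(cl$cancer$y, cl$immune$y)
  k_can <- if (nrow(cl$cancer)) {
    count_within_radius(cl$immune$x, cl$immune$y,
                        cl$cancer$x, cl$cancer$y, cfg$neighbor_radius)
  } else integer(n_imm)
  k_all <- count_within_radius(cl$immune$x, cl$immune$y, allx, ally,
                               cfg$neighbor_radius) - 1L # drop the focal cell
  f <- ifelse(k_all > 0L, k_can / k_all, 0)
  mean(f)
}

# mean of all pairwise distances within a point set (>= 2 points)
mean_pairwise_dist <- function(xy) mean(stats::dist(xy))

# mean distance over all cross pairs a x b
mean_cross_dist <- function(a, b) {
  dx <- outer(a$x, b$x, "-")
  dy <- outer(a$y, b$y, "-")
  mean(sqrt(dx * dx + dy * dy))
}

# subsample rows with a local, restored RNG state so metric calls do not
# perturb simulation reproducibility
subsample_rows <- function(df, n_max, seed = 20230501L) {
  if (nrow(df) <= n_max) return(df)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  df[sample.int(nrow(df), n_max), , drop = FALSE]
}

#' Spatial Shannon entropy of the cancer cells
#'
#' Distance-weighted Shannon entropy restricted to the cancer class:
#' `ESP = -(d_int / d_ext) * p * log2(p)`, where `d_int` is the mean
#' pairwise Euclidean distance among cancer cells, `d_ext` the mean
#' distance over all (cancer, non-cancer) pairs, and `p` the cancer
#' fraction of all cells in the map. A nearly pure cancer map (`p -> 1`)
#' drives the entropy to 0, as in cold patterns; immune infiltration and
#' segregation of the cancer class around an immune-rich core raise it,
#' so high values accompany compartmentalized architecture while mixed
#' patterns sit lower (`d_int/d_ext ~ 1`).
#'
#' Degenerate inputs follow the conventions: `p = 1` (no non-cancer cells)
#' or fewer than 2 cancer cells give 0; an empty map is undefined (`NA`).
#' For maps beyond `cfg$max_class_cells` per class, the all-pairs means are
#' estimated on a fixed-seed subsample unless `cfg$exact_distances`.
#'
#' @inheritParams mixing_score
#' @return Non-negative real (bits-scaled, dimensionless), or `NA` on an
#'   empty map.
#' @export
shannon_entropy <- function(cells, cfg = metric_config()) {
  cl <- split_classes(cells, cfg$grouping)
  n_can <- nrow(cl$cancer)
  n_other <- nrow(cl$immune)
  n_tot <- n_can + n_other
  if (n_tot == 0L) {
    warning("shannon_entropy is undefined on an empty map; returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  if (n_can < 2L || n_other == 0L) return(0)
  p <- n_can / n_tot
  cap <- if (cfg$exact_distances) Inf else cfg$max_class_cells
  can <- if (n_can > cap) subsample_rows(cl$cancer, cfg$max_class_cells)
         else cl$cancer
  oth <- if (n_other > cap) subsample_rows(cl$immune, cfg$max_class_cells,
                                           seed = 20230502L)
         else cl$immune
  d_int <- mean_pairwise_dist(can)
  d_ext <- mean_cross_dist(can, oth)
  -(d_int / d_ext) * p * log2(p)
}

#' Area under the G-cross function
#'
#' Parametric (Poisson-form) cross nearest-neighbor function from immune to
#' cancer cells: `G(s) = 1 - exp(-p_y * pi * s^2)`, with `p_y` the local
#' cancer density seen by each immune cell (cancer cells within the radius
#' `r`, divided by `pi r^2`). `G` is integrated from 0 to `r` by fixed-node
#' trapezoidal quadrature for every immune cell and the per-cell areas are
#' averaged. The result lies in `[0, r]` micrometers; it approaches `r`
#' when every immune cell is embedded in dense cancer (cold patterns) and
#' is larger for mixed than for compartmentalized architectures.
#'
#' @inheritParams mixing_score
#' @return Mean AUC in micrometers, in `[0, gcross_radius]`; `NA` when
#'   there are no immune cells.
#' @export
gcross_auc <- function(cells, cfg = metric_config()) {
  cl <- split_classes(cells, cfg$grouping)
  n_imm <- nrow(cl$immune)
  if (n_imm == 0L) return(undefined_metric("gcross_auc"))
  r <- cfg$gcross_radius
  k <- if (nrow(cl$cancer)) {
    count_within_radius(cl$immune$x, cl$immune$y,
                        cl$cancer$x, cl$cancer$y, r)
  } else integer(n_imm)
  # p_y only depends on the integer neighbor count: integrate per unique k
  uk <- sort(unique(k))
  auc_k <- gcross_auc_uniform(uk / (pi * r^2), r, cfg$quadrature_points)
  mean(auc_k[match(k, uk)])
}

#' G-cross AUC under a uniform cancer density
#'
#' Area under `G(s) = 1 - exp(-p_y * pi * s^2)` from 0 to `r` for a given
#' (spatially uniform) cancer density, by the same fixed-node trapezoidal
#' quadrature the per-cell metric uses. For large `p_y * pi * r^2` the
#' value approaches (but never exceeds) `r`.
#'
#' @param p_y Cancer density in cells/um^2 (vectorized).
#' @param r Integration radius in micrometers (default 50).
#' @param quadrature_points Number of quadrature nodes (default 200).
#' @return AUC in micrometers, same length as `p_y`.
#' @export
gcross_auc_uniform <- function(p_y, r = 50, quadrature_points = 200) {
  s <- seq(0, r, length.out = quadrature_points)
  h <- s[2] - s[1]
  w <- rep(h, length(s)); w[c(1, length(s))] <- h / 2
  vapply(p_y, function(py) sum(w * (1 - exp(-py * pi * s^2))), numeric(1))
}

#' Cancer-to-immune cell ratio
#'
#' @param cells A [cell_map()].
#' @param grouping A [type_grouping()].
#' @return `n_cancer / n_immune`, or `NA` when there are no immune cells.
#' @export
cell_ratio <- function(cells, grouping = type_grouping()) {
  cl <- split_classes(cells, grouping)
  if (nrow(cl$immune) == 0L) return(undefined_metric("cell_ratio"))
  nrow(cl$cancer) / nrow(cl$immune)
}

#' Compute all heterogeneity metrics on one cell map
#'
#' Evaluates the four spatial metrics plus the cancer:immune ratio on a
#' (typically ROI-cropped, 2-D) map and returns them as a one-row record.
#' Metrics that are undefined on the input (no immune cells) are carried
#' as `NA`, never silently as 0.
#'
#' @param cells A 2-D [cell_map()].
#' @param cfg A [metric_config()].
#' @param time Time stamp in days attached to the record (default `NA`).
#' @return A one-row `data.frame` with columns `time`, `mixing_score`,
#'   `avg_neighbor_frequency`, `shannon_entropy`, `gcross_auc`,
#'   `cell_ratio`, `n_cancer`, `n_immune`.
#' @export
compute_metrics <- function(cells, cfg = metric_config(), time = NA_real_) {
  cl <- split_classes(cells, cfg$grouping)
  n_can <- nrow(cl$cancer)
  n_imm <- nrow(cl$immune)
  rec <- data.frame(
    time = time,
    mixing_score = suppressWarnings(mixing_score(cells, cfg)),
    avg_neighbor_frequency = suppressWarnings(avg_neighbor_frequency(cells,
                                                                     cfg)),
    shannon_entropy = suppressWarnings(shannon_entropy(cells, cfg)),
    gcross_auc = suppressWarnings(gcross_auc(cells, cfg)),
    cell_ratio = suppressWarnings(cell_ratio(cells, cfg$grouping)),
    n_cancer = n_can, n_immune = n_imm)
  if (n_imm == 0L)
    warning("no immune cells: immune-dependent metrics recorded as NA",
            call. = FALSE)
  rec
}
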
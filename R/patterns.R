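#' Specification for a synthetic immunoarchitecture pattern
#'
#' Describes a labeled 2-D point pattern emulating one of the three
#' tumor-microenvironment archetypes:
#' * `COLD` — cancer cells uniform over the ROI at high density, immune
#'   cells confined to the ROI margin, each guaranteed (by rejection
#'   sampling against the realized cancer pattern) to have at least one
#'   cancer cell within 50 um, so the mixing score is exactly 1 by
#'   construction;
#' * `MIXED` — both classes uniform i.i.d. over the ROI;
#' * `COMPARTMENTALIZED` — cancer and immune cells uniform in disjoint
#'   regions. The default `"core-rim"` layout places the immune
#'   compartment as a central disc with cancer in the surrounding rim,
#'   the configuration effective checkpoint therapy produces when T cells
#'   hollow out the tumor interior; `"half-split"` puts cancer in the left
#'   and immune in the right half.
#'
#' @param archetype One of `"COLD"`, `"MIXED"`, `"COMPARTMENTALIZED"`.
#' @param roi An [roi()] (default the standard 1 x 1 mm tile at the
#'   origin-corner position `(500, 500)`).
#' @param n_cancer,n_immune Cell counts (>= 0); generated counts match
#'   exactly.
#' @param compartment_geometry `"half-split"` or `"core-rim"` (only used
#'   for `COMPARTMENTALIZED`).
#' @param margin_width Width in micrometers of the marginal band that
#'   holds immune cells in `COLD` patterns (default 60).
#' @param seed Integer seed; generation is a pure function of
#'   `(spec, seed)`.
#' @return A `pattern_spec` object.
#' @export
pattern_spec <- function(archetype = c("COLD", "MIXED", "COMPARTMENTALIZED"),
                         roi = NULL,
                         n_cancer = 1500, n_immune = 150,
                         compartment_geometry = c("core-rim", "half-split"),
                         margin_width = 60, seed = 1L) {
  archetype <- match.arg(archetype)
  compartment_geometry <- match.arg(compartment_geometry)
  if (is.null(roi)) roi <- tmearch::roi(c(500, 500))
  stopifnot(inherits(roi, "roi"))
  if (n_cancer < 0 || n_immune < 0) stop("counts must be >= 0",
                                         call. = FALSE)
  if (archetype == "COLD" && n_cancer == 0 && n_immune > 0)
    stop("a COLD pattern with immune cells requires cancer cells",
         call. = FALSE)
  structure(list(archetype = archetype, roi = roi,
                 n_cancer = as.integer(n_cancer),
                 n_immune = as.integer(n_immune),
                 compartment_geometry = compartment_geometry,
                 margin_width = margin_width, seed = as.integer(seed)),
            class = "pattern_spec")
}

#' Generate a synthetic immunoarchitecture pattern
#'
#' Draws the point pattern described by a [pattern_spec()]. Cancer cells
#' get type `CANCER_PROGENITOR`, immune cells `T_EFF` (the metric layer
#' only sees the cancer/immune classes).
#'
#' @param spec A [pattern_spec()].
#' @return A 2-D [cell_map()] whose bounds are the ROI.
#' @export
generate_pattern <- function(spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  x0 <- spec$roi$center[1] - spec$roi$width / 2
  y0 <- spec$roi$center[2] - spec$roi$height / 2
  w <- spec$roi$width
  h <- spec$roi$height
  runif_rect <- function(n, xa, xb, ya, yb)
    data.frame(x = runif(n, xa, xb), y = runif(n, ya, yb))
  can <- imm <- data.frame(x = numeric(), y = numeric())
  if (spec$archetype == "MIXED") {
    can <- runif_rect(spec$n_cancer, x0, x0 + w, y0, y0 + h)
    imm <- runif_rect(spec$n_immune, x0, x0 + w, y0, y0 + h)
  } else if (spec$archetype == "COLD") {
    can <- runif_rect(spec$n_cancer, x0, x0 + w, y0, y0 + h)
    imm <- cold_margin_immune(spec, can, x0, y0, w, h)
  } else { # COMPARTMENTALIZED
    if (spec$compartment_geometry == "half-split") {
      can <- runif_rect(spec$n_cancer, x0, x0 + w / 2, y0, y0 + h)
      imm <- runif_rect(spec$n_immune, x0 + w / 2, x0 + w, y0, y0 + h)
    } else { # core-rim: immune disc in the center, cancer in the rim
      r_core <- 0.35 * min(w, h)
      cx <- x0 + w / 2; cy <- y0 + h / 2
      imm <- sample_disc(spec$n_immune, cx, cy, r_core)
      can <- sample_rect_outside_disc(spec$n_cancer, x0, y0, w, h,
                                      cx, cy, r_core)
    }
  }
  cells <- rbind(
    if (nrow(can)) data.frame(can, cell_type = "CANCER_PROGENITOR"),
    if (nrow(imm)) data.frame(imm, cell_type = "T_EFF"))
  if (is.null(cells))
    cells <- data.frame(x = numeric(), y = numeric(),
                        cell_type = character())
  cells <- data.frame(id = seq_len(nrow(cells)), cells)
  cell_map(cells, bounds(c(x0, x0 + w), c(y0, y0 + h)))
}

# immune cells on the ROI margin, rejection-sampled so each has >= 1
# cancer cell within 50 um of it
cold_margin_immune <- function(spec, can, x0, y0, w, h) {
  n <- spec$n_immune
  if (n == 0L) return(data.frame(x = numeric(), y = numeric()))
  m <- spec$margin_width
  out <- data.frame(x = numeric(), y = numeric())
  tries <- 0L
  while (nrow(out) < n) {
    tries <- tries + 1L
    if (tries > 200L)
      stop("could not place marginal immune cells with a cancer neighbor",
           call. = FALSE)
    need <- (n - nrow(out)) * 4L
    # uniform over the margin band: sample the full rect, keep the band
    p <- data.frame(x = runif(need, x0, x0 + w), y = runif(need, y0, y0 + h))
    band <- pmin(p$x - x0, x0 + w - p$x, p$y - y0, y0 + h - p$y) <= m
    p <- p[band, , drop = FALSE]
    if (!nrow(p)) next
    k <- count_within_radius(p$x, p$y, can$x, can$y, 50)
    out <- rbind(out, p[k > 0L, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

sample_disc <- function(n, cx, cy, r) {
  th <- runif(n, 0, 2 * pi)
  rr <- r * sqrt(runif(n))
  data.frame(x = cx + rr * cos(th), y = cy + rr * sin(th))
}

sample_rect_outside_disc <- function(n, x0, y0, w, h, cx, cy, r) {
  out <- data.frame(x = numeric(), y = numeric())
  while (nrow(out) < n) {
    p <- data.frame(x = runif(2L * n, x0, x0 + w),
                    y = runif(2L * n, y0, y0 + h))
    keep <- (p$x - cx)^2 + (p$y - cy)^2 > r^2
    out <- rbind(out, p[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Deterministic lattice fixture with known geometry
#'
#' Lays out cancer and immune cells on a regular square lattice with the
#' requested counts and spacing. All pairwise distances are lattice
#' multiples, which makes the metric values hand-computable — useful for
#' analytic unit tests and worked examples.
#'
#' Cells fill a near-square grid row-major, cancer cells first, then
#' immune cells.
#'
#' @param n_cancer,n_immune Exact counts.
#' @param spacing Lattice spacing in micrometers (> 0), default 20.
#' @return A 2-D [cell_map()] bounding the lattice.
#' @export
grid_fixture <- function(n_cancer, n_immune, spacing = 20) {
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  n <- n_cancer + n_immune
  if (n == 0L)
    return(cell_map(data.frame(id = integer(), x = numeric(),
                               y = numeric(), cell_type = character()),
                    bounds(c(0, spacing), c(0, spacing))))
  ncol_ <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  x <- (idx %% ncol_) * spacing
  y <- (idx %/% ncol_) * spacing
  cells <- data.frame(
    id = seq_len(n), x = x, y = y,
    cell_type = c(rep("CANCER_PROGENITOR", n_cancer),
                  rep("T_EFF", n_immune)))
  pad <- spacing / 2
  cell_map(cells, bounds(c(-pad, max(x) + pad), c(-pad, max(y) + pad)))
}
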
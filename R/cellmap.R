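#' Cell type vocabulary
#'
#' The seven cell states tracked by the simulator and understood by the
#' metrics: three cancer states (stem-like, progenitor, senescent) and four
#' T-cell states (effector, cytotoxic, exhausted CD8+ cells, and regulatory
#' T cells).
#'
#' @format Character vector of the seven admissible `cell_type` values.
#' @export
CELL_TYPES <- c("CANCER_CSC", "CANCER_PROGENITOR", "CANCER_SENESCENT",
                "T_EFF", "T_CYT", "T_EXH", "TREG")

#' Map cell types onto metric classes
#'
#' The spatial metrics binarize the seven cell states into cancer vs immune.
#' By default all three cancer states map to `"CANCER"` and all four T-cell
#' states (including regulatory T cells) map to `"IMMUNE"`; individual types
#' can be reassigned, e.g. `type_grouping(TREG = "EXCLUDED")` to drop Tregs
#' from the immune class. Cells mapped to `"EXCLUDED"` are removed before
#' any metric is computed.
#'
#' @param ... Named overrides, one per cell type, each one of
#'   `"CANCER"`, `"IMMUNE"`, `"EXCLUDED"`.
#' @return Named character vector over all seven cell types
#'   (class `"type_grouping"`).
#' @examples
#' type_grouping()
#' type_grouping(TREG = "EXCLUDED")
#' @export
type_grouping <- function(...) {
  g <- c(CANCER_CSC = "CANCER", CANCER_PROGENITOR = "CANCER",
         CANCER_SENESCENT = "CANCER",
         T_EFF = "IMMUNE", T_CYT = "IMMUNE", T_EXH = "IMMUNE",
         TREG = "IMMUNE")
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("overrides must be named by cell type", call. = FALSE)
    bad <- setdiff(names(dots), CELL_TYPES)
    if (length(bad))
      stop("unknown cell type(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    vals <- unlist(dots, use.names = FALSE)
    if (!all(vals %in% c("CANCER", "IMMUNE", "EXCLUDED")))
      stop("classes must be CANCER, IMMUNE or EXCLUDED", call. = FALSE)
    g[names(dots)] <- vals
  }
  structure(g, class = "type_grouping")
}

#' Axis-aligned bounding box
#'
#' @param xlim,ylim,zlim Numeric length-2 ranges in micrometers; `zlim = NULL`
#'   for a 2-D domain.
#' @return A `bounds` object.
#' @export
bounds <- function(xlim, ylim, zlim = NULL) {
  chk <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 2 || any(!is.finite(v)) || v[1] >= v[2])
      stop(nm, " must be a finite, increasing length-2 range", call. = FALSE)
    as.numeric(v)
  }
  b <- list(xlim = chk(xlim, "xlim"), ylim = chk(ylim, "ylim"),
            zlim = if (!is.null(zlim)) chk(zlim, "zlim"))
  structure(b, class = "bounds")
}

#' Marked cell point pattern
#'
#' A `cell_map` bundles a table of cells (id, position in micrometers,
#' cell type) with the bounding box of the domain they live in. It is the
#' common currency between the simulator, the I/O layer, and the spatial
#' metrics. 3-D maps come out of the simulator; 2-D maps arise from
#' [slice_2d()] and mimic a pathology slide.
#'
#' @param cells `data.frame` with columns `id`, `x`, `y`, `cell_type`, and
#'   `z` for 3-D maps. Extra columns (e.g. `birth_time`, `division_count`)
#'   are carried along untouched.
#' @param bounds A [bounds()] object; must have `zlim` iff `cells` has `z`.
#' @return A `cell_map` object.
#' @export
cell_map <- function(cells, bounds) {
  if (!inherits(bounds, "bounds")) stop("bounds must be a bounds object",
                                        call. = FALSE)
  dim3 <- !is.null(bounds$zlim)
  need <- c("id", "x", "y", if (dim3) "z", "cell_type")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("cells is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  cells$cell_type <- as.character(cells$cell_type)
  bad <- !cells$cell_type %in% CELL_TYPES
  if (any(bad))
    stop("unknown cell_type value(s): ",
         paste(unique(cells$cell_type[bad]), collapse = ", "),
         " (row ", which(bad)[1], ")", call. = FALSE)
  if (anyDuplicated(cells$id))
    stop("duplicate cell ids", call. = FALSE)
  coord_ok <- function(v, lim, nm) {
    if (any(!is.finite(v)))
      stop("non-finite ", nm, " coordinate (row ", which(!is.finite(v))[1],
           ")", call. = FALSE)
    out <- v < lim[1] | v > lim[2]
    if (any(out))
      stop(nm, " coordinate outside bounds (row ", which(out)[1], ")",
           call. = FALSE)
  }
  coord_ok(cells$x, bounds$xlim, "x")
  coord_ok(cells$y, bounds$ylim, "y")
  if (dim3) coord_ok(cells$z, bounds$zlim, "z")
  structure(list(cells = cells, bounds = bounds,
                 dimensionality = if (dim3) 3L else 2L),
            class = "cell_map")
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("<cell_map> %d cells, %d-D\n", nrow(x$cells),
              x$dimensionality))
  cat(sprintf("  x: [%g, %g] um  y: [%g, %g] um",
              x$bounds$xlim[1], x$bounds$xlim[2],
              x$bounds$ylim[1], x$bounds$ylim[2]))
  if (!is.null(x$bounds$zlim))
    cat(sprintf("  z: [%g, %g] um", x$bounds$zlim[1], x$bounds$zlim[2]))
  cat("\n")
  tab <- table(x$cells$cell_type)
  if (length(tab))
    cat("  ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' Number of cells in a cell map
#' @param x A `cell_map`.
#' @return Integer count.
#' @export
n_cells <- function(x) nrow(x$cells)

#' Read a cell table
#'
#' Reads a delimiter-separated text file with header columns
#' `id,x,y[,z],cell_type` (coordinates in micrometers; 2-D files omit `z`)
#' and validates it against the given domain bounds.
#'
#' @param path File path.
#' @param bounds A [bounds()] object declaring the domain; its
#'   dimensionality must match the file (presence/absence of a `z` column).
#' @return A [cell_map()].
#' @export
read_cells <- function(path, bounds) {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  dim3 <- !is.null(bounds$zlim)
  need <- c("id", "x", "y", if (dim3) "z", "cell_type")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) {
    df <- data.frame(id = integer(), x = numeric(), y = numeric(),
                     cell_type = character())
    if (dim3) df$z <- numeric()
  }
  cell_map(df[, intersect(c(need, setdiff(names(df), need)), names(df)),
              drop = FALSE], bounds)
}

#' Write a cell table
#'
#' Writes the cells of a map as comma-separated text with a header, at full
#' double precision so that [read_cells()] round-trips exactly.
#'
#' @param cellmap A `cell_map`.
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_cells <- function(cellmap, path) {
  cols <- c("id", "x", "y", if (cellmap$dimensionality == 3L) "z",
            "cell_type")
  df <- cellmap$cells[, cols, drop = FALSE]
  # 17 significant digits: the shortest representation guaranteed to
  # round-trip an IEEE double exactly
  for (v in intersect(c("x", "y", "z"), names(df)))
    df[[v]] <- formatC(df[[v]], digits = 17, format = "g")
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' Take a 2-D slice of a 3-D cell map
#'
#' Retains cells with `|z - z_center| <= thickness/2`, discards `z`, and
#' returns a 2-D map over the same x/y bounds — the in-silico analogue of
#' cutting a histology section. The default slice is one voxel layer
#' (20 um) at the mid-plane of the box.
#'
#' @param cellmap A 3-D `cell_map`.
#' @param z_center Slice center in micrometers; default mid-plane.
#' @param thickness Slab thickness in micrometers (> 0), default 20.
#' @return A 2-D `cell_map`. An empty slice is a valid 0-cell map.
#' @export
slice_2d <- function(cellmap, z_center = NULL, thickness = 20) {
  if (cellmap$dimensionality != 3L) stop("cellmap must be 3-D", call. = FALSE)
  if (!is.numeric(thickness) || thickness <= 0)
    stop("thickness must be > 0", call. = FALSE)
  zl <- cellmap$bounds$zlim
  if (is.null(z_center)) z_center <- mean(zl)
  if (z_center < zl[1] || z_center > zl[2])
    stop("z_center outside domain bounds", call. = FALSE)
  keep <- abs(cellmap$cells$z - z_center) <= thickness / 2
  df <- cellmap$cells[keep, setdiff(names(cellmap$cells), "z"),
                      drop = FALSE]
  cell_map(df, bounds(cellmap$bounds$xlim, cellmap$bounds$ylim))
}

#' Rectangular region of interest
#'
#' @param center Numeric length-2 `(x, y)` center in micrometers.
#' @param width,height Side lengths in micrometers (default 1000 x 1000,
#'   the 1 x 1 mm tile used for all metric computations).
#' @return An `roi` object.
#' @export
roi <- function(center, width = 1000, height = 1000) {
  if (!is.numeric(center) || length(center) != 2 || any(!is.finite(center)))
    stop("center must be a finite (x, y) pair", call. = FALSE)
  if (width <= 0 || height <= 0)
    stop("width and height must be > 0", call. = FALSE)
  structure(list(center = as.numeric(center), width = as.numeric(width),
                 height = as.numeric(height)),
            class = "roi")
}

#' Center-cropped ROI of a slide
#'
#' Convenience constructor: the ROI of the given size centered in the
#' bounds of a 2-D map.
#'
#' @param cellmap A 2-D `cell_map` (or any object with `$bounds`).
#' @param width,height ROI side lengths in micrometers.
#' @return An [roi()].
#' @export
center_roi <- function(cellmap, width = 1000, height = 1000) {
  roi(c(mean(cellmap$bounds$xlim), mean(cellmap$bounds$ylim)),
      width, height)
}

#' Crop a 2-D cell map to a region of interest
#'
#' Cells inside the half-open rectangle `[x0, x0+w) x [y0, y0+h)` are
#' retained (half-open so that tiling an image into ROIs never counts a
#' cell twice); the bounds of the result are the ROI itself.
#'
#' @param cellmap A 2-D `cell_map`.
#' @param roi An [roi()] fully contained in the map's bounds.
#' @return A 2-D `cell_map` over the ROI.
#' @export
crop_roi <- function(cellmap, roi) {
  if (cellmap$dimensionality != 2L) stop("cellmap must be 2-D", call. = FALSE)
  x0 <- roi$center[1] - roi$width / 2
  y0 <- roi$center[2] - roi$height / 2
  x1 <- x0 + roi$width
  y1 <- y0 + roi$height
  b <- cellmap$bounds
  if (x0 < b$xlim[1] || x1 > b$xlim[2] || y0 < b$ylim[1] || y1 > b$ylim[2])
    stop("ROI exceeds slide bounds", call. = FALSE)
  cc <- cellmap$cells
  keep <- cc$x >= x0 & cc$x < x1 & cc$y >= y0 & cc$y < y1
  cell_map(cc[keep, , drop = FALSE], bounds(c(x0, x1), c(y0, y1)))
}

# Split a map's cells into metric classes; drops EXCLUDED cells.
# Returns list(cancer=, immune=) of data.frames with x,y columns.
split_classes <- function(cellmap, grouping = type_grouping()) {
  cls <- unname(grouping[cellmap$cells$cell_type])
  list(cancer = cellmap$cells[cls == "CANCER", c("x", "y"), drop = FALSE],
       immune = cellmap$cells[cls == "IMMUNE", c("x", "y"), drop = FALSE])
}
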
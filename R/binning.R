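#' One subject/section/region marker set
#'
#' Holds the neuron-marker coordinates of a single subject on one section
#' plane in one region, in micrometres. Binning requires coordinates in the
#' registered frame (superior-left contour corner at (0, 0)); use
#' [register_markers()] or [register_to_anchor()] first. An optional z column
#' is carried through but ignored by 2D binning.
#'
#' @param subject_id,condition,region character metadata.
#' @param bregma_mm section plane in mm.
#' @param points n x 2 numeric matrix of (x, y) in micrometres.
#' @param z optional numeric vector of z coordinates (um), length n.
#' @param registered logical: are the coordinates in the registered frame?
#' @return Object of class `marker_set`.
#' @export
marker_set <- function(subject_id, condition, bregma_mm, region, points,
                       z = NULL, registered = FALSE) {
  p <- .as_xy(points)
  if (nrow(p) && !all(is.finite(p))) stop("non-finite marker coordinates")
  if (!is.null(z) && length(z) != nrow(p)) stop("z length must match points")
  structure(list(subject_id = as.character(subject_id),
                 condition = as.character(condition),
                 bregma_mm = as.numeric(bregma_mm),
                 region = as.character(region),
                 points = p, z = z,
                 registered = isTRUE(registered)),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %s/%s %s @ %s mm: %d markers (%sregistered)\n",
              x$subject_id, x$condition, x$region, format(x$bregma_mm),
              nrow(x$points), if (x$registered) "" else "NOT "))
  invisible(x)
}

#' Register a marker set against its contour
#'
#' @param markers a [marker_set] in the same raw frame as `contour`.
#' @param contour the region's [roi_contour].
#' @return List with the registered `markers` and `contour`.
#' @export
register_markers <- function(markers, contour) {
  stopifnot(inherits(markers, "marker_set"))
  reg <- register_to_anchor(markers$points, contour)
  markers$points <- reg$points
  markers$registered <- TRUE
  list(markers = markers, contour = reg$contour)
}

#' Optimal bin area from the 2A/n rule
#'
#' Bin area is twice the sampling (contour) area divided by the mean number
#' of items counted per subject — twice the expected frequency of items in a
#' random field — giving an unbiased, standardised bin dimension. Bins are
#' square: `bin_side = sqrt(bin_area)`.
#'
#' @param contour_area sampling area in square micrometres (> 0).
#' @param mean_count mean number of marked items per subject (> 0).
#' @return List with `bin_area` (um^2) and `bin_side` (um).
#' @examples
#' optimal_bin_area(1000, 20)  # bin_area 100, bin_side 10
#' @export
optimal_bin_area <- function(contour_area, mean_count) {
  if (!is.finite(contour_area) || contour_area <= 0) {
    stop("contour_area must be positive")
  }
  if (!is.finite(mean_count) || mean_count <= 0) {
    stop("mean_count is zero or invalid: enter a manual bin size instead")
  }
  bin_area <- 2 * contour_area / mean_count
  list(bin_area = bin_area, bin_side = sqrt(bin_area))
}

#' Build a uniform square bin grid
#'
#' Edges start at (`x_min`, `y_min`) and advance in steps of `bin_side` until
#' the final edge reaches or passes the maximum, so the grid always covers
#' every input coordinate; a final bin extending past the data range is
#' flagged as overhang.
#'
#' @param x_min,x_max,y_min,y_max data extent in micrometres.
#' @param bin_side bin edge length in micrometres (> 0).
#' @return Object of class `bin_grid` with `x_edges`, `y_edges`, `bin_side`,
#'   `bin_area`, `n_x`, `n_y`, `overhang` (logical x/y).
#' @export
build_grid <- function(x_min, x_max, y_min, y_max, bin_side) {
  if (!is.finite(bin_side) || bin_side <= 0) stop("bin_side must be positive")
  if (!(x_max > x_min) || !(y_max > y_min)) {
    stop("max extent must exceed min extent on both axes")
  }
  eps <- 1e-9 * bin_side
  nx <- max(1L, as.integer(ceiling((x_max - x_min) / bin_side - eps)))
  ny <- max(1L, as.integer(ceiling((y_max - y_min) / bin_side - eps)))
  xe <- x_min + bin_side * (0:nx)
  ye <- y_min + bin_side * (0:ny)
  structure(list(x_edges = xe, y_edges = ye, bin_side = bin_side,
                 bin_area = bin_side^2, n_x = nx, n_y = ny,
                 overhang = c(x = xe[nx + 1L] > x_max + eps,
                              y = ye[ny + 1L] > y_max + eps)),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> %d x %d bins of %.3g um (area %.3g um^2), x [%.3g, %.3g], y [%.3g, %.3g]\n",
              x$n_x, x$n_y, x$bin_side, x$bin_area,
              x$x_edges[1], x$x_edges[length(x$x_edges)],
              x$y_edges[1], x$y_edges[length(x$y_edges)]))
  invisible(x)
}

#' Grid from the pooled extent of several marker sets
#'
#' Mirrors the manual dialog: the minimum bin beginning and maximum bin end
#' per axis default to the smallest and largest coordinates over all files,
#' each overridable.
#'
#' @param marker_sets list of [marker_set] objects.
#' @param bin_side bin edge length (um).
#' @param x_min,x_max,y_min,y_max optional manual extent overrides.
#' @return A [build_grid()] `bin_grid`.
#' @export
grid_from_markers <- function(marker_sets, bin_side, x_min = NULL,
                              x_max = NULL, y_min = NULL, y_max = NULL) {
  pts <- do.call(rbind, lapply(marker_sets, function(m) m$points))
  if (is.null(pts) || !nrow(pts)) stop("no markers to derive a grid extent from")
  build_grid(x_min %||% min(pts[, 1]), x_max %||% max(pts[, 1]),
             y_min %||% min(pts[, 2]), y_max %||% max(pts[, 2]), bin_side)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## bin index per axis under the half-open [lo, hi) rule, terminal edge closed
.axis_bin <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[x < edges[1L] | x > edges[length(edges)]] <- 0L  # outside
  i
}

#' Count markers per grid bin
#'
#' Each point falls in the bin `[edge_i, edge_{i+1})` on both axes; points on
#' a shared edge go to the higher-index bin, and points exactly on the final
#' edge belong to the last bin. Points outside the grid are counted and
#' reported, never silently dropped.
#'
#' @param markers a registered [marker_set].
#' @param grid a [bin_grid].
#' @return List with `counts` (`n_x` x `n_y` integer matrix), `n_inside`,
#'   `n_outside`.
#' @export
bin_counts <- function(markers, grid) {
  stopifnot(inherits(markers, "marker_set"), inherits(grid, "bin_grid"))
  if (!markers$registered) {
    stop("marker set must be registered before binning (see register_markers)")
  }
  p <- markers$points
  cnt <- matrix(0L, grid$n_x, grid$n_y)
  if (nrow(p)) {
    ix <- .axis_bin(p[, 1], grid$x_edges)
    iy <- .axis_bin(p[, 2], grid$y_edges)
    ok <- ix >= 1L & iy >= 1L
    if (any(ok)) {
      tab <- table(factor(ix[ok], levels = seq_len(grid$n_x)),
                   factor(iy[ok], levels = seq_len(grid$n_y)))
      cnt <- matrix(as.integer(tab), grid$n_x, grid$n_y)
    }
    n_out <- sum(!ok)
  } else n_out <- 0L
  list(counts = cnt, n_inside = sum(cnt), n_outside = n_out)
}

## flat bin order: x index fastest, matching as.vector(counts_matrix)
.bin_names <- function(grid) {
  idx <- expand.grid(i = seq_len(grid$n_x), j = seq_len(grid$n_y))
  sprintf("bin_%d_%d", idx$i, idx$j)
}

#' Bin centre coordinates in flat bin order
#'
#' @param grid a [bin_grid].
#' @return `data.frame` with `i`, `j`, `x_center_um`, `y_center_um`.
#' @export
bin_centers <- function(grid) {
  stopifnot(inherits(grid, "bin_grid"))
  xc <- (grid$x_edges[-1L] + grid$x_edges[-(grid$n_x + 1L)]) / 2
  yc <- (grid$y_edges[-1L] + grid$y_edges[-(grid$n_y + 1L)]) / 2
  idx <- expand.grid(i = seq_len(grid$n_x), j = seq_len(grid$n_y))
  data.frame(i = idx$i, j = idx$j,
             x_center_um = xc[idx$i], y_center_um = yc[idx$j])
}

## TRUE where a bin intersects the contour, probed on a 3x3 lattice per bin
.bins_in_contour <- function(grid, contour) {
  cen <- bin_centers(grid)
  s <- grid$bin_side
  offs <- expand.grid(dx = c(-0.45, 0, 0.45) * s, dy = c(-0.45, 0, 0.45) * s)
  inside <- rep(FALSE, nrow(cen))
  for (k in seq_len(nrow(offs))) {
    probe <- cbind(cen$x_center_um + offs$dx[k], cen$y_center_um + offs$dy[k])
    inside <- inside | point_in_contour(probe, contour)
  }
  inside
}

#' Assemble the subjects x bins count matrix
#'
#' Bins every marker set on one shared grid and stacks the flattened counts
#' into one row per (subject, section), sorted by condition then subject_id.
#' When a contour is supplied, bins lying wholly outside it are flagged
#' `in_contour = FALSE` (retained, so statistics can mask them).
#'
#' @param marker_sets list of registered [marker_set] objects sharing one
#'   region and Bregma plane.
#' @param grid shared [bin_grid].
#' @param contour optional registered [roi_contour] for out-of-contour flags.
#' @param allow_mixed allow mixed regions/planes (default `FALSE`).
#' @return Object of class `bin_matrix`: `grid`, `counts` (rows x bins
#'   integer matrix, columns named `bin_i_j`), `meta` (`subject_id`,
#'   `condition`, `bregma_mm`, `region`, `n_outside`), `in_contour` (logical
#'   per bin or `NULL`).
#' @export
assemble_matrix <- function(marker_sets, grid, contour = NULL,
                            allow_mixed = FALSE) {
  stopifnot(length(marker_sets) >= 1L, inherits(grid, "bin_grid"))
  regions <- unique(vapply(marker_sets, `[[`, "", "region"))
  planes <- unique(vapply(marker_sets, `[[`, 0, "bregma_mm"))
  if (!allow_mixed && (length(regions) > 1L || length(planes) > 1L)) {
    stop("marker sets mix regions/planes (",
         paste(regions, collapse = ","), " @ ",
         paste(format(planes), collapse = ","),
         "); pass allow_mixed = TRUE to override")
  }
  ord <- order(vapply(marker_sets, `[[`, "", "condition"),
               vapply(marker_sets, `[[`, "", "subject_id"))
  marker_sets <- marker_sets[ord]
  rows <- lapply(marker_sets, bin_counts, grid = grid)
  counts <- do.call(rbind, lapply(rows, function(r) as.vector(r$counts)))
  colnames(counts) <- .bin_names(grid)
  meta <- data.frame(
    subject_id = vapply(marker_sets, `[[`, "", "subject_id"),
    condition = vapply(marker_sets, `[[`, "", "condition"),
    bregma_mm = vapply(marker_sets, `[[`, 0, "bregma_mm"),
    region = vapply(marker_sets, `[[`, "", "region"),
    n_outside = vapply(rows, `[[`, 0L, "n_outside"),
    stringsAsFactors = FALSE)
  in_contour <- if (!is.null(contour)) .bins_in_contour(grid, contour) else NULL
  structure(list(grid = grid, counts = counts, meta = meta,
                 in_contour = in_contour),
            class = "bin_matrix")
}

#' @export
print.bin_matrix <- function(x, ...) {
  cat(sprintf("<bin_matrix> %d rows x %d bins (%d x %d grid); conditions: %s\n",
              nrow(x$counts), ncol(x$counts), x$grid$n_x, x$grid$n_y,
              paste(unique(x$meta$condition), collapse = ", ")))
  if (!is.null(x$in_contour)) {
    cat(sprintf("  %d/%d bins intersect the contour\n", sum(x$in_contour),
                length(x$in_contour)))
  }
  invisible(x)
}

#' Average multiple section rows to one row per subject
#'
#' Statistics require independent replicates: the same individual must not be
#' represented twice. Rows sharing a subject_id (multiple sections at one
#' plane) are averaged bin-wise.
#'
#' @param bm a [assemble_matrix()] `bin_matrix`.
#' @return A `bin_matrix` with one row per subject (counts may be fractional).
#' @export
aggregate_subjects <- function(bm) {
  stopifnot(inherits(bm, "bin_matrix"))
  if (!anyDuplicated(bm$meta$subject_id)) return(bm)
  sid <- bm$meta$subject_id
  keep <- !duplicated(sid)
  counts <- rowsum(bm$counts, sid, reorder = FALSE) /
    as.vector(table(factor(sid, levels = unique(sid))))
  meta <- bm$meta[keep, , drop = FALSE]
  meta$n_outside <- as.vector(rowsum(bm$meta$n_outside, sid, reorder = FALSE))
  rownames(meta) <- NULL
  bm$counts <- counts
  bm$meta <- meta
  bm
}
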
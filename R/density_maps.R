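## internal density_map constructor
.density_map <- function(grid, values, statistic, condition, n_subjects,
                         mask) {
  structure(list(grid = grid, values = values, statistic = statistic,
                 condition = condition, n_subjects = n_subjects,
                 mask = mask),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<density_map> %s [%s], n = %d, %d/%d valid bins, range [%.4g, %.4g]\n",
              x$statistic, paste(x$condition, collapse = " - "), x$n_subjects,
              sum(x$mask), length(x$mask),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

.condition_rows <- function(bm, condition) {
  rows <- which(bm$meta$condition == condition)
  if (!length(rows)) {
    stop(sprintf("unknown condition '%s'; available: %s", condition,
                 paste(unique(bm$meta$condition), collapse = ", ")))
  }
  rows
}

.base_mask <- function(bm) {
  if (is.null(bm$in_contour)) rep(TRUE, ncol(bm$counts)) else bm$in_contour
}

#' Mean density map for one condition
#'
#' Per-bin arithmetic mean over a condition's rows (the average "across all
#' sheets"). With `normalize = "rate"` each row is first divided by its total
#' in-grid count, so subjects with unequal totals contribute equal weight.
#'
#' @param bm a `bin_matrix`.
#' @param condition condition label to average.
#' @param normalize `"none"` (raw counts, default) or `"rate"`.
#' @return A `density_map` with `statistic = "mean"` (units: neurons/bin, or
#'   fraction of a subject's markers per bin under `"rate"`).
#' @export
mean_map <- function(bm, condition, normalize = c("none", "rate")) {
  stopifnot(inherits(bm, "bin_matrix"))
  normalize <- match.arg(normalize)
  rows <- .condition_rows(bm, condition)
  y <- bm$counts[rows, , drop = FALSE]
  if (normalize == "rate") {
    tot <- rowSums(y)
    tot[tot == 0] <- 1
    y <- y / tot
  }
  .density_map(bm$grid, colMeans(y), "mean", condition,
               length(unique(bm$meta$subject_id[rows])), .base_mask(bm))
}

#' Standard-deviation map for one condition
#'
#' Per-bin sample (n-1) SD across a condition's rows.
#'
#' @inheritParams mean_map
#' @return A `density_map` with `statistic = "sd"`.
#' @export
sd_map <- function(bm, condition) {
  stopifnot(inherits(bm, "bin_matrix"))
  rows <- .condition_rows(bm, condition)
  if (length(rows) < 2L) stop("sd_map needs >= 2 rows in the condition")
  y <- bm$counts[rows, , drop = FALSE]
  .density_map(bm$grid, apply(y, 2L, stats::sd), "sd", condition,
               length(unique(bm$meta$subject_id[rows])), .base_mask(bm))
}

#' Coefficient-of-variance map for one condition
#'
#' Per-bin sample SD divided by the mean: a unitless across-subject
#' consistency measure. Bins with zero mean are masked invalid (0/0 carries
#' no information), not set to zero or infinity.
#'
#' @inheritParams mean_map
#' @return A `density_map` with `statistic = "cv"`.
#' @export
cv_map <- function(bm, condition) {
  stopifnot(inherits(bm, "bin_matrix"))
  rows <- .condition_rows(bm, condition)
  if (length(rows) < 2L) {
    stop("cv_map needs >= 2 subjects (sample SD undefined for one)")
  }
  y <- bm$counts[rows, , drop = FALSE]
  m <- colMeans(y)
  s <- apply(y, 2L, stats::sd)
  cv <- ifelse(m > 0, s / m, NA_real_)
  mask <- .base_mask(bm) & m > 0
  .density_map(bm$grid, cv, "cv", condition,
               length(unique(bm$meta$subject_id[rows])), mask)
}

#' Difference map between two condition means
#'
#' Per-bin `a - b` of two mean maps on the identical grid; masks intersect.
#' Grids must match exactly — no silent resampling.
#'
#' @param map_a,map_b `density_map`s with `statistic = "mean"`.
#' @return A `density_map` with `statistic = "difference"`.
#' @export
difference_map <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "density_map"), inherits(map_b, "density_map"))
  if (map_a$statistic != "mean" || map_b$statistic != "mean") {
    stop("difference_map requires two mean maps")
  }
  ga <- map_a$grid; gb <- map_b$grid
  same <- length(ga$x_edges) == length(gb$x_edges) &&
    length(ga$y_edges) == length(gb$y_edges) &&
    max(abs(ga$x_edges - gb$x_edges), abs(ga$y_edges - gb$y_edges)) < 1e-9
  if (!same) stop("grid mismatch between maps; rebin on a shared grid")
  .density_map(ga, map_a$values - map_b$values, "difference",
               c(map_a$condition, map_b$condition),
               min(map_a$n_subjects, map_b$n_subjects),
               map_a$mask & map_b$mask)
}

#' Map of FDR q-values onto the bin grid
#'
#' @param mroi an [mroi_detect()] result.
#' @return A `density_map` with `statistic = "qvalue"`.
#' @export
qvalue_map <- function(mroi) {
  stopifnot(inherits(mroi, "mroi_result"))
  q <- rep(NA_real_, mroi$grid$n_x * mroi$grid$n_y)
  q[mroi$table$bin] <- mroi$table$q
  mask <- !is.na(q)
  .density_map(mroi$grid, q, "qvalue", "all", mroi$n_subjects, mask)
}

#' Render a density map as a heat-map image with a numeric sidecar
#'
#' Writes a PNG or SVG of per-bin colour cells (masked bins grey), an
#' optional contour outline, an optional calibrated background raster, and a
#' colour bar, plus a machine-readable sidecar table
#' (`<file>.sidecar.tsv`: bin_i, bin_j, x_center_um, y_center_um, value,
#' mask) recording exactly the numbers rendered. The y axis is drawn in
#' image convention (ventral downward) and labelled so maps read like the
#' sections they came from.
#'
#' @param map a `density_map`.
#' @param file output image path; format from extension unless `format`
#'   given.
#' @param contour optional registered [roi_contour] to outline.
#' @param background optional list `(image = , um_per_px = , offset_um = )`
#'   with a numeric matrix or rgb array in `[0, 1]`; both calibration
#'   entries are mandatory when an image is supplied.
#' @param zlim optional length-2 colour-scale limits.
#' @param palette colour vector; default a perceptually uniform ramp.
#' @param format `"png"` or `"svg"` (default from `file` extension).
#' @param width,height device size in pixels (png) / inches (svg).
#' @return Invisibly, list with `file` and `sidecar` paths.
#' @export
render_map <- function(map, file, contour = NULL, background = NULL,
                       zlim = NULL, palette = grDevices::hcl.colors(64, "viridis"),
                       format = NULL, width = 800, height = 700) {
  stopifnot(inherits(map, "density_map"))
  format <- format %||% tolower(tools::file_ext(file))
  if (!format %in% c("png", "svg")) stop("format must be png or svg")
  if (!is.null(background)) {
    if (is.null(background$um_per_px) || is.null(background$offset_um)) {
      stop("background image requires um_per_px and offset_um calibration")
    }
  }
  g <- map$grid
  vals <- matrix(map$values, g$n_x, g$n_y)
  vals[!matrix(map$mask, g$n_x, g$n_y)] <- NA
  zlim <- zlim %||% range(vals, na.rm = TRUE)
  if (!all(is.finite(zlim)) || zlim[1] == zlim[2]) zlim <- zlim[1] + c(-0.5, 0.5)

  dir.create(dirname(file), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    if (format == "png") grDevices::png(file, width, height)
    else grDevices::svg(file, width / 100, height / 100)
    TRUE
  }, error = function(e) stop("cannot open image device for ", file))
  on.exit(grDevices::dev.off(), add = TRUE)

  graphics::layout(matrix(1:2, 1L), widths = c(5, 1))
  graphics::par(mar = c(4.5, 4.5, 3, 1))
  xr <- range(g$x_edges); yr <- range(g$y_edges)
  # y reversed: image convention, ventral downward
  graphics::plot(NA, xlim = xr, ylim = rev(yr), asp = 1,
                 xlab = "x (µm)", ylab = "y (µm, ventral →)",
                 main = sprintf("%s map [%s], n = %d", map$statistic,
                                paste(map$condition, collapse = " − "),
                                map$n_subjects))
  if (!is.null(background)) {
    img <- background$image
    h_um <- nrow(as.array(img)) * background$um_per_px
    w_um <- ncol(as.array(img)) * background$um_per_px
    graphics::rasterImage(img, background$offset_um[1],
                          background$offset_um[2] + h_um,
                          background$offset_um[1] + w_um,
                          background$offset_um[2])
  }
  zcut <- pmin(pmax(vals, zlim[1]), zlim[2])
  cols <- matrix(palette[1L + round((zcut - zlim[1]) / diff(zlim) *
                                      (length(palette) - 1L))], g$n_x, g$n_y)
  cols[is.na(vals)] <- grDevices::grey(0.85)
  for (j in seq_len(g$n_y)) {
    graphics::rect(g$x_edges[seq_len(g$n_x)], g$y_edges[j],
                   g$x_edges[seq_len(g$n_x) + 1L], g$y_edges[j + 1L],
                   col = cols[, j], border = NA)
  }
  if (!is.null(contour)) {
    stopifnot(inherits(contour, "roi_contour"))
    v <- rbind(contour$vertices, contour$vertices[1L, ])
    graphics::lines(v[, 1], v[, 2], lwd = 2, col = "black")
  }
  graphics::box()
  # colour bar
  graphics::par(mar = c(4.5, 0.5, 3, 2.5))
  graphics::image(1, seq(zlim[1], zlim[2], length.out = length(palette)),
                  matrix(seq_along(palette), 1L), col = palette,
                  axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext(.map_units(map$statistic), side = 4, line = 1.5, cex = 0.8)

  sidecar <- paste0(file, ".sidecar.tsv")
  cen <- bin_centers(g)
  side_df <- data.frame(bin_i = cen$i, bin_j = cen$j,
                        x_center_um = cen$x_center_um,
                        y_center_um = cen$y_center_um,
                        value = map$values, mask = map$mask)
  utils::write.table(format(side_df, digits = 15, trim = TRUE, scientific = FALSE),
                     sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(file = file, sidecar = sidecar))
}

.map_units <- function(statistic) {
  switch(statistic,
         mean = "neurons / bin", sd = "neurons / bin",
         difference = "Δ neurons / bin",
         cv = "CV (unitless)", qvalue = "q", "")
}
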
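#' Anatomical contour (closed polygon in micrometres)
#'
#' Constructs a validated closed region-of-interest polygon: the spatial
#' reference frame that markers, bin grids and maps all register to. Vertices
#' are in micrometres in image convention (y increases ventrally). A trailing
#' vertex duplicating the first (explicit closure) is stripped; closure is
#' implicit.
#'
#' @param vertices two-column numeric matrix (or data.frame) of x, y vertex
#'   coordinates in micrometres, ordered along the boundary.
#' @param label region name, e.g. `"LAd"`, `"PL"`, `"IL"`.
#' @param bregma_mm signed rostrocaudal Bregma coordinate of the section plane
#'   in millimetres (positive = anterior).
#' @return An object of class `roi_contour` with elements `vertices`, `label`,
#'   `bregma_mm`.
#' @examples
#' sq <- roi_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), label = "unit")
#' polygon_area(sq)
#' @export
roi_contour <- function(vertices, label = "ROI", bregma_mm = NA_real_) {
  v <- as.matrix(vertices)
  if (ncol(v) < 2L) stop("contour vertices need x and y columns")
  v <- v[, 1:2, drop = FALSE]
  storage.mode(v) <- "double"
  if (!all(is.finite(v))) stop("contour vertices must be finite")
  n <- nrow(v)
  if (n >= 4L && all(v[1L, ] == v[n, ])) v <- v[-n, , drop = FALSE]
  n <- nrow(v)
  if (n < 3L) stop("a contour needs at least 3 vertices")
  nxt <- c(2:n, 1L)
  if (any(rowSums(abs(v - v[nxt, , drop = FALSE])) == 0)) {
    stop("consecutive duplicate vertices in contour")
  }
  if (.shoelace(v) < .Machine$double.eps * max(abs(v), 1)^2) {
    stop("invalid geometry: degenerate polygon (zero enclosed area)")
  }
  if (!.is_simple_polygon(v)) {
    stop("invalid geometry: polygon is self-intersecting")
  }
  structure(
    list(vertices = unname(v), label = as.character(label),
         bregma_mm = as.numeric(bregma_mm)),
    class = "roi_contour"
  )
}

#' @export
print.roi_contour <- function(x, ...) {
  cat(sprintf("<roi_contour> %s | Bregma %s mm | %d vertices | area %.1f um^2\n",
              x$label, format(x$bregma_mm), nrow(x$vertices), polygon_area(x)))
  invisible(x)
}

## unsigned shoelace area of a vertex matrix (no validation)
.shoelace <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

## proper / improper segment intersection test over all non-adjacent edge
## pairs; O(n^2), fine for traced contours (tens of vertices)
.is_simple_polygon <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  ax <- v[, 1]; ay <- v[, 2]
  bx <- v[j, 1]; by <- v[j, 2]
  cross3 <- function(ox, oy, px, py, qx, qy) {
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  }
  on_seg <- function(ox, oy, px, py, qx, qy) {
    qx >= pmin(ox, px) & qx <= pmax(ox, px) &
      qy >= pmin(oy, py) & qy <= pmax(oy, py)
  }
  for (i in seq_len(n - 2L)) {
    ks <- (i + 2L):n
    if (i == 1L) ks <- ks[ks != n]  # edge n..1 is adjacent to edge 1..2
    if (!length(ks)) next
    d1 <- cross3(ax[i], ay[i], bx[i], by[i], ax[ks], ay[ks])
    d2 <- cross3(ax[i], ay[i], bx[i], by[i], bx[ks], by[ks])
    d3 <- cross3(ax[ks], ay[ks], bx[ks], by[ks], ax[i], ay[i])
    d4 <- cross3(ax[ks], ay[ks], bx[ks], by[ks], bx[i], by[i])
    proper <- (sign(d1) * sign(d2) < 0) & (sign(d3) * sign(d4) < 0)
    if (any(proper)) return(FALSE)
    touch <- (d1 == 0 & on_seg(ax[i], ay[i], bx[i], by[i], ax[ks], ay[ks])) |
      (d2 == 0 & on_seg(ax[i], ay[i], bx[i], by[i], bx[ks], by[ks])) |
      (d3 == 0 & on_seg(ax[ks], ay[ks], bx[ks], by[ks], ax[i], ay[i])) |
      (d4 == 0 & on_seg(ax[ks], ay[ks], bx[ks], by[ks], bx[i], by[i]))
    if (any(touch)) return(FALSE)
  }
  TRUE
}

.as_xy <- function(points) {
  if (is.null(points) || (is.matrix(points) && nrow(points) == 0L)) {
    return(matrix(numeric(0), ncol = 2L))
  }
  p <- as.matrix(points)
  if (length(p) == 2L && ncol(p) != 2L) p <- matrix(as.numeric(p), ncol = 2L)
  if (ncol(p) < 2L) stop("points need x and y columns")
  p <- p[, 1:2, drop = FALSE]
  storage.mode(p) <- "double"
  p
}

#' Enclosed contour area (shoelace formula)
#'
#' @param contour an [roi_contour].
#' @return Area in square micrometres; independent of vertex orientation and
#'   starting vertex.
#' @export
polygon_area <- function(contour) {
  stopifnot(inherits(contour, "roi_contour"))
  .shoelace(contour$vertices)
}

#' Maximum Feret diameter of a contour
#'
#' The maximum caliper distance across the shape: the largest distance between
#' two parallel tangent lines, attained between two vertices of the convex
#' hull. Computed by exhaustive pairwise distances over the hull (hulls of
#' traced contours are small; rotating calipers is unnecessary).
#'
#' @param contour an [roi_contour].
#' @return Maximum Feret length in micrometres.
#' @export
max_feret <- function(contour) {
  stopifnot(inherits(contour, "roi_contour"))
  v <- unique(contour$vertices)
  if (nrow(v) < 2L) stop("invalid geometry: fewer than 2 distinct vertices")
  h <- v[grDevices::chull(v), , drop = FALSE]
  max(stats::dist(h))
}

#' Register a contour (and markers) to the superior-left anchor
#'
#' Translates the contour so the (min x, min y) corner of its bounding box —
#' the "superior left corner" in image convention — lands on (0, 0), and
#' applies the identical translation to any marker points. A rigid
#' translation: all relative geometry is preserved; idempotent.
#'
#' @param points optional n x 2 matrix of marker coordinates (micrometres) in
#'   the contour's frame; may be `NULL` or empty for contour-only
#'   registration.
#' @param contour an [roi_contour].
#' @return List with `points` (translated matrix, possibly 0-row), `contour`
#'   (translated [roi_contour]) and `offset` (the subtracted (x, y) anchor).
#' @export
register_to_anchor <- function(points = NULL, contour) {
  stopifnot(inherits(contour, "roi_contour"))
  p <- .as_xy(points)
  if (nrow(p) && !all(is.finite(p))) stop("non-finite marker coordinates")
  anchor <- c(min(contour$vertices[, 1]), min(contour$vertices[, 2]))
  ctr <- contour
  ctr$vertices <- sweep(contour$vertices, 2L, anchor)
  if (nrow(p)) p <- sweep(p, 2L, anchor)
  list(points = p, contour = ctr, offset = anchor)
}

#' Rotate points in the section plane
#'
#' Standard planar rotation (counter-clockwise for positive angles in a y-up
#' frame; in the package's y-down image convention positive angles turn
#' clockwise on screen). Distances are preserved.
#'
#' @param points n x 2 matrix of (x, y) in micrometres.
#' @param angle_degrees rotation angle in degrees.
#' @param pivot length-2 centre of rotation, default the origin.
#' @return Rotated n x 2 matrix.
#' @export
rotate_points <- function(points, angle_degrees, pivot = c(0, 0)) {
  p <- .as_xy(points)
  if (!all(is.finite(p)) || !all(is.finite(pivot)) ||
      !is.finite(angle_degrees)) {
    stop("non-finite input to rotate_points")
  }
  th <- angle_degrees * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  sweep(sweep(p, 2L, pivot) %*% t(R), 2L, pivot, `+`)
}

#' Number of sections between two Bregma planes
#'
#' Bregma distances are millimetres, section thickness micrometres; e.g.
#' Bregma 2.76 mm is 0.48 mm from 3.24 mm, giving 8 sections of 60 um or 12
#' sections of 40 um. Non-exact multiples are flagged, not errored: real
#' cutting thickness varies.
#'
#' @param bregma_a_mm,bregma_b_mm section planes in mm (order irrelevant).
#' @param thickness_um section thickness in micrometres (> 0).
#' @return List with `count` (integer, nearest), `exact_multiple` (logical)
#'   and `distance_um`.
#' @export
sections_between <- function(bregma_a_mm, bregma_b_mm, thickness_um) {
  if (!is.finite(thickness_um) || thickness_um <= 0) {
    stop("section thickness must be a positive number of micrometres")
  }
  d_um <- abs(bregma_a_mm - bregma_b_mm) * 1000
  n_real <- d_um / thickness_um
  count <- as.integer(round(n_real))
  exact <- isTRUE(abs(n_real - count) < 1e-6 * max(1, n_real))
  if (!exact) {
    warning(sprintf("Bregma interval %.3f mm is not an exact multiple of %g um",
                    d_um / 1000, thickness_um))
  }
  list(count = count, exact_multiple = exact, distance_um = d_um)
}

#' Point-in-contour test
#'
#' Crossing-number containment, vectorised over points. Boundary points count
#' as inside (convention: prevents silent loss of markers placed on traced
#' edges).
#'
#' @param points n x 2 matrix (or length-2 vector) of (x, y) micrometres.
#' @param contour an [roi_contour].
#' @param tol boundary tolerance in micrometres.
#' @return Logical vector, one verdict per point.
#' @export
point_in_contour <- function(points, contour, tol = 1e-9) {
  stopifnot(inherits(contour, "roi_contour"))
  p <- .as_xy(points)
  if (!nrow(p)) return(logical(0))
  v <- contour$vertices
  n <- nrow(v)
  px <- p[, 1]; py <- p[, 2]
  inside <- rep(FALSE, nrow(p))
  on_bd <- rep(FALSE, nrow(p))
  j <- n
  for (i in seq_len(n)) {
    x1 <- v[j, 1]; y1 <- v[j, 2]; x2 <- v[i, 1]; y2 <- v[i, 2]
    # distance to segment (vectorised over points)
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    t_ <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
    d2 <- (x1 + t_ * dx - px)^2 + (y1 + t_ * dy - py)^2
    on_bd <- on_bd | d2 <= tol * tol
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xint <- x1 + (py - y1) * dx / dy
      inside <- xor(inside, crosses & px < xint)
    }
    j <- i
  }
  inside | on_bd
}
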
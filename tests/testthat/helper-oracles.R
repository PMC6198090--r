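# Independent oracles and fixture builders. Everything here is deliberately
# written by a different route than the package code it checks.

# star-shaped simple polygon: random radii at sorted angles around a centre
random_simple_polygon <- function(n_vertices, centre = c(0, 0), r = c(0.5, 1.5)) {
  th <- sort(runif(n_vertices, 0, 2 * pi))
  rad <- runif(n_vertices, r[1], r[2])
  cbind(centre[1] + rad * cos(th), centre[2] + rad * sin(th))
}

# Monte-Carlo polygon area by rejection sampling against an sp winding test
mc_polygon_area <- function(v, n = 1e6) {
  xr <- range(v[, 1]); yr <- range(v[, 2])
  px <- runif(n, xr[1], xr[2]); py <- runif(n, yr[1], yr[2])
  frac <- mean(winding_inside(px, py, v))
  frac * diff(xr) * diff(yr)
}

# winding-number containment (angle-summation route, independent of the
# package's crossing-number implementation); boundary behaviour undefined
winding_inside <- function(px, py, v) {
  n <- nrow(v)
  total <- rep(0, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a1 <- atan2(v[i, 2] - py, v[i, 1] - px)
    a2 <- atan2(v[j, 2] - py, v[j, 1] - px)
    d <- a2 - a1
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    total <- total + d
  }
  abs(total) > pi
}

# brute-force max pairwise distance over *all* vertices (no hull)
brute_feret <- function(v) {
  mx <- 0
  for (i in seq_len(nrow(v) - 1L)) {
    for (j in (i + 1L):nrow(v)) {
      mx <- max(mx, sqrt(sum((v[i, ] - v[j, ])^2)))
    }
  }
  mx
}

# per-point loop binning oracle under the same half-open convention
brute_bin_counts <- function(pts, x_edges, y_edges) {
  nx <- length(x_edges) - 1L; ny <- length(y_edges) - 1L
  cnt <- matrix(0L, nx, ny)
  n_out <- 0L
  for (r in seq_len(nrow(pts))) {
    x <- pts[r, 1]; y <- pts[r, 2]
    ix <- iy <- 0L
    for (i in seq_len(nx)) {
      hi_ok <- if (i == nx) x <= x_edges[i + 1L] else x < x_edges[i + 1L]
      if (x >= x_edges[i] && hi_ok) { ix <- i; break }
    }
    for (j in seq_len(ny)) {
      hi_ok <- if (j == ny) y <= y_edges[j + 1L] else y < y_edges[j + 1L]
      if (y >= y_edges[j] && hi_ok) { iy <- j; break }
    }
    if (ix > 0L && iy > 0L) cnt[ix, iy] <- cnt[ix, iy] + 1L else
      n_out <- n_out + 1L
  }
  list(counts = cnt, n_outside = n_out)
}

# definition-level BH step-up: largest k with p_(k) <= k*q/m, reject those
bh_stepup_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= seq_len(m) * q / m)
  if (!length(ks)) return(integer(0))
  sort(o[seq_len(max(ks))])
}

# one-way ANOVA by a different route (stats::aov)
aov_oracle <- function(values, group) {
  sm <- summary(stats::aov(values ~ factor(group)))[[1]]
  list(F = sm$`F value`[1], p = sm$`Pr(>F)`[1])
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of group
# assignments (tie-free data only)
mw_enumeration_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    ra <- rank(pooled)[idx]
    sum(ra) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  combs <- combn(length(pooled), na)
  us <- apply(combs, 2L, u_of)
  mu <- na * length(b) / 2
  if (u_obs == mu) return(1)
  p_tail <- if (u_obs > mu) mean(us >= u_obs) else mean(us <= u_obs)
  min(1, 2 * p_tail)
}

# canonical correlations between predictors and group indicators: equals the
# discriminant analysis canonical correlations
cancor_oracle <- function(X, g) {
  g <- factor(g)
  G <- stats::model.matrix(~ g)[, -1, drop = FALSE]
  cc <- stats::cancor(X, G)
  cc$cor
}

# square test contour helpers
square_contour <- function(side = 1, origin = c(0, 0), label = "sq") {
  roi_contour(cbind(origin[1] + c(0, side, side, 0),
                    origin[2] + c(0, 0, side, side)), label = label)
}

# bin_matrix built directly from count rows (bypasses marker plumbing)
counts_bin_matrix <- function(counts, condition, subject_id = NULL,
                              bin_side = 10) {
  n_bins <- ncol(counts)
  grid <- build_grid(0, n_bins * bin_side, 0, bin_side, bin_side)
  sets <- lapply(seq_len(nrow(counts)), function(r) {
    pts <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
      k <- counts[r, b]
      if (k == 0) return(NULL)
      cbind(rep((b - 0.5) * bin_side, k), rep(bin_side / 2, k))
    }))
    if (is.null(pts)) pts <- matrix(numeric(0), ncol = 2)
    marker_set(subject_id[r] %||% sprintf("s%02d", r), condition[r],
               -3.3, "ROI", pts, registered = TRUE)
  })
  assemble_matrix(sets, grid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flat index of the grid bin containing a point (test-side route)
bin_of_point <- function(grid, pt) {
  i <- findInterval(pt[1], grid$x_edges, rightmost.closed = TRUE)
  j <- findInterval(pt[2], grid$y_edges, rightmost.closed = TRUE)
  (j - 1L) * grid$n_x + i
}

# assemble the standard scenario matrix the way the pipeline does
scenario_matrix <- function(sc) {
  n_mean <- mean(vapply(sc$markers, function(m) nrow(m$points), 0))
  side <- optimal_bin_area(polygon_area(sc$contour), n_mean)$bin_side
  assemble_matrix(sc$markers, grid_from_markers(sc$markers, side),
                  contour = sc$contour)
}

# fraction of significant bins in the 8-connected component containing the
# hotspot bin (flood fill over (i, j) indices)
hotspot_component_fraction <- function(sig_ij, grid, hotspot_bin) {
  if (!nrow(sig_ij)) return(0)
  hi <- (hotspot_bin - 1L) %% grid$n_x + 1L
  hj <- (hotspot_bin - 1L) %/% grid$n_x + 1L
  in_comp <- sig_ij$i == hi & sig_ij$j == hj
  if (!any(in_comp)) return(0)
  repeat {
    grow <- !in_comp & vapply(seq_len(nrow(sig_ij)), function(k) {
      any(abs(sig_ij$i[k] - sig_ij$i[in_comp]) <= 1 &
            abs(sig_ij$j[k] - sig_ij$j[in_comp]) <= 1)
    }, logical(1))
    if (!any(grow)) break
    in_comp <- in_comp | grow
  }
  mean(in_comp)
}
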
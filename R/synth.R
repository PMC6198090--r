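## run expr with a locally seeded RNG, restoring global state afterwards
.with_seed <- function(seed, expr) {
  seed <- as.integer(seed)  # force *before* snapshotting the RNG state:
                            # the seed expression may itself consume randomness
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Synthetic cohort configuration
#'
#' The stated world for the generator: a shared ROI contour, per-condition
#' cohort sizes, a uniform background intensity of activated neurons, and
#' optional condition-specific Gaussian hotspots of extra activated neurons.
#' All generation is a pure function of (config, seed).
#'
#' @param contour the shared [roi_contour] (treated as the registered
#'   frame).
#' @param n_subjects named integer vector, subjects per condition, e.g.
#'   `c(conditioned = 7, control = 7)`.
#' @param background_rate uniform intensity in neurons per square
#'   micrometre.
#' @param hotspots named list (one entry per condition that has hotspots) of
#'   lists of `list(centre = c(x, y), sd = um, n_extra = expected extra
#'   neurons)`; centres must lie inside the contour.
#' @param seed integer RNG seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(contour, n_subjects, background_rate,
                       hotspots = list(), seed = 1L) {
  stopifnot(inherits(contour, "roi_contour"))
  if (is.null(names(n_subjects)) || any(!nzchar(names(n_subjects)))) {
    stop("n_subjects must be a named vector (names = condition labels)")
  }
  if (!is.finite(background_rate) || background_rate < 0) {
    stop("background_rate must be >= 0")
  }
  for (cond in names(hotspots)) {
    if (!cond %in% names(n_subjects)) {
      stop("hotspots name unknown condition '", cond, "'")
    }
    for (h in hotspots[[cond]]) {
      if (!is.finite(h$sd) || h$sd <= 0) stop("hotspot sd must be > 0")
      if (!is.finite(h$n_extra) || h$n_extra < 0) {
        stop("hotspot n_extra must be >= 0")
      }
      if (!point_in_contour(matrix(h$centre, 1L), contour)) {
        stop("hotspot centre lies outside the contour")
      }
    }
  }
  structure(list(contour = contour, n_subjects = n_subjects,
                 background_rate = background_rate, hotspots = hotspots,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## uniform points inside a polygon by rejection from the bounding box
.runif_in_contour <- function(n, contour) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2L))
  v <- contour$vertices
  xr <- range(v[, 1]); yr <- range(v[, 2])
  out <- matrix(numeric(0), ncol = 2L)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    cand <- cbind(stats::runif(m, xr[1], xr[2]), stats::runif(m, yr[1], yr[2]))
    out <- rbind(out, cand[point_in_contour(cand, contour), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

## Gaussian points truncated to the polygon (outside draws are redrawn)
.rnorm_in_contour <- function(n, centre, sd, contour) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2L))
  out <- matrix(numeric(0), ncol = 2L)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    cand <- cbind(stats::rnorm(m, centre[1], sd), stats::rnorm(m, centre[2], sd))
    out <- rbind(out, cand[point_in_contour(cand, contour), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Simulate per-subject marker sets
#'
#' Each subject is an independent realisation of an inhomogeneous Poisson
#' process: `Poisson(background_rate x contour area)` uniform points inside
#' the contour plus, per hotspot of the subject's condition,
#' `Poisson(n_extra)` points from a 2D Gaussian truncated to the contour
#' (out-of-contour draws are redrawn, so the expected extra count inside the
#' ROI is met exactly). Per-point origin labels ("background" or
#' "hotspot<k>") are kept in the `origin` attribute of each set.
#'
#' @param config a [sim_config].
#' @param bregma_mm,region metadata stamped on every generated set.
#' @return List of registered [marker_set] objects, one per subject,
#'   deterministic given `config$seed`.
#' @export
simulate_markers <- function(config, bregma_mm = -3.3, region = "ROI") {
  stopifnot(inherits(config, "sim_config"))
  area <- polygon_area(config$contour)
  .with_seed(config$seed, {
    sets <- list()
    for (cond in names(config$n_subjects)) {
      hs <- config$hotspots[[cond]] %||% list()
      for (s in seq_len(config$n_subjects[[cond]])) {
        sid <- sprintf("%s_%02d", cond, s)
        n_bg <- stats::rpois(1L, config$background_rate * area)
        pts <- .runif_in_contour(n_bg, config$contour)
        origin <- rep("background", n_bg)
        for (k in seq_along(hs)) {
          n_h <- stats::rpois(1L, hs[[k]]$n_extra)
          pts <- rbind(pts, .rnorm_in_contour(n_h, hs[[k]]$centre,
                                              hs[[k]]$sd, config$contour))
          origin <- c(origin, rep(sprintf("hotspot%d", k), n_h))
        }
        ms <- marker_set(sid, cond, bregma_mm, region, pts,
                         registered = TRUE)
        attr(ms, "origin") <- origin
        sets[[sid]] <- ms
      }
    }
    sets
  })
}

#' Simulate a paired Feret-length table
#'
#' Every subject is measured at every plane: per-plane landmark means plus
#' independent normal subject noise, mimicking serial sections of a landmark
#' that widens and lengthens along the rostrocaudal axis.
#'
#' @param planes numeric Bregma planes (mm).
#' @param plane_means positive mean Feret lengths (um), one per plane.
#' @param noise_sd normal noise SD (um, >= 0).
#' @param subjects character subject ids.
#' @param conditions optional condition label per subject (recycled;
#'   default `"control"`).
#' @param seed integer RNG seed.
#' @return A [feret_records] table with `length(planes) * length(subjects)`
#'   rows.
#' @export
simulate_feret_table <- function(planes, plane_means, noise_sd, subjects,
                                 conditions = "control", seed = 1L) {
  stopifnot(length(planes) == length(plane_means))
  if (any(!is.finite(plane_means)) || any(plane_means <= 0)) {
    stop("plane means must be positive")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  conditions <- rep_len(conditions, length(subjects))
  .with_seed(seed, {
    grid <- expand.grid(s = seq_along(subjects), p = seq_along(planes))
    feret <- plane_means[grid$p] +
      stats::rnorm(nrow(grid), 0, noise_sd)
    feret <- pmax(feret, 1e-6)   # Feret lengths are physical: > 0
    feret_records(subjects[grid$s], conditions[grid$s], planes[grid$p],
                  feret)
  })
}

## LA-like reference contour: 16-gon approximating a 600 x 450 um ellipse,
## registered so the superior-left bounding corner is (0, 0)
.default_contour <- function(label = "LAd", bregma_mm = -3.3) {
  th <- 2 * pi * (0:15) / 16
  v <- cbind(300 + 300 * cos(th), 225 + 225 * sin(th))
  register_to_anchor(NULL, roi_contour(v, label, bregma_mm))$contour
}

.scenario <- function(seed, effect) {
  ctr <- .default_contour()
  hotspots <- if (effect) {
    list(conditioned = list(list(centre = c(210, 160), sd = 45,
                                 n_extra = 60)))
  } else list()
  cfg <- sim_config(ctr, c(conditioned = 7L, control = 7L),
                    background_rate = 140 / polygon_area(ctr),
                    hotspots = hotspots, seed = seed)
  markers <- simulate_markers(cfg, bregma_mm = ctr$bregma_mm,
                              region = ctr$label)
  feret <- simulate_feret_table(
    planes = c(-3.32, -3.36, -3.40),
    plane_means = c(2400, 2550, 2700), noise_sd = 40,
    subjects = names(markers),
    conditions = vapply(markers, `[[`, "", "condition"),
    seed = seed + 1000L)
  list(contour = ctr, markers = markers, feret = feret, config = cfg,
       truth = list(effect = effect,
                    hotspot_centre = if (effect) c(210, 160) else NULL,
                    hotspot_sd = if (effect) 45 else NULL))
}

#' Packaged two-condition study scenarios
#'
#' `scenario_effect()` is a 7 + 7 subject study ("conditioned" vs "control",
#' ~140 background markers per subject) with a planted dorsolateral hotspot
#' (60 extra activated neurons, SD 45 um) in the conditioned group only;
#' `scenario_null()` is the matched study with no hotspot. When `dir` is
#' given the bundle is written in the package's file dialects (marker files,
#' contour file, Feret table, manifest) so synthetic studies exercise the
#' real I/O path.
#'
#' @param seed integer RNG seed; bundles regenerate byte-identically from it.
#' @param dir optional output directory for an on-disk bundle.
#' @return List with `contour`, `markers` (list of [marker_set]), `feret`,
#'   `config`, `truth` (ground-truth hotspot description), and — when `dir`
#'   is given — `manifest` (path to the written manifest).
#' @export
scenario_effect <- function(seed = 1L, dir = NULL) {
  sc <- .scenario(seed, effect = TRUE)
  if (!is.null(dir)) sc$manifest <- write_scenario(sc, dir)
  sc
}

#' @rdname scenario_effect
#' @export
scenario_null <- function(seed = 1L, dir = NULL) {
  sc <- .scenario(seed, effect = FALSE)
  if (!is.null(dir)) sc$manifest <- write_scenario(sc, dir)
  sc
}
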
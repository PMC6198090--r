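test_that("optimal_bin_area implements the 2A/n rule with its limits", {
  r <- optimal_bin_area(1000, 20)
  expect_equal(r$bin_area, 100)
  expect_equal(r$bin_side, 10)
  # n = 2: one bin covers the whole sampling area
  expect_equal(optimal_bin_area(5432.1, 2)$bin_area, 5432.1)
  # homogeneity: doubling n halves the area exactly
  set.seed(1)
  for (k in 1:5) {
    A <- runif(1, 100, 1e6); n <- runif(1, 1, 500)
    expect_identical(optimal_bin_area(A, 2 * n)$bin_area,
                     optimal_bin_area(A, n)$bin_area / 2)
  }
  expect_error(optimal_bin_area(1000, 0), "manual bin size")
  expect_error(optimal_bin_area(-1, 10), "positive")
})

test_that("build_grid covers the extent, with the overhang rule", {
  g <- build_grid(0, 100, 0, 100, 10)
  expect_identical(g$n_x, 10L)
  expect_equal(g$x_edges, seq(0, 100, 10))
  expect_false(any(g$overhang))
  g2 <- build_grid(0, 95, 0, 95, 10)
  expect_identical(g2$n_x, 10L)
  expect_equal(g2$x_edges[11], 100)
  expect_true(g2$overhang[["x"]])
  expect_error(build_grid(0, 10, 0, 10, 0), "positive")
  expect_error(build_grid(5, 5, 0, 10, 1), "exceed")
})

test_that("a pooled grid contains every marker of every subject", {
  set.seed(2)
  sets <- lapply(1:6, function(s) {
    marker_set(paste0("s", s), "c", -3.3, "R",
               cbind(runif(50, -200, 700), runif(50, 100, 400)),
               registered = TRUE)
  })
  g <- grid_from_markers(sets, bin_side = 37)
  for (ms in sets) {
    r <- bin_counts(ms, g)
    expect_identical(r$n_outside, 0L)
    expect_identical(r$n_inside, 50L)
  }
})

test_that("bin_counts follows the half-open edge convention", {
  g <- build_grid(0, 30, 0, 30, 10)
  one <- function(x, y) bin_counts(marker_set("s", "c", 0, "R",
                                              cbind(x, y), registered = TRUE), g)
  r <- one(15, 5)                       # interior of bin (2, 1)
  expect_identical(r$counts[2, 1], 1L)
  expect_identical(sum(r$counts), 1L)
  # point on a shared vertical edge goes to the right-hand bin
  expect_identical(one(10, 5)$counts[2, 1], 1L)
  # terminal edge belongs to the last bin
  expect_identical(one(30, 30)$counts[3, 3], 1L)
  # outside points are reported, not dropped silently
  r_out <- one(-1, 5)
  expect_identical(r_out$n_outside, 1L)
  expect_identical(sum(r_out$counts), 0L)
  # empty set: all-zero counts
  empty <- marker_set("s", "c", 0, "R", NULL, registered = TRUE)
  expect_identical(sum(bin_counts(empty, g)$counts), 0L)
  # binning requires the registered frame
  raw <- marker_set("s", "c", 0, "R", cbind(1, 1))
  expect_error(bin_counts(raw, g), "registered")
})

test_that("bin_counts equals the per-point brute-force oracle", {
  set.seed(3)
  g <- build_grid(-20, 80, 10, 120, 13)
  pts <- cbind(runif(500, -30, 90), runif(500, 0, 130))
  mine <- bin_counts(marker_set("s", "c", 0, "R", pts, registered = TRUE), g)
  oracle <- brute_bin_counts(pts, g$x_edges, g$y_edges)
  expect_identical(mine$counts, oracle$counts)
  expect_identical(mine$n_outside, oracle$n_outside)
})

test_that("counts are translation-equivariant and refine consistently", {
  set.seed(4)
  pts <- cbind(runif(300, 0, 100), runif(300, 0, 60))
  ms <- function(p) marker_set("s", "c", 0, "R", p, registered = TRUE)
  g <- build_grid(0, 100, 0, 60, 10)
  base <- bin_counts(ms(pts), g)$counts
  # translation of markers and edges together leaves counts identical
  shift <- c(123.25, -45.5)
  g2 <- build_grid(shift[1], 100 + shift[1], shift[2], 60 + shift[2], 10)
  expect_identical(bin_counts(ms(sweep(pts, 2, shift, `+`)), g2)$counts, base)
  # halving bin_side: 2x2 child-block sums reproduce parent counts exactly
  gc <- build_grid(0, 100, 0, 60, 5)
  child <- bin_counts(ms(pts), gc)$counts
  pooled <- child[c(TRUE, FALSE), c(TRUE, FALSE)] +
    child[c(FALSE, TRUE), c(TRUE, FALSE)] +
    child[c(TRUE, FALSE), c(FALSE, TRUE)] +
    child[c(FALSE, TRUE), c(FALSE, TRUE)]
  expect_identical(pooled, base)
})

test_that("assemble_matrix conserves counts with deterministic row order", {
  g <- build_grid(0, 30, 0, 30, 10)
  s1 <- marker_set("s2", "treat", -3.3, "R", cbind(5, 5), registered = TRUE)
  s2 <- marker_set("s1", "ctl", -3.3, "R", cbind(25, 25), registered = TRUE)
  bm <- assemble_matrix(list(s1, s2), g)
  # sorted by condition then subject: ctl/s1 first
  expect_identical(bm$meta$subject_id, c("s1", "s2"))
  expect_identical(unname(rowSums(bm$counts)), c(1, 1))
  expect_identical(unname(which(bm$counts[1, ] == 1)),
                   which(colnames(bm$counts) == "bin_3_3"))
  expect_identical(unname(which(bm$counts[2, ] == 1)),
                   which(colnames(bm$counts) == "bin_1_1"))
  # mixed planes refuse without an override
  s3 <- marker_set("s3", "ctl", -3.4, "R", cbind(5, 5), registered = TRUE)
  expect_error(assemble_matrix(list(s1, s3), g), "mix")
  expect_silent(assemble_matrix(list(s1, s3), g, allow_mixed = TRUE))
  set.seed(5)
  sets <- lapply(1:4, function(s) {
    marker_set(paste0("s", s), "c", -3.3, "R",
               cbind(runif(120, 0, 30), runif(120, 0, 30)), registered = TRUE)
  })
  bm2 <- assemble_matrix(sets, g)
  expect_identical(unname(rowSums(bm2$counts)), rep(120, 4))
})

test_that("matrix column means recover the generating intensity shape", {
  # square contour so polygon clipping plays no role; uniform background
  # plus one Gaussian hotspot with an analytic per-bin expectation
  set.seed(6)
  ctr <- square_contour(side = 400)
  n_bg <- 100; n_hot <- 100; hs_sd <- 100; hs_c <- c(160, 240)
  cfg <- sim_config(ctr, c(a = 6L, b = 6L), background_rate = n_bg / 400^2,
                    hotspots = list(a = list(list(centre = hs_c, sd = hs_sd,
                                                  n_extra = n_hot)),
                                    b = list(list(centre = hs_c, sd = hs_sd,
                                                  n_extra = n_hot))),
                    seed = 6L)
  sets <- simulate_markers(cfg)
  # 80-um bins: every bin's expected count is large enough that ranks are
  # signal- rather than noise-driven at 200 markers/subject
  g <- build_grid(0, 400, 0, 400, 80)
  bm <- assemble_matrix(sets, g)
  cen <- bin_centers(g)
  gauss_mass <- function(lo, hi, mu) pnorm(hi, mu, hs_sd) - pnorm(lo, mu, hs_sd)
  expected <- n_bg * (80^2 / 400^2) +
    n_hot * gauss_mass(cen$x_center_um - 40, cen$x_center_um + 40, hs_c[1]) *
    gauss_mass(cen$y_center_um - 40, cen$y_center_um + 40, hs_c[2])
  expect_gt(cor(colMeans(bm$counts), expected, method = "spearman"), 0.9)
})

test_that("the 2A/n rule yields ~2 expected markers per bin under uniformity", {
  set.seed(8)
  ctr <- square_contour(side = 500)
  n_mean <- 200
  cfg <- sim_config(ctr, c(u = 12L), background_rate = n_mean / 500^2,
                    seed = 8L)
  sets <- simulate_markers(cfg)
  side <- optimal_bin_area(polygon_area(ctr), n_mean)$bin_side
  bm <- assemble_matrix(sets, build_grid(0, 500, 0, 500, side))
  # interior bins (grid covers the square fully): mean count per bin ~ 2
  expect_equal(mean(colMeans(bm$counts)), 2,
               tolerance = 0.15)  # ~3 SE of the pooled Poisson mean
})

test_that("aggregate_subjects averages repeated sections per subject", {
  counts <- rbind(c(2, 0, 4), c(4, 2, 0), c(1, 1, 1))
  bm <- counts_bin_matrix(counts, condition = c("a", "a", "b"),
                          subject_id = c("s1", "s1", "s2"))
  ag <- aggregate_subjects(bm)
  expect_identical(nrow(ag$counts), 2L)
  expect_equal(unname(ag$counts[ag$meta$subject_id == "s1", ]), c(3, 1, 2))
  expect_equal(unname(ag$counts[ag$meta$subject_id == "s2", ]), c(1, 1, 1))
})
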
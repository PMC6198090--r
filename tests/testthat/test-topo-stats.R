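test_that("mass_univariate matches the aov oracle bin by bin", {
  set.seed(20)
  counts <- matrix(rpois(12 * 20, 4), 12, 20)
  cond <- rep(c("a", "b", "c"), each = 4)
  bm <- counts_bin_matrix(counts, condition = cond)
  res <- mass_univariate(bm)
  g <- bm$meta$condition   # assemble_matrix sorted rows
  for (b in seq_len(20)) {
    o <- aov_oracle(bm$counts[, b], g)
    expect_equal(res$F[b], o$F, tolerance = 1e-9)
    expect_equal(res$p[b], o$p, tolerance = 1e-9)
  }
})

test_that("mass_univariate flags degenerate bins and finds planted effects", {
  counts <- matrix(2, 8, 5)                       # constant everywhere
  counts[, 3] <- rep(c(0, 10), each = 4)          # planted shift, zero within-var
  counts[1:4, 5] <- 3                             # between-variance only in bin 5
  bm <- counts_bin_matrix(counts, condition = rep(c("a", "b"), each = 4))
  res <- mass_univariate(bm)
  expect_true(all(res$zero_variance[c(1, 2, 4)]))
  expect_equal(res$p[c(1, 2, 4)], rep(1, 3))
  expect_identical(res$p[3], 0)                   # certain rejection
  expect_identical(which.min(res$p), 3L)
  expect_error(mass_univariate(counts_bin_matrix(counts, rep("a", 8))),
               ">= 2 conditions")
  expect_error(mass_univariate(counts_bin_matrix(counts,
                                                 c("a", rep("b", 7)))),
               "single row")
})

test_that("per-bin ANOVA holds its type-I error over 1000 x 46 null bins", {
  set.seed(21)
  n_sim <- 1000
  frac <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    y <- matrix(rnorm(10 * 46), 10, 46)
    bm <- counts_bin_matrix(matrix(0L, 10, 46), rep(c("a", "b"), each = 5))
    bm$counts <- y
    frac[i] <- mean(mass_univariate(bm)$p < 0.05)
  }
  mc_sd <- sqrt(0.05 * 0.95 / (n_sim * 46))
  expect_lt(abs(mean(frac) - 0.05), 3 * mc_sd)
})

test_that("fdr_bh equals the definition-level step-up oracle", {
  set.seed(22)
  for (i in 1:1000) {
    p <- switch(1 + i %% 3,
                runif(46),
                c(runif(36), rbeta(10, 0.1, 1)),   # mixed null/alternative
                round(runif(46), 2))               # heavy ties
    r <- fdr_bh(p, 0.1)
    expect_identical(r$significant, bh_stepup_oracle(p, 0.1))
  }
  # spot checks
  expect_length(fdr_bh(c(0.5, 0.5, 0.5), 0.1)$significant, 0)
  expect_equal(fdr_bh(0.037, 0.1)$q, 0.037)        # m = 1: q = p
  expect_error(fdr_bh(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_bh(0.5, q_threshold = -1), "q_threshold")
})

test_that("fdr_bh q-values are monotone and threshold-monotone", {
  set.seed(23)
  for (i in 1:20) {
    p <- runif(46)
    r <- fdr_bh(p, 0.1)
    expect_true(all(diff(r$q[order(p)]) >= -1e-12))
    # enlarging q never shrinks the significant set
    expect_true(all(r$significant %in% fdr_bh(p, 0.3)$significant))
    # BY is never more liberal than BH
    expect_true(all(fdr_bh(p, 0.1, method = "BY")$significant %in%
                      r$significant))
  }
})

test_that("empirical FDR of fdr_bh stays within the q = 0.1 budget", {
  set.seed(24)
  n_sim <- 1000
  fdp_null <- fdp_mixed <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    p0 <- runif(46)
    r0 <- fdr_bh(p0, 0.1)
    fdp_null[i] <- length(r0$significant) > 0
    # 10 true effects with tiny p, 36 true nulls
    p1 <- c(rbeta(10, 0.02, 1), runif(36))
    r1 <- fdr_bh(p1, 0.1)
    v <- sum(r1$significant > 10)
    fdp_mixed[i] <- v / max(length(r1$significant), 1)
  }
  expect_lte(mean(fdp_null), 0.1 + 2 * sd(fdp_null) / sqrt(n_sim))
  expect_lte(mean(fdp_mixed), 0.1 + 2 * sd(fdp_mixed) / sqrt(n_sim))
})

test_that("bonferroni reduces to p <= alpha at m = 1 and is BH-dominated", {
  expect_identical(bonferroni(0.04, 0.05)$significant, 1L)
  expect_length(bonferroni(0.06, 0.05)$significant, 0)
  set.seed(25)
  for (i in 1:50) {
    p <- runif(30)
    bf <- bonferroni(p, 0.05)
    expect_identical(bf$significant, which(p <= 0.05 / 30))  # direct oracle
    expect_true(all(bf$significant %in% fdr_bh(p, 0.05)$significant))
  }
})

test_that("planned_contrasts: null behaviour and the Mann-Whitney oracle", {
  counts <- rbind(matrix(c(3, 5), 4, 2, byrow = TRUE),
                  matrix(c(3, 5), 4, 2, byrow = TRUE))
  bm <- counts_bin_matrix(counts, rep(c("a", "b"), each = 4))
  r <- planned_contrasts(bm, list(c("a", "b")))
  expect_equal(r$statistic, rep(0, 2))
  expect_equal(r$p, rep(1, 2))
  expect_error(planned_contrasts(bm, list(c("a", "zzz"))), "available")
  # exact Mann-Whitney p vs exhaustive rank-assignment enumeration
  set.seed(26)
  for (k in 1:5) {
    va <- rnorm(6); vb <- rnorm(6, 1)
    cm <- counts_bin_matrix(matrix(0, 12, 1), rep(c("a", "b"), each = 6))
    cm$counts[, 1] <- c(va, vb)
    rw <- planned_contrasts(cm, list(c("a", "b")), test = "wilcoxon")
    expect_equal(rw$p, mw_enumeration_p(va, vb), tolerance = 1e-12)
  }
})

test_that("a planted shift survives Bonferroni alone in >= 95% of 200 runs", {
  set.seed(27)
  n_sim <- 200
  only_planted <- logical(n_sim)
  mroi_bins <- c(2, 5, 7, 11, 17)
  for (i in seq_len(n_sim)) {
    y <- matrix(rnorm(14 * 20), 14, 20)
    y[8:14, 7] <- y[8:14, 7] + 10          # large effect in bin 7, group b
    bm <- counts_bin_matrix(matrix(0L, 14, 20), rep(c("a", "b"), each = 7))
    bm$counts <- y
    r <- planned_contrasts(bm, list(c("a", "b")), bins = mroi_bins)
    hits <- r$bin[r$significant]
    only_planted[i] <- identical(hits, 7)
  }
  expect_gte(mean(only_planted), 0.95)
})

test_that("pca_topography: degenerate geometry and exact reconstruction", {
  # data exactly on a line through the centroid -> PC1 explains everything
  t_ <- c(-2, -1, 0, 1, 2)
  dirv <- c(1, 2, 3, 4)
  X <- 5 + outer(t_, dirv)
  bm <- counts_bin_matrix(matrix(0L, 5, 4), c("a", "a", "a", "b", "b"))
  bm$counts <- X
  pc <- pca_topography(bm)
  expect_equal(pc$explained[1], 1, tolerance = 1e-12)
  # completeness: scores %*% t(loadings) reproduces the centred matrix
  set.seed(28)
  bm$counts <- matrix(rnorm(20), 5, 4)
  pc2 <- pca_topography(bm)
  recon <- pc2$scores %*% t(pc2$loadings)
  centred <- sweep(bm$counts, 2, colMeans(bm$counts))
  expect_equal(unname(recon), unname(centred), tolerance = 1e-8)
  expect_error(pca_topography(counts_bin_matrix(matrix(0L, 2, 4),
                                                c("a", "b"))), ">= 3")
})

test_that("pca_topography recovers a planted condition-separating pattern", {
  set.seed(29)
  n_bins <- 40
  pattern <- rnorm(n_bins); pattern <- pattern / sqrt(sum(pattern^2))
  X <- matrix(rnorm(12 * n_bins, sd = 1), 12, n_bins)
  X[7:12, ] <- X[7:12, ] + 8 * rep(pattern, each = 6)   # 8-SD shift vs unit noise
  bm <- counts_bin_matrix(matrix(0L, 12, n_bins), rep(c("a", "b"), each = 6))
  bm$counts <- X
  pc <- pca_topography(bm)
  expect_gt(abs(cor(pc$sep_loadings, pattern)), 0.9)
  # scores invariant (exactly) under adding a constant to one bin's counts
  bm2 <- bm; bm2$counts[, 3] <- bm2$counts[, 3] + 100
  pc2 <- pca_topography(bm2)
  expect_equal(abs(pc2$scores), abs(pc$scores), tolerance = 1e-8)
})

test_that("mda matches the Fisher discriminant and the cancor oracle", {
  set.seed(30)
  X <- matrix(rnorm(12 * 3), 12, 3,
              dimnames = list(NULL, c("LAd", "LAvm", "B")))
  g <- rep(c("fear", "ctl"), each = 6)
  X[1:6, 1] <- X[1:6, 1] + 2
  md <- mda(X, g)
  # two groups: variate 1 collinear with solve(W) %*% (m1 - m2)
  m1 <- colMeans(X[1:6, ]); m2 <- colMeans(X[7:12, ])
  Xw <- rbind(scale(X[1:6, ], scale = FALSE), scale(X[7:12, ], scale = FALSE))
  fisher <- solve(crossprod(Xw), m1 - m2)
  v1 <- md$coefficients[, 1]
  cosang <- sum(fisher * v1) / sqrt(sum(fisher^2) * sum(v1^2))
  expect_equal(abs(cosang), 1, tolerance = 1e-8)
  # canonical correlations against the independent cancor route
  expect_equal(md$canonical_correlations, cancor_oracle(X, g),
               tolerance = 1e-8)
  expect_identical(md$top_predictor, "LAd")
})

test_that("mda canonical correlations are invariant to predictor rescaling", {
  set.seed(31)
  X <- matrix(rnorm(18 * 3), 18, 3)
  g <- rep(c("a", "b", "c"), each = 6)
  X[1:6, 2] <- X[1:6, 2] + 1.5
  r0 <- mda(X, g)$canonical_correlations
  Xs <- sweep(sweep(X, 2, c(3, 0.2, 7), `*`), 2, c(-5, 2, 100), `+`)
  expect_equal(mda(Xs, g)$canonical_correlations, r0, tolerance = 1e-9)
  # 3 groups, 3 predictors -> 2 variates, correlations ordered in [0, 1]
  expect_length(r0, 2)
  expect_true(all(r0 >= 0 & r0 <= 1) && diff(r0) <= 1e-12)
})

test_that("mda guards its preconditions", {
  X <- matrix(rnorm(12 * 3), 12, 3)
  expect_error(mda(X, rep("a", 12)), ">= 2 groups")
  expect_error(mda(matrix(rnorm(10 * 9), 10, 9), rep(c("a", "b"), 5)),
               "too few subjects")
  Xs <- cbind(X[, 1], X[, 1], X[, 2])  # collinear predictors
  expect_error(mda(Xs, rep(c("a", "b"), each = 6)), "singular")
})

test_that("mda separates planted effects against a permutation null", {
  set.seed(32)
  n <- 16
  X <- matrix(rnorm(n * 3), n, 3)
  g <- rep(c("a", "b"), each = 8)
  perm_quantile <- function(X, g) {
    obs <- mda(X, g)$canonical_correlations[1]
    perm <- replicate(500, mda(X, sample(g))$canonical_correlations[1])
    c(obs = obs, q95 = unname(quantile(perm, 0.95)))
  }
  null_case <- perm_quantile(X, g)
  expect_lte(null_case["obs"], null_case["q95"])
  Xeff <- X; Xeff[g == "a", 2] <- Xeff[g == "a", 2] + 2.5
  eff_case <- perm_quantile(Xeff, g)
  expect_gt(eff_case["obs"], eff_case["q95"])
})

test_that("condition_anova: single-region reduction and the F oracle", {
  set.seed(33)
  X <- matrix(rnorm(18 * 3, 10), 18, 3,
              dimnames = list(NULL, c("PL", "IL", "LAd")))
  g <- rep(c("a", "b", "c"), each = 6)
  X[g == "a", 3] <- X[g == "a", 3] + 3
  r <- condition_anova(X, g)
  for (j in 1:3) {
    o <- aov_oracle(X[, j], g)
    expect_equal(r$per_region$F[j], o$F, tolerance = 1e-9)
    expect_equal(r$per_region$p[j], o$p, tolerance = 1e-9)
  }
  expect_lt(r$manova$p, 0.01)
  r1 <- condition_anova(X[, 1, drop = FALSE], g)
  expect_equal(r1$manova$p, r1$per_region$p[1])
})

test_that("condition_anova holds type-I error under a null simulation", {
  set.seed(34)
  n_sim <- 1000
  rej_region <- rej_manova <- logical(n_sim)
  g <- rep(c("a", "b"), each = 8)
  for (i in seq_len(n_sim)) {
    X <- matrix(rnorm(16 * 2), 16, 2)
    r <- condition_anova(X, g)
    rej_region[i] <- r$per_region$p[1] < 0.05
    rej_manova[i] <- r$manova$p < 0.05
  }
  mc_sd <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(mean(rej_region) - 0.05), 3 * mc_sd)
  expect_lt(abs(mean(rej_manova) - 0.05), 3 * mc_sd)
})

test_that("the full stack flags a contiguous MROI set around the hotspot", {
  sc <- scenario_effect(seed = 99)
  bm <- scenario_matrix(sc)
  mroi <- mroi_detect(bm, q_threshold = 0.1)
  expect_gt(length(mroi$significant), 0)
  hs <- sc$truth$hotspot_centre
  hb <- bin_of_point(bm$grid, hs)
  expect_true(hb %in% mroi$significant)
  # the 8-connected component around the hotspot bin carries the bulk of the
  # discoveries; the FDR budget allows isolated strays elsewhere
  sig <- mroi$table[mroi$table$significant, c("i", "j")]
  expect_gte(hotspot_component_fraction(sig, bm$grid, hb), 2 / 3)
  # q-value map carries the q's onto the grid
  qm <- qvalue_map(mroi)
  expect_equal(unname(qm$values[mroi$table$bin]), mroi$table$q)
})
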
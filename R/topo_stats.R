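#' Mass-univariate per-bin tests across conditions
#'
#' Runs the same one-way test independently in every bin of the subjects x
#' bins matrix: one-way ANOVA on raw counts by default, or Kruskal-Wallis as
#' a rank-based alternative. Multiple section rows per subject are averaged
#' first (`aggregate = TRUE`) so no individual is represented twice. Bins
#' with zero variance everywhere are given p = 1 by convention and flagged.
#' Out-of-contour bins are excluded from the family by default.
#'
#' @param bm a `bin_matrix`.
#' @param test `"anova"` (default) or `"kruskal"`.
#' @param aggregate average sections to one row per subject first.
#' @param sqrt_transform apply a square-root variance-stabilising transform
#'   to the counts before testing (off by default; a documented deviation
#'   from testing raw counts).
#' @param mask_out_of_contour drop bins flagged outside the contour from the
#'   tested family.
#' @return `data.frame` with one row per tested bin: `bin` (flat index), `i`,
#'   `j`, `x_center_um`, `y_center_um`, `F` (or Kruskal-Wallis chi-square),
#'   `df1`, `df2`, `p`, `zero_variance`.
#' @export
mass_univariate <- function(bm, test = c("anova", "kruskal"),
                            aggregate = TRUE, sqrt_transform = FALSE,
                            mask_out_of_contour = TRUE) {
  stopifnot(inherits(bm, "bin_matrix"))
  test <- match.arg(test)
  if (aggregate) bm <- aggregate_subjects(bm)
  g <- factor(bm$meta$condition)
  if (nlevels(g) < 2L) stop("mass_univariate needs >= 2 conditions")
  ng <- tabulate(g)
  if (any(ng < 2L)) {
    stop("condition(s) with a single row: ",
         paste(levels(g)[ng < 2L], collapse = ", "))
  }
  keep <- if (mask_out_of_contour && !is.null(bm$in_contour)) {
    which(bm$in_contour)
  } else seq_len(ncol(bm$counts))
  y <- bm$counts[, keep, drop = FALSE]
  if (sqrt_transform) y <- sqrt(y)
  cen <- bin_centers(bm$grid)[keep, , drop = FALSE]
  n <- nrow(y); k <- nlevels(g)
  if (test == "anova") {
    gmeans <- rowsum(y, g) / ng                     # k x m group means
    grand <- colMeans(y)
    ssb <- colSums(ng * (gmeans - rep(grand, each = k))^2)
    sst <- colSums(y^2) - n * grand^2
    ssw <- pmax(sst - ssb, 0)
    df1 <- k - 1L; df2 <- n - k
    Fst <- (ssb / df1) / (ssw / df2)
    zerovar <- sst <= .Machine$double.eps * n * pmax(1, grand)^2
    p <- stats::pf(Fst, df1, df2, lower.tail = FALSE)
    p[zerovar] <- 1; Fst[zerovar] <- NA_real_
    # planted effect with zero within-variance: certain rejection
    p[!zerovar & ssw == 0] <- 0; Fst[!zerovar & ssw == 0] <- Inf
    out <- data.frame(stat = Fst, df1 = df1, df2 = df2, p = p,
                      zero_variance = zerovar)
  } else {
    res <- apply(y, 2L, function(col) {
      if (max(col) == min(col)) return(c(NA_real_, 1, TRUE))
      kt <- suppressWarnings(stats::kruskal.test(col, g))
      c(unname(kt$statistic), kt$p.value, FALSE)
    })
    out <- data.frame(stat = res[1L, ], df1 = k - 1L, df2 = NA_integer_,
                      p = res[2L, ], zero_variance = as.logical(res[3L, ]))
  }
  data.frame(bin = keep, i = cen$i, j = cen$j,
             x_center_um = cen$x_center_um, y_center_um = cen$y_center_um,
             F = out$stat, df1 = out$df1, df2 = out$df2, p = out$p,
             zero_variance = out$zero_variance, row.names = NULL)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR control: q-values are the BH-adjusted p-values and the
#' significant set is every test with q <= `q_threshold` (the tolerable
#' expected proportion of false rejections among rejections; 0.1 by
#' default). `method = "BY"` applies the Benjamini-Yekutieli correction for
#' arbitrary dependence (neighbouring bins are spatially correlated).
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @param q_threshold tolerated FDR level in `[0, 1]`.
#' @param method `"BH"` (independence, default) or `"BY"`.
#' @return List with `q` (adjusted values, input order), `significant`
#'   (integer indices), `q_threshold`, `method`.
#' @export
fdr_bh <- function(p_values, q_threshold = 0.1, method = c("BH", "BY")) {
  method <- match.arg(method)
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (!is.finite(q_threshold) || q_threshold < 0 || q_threshold > 1) {
    stop("q_threshold must lie in [0, 1]")
  }
  m <- length(p)
  if (!m) return(list(q = numeric(0), significant = integer(0),
                      q_threshold = q_threshold, method = method))
  cm <- if (method == "BY") sum(1 / seq_len(m)) else 1
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * cm * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  list(q = q, significant = which(q <= q_threshold),
       q_threshold = q_threshold, method = method)
}

#' Bonferroni correction
#'
#' Significant iff p <= alpha / m: stringent type-I control at the cost of
#' power. Anything Bonferroni-significant is BH-significant at q = alpha.
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @param alpha family-wise error level.
#' @return List with `p_adjusted` (`pmin(1, p * m)`), `significant` indices,
#'   `alpha`.
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  list(p_adjusted = pmin(1, p * m), significant = which(p <= alpha / m),
       alpha = alpha)
}

#' Detect micro-regions of interest (MROIs)
#'
#' The package's core inference: mass-univariate per-bin tests across
#' conditions followed by FDR control at `q_threshold`. Bins surviving at
#' q <= `q_threshold` form the MROI set.
#'
#' @inheritParams mass_univariate
#' @param q_threshold tolerated FDR (default 0.1).
#' @param fdr_method `"BH"` or `"BY"`.
#' @return Object of class `mroi_result`: `table` (per-bin F, p, q,
#'   significant, centre coordinates), `significant` (flat bin indices),
#'   `grid`, `q_threshold`, `n_subjects`.
#' @export
mroi_detect <- function(bm, q_threshold = 0.1, test = c("anova", "kruskal"),
                        fdr_method = c("BH", "BY"), aggregate = TRUE,
                        sqrt_transform = FALSE, mask_out_of_contour = TRUE) {
  tab <- mass_univariate(bm, test = test, aggregate = aggregate,
                         sqrt_transform = sqrt_transform,
                         mask_out_of_contour = mask_out_of_contour)
  fdr <- fdr_bh(tab$p, q_threshold, match.arg(fdr_method))
  tab$q <- fdr$q
  tab$significant <- tab$q <= q_threshold
  if (aggregate) bm <- aggregate_subjects(bm)
  structure(list(table = tab, significant = tab$bin[tab$significant],
                 grid = bm$grid, q_threshold = q_threshold,
                 n_subjects = nrow(bm$counts)),
            class = "mroi_result")
}

#' @export
print.mroi_result <- function(x, ...) {
  cat(sprintf("<mroi_result> %d/%d bins significant at q <= %g\n",
              length(x$significant), nrow(x$table), x$q_threshold))
  invisible(x)
}

#' Planned contrasts within the MROI bins
#'
#' Two-group comparisons (Student t or Mann-Whitney rank test) for each
#' requested contrast in each MROI bin, Bonferroni-corrected over every
#' (contrast, bin) test performed.
#'
#' @param bm a `bin_matrix`.
#' @param contrasts list of length-2 character vectors of condition labels,
#'   e.g. `list(c("conditioned", "control"))`.
#' @param bins flat bin indices to test (e.g. `mroi$significant`); `NULL`
#'   tests all in-family bins.
#' @param test `"t"` (two-sample, pooled variance) or `"wilcoxon"`
#'   (Mann-Whitney).
#' @param alpha family-wise level for the Bonferroni verdict.
#' @param aggregate average sections to one row per subject first.
#' @return `data.frame`: `contrast`, `bin`, `statistic`, `p`, `p_corrected`,
#'   `significant`.
#' @export
planned_contrasts <- function(bm, contrasts, bins = NULL,
                              test = c("t", "wilcoxon"), alpha = 0.05,
                              aggregate = TRUE) {
  stopifnot(inherits(bm, "bin_matrix"), is.list(contrasts))
  test <- match.arg(test)
  if (aggregate) bm <- aggregate_subjects(bm)
  conds <- unique(bm$meta$condition)
  for (ct in contrasts) {
    if (length(ct) != 2L || !all(ct %in% conds)) {
      stop("each contrast must name two existing conditions; available: ",
           paste(conds, collapse = ", "))
    }
  }
  if (is.null(bins)) {
    bins <- if (!is.null(bm$in_contour)) which(bm$in_contour)
    else seq_len(ncol(bm$counts))
  }
  if (!length(bins)) {
    return(data.frame(contrast = character(0), bin = integer(0),
                      statistic = numeric(0), p = numeric(0),
                      p_corrected = numeric(0), significant = logical(0)))
  }
  res <- list()
  for (ct in contrasts) {
    a <- bm$counts[bm$meta$condition == ct[1L], bins, drop = FALSE]
    b <- bm$counts[bm$meta$condition == ct[2L], bins, drop = FALSE]
    for (kk in seq_along(bins)) {
      va <- a[, kk]; vb <- b[, kk]
      if (test == "t") {
        if (stats::sd(c(va, vb)) == 0) {
          stat <- 0; p <- 1
        } else {
          ht <- stats::t.test(va, vb, var.equal = TRUE)
          stat <- unname(ht$statistic); p <- ht$p.value
        }
      } else {
        ht <- suppressWarnings(stats::wilcox.test(va, vb, exact = TRUE))
        stat <- unname(ht$statistic); p <- ht$p.value
      }
      res[[length(res) + 1L]] <- data.frame(
        contrast = paste(ct, collapse = " vs "), bin = bins[kk],
        statistic = stat, p = p)
    }
  }
  out <- do.call(rbind, res)
  m <- nrow(out)
  out$p_corrected <- pmin(1, out$p * m)
  out$significant <- out$p <= alpha / m
  out
}

#' PCA of the subject x bin matrix
#'
#' Singular-value decomposition of the centred (optionally scaled) subject x
#' bin count matrix — well-posed even with many more bins than subjects —
#' plus identification of the condition-separating component: the component
#' whose subject scores maximise the standardised between-condition
#' difference (one-way F statistic of scores on condition). Its per-bin
#' loadings form a spatial pattern mappable back onto the grid.
#'
#' @param bm a `bin_matrix`.
#' @param aggregate average sections to one row per subject first.
#' @param scale. scale bins to unit variance (default `FALSE`: counts share
#'   units).
#' @param mask_out_of_contour restrict to in-contour bins.
#' @return Object of class `pca_result`: `scores` (subjects x components),
#'   `loadings` (bins x components), `explained` (variance fractions),
#'   `sep_component` (index), `sep_loadings` (named by bin), `bins` (flat
#'   indices used), `condition`.
#' @export
pca_topography <- function(bm, aggregate = TRUE, scale. = FALSE,
                           mask_out_of_contour = TRUE) {
  stopifnot(inherits(bm, "bin_matrix"))
  if (aggregate) bm <- aggregate_subjects(bm)
  if (nrow(bm$counts) < 3L) stop("pca_topography needs >= 3 subjects")
  keep <- if (mask_out_of_contour && !is.null(bm$in_contour)) {
    which(bm$in_contour)
  } else seq_len(ncol(bm$counts))
  y <- bm$counts[, keep, drop = FALSE]
  if (scale.) {
    v <- apply(y, 2L, stats::sd)
    keep <- keep[v > 0]
    y <- y[, v > 0, drop = FALSE]
  }
  pc <- stats::prcomp(y, center = TRUE, scale. = scale.)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  g <- factor(bm$meta$condition)
  sep <- if (nlevels(g) >= 2L) {
    fs <- apply(pc$x, 2L, function(s) {
      r <- .oneway_f(s, g)
      if (is.na(r$F)) 0 else r$F
    })
    unname(which.max(fs))
  } else 1L
  structure(list(scores = pc$x, loadings = pc$rotation, explained = expl,
                 sep_component = sep,
                 sep_loadings = stats::setNames(pc$rotation[, sep], colnames(y)),
                 bins = keep, condition = bm$meta$condition,
                 subject_id = bm$meta$subject_id),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components; separating component PC%d (%.1f%% var)\n",
              ncol(x$scores), x$sep_component,
              100 * x$explained[x$sep_component]))
  invisible(x)
}

#' Multiple (canonical) discriminant analysis of regional densities
#'
#' Canonical variates of the between-/within-group generalized eigenproblem
#' on a subjects x regions density table: how a set of continuous regional
#' densities discriminates predefined groups. Loading values are structure
#' coefficients — pooled within-group correlations between each predictor
#' and the canonical scores — and the predictor with the largest absolute
#' loading on variate 1 is reported as contributing most to the group
#' difference.
#'
#' @param x numeric matrix or data.frame, subjects x predictor regions.
#' @param grouping factor (or coercible) of group labels, one per subject.
#' @return Object of class `mda_result`: `scores` (subjects x variates,
#'   unit pooled within-group variance), `loadings` (structure
#'   coefficients), `canonical_correlations`, `centroids` (groups x
#'   variates), `coefficients` (raw discriminant weights), `top_predictor`.
#' @export
mda <- function(x, grouping) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  g <- factor(grouping)
  n <- nrow(X); p <- ncol(X); k <- nlevels(g)
  if (k < 2L) stop("mda needs >= 2 groups")
  if (n <= p + k) {
    stop("too few subjects (", n, ") for ", p, " predictors and ", k,
         " groups; reduce predictors")
  }
  gm <- rowsum(X, g) / tabulate(g)                 # group means
  grand <- colMeans(X)
  Xw <- X - gm[as.integer(g), , drop = FALSE]      # within-group centred
  W <- crossprod(Xw)                               # within scatter
  B <- crossprod(sweep(gm, 2L, grand) * sqrt(tabulate(g)))  # between scatter
  Winv <- tryCatch(solve(W), error = function(e) {
    stop("singular within-group covariance; drop collinear predictors or ",
         "add a ridge before calling mda")
  })
  ev <- eigen(Winv %*% B)
  s <- min(k - 1L, p)
  lam <- Re(ev$values[seq_len(s)])
  lam[lam < 0] <- 0
  A <- Re(ev$vectors[, seq_len(s), drop = FALSE])
  # scale coefficients to unit pooled within-group variance of scores
  wsd <- sqrt(diag(crossprod(Xw %*% A)) / (n - k))
  A <- sweep(A, 2L, wsd, `/`)
  scores <- sweep(X, 2L, grand) %*% A
  rs <- sqrt(lam / (1 + lam))
  # structure coefficients: pooled within-group predictor-score correlations
  Sw <- Xw %*% A
  loadings <- stats::cor(Xw, Sw)
  dimnames(loadings) <- list(colnames(X) %||% paste0("pred", seq_len(p)),
                             paste0("CV", seq_len(s)))
  colnames(scores) <- paste0("CV", seq_len(s))
  centroids <- rowsum(scores, g) / tabulate(g)
  top <- rownames(loadings)[which.max(abs(loadings[, 1L]))]
  structure(list(scores = scores, loadings = loadings,
                 canonical_correlations = rs, centroids = centroids,
                 coefficients = A, grouping = g, top_predictor = top),
            class = "mda_result")
}

#' @export
print.mda_result <- function(x, ...) {
  cat(sprintf("<mda_result> %d canonical variate(s), r = %s; top predictor: %s\n",
              length(x$canonical_correlations),
              paste(sprintf("%.3f", x$canonical_correlations), collapse = ", "),
              x$top_predictor))
  invisible(x)
}

#' MANOVA gate plus per-region one-way ANOVAs
#'
#' First a multivariate test (Wilks' lambda) of whether regional densities
#' jointly differ across conditions; then, region by region, a one-way
#' ANOVA. With one region the multivariate step reduces to that ANOVA.
#'
#' @param x numeric matrix or data.frame, subjects x regions (per-subject
#'   total or mean densities).
#' @param grouping group labels, one per subject.
#' @return List with `manova` (`statistic` Wilks' lambda, `F`, `df1`, `df2`,
#'   `p`) and `per_region` (`data.frame` of region, F, df1, df2, p).
#' @export
condition_anova <- function(x, grouping) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  g <- factor(grouping)
  if (nlevels(g) < 2L) stop("condition_anova needs >= 2 groups")
  if (any(tabulate(g) < 2L)) stop("every group needs >= 2 subjects")
  regions <- colnames(X) %||% paste0("region", seq_len(ncol(X)))
  per <- do.call(rbind, lapply(seq_len(ncol(X)), function(j) {
    r <- .oneway_f(X[, j], g)
    data.frame(region = regions[j], F = r$F, df1 = r$df1, df2 = r$df2,
               p = r$p)
  }))
  if (ncol(X) == 1L) {
    mv <- list(statistic = NA_real_, F = per$F[1L], df1 = per$df1[1L],
               df2 = per$df2[1L], p = per$p[1L])
  } else {
    fit <- stats::manova(X ~ g)
    sm <- summary(fit, test = "Wilks")$stats
    mv <- list(statistic = sm[1L, "Wilks"], F = sm[1L, "approx F"],
               df1 = sm[1L, "num Df"], df2 = sm[1L, "den Df"],
               p = sm[1L, "Pr(>F)"])
  }
  list(manova = mv, per_region = per)
}
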
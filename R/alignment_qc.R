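#' Per-section Feret length records
#'
#' One row per (subject, Bregma plane) measurement of an anatomical landmark's
#' maximum Feret length (e.g. the caudate putamen), used to verify that
#' sections assigned to the same plane are mutually consistent and that
#' planes are mutually distinct.
#'
#' @param subject_id character vector of subject identifiers.
#' @param condition character vector of experimental condition labels.
#' @param bregma_mm numeric Bregma plane (mm) of each measurement.
#' @param feret_um positive maximum Feret length in micrometres.
#' @return A `data.frame` of class `feret_records`.
#' @export
feret_records <- function(subject_id, condition, bregma_mm, feret_um) {
  d <- data.frame(subject_id = as.character(subject_id),
                  condition = as.character(condition),
                  bregma_mm = as.numeric(bregma_mm),
                  feret_um = as.numeric(feret_um),
                  stringsAsFactors = FALSE)
  if (any(!is.finite(d$feret_um)) || any(d$feret_um <= 0)) {
    stop("feret_um must be positive and finite")
  }
  if (any(!is.finite(d$bregma_mm))) stop("bregma_mm must be finite")
  if (anyDuplicated(d[, c("subject_id", "bregma_mm")])) {
    stop("duplicate (subject_id, bregma_mm) Feret records")
  }
  class(d) <- c("feret_records", "data.frame")
  d
}

#' Z-score outlier flagging
#'
#' Standardises values with the sample (n-1) SD and flags |z| > `threshold`
#' (the +/- 3.0 SD rule by default, which retains ~99.9% of a normal
#' population). Constant input has no defined z-scores: reported as a
#' no-variance condition with zero flags rather than an error.
#'
#' @param values numeric vector (>= 3 values), e.g. Feret lengths in um.
#' @param threshold flag limit in SD units (default 3.0).
#' @return List with `z` (numeric, `NA` when no variance), `flagged`
#'   (logical), `no_variance` (logical scalar), `mean`, `sd`.
#' @export
zscore_flag <- function(values, threshold = 3.0) {
  v <- as.numeric(values)
  if (length(v) < 3L) stop("zscore_flag needs at least 3 values")
  if (any(!is.finite(v))) stop("non-finite values")
  if (threshold < 0) stop("threshold must be >= 0")
  m <- mean(v)
  s <- stats::sd(v)
  if (s == 0) {
    return(list(z = rep(NA_real_, length(v)),
                flagged = rep(FALSE, length(v)),
                no_variance = TRUE, mean = m, sd = s))
  }
  z <- (v - m) / s
  list(z = z, flagged = abs(z) > threshold, no_variance = FALSE,
       mean = m, sd = s)
}

#' Pairwise plane distinctness (paired t-tests on Feret lengths)
#'
#' For every pair of Bregma planes, a paired t-test (pairing by subject) on
#' the Feret measurements. A plane pair is "distinct" when p < `alpha`:
#' evidence that the two plane assignments capture genuinely different
#' anatomical levels. Subjects missing either plane of a pair are dropped
#' with a warning.
#'
#' @param records a [feret_records] table covering >= 2 planes.
#' @param alpha significance level for the distinctness verdict.
#' @return `data.frame` with columns `plane_a`, `plane_b`, `n_pairs`, `t`,
#'   `df`, `p`, `distinct`.
#' @export
plane_distinctness <- function(records, alpha = 0.05) {
  stopifnot(inherits(records, "feret_records"))
  planes <- sort(unique(records$bregma_mm))
  if (length(planes) < 2L) stop("plane_distinctness needs >= 2 planes")
  pairs <- utils::combn(planes, 2L)
  out <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    pa <- pairs[1L, k]; pb <- pairs[2L, k]
    a <- records[records$bregma_mm == pa, c("subject_id", "feret_um")]
    b <- records[records$bregma_mm == pb, c("subject_id", "feret_um")]
    common <- intersect(a$subject_id, b$subject_id)
    dropped <- setdiff(union(a$subject_id, b$subject_id), common)
    if (length(dropped)) {
      warning(sprintf("planes %g/%g: dropping unpaired subjects: %s",
                      pa, pb, paste(dropped, collapse = ", ")))
    }
    if (length(common) < 2L) {
      stop(sprintf("planes %g and %g have < 2 complete subject pairs", pa, pb))
    }
    d <- a$feret_um[match(common, a$subject_id)] -
      b$feret_um[match(common, b$subject_id)]
    n <- length(d)
    sdd <- stats::sd(d)
    if (sdd == 0) {                         # constant differences
      tstat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p <- if (mean(d) == 0) 1 else 0
    } else {
      tstat <- mean(d) / (sdd / sqrt(n))
      p <- 2 * stats::pt(-abs(tstat), df = n - 1L)
    }
    out[[k]] <- data.frame(plane_a = pa, plane_b = pb, n_pairs = n,
                           t = tstat, df = n - 1L, p = p,
                           distinct = p < alpha)
  }
  do.call(rbind, out)
}

## one-way ANOVA from group membership; returns F, dfs, p
.oneway_f <- function(values, group) {
  g <- factor(group)
  k <- nlevels(g)
  n <- length(values)
  gm <- tapply(values, g, mean)
  ng <- tabulate(g)
  grand <- mean(values)
  ssb <- sum(ng * (gm - grand)^2)
  ssw <- sum((values - gm[as.integer(g)])^2)
  df1 <- k - 1L
  df2 <- n - k
  if (ssw == 0) {
    if (ssb == 0) return(list(F = NA_real_, df1 = df1, df2 = df2, p = 1))
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0))
  }
  Fst <- (ssb / df1) / (ssw / df2)
  list(F = Fst, df1 = df1, df2 = df2, p = stats::pf(Fst, df1, df2,
                                                    lower.tail = FALSE))
}

#' Condition homogeneity of Feret lengths at one plane
#'
#' One-way ANOVA of Feret length across experimental conditions at a single
#' Bregma plane. A non-significant result (p >= `alpha`) yields the verdict
#' `aligned = TRUE`, reported as "no evidence of misalignment" — failure to
#' detect a condition effect, never proof of alignment. Conditions with
#' fewer than 2 subjects are excluded with a warning.
#'
#' @param records a [feret_records] table.
#' @param plane the Bregma plane (mm) to test.
#' @param alpha significance level.
#' @return List with `F`, `df1`, `df2`, `p`, `aligned`, `n_per_condition`.
#' @export
condition_homogeneity <- function(records, plane, alpha = 0.05) {
  stopifnot(inherits(records, "feret_records"))
  r <- records[records$bregma_mm == plane, , drop = FALSE]
  if (!nrow(r)) stop(sprintf("no records at plane %g mm", plane))
  ns <- table(r$condition)
  small <- names(ns)[ns < 2L]
  if (length(small)) {
    warning("excluding conditions with < 2 subjects: ",
            paste(small, collapse = ", "))
    r <- r[!(r$condition %in% small), , drop = FALSE]
  }
  if (length(unique(r$condition)) < 2L) {
    stop("condition_homogeneity needs >= 2 conditions with >= 2 subjects")
  }
  res <- .oneway_f(r$feret_um, r$condition)
  c(res, list(aligned = res$p >= alpha,
              n_per_condition = table(r$condition)))
}

#' Full section-alignment QC report
#'
#' Combines z-score outlier screening (within each plane by default, or
#' within plane x condition), pairwise plane-distinctness t-tests, and
#' per-plane condition-homogeneity ANOVAs. Flagged records are never dropped
#' here; downstream exclusion requires an explicit flag.
#'
#' @param records a [feret_records] table.
#' @param threshold z-score flag limit in SD units.
#' @param alpha significance level for both tests.
#' @param group_by `"plane"` (default, pooled across conditions) or
#'   `"plane_condition"` for the z-score grouping.
#' @return An object of class `qc_report`: `records` (with `z` and `flagged`
#'   columns), `plane_tests`, `condition_tests`, `no_variance_groups`,
#'   `params`.
#' @export
qc_report <- function(records, threshold = 3.0, alpha = 0.05,
                      group_by = c("plane", "plane_condition")) {
  stopifnot(inherits(records, "feret_records"))
  group_by <- match.arg(group_by)
  key <- if (group_by == "plane") {
    format(records$bregma_mm)
  } else {
    paste(format(records$bregma_mm), records$condition)
  }
  records$z <- NA_real_
  records$flagged <- FALSE
  novar <- character(0)
  for (g in unique(key)) {
    idx <- which(key == g)
    if (length(idx) < 3L) {
      novar <- c(novar, paste0(g, " (n<3, not screened)"))
      next
    }
    zf <- zscore_flag(records$feret_um[idx], threshold)
    records$z[idx] <- zf$z
    records$flagged[idx] <- zf$flagged
    if (zf$no_variance) novar <- c(novar, g)
  }
  planes <- sort(unique(records$bregma_mm))
  plane_tests <- if (length(planes) >= 2L) {
    plane_distinctness(records, alpha)
  } else NULL
  cond_tests <- lapply(planes, function(pl) {
    res <- tryCatch(condition_homogeneity(records, pl, alpha),
                    error = function(e) NULL, warning = function(w) NULL)
    if (is.null(res)) return(NULL)
    data.frame(plane = pl, F = res$F, df1 = res$df1, df2 = res$df2,
               p = res$p, aligned = res$aligned)
  })
  cond_tests <- do.call(rbind, cond_tests)
  structure(list(records = records, plane_tests = plane_tests,
                 condition_tests = cond_tests, no_variance_groups = novar,
                 params = list(threshold = threshold, alpha = alpha,
                               group_by = group_by)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  %d records, %d flagged (|z| > %g)\n", nrow(x$records),
              sum(x$records$flagged), x$params$threshold))
  if (!is.null(x$plane_tests)) {
    nd <- sum(!x$plane_tests$distinct)
    cat(sprintf("  plane pairs: %d tested, %d NOT distinct at alpha = %g\n",
                nrow(x$plane_tests), nd, x$params$alpha))
  }
  if (!is.null(x$condition_tests)) {
    cat(sprintf("  condition ANOVAs: %d planes, %d with evidence of misalignment\n",
                nrow(x$condition_tests), sum(!x$condition_tests$aligned)))
  }
  invisible(x)
}
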
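#' Pipeline configuration
#'
#' Defaults mirror the method's stated parameters: FDR quotient q = 0.1,
#' alpha = 0.05 for QC tests, bin size from the 2A/n formula with n = the
#' mean marker count per subject.
#'
#' @param q_threshold tolerated FDR for MROI detection.
#' @param alpha significance level for QC tests and contrasts.
#' @param bin_side manual bin side in um; `NULL` (default) uses the 2A/n
#'   formula.
#' @param bin_n `"mean"` (per-subject mean count, default) or `"total"`
#'   (pooled total) as the n of the 2A/n rule.
#' @param test per-bin test, `"anova"` or `"kruskal"`.
#' @param contrast_test `"t"` or `"wilcoxon"` for planned contrasts.
#' @param normalize `"none"` or `"rate"` for mean maps.
#' @param exclude_flagged drop Feret-flagged subjects before binning.
#' @param force continue past a QC hard failure (indistinct planes).
#' @param seed integer seed recorded in the run log (the pipeline itself is
#'   deterministic; the seed feeds any simulation steps).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(q_threshold = 0.1, alpha = 0.05, bin_side = NULL,
                            bin_n = c("mean", "total"),
                            test = c("anova", "kruskal"),
                            contrast_test = c("t", "wilcoxon"),
                            normalize = c("none", "rate"),
                            exclude_flagged = FALSE, force = FALSE,
                            seed = 1L) {
  structure(list(q_threshold = q_threshold, alpha = alpha,
                 bin_side = bin_side, bin_n = match.arg(bin_n),
                 test = match.arg(test),
                 contrast_test = match.arg(contrast_test),
                 normalize = match.arg(normalize),
                 exclude_flagged = isTRUE(exclude_flagged),
                 force = isTRUE(force), seed = as.integer(seed)),
            class = "pipeline_config")
}

.log_line <- function(log, fmt, ...) c(log, sprintf(fmt, ...))

#' Run the full mapping-and-statistics pipeline from a manifest
#'
#' Executes register -> QC -> bin -> maps -> statistics for each (region,
#' plane) in the study: reads and registers contour and markers, verifies
#' section alignment from the Feret table (pairwise plane distinctness and
#' per-plane condition homogeneity; indistinct planes abort unless
#' `config$force`), sizes bins by the 2A/n rule (or a manual side), builds
#' the subjects x bins matrix, renders mean / CV / difference / q-value
#' maps with sidecars, and writes MROI, contrast, PCA (and, with >= 2
#' regions, MANOVA + MDA) tables plus a run log capturing every parameter.
#' Identical inputs + config give identical numeric outputs.
#'
#' @param manifest a `study_manifest` or path to one.
#' @param out_dir output directory (created).
#' @param config a [pipeline_config()].
#' @param stages subset of `c("qc", "bin", "map", "stats")` to run (earlier
#'   prerequisites are always run in-memory).
#' @return Invisibly, a list of in-memory results per (region, plane) plus
#'   `qc`, `log`, and `ok` (logical: no hard failure).
#' @export
run_pipeline <- function(manifest, out_dir,
                         config = pipeline_config(),
                         stages = c("qc", "bin", "map", "stats")) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "study_manifest"),
            inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- .log_line(character(0), "topodens %s | run started %s",
                   as.character(utils::packageVersion("topodens")),
                   format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  for (nm in names(config)) {
    log <- .log_line(log, "param %s = %s", nm,
                     paste(format(config[[nm]]), collapse = ","))
  }
  ok <- TRUE
  results <- list()

  ## ---- QC on the Feret table, if present -------------------------------
  qc <- NULL
  excluded_subjects <- character(0)
  fer_rows <- manifest[manifest$role == "feret", , drop = FALSE]
  if (nrow(fer_rows) && "qc" %in% stages) {
    fer <- read_feret(fer_rows$path[1L])
    qc <- qc_report(fer, alpha = config$alpha)
    utils::write.table(qc$records, file.path(out_dir, "qc_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(qc$plane_tests)) {
      utils::write.table(qc$plane_tests, file.path(out_dir, "qc_planes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (any(!qc$plane_tests$distinct)) {
        log <- .log_line(log,
                         "QC FAILURE: %d plane pair(s) not distinct at alpha = %g",
                         sum(!qc$plane_tests$distinct), config$alpha)
        if (!config$force) {
          writeLines(c(log, "FAILED"), file.path(out_dir, "run_log.txt"))
          file.create(file.path(out_dir, "FAILED"))
          stop("plane distinctness QC failed; re-run with force = TRUE to override")
        }
        ok <- FALSE
      }
    }
    if (!is.null(qc$condition_tests) && any(!qc$condition_tests$aligned)) {
      log <- .log_line(log,
                       "QC warning: condition effect on Feret length at plane(s) %s",
                       paste(qc$condition_tests$plane[!qc$condition_tests$aligned],
                             collapse = ", "))
    }
    if (config$exclude_flagged && any(qc$records$flagged)) {
      excluded_subjects <- unique(qc$records$subject_id[qc$records$flagged])
      log <- .log_line(log, "excluding flagged subject(s): %s",
                       paste(excluded_subjects, collapse = ", "))
    }
    log <- .log_line(log, "QC: %d Feret records, %d flagged at |z| > 3",
                     nrow(qc$records), sum(qc$records$flagged))
  }

  ## ---- per (region, plane) group ---------------------------------------
  mk <- manifest[manifest$role == "markers", , drop = FALSE]
  mk <- mk[!(mk$subject_id %in% excluded_subjects), , drop = FALSE]
  groups <- unique(mk[, c("region", "bregma_mm")])
  region_totals <- list()
  for (gi in seq_len(nrow(groups))) {
    region <- groups$region[gi]
    plane <- groups$bregma_mm[gi]
    tag <- sprintf("%s_bregma%s", region, format(plane))
    sel <- mk[mk$region == region & mk$bregma_mm == plane, , drop = FALSE]
    ctr_rows <- manifest[manifest$role == "contour" &
                           manifest$region == region, , drop = FALSE]
    contour <- read_contour(ctr_rows$path[1L])
    reg <- register_to_anchor(NULL, contour)
    contour <- reg$contour
    sets <- lapply(seq_len(nrow(sel)), function(r) {
      ms <- read_markers(sel$path[r], subject_id = sel$subject_id[r],
                         condition = sel$condition[r], region = region,
                         bregma_mm = plane)
      ms$points <- sweep(ms$points, 2L, reg$offset)
      ms$registered <- TRUE
      ms
    })
    log <- .log_line(log, "[%s] %d marker sets registered (anchor offset %s)",
                     tag, length(sets),
                     paste(format(reg$offset), collapse = ", "))

    ## bin sizing: 2A/n formula unless a manual side was given
    area <- polygon_area(contour)
    counts <- vapply(sets, function(m) nrow(m$points), 0)
    if (is.null(config$bin_side)) {
      n_items <- if (config$bin_n == "mean") mean(counts) else sum(counts)
      ob <- optimal_bin_area(area, n_items)
      bin_side <- ob$bin_side
      log <- .log_line(log,
                       "[%s] bin size rule 2A/n: A = %.1f um^2, n = %.1f (%s) -> side %.2f um",
                       tag, area, n_items, config$bin_n, bin_side)
    } else {
      bin_side <- config$bin_side
      log <- .log_line(log, "[%s] bin size: manual, side %.2f um", tag,
                       bin_side)
    }
    grid <- grid_from_markers(sets, bin_side)
    bmx <- assemble_matrix(sets, grid, contour = contour)
    if ("bin" %in% stages) {
      write_bin_matrix(bmx, file.path(out_dir, sprintf("bin_matrix_%s.tsv", tag)))
    }
    region_totals[[region]] <- data.frame(
      subject_id = bmx$meta$subject_id, condition = bmx$meta$condition,
      total = rowSums(bmx$counts), region = region)

    conds <- unique(bmx$meta$condition)
    res <- list(contour = contour, grid = grid, matrix = bmx)

    if ("map" %in% stages) {
      for (cd in conds) {
        mm <- mean_map(bmx, cd, normalize = config$normalize)
        render_map(mm, file.path(out_dir, sprintf("mean_%s_%s.png", tag, cd)),
                   contour = contour)
        if (sum(bmx$meta$condition == cd) >= 2L) {
          render_map(cv_map(bmx, cd),
                     file.path(out_dir, sprintf("cv_%s_%s.png", tag, cd)),
                     contour = contour)
        }
      }
      if (length(conds) >= 2L) {
        dm <- difference_map(mean_map(bmx, conds[1L], config$normalize),
                             mean_map(bmx, conds[2L], config$normalize))
        render_map(dm, file.path(out_dir, sprintf("diff_%s.png", tag)),
                   contour = contour)
      }
      log <- .log_line(log, "[%s] maps rendered for conditions: %s", tag,
                       paste(conds, collapse = ", "))
    }

    if ("stats" %in% stages && length(conds) >= 2L &&
        all(table(bmx$meta$condition) >= 2L)) {
      mroi <- mroi_detect(bmx, q_threshold = config$q_threshold,
                          test = config$test)
      utils::write.table(mroi$table,
                         file.path(out_dir, sprintf("mroi_%s.tsv", tag)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      render_map(qvalue_map(mroi),
                 file.path(out_dir, sprintf("qmap_%s.png", tag)),
                 contour = contour, zlim = c(0, 1))
      log <- .log_line(log, "[%s] MROI: %d/%d bins at q <= %g", tag,
                       length(mroi$significant), nrow(mroi$table),
                       config$q_threshold)
      res$mroi <- mroi
      if (length(mroi$significant)) {
        ctrs <- planned_contrasts(bmx, list(conds[1:2]),
                                  bins = mroi$significant,
                                  test = config$contrast_test,
                                  alpha = config$alpha)
        utils::write.table(ctrs,
                           file.path(out_dir, sprintf("contrasts_%s.tsv", tag)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        res$contrasts <- ctrs
      }
      if (nrow(aggregate_subjects(bmx)$counts) >= 3L) {
        pca <- pca_topography(bmx)
        utils::write.table(
          data.frame(subject_id = pca$subject_id, condition = pca$condition,
                     pca$scores),
          file.path(out_dir, sprintf("pca_scores_%s.tsv", tag)),
          sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(
          data.frame(bin = pca$bins, loading = pca$sep_loadings),
          file.path(out_dir, sprintf("pca_loadings_%s.tsv", tag)),
          sep = "\t", quote = FALSE, row.names = FALSE)
        log <- .log_line(log, "[%s] PCA: separating component PC%d (%.1f%% var)",
                         tag, pca$sep_component,
                         100 * pca$explained[pca$sep_component])
        res$pca <- pca
      }
    }
    results[[tag]] <- res
  }

  ## ---- cross-region MANOVA + MDA ---------------------------------------
  if ("stats" %in% stages && length(region_totals) >= 2L) {
    tot <- do.call(rbind, region_totals)
    wide <- tapply(tot$total, list(tot$subject_id, tot$region), mean)
    cond <- tot$condition[match(rownames(wide), tot$subject_id)]
    complete <- stats::complete.cases(wide)
    wide <- wide[complete, , drop = FALSE]
    cond <- cond[complete]
    if (nrow(wide) > ncol(wide) + length(unique(cond))) {
      ca <- condition_anova(wide, cond)
      utils::write.table(ca$per_region, file.path(out_dir, "region_anova.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      md <- tryCatch(mda(wide, cond), error = function(e) NULL)
      if (!is.null(md)) {
        utils::write.table(
          data.frame(region = rownames(md$loadings), md$loadings),
          file.path(out_dir, "mda_loadings.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
        log <- .log_line(log, "MDA across %d regions: top predictor %s (r1 = %.3f)",
                         ncol(wide), md$top_predictor,
                         md$canonical_correlations[1L])
        results$mda <- md
      }
      results$region_anova <- ca
    }
  }

  log <- .log_line(log, "run %s", if (ok) "completed" else
    "completed WITH QC FAILURES (forced)")
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(c(results, list(qc = qc, log = log, ok = ok)))
}
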
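## split a delimited data line tolerantly: tabs, commas or runs of spaces
.split_fields <- function(line) {
  strsplit(trimws(gsub(",", " ", gsub("\t", " ", line))), "[[:space:]]+")[[1]]
}

.is_comment <- function(lines) grepl("^[[:space:]]*[#;]", lines) |
  !nzchar(trimws(lines))

#' Read a marker-coordinate file
#'
#' Parses plain-text marker exports (Neurolucida-ASCII-tolerant): columns
#' x, y (optionally z, then a marker name), delimited by tabs, commas or
#' whitespace; lines starting `#` or `;` and non-numeric header lines are
#' skipped and logged. Coordinates are taken to be micrometres.
#'
#' @param path file path.
#' @param subject_id,condition,region,bregma_mm metadata for the resulting
#'   set (normally from the study manifest).
#' @param registered whether the file's coordinates are already in the
#'   registered frame.
#' @param quiet suppress the row-count message.
#' @return A [marker_set].
#' @export
read_markers <- function(path, subject_id = "unknown", condition = "unknown",
                         region = "ROI", bregma_mm = NA_real_,
                         registered = FALSE, quiet = TRUE) {
  if (!file.exists(path)) stop("no such marker file: ", path)
  lines <- readLines(path, warn = FALSE)
  data_lines <- lines[!.is_comment(lines)]
  pts <- matrix(numeric(0), ncol = 2L)
  z <- numeric(0)
  dropped <- 0L
  first_bad <- NULL
  for (ln in data_lines) {
    f <- suppressWarnings(as.numeric(.split_fields(ln)))
    nn <- which(!is.na(f))
    if (length(nn) >= 2L && all(1:2 %in% nn)) {
      pts <- rbind(pts, f[1:2])
      z <- c(z, if (length(f) >= 3L && !is.na(f[3L])) f[3L] else NA_real_)
    } else {
      dropped <- dropped + 1L
      if (is.null(first_bad)) first_bad <- ln
    }
  }
  if (!nrow(pts)) {
    stop("no parseable coordinate rows in ", path,
         if (!is.null(first_bad)) paste0("; first offending line: '",
                                         first_bad, "'"))
  }
  if (!quiet) {
    message(sprintf("read %d markers from %s (%d line(s) dropped)",
                    nrow(pts), path, dropped))
  }
  marker_set(subject_id, condition, bregma_mm, region, pts,
             z = if (all(is.na(z))) NULL else z, registered = registered)
}

#' Write a marker-coordinate file
#'
#' Canonical dialect: one-line `#` header, tab-separated x, y (and z when
#' present) in micrometres.
#'
#' @param markers a [marker_set].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_markers <- function(markers, path) {
  stopifnot(inherits(markers, "marker_set"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# topodens markers subject=%s condition=%s region=%s bregma_mm=%s x_um y_um%s",
                 markers$subject_id, markers$condition, markers$region,
                 format(markers$bregma_mm),
                 if (!is.null(markers$z)) " z_um" else "")
  body <- if (is.null(markers$z)) markers$points else
    cbind(markers$points, markers$z)
  writeLines(c(hdr, apply(format(body, digits = 12, trim = TRUE,
                                 scientific = FALSE), 1L, paste,
                          collapse = "\t")), path)
  invisible(path)
}

#' Read a contour file
#'
#' Plain text: one `x<TAB>y` vertex per line in micrometres (comma
#' delimiters tolerated), with header lines `# label=<region>` and
#' `# bregma_mm=<value>`.
#'
#' @param path file path.
#' @return An [roi_contour].
#' @export
read_contour <- function(path) {
  if (!file.exists(path)) stop("no such contour file: ", path)
  lines <- readLines(path, warn = FALSE)
  label <- "ROI"; bregma <- NA_real_
  for (h in lines[.is_comment(lines)]) {
    m <- regmatches(h, regexec("label[[:space:]]*=[[:space:]]*([^[:space:]]+)", h))[[1]]
    if (length(m) == 2L) label <- m[2L]
    m <- regmatches(h, regexec("bregma_mm[[:space:]]*=[[:space:]]*(-?[0-9.]+)", h))[[1]]
    if (length(m) == 2L) bregma <- as.numeric(m[2L])
  }
  rows <- lapply(lines[!.is_comment(lines)], function(ln) {
    f <- suppressWarnings(as.numeric(.split_fields(ln)))
    if (length(f) >= 2L && !anyNA(f[1:2])) f[1:2] else NULL
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) < 3L) {
    stop("contour file ", path, " has fewer than 3 parseable vertices")
  }
  roi_contour(rows, label = label, bregma_mm = bregma)
}

#' Write a contour file
#'
#' @param contour an [roi_contour].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_contour <- function(contour, path) {
  stopifnot(inherits(contour, "roi_contour"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(c(sprintf("# label=%s", contour$label),
               sprintf("# bregma_mm=%s", format(contour$bregma_mm)),
               apply(format(contour$vertices, digits = 12, trim = TRUE,
                            scientific = FALSE), 1L, paste,
                     collapse = "\t")), path)
  invisible(path)
}

#' Read / write a Feret-length table
#'
#' Delimited text with header columns `subject_id`, `condition`,
#' `bregma_mm`, `feret_um`.
#'
#' @param path file path.
#' @return `read_feret`: a [feret_records] table.
#' @export
read_feret <- function(path) {
  if (!file.exists(path)) stop("no such Feret table: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "",
                         stringsAsFactors = FALSE)
  need <- c("subject_id", "condition", "bregma_mm", "feret_um")
  if (!all(need %in% names(d))) {
    stop("Feret table must have columns: ", paste(need, collapse = ", "))
  }
  feret_records(d$subject_id, d$condition, d$bregma_mm, d$feret_um)
}

#' @rdname read_feret
#' @param records a [feret_records] table.
#' @export
write_feret <- function(records, path) {
  stopifnot(inherits(records, "feret_records"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a study manifest
#'
#' A tab-separated table mapping files to their role and metadata: columns
#' `path`, `role` (`markers` | `contour` | `feret`), `subject_id`,
#' `condition`, `bregma_mm`, `region`. Relative paths resolve against the
#' manifest's directory. Validated: every path exists, (subject, plane,
#' region) marker entries are unique, and every marker entry has a contour
#' entry for its region.
#'
#' @param path manifest path.
#' @return `data.frame` of class `study_manifest` with absolute `path`s.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("path", "role", "subject_id", "condition", "bregma_mm", "region")
  if (!all(need %in% names(d))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", d$path), d$path,
                file.path(base, d$path))
  missing <- abs[!file.exists(abs)]
  if (length(missing)) {
    stop("manifest references missing file(s): ",
         paste(missing, collapse = ", "))
  }
  d$path <- abs
  mk <- d[d$role == "markers", , drop = FALSE]
  if (anyDuplicated(mk[, c("subject_id", "bregma_mm", "region")])) {
    stop("duplicate (subject, plane, region) marker entries in manifest")
  }
  for (r in unique(mk$region)) {
    if (!any(d$role == "contour" & d$region == r)) {
      stop("no contour entry for region '", r, "' in manifest")
    }
  }
  class(d) <- c("study_manifest", "data.frame")
  d
}

#' Write a synthetic study bundle to disk
#'
#' Serialises a [scenario_effect()] / [scenario_null()] bundle in the
#' package's file dialects: one marker file per subject, the shared contour,
#' the Feret table, and a `manifest.tsv` tying them together.
#'
#' @param scenario a scenario bundle list.
#' @param dir output directory (created).
#' @return The manifest path, invisibly usable with [read_manifest()].
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ctr_path <- file.path(dir, "contour.txt")
  write_contour(scenario$contour, ctr_path)
  rows <- list(data.frame(path = "contour.txt", role = "contour",
                          subject_id = NA, condition = NA,
                          bregma_mm = scenario$contour$bregma_mm,
                          region = scenario$contour$label))
  for (ms in scenario$markers) {
    f <- sprintf("markers_%s.txt", ms$subject_id)
    write_markers(ms, file.path(dir, f))
    rows[[length(rows) + 1L]] <- data.frame(
      path = f, role = "markers", subject_id = ms$subject_id,
      condition = ms$condition, bregma_mm = ms$bregma_mm,
      region = ms$region)
  }
  if (!is.null(scenario$feret)) {
    write_feret(scenario$feret, file.path(dir, "feret.tsv"))
    rows[[length(rows) + 1L]] <- data.frame(
      path = "feret.tsv", role = "feret", subject_id = NA, condition = NA,
      bregma_mm = NA, region = scenario$contour$label)
  }
  man <- do.call(rbind, rows)
  man_path <- file.path(dir, "manifest.tsv")
  utils::write.table(man, man_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  man_path
}

#' Export a bin matrix as delimited text
#'
#' One row per subject-section with metadata columns followed by `bin_i_j`
#' count columns; the grid is written alongside as a sidecar of edges in
#' micrometres.
#'
#' @param bm a `bin_matrix`.
#' @param path output path (`<path>.grid.tsv` sidecar added).
#' @return Invisibly, `path`.
#' @export
write_bin_matrix <- function(bm, path) {
  stopifnot(inherits(bm, "bin_matrix"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  out <- cbind(bm$meta, as.data.frame(bm$counts))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- bm$grid
  ne <- max(length(g$x_edges), length(g$y_edges))
  grid_df <- data.frame(
    axis = rep(c("x", "y"), c(length(g$x_edges), length(g$y_edges))),
    edge_um = c(g$x_edges, g$y_edges))
  utils::write.table(grid_df, paste0(path, ".grid.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
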
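# Domain model: probe -> probe set -> transcript cluster hierarchy, the
# sample design, and the TSV interchange formats. TSV dialect: tab-separated,
# UTF-8, '.' decimal, header row; empty string encodes NONE/NA.

.probe_cols <- c("probe_id", "probeset_id", "gc_count", "is_background")
.probeset_cols <- c("probeset_id", "tc_id", "exon_index", "n_exons",
                    "rank_in_exon", "n_probesets_in_exon", "is_constitutive",
                    "known_event", "crosshyb")
.design_cols <- c("sample_id", "group", "replicate")

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    format_error(sprintf("%s: missing column(s): %s", what,
                         paste(missing, collapse = ", ")))
}

.as_logical_col <- function(x, what) {
  if (is.logical(x)) return(x)
  v <- toupper(trimws(as.character(x)))
  out <- v %in% c("TRUE", "T", "1")
  bad <- !v %in% c("TRUE", "T", "1", "FALSE", "F", "0")
  if (any(bad))
    format_error(sprintf("%s: non-boolean value '%s'", what, v[bad][1L]))
  out
}

#' Validate a probe annotation table
#'
#' Checks the invariants of the probe level of the hierarchy: unique probe
#' ids, GC counts in 0..25, `is_background` true exactly when `probeset_id`
#' is absent, and (when a probe-set table is supplied) that every referenced
#' probe set exists.
#'
#' @param probes data.frame with columns `probe_id`, `probeset_id` (NA for
#'   background probes), `gc_count`, `is_background`.
#' @param probesets optional probe-set annotation for reference checking.
#' @return `probes`, invisibly, with normalized column types.
#' @export
validate_probes <- function(probes, probesets = NULL) {
  .require_cols(probes, .probe_cols, "probes")
  probes$probe_id <- as.character(probes$probe_id)
  probes$probeset_id <- as.character(probes$probeset_id)
  probes$probeset_id[!is.na(probes$probeset_id) &
                       probes$probeset_id == ""] <- NA_character_
  probes$gc_count <- as.integer(probes$gc_count)
  probes$is_background <- .as_logical_col(probes$is_background,
                                          "probes$is_background")
  dup <- duplicated(probes$probe_id)
  if (any(dup))
    consistency_error(sprintf("probes: duplicate probe_id '%s' (row %d)",
                              probes$probe_id[dup][1L], which(dup)[1L]))
  bad_gc <- is.na(probes$gc_count) | probes$gc_count < 0 | probes$gc_count > 25
  if (any(bad_gc))
    format_error(sprintf("probes: gc_count out of range 0..25 at row %d",
                         which(bad_gc)[1L]))
  mismatch <- probes$is_background != is.na(probes$probeset_id)
  if (any(mismatch))
    consistency_error(sprintf(
      "probes: is_background must be true iff probeset_id is empty (row %d, probe '%s')",
      which(mismatch)[1L], probes$probe_id[mismatch][1L]))
  if (!is.null(probesets)) {
    refs <- probes$probeset_id[!is.na(probes$probeset_id)]
    orphan <- setdiff(refs, probesets$probeset_id)
    if (length(orphan))
      consistency_error(sprintf(
        "probes: probeset_id '%s' not present in probe-set annotation",
        orphan[1L]))
  }
  invisible(probes)
}

#' Validate a probe-set annotation table
#'
#' Enforces 1-based exon and rank ordinals within their declared totals,
#' one transcript cluster per probe set, a known event vocabulary, and that
#' constitutive probe sets carry no known event annotation.
#'
#' @param probesets data.frame with the `probesets.tsv` columns.
#' @return `probesets`, invisibly, with normalized types.
#' @export
validate_probesets <- function(probesets) {
  .require_cols(probesets, .probeset_cols, "probesets")
  for (cc in c("exon_index", "n_exons", "rank_in_exon", "n_probesets_in_exon"))
    probesets[[cc]] <- as.integer(probesets[[cc]])
  probesets$probeset_id <- as.character(probesets$probeset_id)
  probesets$tc_id <- as.character(probesets$tc_id)
  probesets$known_event <- as.character(probesets$known_event)
  probesets$known_event[is.na(probesets$known_event) |
                          probesets$known_event == ""] <- "NONE"
  probesets$is_constitutive <- .as_logical_col(probesets$is_constitutive,
                                               "probesets$is_constitutive")
  probesets$crosshyb <- .as_logical_col(probesets$crosshyb,
                                        "probesets$crosshyb")
  dup <- duplicated(probesets$probeset_id)
  if (any(dup))
    consistency_error(sprintf("probesets: duplicate probeset_id '%s'",
                              probesets$probeset_id[dup][1L]))
  bad <- probesets$exon_index < 1L | probesets$exon_index > probesets$n_exons
  if (any(bad))
    format_error(sprintf(
      "probesets: exon_index outside 1..n_exons at row %d (probeset '%s')",
      which(bad)[1L], probesets$probeset_id[bad][1L]))
  bad <- probesets$rank_in_exon < 1L |
    probesets$rank_in_exon > probesets$n_probesets_in_exon
  if (any(bad))
    format_error(sprintf(
      "probesets: rank_in_exon outside 1..n_probesets_in_exon at row %d",
      which(bad)[1L]))
  unknown <- !probesets$known_event %in% known_event_levels
  if (any(unknown))
    format_error(sprintf("probesets: unknown known_event '%s' at row %d",
                         probesets$known_event[unknown][1L],
                         which(unknown)[1L]))
  bad <- probesets$is_constitutive & probesets$known_event != "NONE"
  if (any(bad))
    consistency_error(sprintf(
      "probesets: is_constitutive implies known_event == NONE (probeset '%s')",
      probesets$probeset_id[bad][1L]))
  invisible(probesets)
}

#' Validate a sample design table
#'
#' A two-group design with at least two replicate samples per group.
#'
#' @param design data.frame with columns `sample_id`, `group`, `replicate`.
#' @return `design`, invisibly, with normalized types.
#' @export
validate_design <- function(design) {
  .require_cols(design, .design_cols, "design")
  design$sample_id <- as.character(design$sample_id)
  design$group <- as.character(design$group)
  design$replicate <- as.integer(design$replicate)
  if (anyDuplicated(design$sample_id))
    consistency_error("design: duplicate sample_id")
  groups <- unique(design$group)
  if (length(groups) != 2L)
    config_error(sprintf("design: exactly two groups required, found %d",
                         length(groups)))
  n_per <- table(design$group)
  if (any(n_per < 2L))
    config_error("design: at least 2 samples per group required")
  invisible(design)
}

#' Read probe and probe-set annotation tables
#'
#' Parses the two annotation TSVs and verifies every hierarchy invariant;
#' violations raise structured errors naming the offending row and field.
#'
#' @param probes_path path to `probes.tsv`
#'   (`probe_id`, `probeset_id`, `gc_count`, `is_background`).
#' @param probesets_path path to `probesets.tsv`.
#' @return list with validated `probes` and `probesets` data.frames.
#' @export
read_annotation <- function(probes_path, probesets_path) {
  probes <- read.delim(probes_path, colClasses = "character",
                       na.strings = character())
  probesets <- read.delim(probesets_path, colClasses = "character",
                          na.strings = character())
  probesets <- validate_probesets(probesets)
  probes <- validate_probes(probes, probesets)
  list(probes = probes, probesets = probesets)
}

#' Write probe and probe-set annotation tables
#'
#' Inverse of [read_annotation()]; `NA` probe-set references serialize as the
#' empty string.
#'
#' @param annotation list with `probes` and `probesets`.
#' @param probes_path,probesets_path output paths.
#' @return invisibly, the two paths.
#' @export
write_annotation <- function(annotation, probes_path, probesets_path) {
  .write_tsv(annotation$probes, probes_path)
  .write_tsv(annotation$probesets, probesets_path)
  invisible(c(probes_path, probesets_path))
}

.write_tsv <- function(df, path) {
  df[] <- lapply(df, function(x) {
    if (is.logical(x)) return(ifelse(x, "TRUE", "FALSE"))
    x
  })
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    exonsplice_stop(sprintf("cannot write '%s': %s", path,
                            conditionMessage(ok)), "exonsplice_io_error")
  invisible(path)
}

#' Read a sample design table
#' @param path path to `design.tsv`.
#' @return validated design data.frame.
#' @export
read_design <- function(path) {
  validate_design(read.delim(path, colClasses = "character"))
}

#' Read a probe intensity matrix
#'
#' Reads `intensities.tsv` (`probe_id` plus one column per sample) into a
#' strictly positive numeric matrix whose columns follow the design order.
#'
#' @param path path to the intensity TSV.
#' @param design validated sample design; every design sample must be present.
#' @return numeric matrix, probes x samples.
#' @export
read_intensities <- function(path, design) {
  design <- validate_design(design)
  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (!"probe_id" %in% names(tab))
    format_error("intensities: missing 'probe_id' column")
  missing <- setdiff(design$sample_id, names(tab))
  if (length(missing))
    consistency_error(sprintf("intensities: design sample(s) absent: %s",
                              paste(missing, collapse = ", ")))
  ids <- tab$probe_id
  if (anyDuplicated(ids))
    consistency_error("intensities: duplicate probe_id")
  mat <- matrix(NA_real_, nrow(tab), nrow(design),
                dimnames = list(ids, design$sample_id))
  for (s in design$sample_id) {
    v <- suppressWarnings(as.numeric(tab[[s]]))
    bad <- is.na(v) | v <= 0
    if (any(bad))
      format_error(sprintf(
        "intensities: non-positive or non-numeric value '%s' at row %d, sample '%s'",
        tab[[s]][bad][1L], which(bad)[1L], s))
    mat[, s] <- v
  }
  mat
}

#' Write a probe intensity matrix
#' @param mat probes x samples matrix with dimnames.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_intensities <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat),
                   signif(mat, 9), check.names = FALSE)
  .write_tsv(df, path)
}

#' Write gene- and probe-set-level result tables
#'
#' Serializes the two result tables deterministically (columns in canonical
#' order, rows sorted by feature id) so repeat runs are byte-identical.
#'
#' @param gene_results gene-level result data.frame (one row per transcript
#'   cluster).
#' @param splice_results probe-set-level result data.frame.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the two file paths.
#' @export
write_results <- function(gene_results, splice_results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- gene_results[order(gene_results$tc_id), , drop = FALSE]
  s <- splice_results[order(splice_results$probeset_id), , drop = FALSE]
  gp <- file.path(out_dir, "gene_results.tsv")
  sp <- file.path(out_dir, "splice_results.tsv")
  .write_tsv(.round_num(g), gp)
  .write_tsv(.round_num(s), sp)
  invisible(c(gp, sp))
}

.round_num <- function(df) {
  df[] <- lapply(df, function(x) if (is.numeric(x)) signif(x, 9) else x)
  df
}

# level/algorithm-tagged expression matrix ------------------------------------

#' Tag a summarized matrix with its level and algorithm
#'
#' Expression matrices are plain numeric matrices (features x samples,
#' log2 scale) carrying `level` ("PROBESET" or "TRANSCRIPT_CLUSTER") and
#' `algorithm` ("RMA" or "ITERPLIER") attributes for downstream traceability.
#'
#' @param mat numeric matrix of log2 expression values.
#' @param level one of "PROBESET", "TRANSCRIPT_CLUSTER".
#' @param algorithm one of "RMA", "ITERPLIER".
#' @return the tagged matrix.
#' @export
expression_matrix <- function(mat, level, algorithm) {
  level <- match.arg(level, c("PROBESET", "TRANSCRIPT_CLUSTER"))
  algorithm <- match.arg(algorithm, c("RMA", "ITERPLIER"))
  if (any(!is.finite(mat)))
    consistency_error("expression matrix contains non-finite values")
  structure(mat, level = level, algorithm = algorithm)
}
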
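# Differential expression, the five-filter false-positive cascade, the
# Splice Index, dual-algorithm consensus, and positional event
# classification.
#
# Conventions fixed here and documented in the vignette:
#   * group2 (second group of the design, e.g. hypoxia) is the contrast
#     numerator: log2FC and SI are group2 minus group1 on the log2 scale,
#     so a group2-skipped cassette exon has negative SI;
#   * the significance screen is a two-sided Welch t-test on per-sample
#     log2 values (genes) and log2 NI (probe sets), unadjusted; BH q-values
#     are reported alongside but not used for consensus.

#' Analysis thresholds
#'
#' @param fold_threshold linear fold-change threshold (consensus requires
#'   a strictly greater than `fold_threshold`-fold change).
#' @param p_threshold p-value threshold (strictly less than).
#' @param dabg_alpha DABG p-value above which a probe set is undetected in a
#'   sample.
#' @param dabg_sample_fraction fraction of a group's samples that must be
#'   undetected before a probe set counts as not expressed in that group.
#' @param tc_undetected_fraction fraction of a transcript cluster's probe
#'   sets that must be not expressed before the cluster is flagged.
#' @param gene_fc_cap linear gene-level fold-change cap (filter iv).
#' @param ni_cap linear cap on the gene-level normalized intensity
#'   (filter v; applied as |log2 NI| > log2(ni_cap) in any sample).
#' @return an `si_thresholds` list.
#' @export
si_thresholds <- function(fold_threshold = 2, p_threshold = 0.01,
                          dabg_alpha = 0.05, dabg_sample_fraction = 0.5,
                          tc_undetected_fraction = 0.5, gene_fc_cap = 10,
                          ni_cap = 5) {
  th <- list(fold_threshold = fold_threshold, p_threshold = p_threshold,
             dabg_alpha = dabg_alpha,
             dabg_sample_fraction = dabg_sample_fraction,
             tc_undetected_fraction = tc_undetected_fraction,
             gene_fc_cap = gene_fc_cap, ni_cap = ni_cap)
  if (any(unlist(th) <= 0)) config_error("si_thresholds: all thresholds must be positive")
  if (th$dabg_sample_fraction >= 1 || th$tc_undetected_fraction >= 1)
    config_error("si_thresholds: fractions must lie in (0, 1)")
  class(th) <- "si_thresholds"
  th
}

# Vectorized two-sided Welch t-test on rows of a matrix, group2 - group1.
# Variance floor 1e-8 on the pooled squared standard error guards
# zero-variance degeneracies: equal means then give p = 1, unequal means a
# p-value indistinguishable from 0.
.welch_rows <- function(mat, idx1, idx2, var_floor = 1e-8) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(mat[, idx1, drop = FALSE])
  m2 <- rowMeans(mat[, idx2, drop = FALSE])
  v1 <- rowSums((mat[, idx1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((mat[, idx2, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- pmax(v1 / n1 + v2 / n2, var_floor)
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  df[!is.finite(df)] <- n1 + n2 - 2
  df <- pmax(df, 1)
  p <- 2 * pt(-abs(tstat), df)
  list(effect = m2 - m1, t = tstat, df = df, p = p)
}

.group_index <- function(expr, design, groups = NULL) {
  design <- validate_design(design)
  if (!all(design$sample_id %in% colnames(expr)))
    consistency_error("expression matrix lacks design sample column(s)")
  if (is.null(groups)) groups <- unique(design$group)
  if (length(groups) != 2L || !setequal(groups, unique(design$group)))
    config_error("groups must name the design's two conditions")
  list(idx1 = match(design$sample_id[design$group == groups[1L]], colnames(expr)),
       idx2 = match(design$sample_id[design$group == groups[2L]], colnames(expr)),
       groups = groups)
}

#' Per-feature differential expression (Welch t-test)
#'
#' log2FC = mean(group2) - mean(group1) of the per-sample log2 values; p
#' from a two-sided Welch t-test; BH q-values reported alongside.
#'
#' @param expr log2 expression matrix (features x samples).
#' @param design validated two-group design.
#' @param groups optional length-2 vector fixing the contrast orientation
#'   (reference first, numerator second); defaults to design row order.
#' @return data.frame(feature_id, log2fc, p_value, q_value).
#' @export
differential_expression <- function(expr, design, groups = NULL) {
  gi <- .group_index(expr, design, groups)
  w <- .welch_rows(expr, gi$idx1, gi$idx2)
  data.frame(feature_id = rownames(expr), log2fc = unname(w$effect),
             p_value = unname(w$p),
             q_value = p.adjust(w$p, "BH"), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Splice Index with significance
#'
#' Per sample, log2 NI = log2 probe-set expression - log2 transcript-cluster
#' expression; SI = mean log2 NI(group2) - mean log2 NI(group1); p from a
#' two-sided Welch t-test on the per-sample log2 NI.
#'
#' @param ps_expr probe-set-level log2 expression matrix.
#' @param gene_expr transcript-cluster-level log2 expression matrix from the
#'   same algorithm run.
#' @param annotation list(probes, probesets) mapping probe sets to clusters.
#' @param design validated two-group design.
#' @param groups optional length-2 vector fixing the contrast orientation
#'   (reference first, numerator second); defaults to design row order.
#' @return data.frame(probeset_id, tc_id, si, p_value, q_value) carrying the
#'   per-sample log2 NI matrix as attribute `"ni"`.
#' @export
splice_index <- function(ps_expr, gene_expr, annotation, design,
                         groups = NULL) {
  gi <- .group_index(ps_expr, design, groups)
  ps_ids <- rownames(ps_expr)
  tc_ids <- annotation$probesets$tc_id[match(ps_ids,
                                             annotation$probesets$probeset_id)]
  if (anyNA(tc_ids))
    consistency_error("splice_index: probe set(s) missing from the annotation")
  if (!all(tc_ids %in% rownames(gene_expr)))
    consistency_error("splice_index: transcript cluster(s) missing from gene_expr")
  ni <- ps_expr - gene_expr[tc_ids, colnames(ps_expr), drop = FALSE]
  w <- .welch_rows(ni, gi$idx1, gi$idx2)
  out <- data.frame(probeset_id = ps_ids, tc_id = tc_ids,
                    si = unname(w$effect), p_value = unname(w$p),
                    q_value = p.adjust(w$p, "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "ni") <- ni
  out
}

#' The five-filter false-positive cascade
#'
#' Flags per probe set (TRUE = removed by that filter); all five flags are
#' always computed (no short-circuiting) so a report can show every reason
#' for removal:
#' \describe{
#'   \item{f1}{not expressed in one group: DABG p > `dabg_alpha` in more
#'     than `dabg_sample_fraction` of the samples of at least one group.}
#'   \item{f2}{transcript cluster not expressed: more than
#'     `tc_undetected_fraction` of its probe sets are undetected (as in f1)
#'     in one group; propagates to all the cluster's probe sets.}
#'   \item{f3}{cross-hybridization risk (annotation flag).}
#'   \item{f4}{cluster with more than `gene_fc_cap`-fold gene-level
#'     expression difference; propagates.}
#'   \item{f5}{gene-level normalized intensity beyond `ni_cap`-fold of the
#'     cluster level (|log2 NI| > log2 `ni_cap`) in any sample.}
#' }
#'
#' @param gene_expr,ps_expr log2 expression matrices from one algorithm run.
#' @param dabg_table probe set x sample DABG p-value matrix.
#' @param annotation list(probes, probesets).
#' @param design validated two-group design.
#' @param thresholds an [si_thresholds()].
#' @return data.frame(probeset_id, f1..f5, pass) with
#'   `pass == !(f1|f2|f3|f4|f5)`.
#' @export
apply_filters <- function(gene_expr, ps_expr, dabg_table, annotation, design,
                          thresholds = si_thresholds()) {
  design <- validate_design(design)
  ps_ids <- rownames(ps_expr)
  if (!all(ps_ids %in% rownames(dabg_table)))
    consistency_error("apply_filters: probe set(s) missing from the DABG table")
  anns <- annotation$probesets[match(ps_ids, annotation$probesets$probeset_id), ]
  if (anyNA(anns$probeset_id))
    consistency_error("apply_filters: probe set(s) missing from the annotation")
  groups <- unique(design$group)

  # per-group undetected status of each probe set (the f1 building block)
  undetected <- sapply(groups, function(g) {
    cols <- design$sample_id[design$group == g]
    rowMeans(dabg_table[ps_ids, cols, drop = FALSE] > thresholds$dabg_alpha) >
      thresholds$dabg_sample_fraction
  })
  f1 <- rowSums(undetected) > 0

  tc_flagged <- tapply(seq_along(ps_ids), anns$tc_id, function(ii) {
    any(colMeans(undetected[ii, , drop = FALSE]) >
          thresholds$tc_undetected_fraction)
  })
  f2 <- unname(tc_flagged[anns$tc_id])

  f3 <- anns$crosshyb

  de <- differential_expression(gene_expr, design)
  big <- de$feature_id[abs(de$log2fc) > log2(thresholds$gene_fc_cap)]
  f4 <- anns$tc_id %in% big

  ni <- ps_expr - gene_expr[anns$tc_id, colnames(ps_expr), drop = FALSE]
  f5 <- apply(abs(ni) > log2(thresholds$ni_cap), 1L, any)

  data.frame(probeset_id = ps_ids, f1 = unname(f1), f2 = f2, f3 = f3,
             f4 = f4, f5 = unname(f5),
             pass = !(f1 | f2 | f3 | f4 | f5),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Dual-algorithm consensus calls
#'
#' A feature is in consensus iff, under BOTH algorithms, it changes more
#' than `fold_threshold`-fold with p below `p_threshold`, the effect signs
#' agree, and (at probe-set level) all five filters pass.
#'
#' @param results_rma,results_iterplier data.frames with columns `id`,
#'   `effect` (log2FC or SI), `p`, and optionally `pass` (filter status,
#'   required at probe-set level).
#' @param thresholds an [si_thresholds()].
#' @param level "gene" or "probeset".
#' @return character vector of consensus ids.
#' @export
consensus <- function(results_rma, results_iterplier,
                      thresholds = si_thresholds(),
                      level = c("gene", "probeset")) {
  level <- match.arg(level)
  hit <- function(res) {
    ok <- abs(res$effect) > log2(thresholds$fold_threshold) &
      res$p < thresholds$p_threshold
    if (level == "probeset") {
      if (is.null(res$pass))
        config_error("consensus: probe-set results need a 'pass' column")
      ok <- ok & res$pass
    }
    res$id[ok]
  }
  a <- results_rma[match(hit(results_rma), results_rma$id), ]
  b <- results_iterplier[match(hit(results_iterplier), results_iterplier$id), ]
  ids <- intersect(a$id, b$id)
  agree <- sign(a$effect[match(ids, a$id)]) ==
    sign(b$effect[match(ids, b$id)])
  sort(ids[agree])
}

#' Classify consensus probe sets into the four positional event groups
#'
#' Precedence: known alternative-splicing event (annotation `known_event`),
#' then sole probe set of a terminal exon (candidate UTR length change),
#' then one-of-several probe sets of a terminal exon, then constitutive
#' exon; anything else is reported UNCLASSIFIED.
#'
#' @param probeset_ids probe sets to classify.
#' @param annotation list(probes, probesets).
#' @return data.frame(probeset_id, category, event_type).
#' @export
classify_events <- function(probeset_ids, annotation) {
  ann <- annotation$probesets
  ii <- match(probeset_ids, ann$probeset_id)
  if (anyNA(ii))
    consistency_error(sprintf("classify_events: unknown probeset id '%s'",
                              probeset_ids[is.na(ii)][1L]))
  a <- ann[ii, ]
  terminal <- a$exon_index == 1L | a$exon_index == a$n_exons
  category <- ifelse(a$known_event != "NONE", "KNOWN_AS_EVENT",
              ifelse(terminal & a$n_probesets_in_exon == 1L,
                     "TERMINAL_UTR_PROBESET",
              ifelse(terminal & a$n_probesets_in_exon > 1L,
                     "TERMINAL_EXON_PROBESET",
              ifelse(a$is_constitutive, "CONSTITUTIVE_EXON",
                     "UNCLASSIFIED"))))
  data.frame(probeset_id = probeset_ids, category = category,
             event_type = ifelse(a$known_event != "NONE", a$known_event,
                                 NA_character_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full two-algorithm splice analysis
#'
#' Assembles the gene- and probe-set-level result tables from the four
#' summarized matrices, the DABG table, the annotation and the thresholds:
#' per-algorithm differential expression and Splice Index, the filter
#' cascade per algorithm, dual-algorithm consensus at both levels, and the
#' event classification of consensus probe sets.
#'
#' @param expr list with elements `rma_gene`, `rma_ps`, `plier_gene`,
#'   `plier_ps` (log2 expression matrices).
#' @param dabg_table probe set x sample DABG p-values.
#' @param annotation list(probes, probesets).
#' @param design validated two-group design.
#' @param thresholds an [si_thresholds()].
#' @return list(gene_results, splice_results, filters = per-algorithm flag
#'   tables).
#' @export
splice_analysis <- function(expr, dabg_table, annotation, design,
                            thresholds = si_thresholds()) {
  de_r <- differential_expression(expr$rma_gene, design)
  de_p <- differential_expression(expr$plier_gene, design)
  si_r <- splice_index(expr$rma_ps, expr$rma_gene, annotation, design)
  si_p <- splice_index(expr$plier_ps, expr$plier_gene, annotation, design)
  fl_r <- apply_filters(expr$rma_gene, expr$rma_ps, dabg_table, annotation,
                        design, thresholds)
  fl_p <- apply_filters(expr$plier_gene, expr$plier_ps, dabg_table,
                        annotation, design, thresholds)

  gene_cons <- consensus(
    data.frame(id = de_r$feature_id, effect = de_r$log2fc, p = de_r$p_value),
    data.frame(id = de_p$feature_id, effect = de_p$log2fc, p = de_p$p_value),
    thresholds, "gene")
  gene_results <- data.frame(
    tc_id = de_r$feature_id,
    log2fc_rma = de_r$log2fc, p_rma = de_r$p_value, q_rma = de_r$q_value,
    log2fc_iterplier = de_p$log2fc[match(de_r$feature_id, de_p$feature_id)],
    p_iterplier = de_p$p_value[match(de_r$feature_id, de_p$feature_id)],
    q_iterplier = de_p$q_value[match(de_r$feature_id, de_p$feature_id)],
    stringsAsFactors = FALSE)
  gene_results$hit_rma <-
    abs(gene_results$log2fc_rma) > log2(thresholds$fold_threshold) &
    gene_results$p_rma < thresholds$p_threshold
  gene_results$hit_iterplier <-
    abs(gene_results$log2fc_iterplier) > log2(thresholds$fold_threshold) &
    gene_results$p_iterplier < thresholds$p_threshold
  gene_results$consensus <- gene_results$tc_id %in% gene_cons
  gene_results$direction <- ifelse(!gene_results$consensus, NA_character_,
                                   ifelse(gene_results$log2fc_rma > 0, "UP",
                                          "DOWN"))

  stopifnot(identical(si_r$probeset_id, fl_r$probeset_id),
            identical(si_p$probeset_id, fl_p$probeset_id))
  ps_cons <- consensus(
    data.frame(id = si_r$probeset_id, effect = si_r$si, p = si_r$p_value,
               pass = fl_r$pass),
    data.frame(id = si_p$probeset_id, effect = si_p$si, p = si_p$p_value,
               pass = fl_p$pass),
    thresholds, "probeset")

  flags <- c("f1", "f2", "f3", "f4", "f5")
  splice_results <- data.frame(
    probeset_id = si_r$probeset_id, tc_id = si_r$tc_id,
    si_rma = si_r$si, p_rma = si_r$p_value, q_rma = si_r$q_value,
    si_iterplier = si_p$si[match(si_r$probeset_id, si_p$probeset_id)],
    p_iterplier = si_p$p_value[match(si_r$probeset_id, si_p$probeset_id)],
    q_iterplier = si_p$q_value[match(si_r$probeset_id, si_p$probeset_id)],
    stringsAsFactors = FALSE)
  for (f in flags)
    splice_results[[f]] <- fl_r[[f]] |
      fl_p[[f]][match(si_r$probeset_id, fl_p$probeset_id)]
  splice_results$pass_rma <- fl_r$pass
  splice_results$pass_iterplier <-
    fl_p$pass[match(si_r$probeset_id, fl_p$probeset_id)]
  splice_results$pass <- splice_results$pass_rma &
    splice_results$pass_iterplier
  lf <- log2(thresholds$fold_threshold)
  splice_results$hit_rma <- splice_results$pass_rma &
    abs(splice_results$si_rma) > lf &
    splice_results$p_rma < thresholds$p_threshold
  splice_results$hit_iterplier <- splice_results$pass_iterplier &
    abs(splice_results$si_iterplier) > lf &
    splice_results$p_iterplier < thresholds$p_threshold
  splice_results$consensus <- splice_results$probeset_id %in% ps_cons
  cl <- classify_events(splice_results$probeset_id, annotation)
  splice_results$category <- ifelse(splice_results$consensus, cl$category,
                                    NA_character_)
  splice_results$event_type <- ifelse(splice_results$consensus,
                                      cl$event_type, NA_character_)
  list(gene_results = gene_results, splice_results = splice_results,
       filters = list(RMA = fl_r, ITERPLIER = fl_p))
}
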
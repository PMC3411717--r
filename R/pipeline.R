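# End-to-end orchestration: (simulate | read) -> summarize with both
# algorithms at both levels -> DABG -> filters/SI/consensus/classification
# -> optional enrichment -> result files and the run summary.

#' Pipeline run configuration
#'
#' Either `input_dir` (holding `probes.tsv`, `probesets.tsv`, `design.tsv`,
#' `intensities.tsv`, optionally `truth.tsv`) or a [sim_config()] for a
#' self-generated run must be given.
#'
#' @param input_dir directory of input TSVs, or NULL.
#' @param sim simulation configuration, or NULL.
#' @param design design used for simulated runs (default 3 vs 3).
#' @param thresholds an [si_thresholds()].
#' @param rma an [rma_params()].
#' @param plier a [plier_params()].
#' @param term_map_path optional term membership TSV for enrichment.
#' @param out_dir output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(input_dir = NULL, sim = NULL, design = sim_design(),
                       thresholds = si_thresholds(), rma = rma_params(),
                       plier = plier_params(), term_map_path = NULL,
                       out_dir = tempfile("exonsplice_run_")) {
  if (is.null(input_dir) && is.null(sim))
    config_error("run_config: either input_dir or a sim config is required")
  if (!is.null(input_dir) && !is.null(sim))
    config_error("run_config: give input_dir or a sim config, not both")
  structure(list(input_dir = input_dir, sim = sim, design = design,
                 thresholds = thresholds, rma = rma, plier = plier,
                 term_map_path = term_map_path, out_dir = out_dir),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, exonsplice_error = function(e) {
    exonsplice_stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
                    class(e)[1L])
  })
}

#' Run the full analysis pipeline
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with the dataset, expression matrices, result
#'   tables, counts, and output paths.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  ds <- .stage("input", {
    if (!is.null(config$sim)) {
      say("simulate: n_tcs=%d seed=%d", config$sim$n_tcs, config$sim$seed)
      simulate_dataset(config$sim, config$design)
    } else {
      ann <- read_annotation(file.path(config$input_dir, "probes.tsv"),
                             file.path(config$input_dir, "probesets.tsv"))
      design <- read_design(file.path(config$input_dir, "design.tsv"))
      raw <- read_intensities(file.path(config$input_dir, "intensities.tsv"),
                              design)
      list(probes = ann$probes, probesets = ann$probesets, design = design,
           intensities = raw, truth = NULL)
    }
  })
  ann <- list(probes = ds$probes, probesets = ds$probesets)

  expr <- .stage("summarize", list(
    rma_gene = rma(ds$intensities, ann, "TRANSCRIPT_CLUSTER", config$rma),
    rma_ps = rma(ds$intensities, ann, "PROBESET", config$rma),
    plier_gene = iter_plier(ds$intensities, ann, "TRANSCRIPT_CLUSTER",
                            config$plier),
    plier_ps = iter_plier(ds$intensities, ann, "PROBESET", config$plier)))
  say("summarize: %d probe sets, %d transcript clusters",
      nrow(expr$rma_ps), nrow(expr$rma_gene))

  dabg_table <- .stage("dabg", dabg(ds$intensities, ann, ds$design))
  res <- .stage("call", splice_analysis(expr, dabg_table, ann, ds$design,
                                        config$thresholds))
  counts <- summarize_counts(res$gene_results, res$splice_results)

  enr <- NULL
  if (!is.null(config$term_map_path)) {
    enr <- .stage("enrich", {
      tm <- read_term_map(config$term_map_path)
      universe <- res$gene_results$tc_id
      up <- res$gene_results$tc_id[res$gene_results$consensus &
                                     res$gene_results$direction == "UP"]
      down <- res$gene_results$tc_id[res$gene_results$consensus &
                                       res$gene_results$direction == "DOWN"]
      rbind(cbind(list_name = "up", ora(up, universe, tm)),
            cbind(list_name = "down", ora(down, universe, tm)))
    })
  }

  recovery <- if (!is.null(ds$truth)) .truth_recovery(ds$truth, res) else NULL

  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .stage("write", {
    write_results(res$gene_results, res$splice_results, out_dir)
    .write_tsv(data.frame(probeset_id = rownames(dabg_table),
                          signif(dabg_table, 6), check.names = FALSE),
               file.path(out_dir, "dabg.tsv"))
    if (!is.null(enr)) .write_tsv(.round_num(enr),
                                  file.path(out_dir, "enrichment.tsv"))
    if (!is.null(recovery)) .write_tsv(.round_num(recovery),
                                       file.path(out_dir, "truth_recovery.tsv"))
    writeLines(format_summary(counts, config), file.path(out_dir, "summary.txt"))
  })
  say("done: %s", out_dir)
  invisible(list(dataset = ds, expr = expr, dabg = dabg_table,
                 gene_results = res$gene_results,
                 splice_results = res$splice_results, counts = counts,
                 enrichment = enr, recovery = recovery, out_dir = out_dir))
}

.truth_recovery <- function(truth, res) {
  g <- truth$tc[truth$tc$true_log2fc != 0, , drop = FALSE]
  gr <- res$gene_results[match(g$tc_id, res$gene_results$tc_id), , drop = FALSE]
  gene_rows <- data.frame(
    feature_id = g$tc_id,
    level = rep("TRANSCRIPT_CLUSTER", nrow(g)),
    event_type = rep("NONE", nrow(g)),
    true_effect = g$true_log2fc, observed_effect = gr$log2fc_rma,
    recovered = gr$consensus %in% TRUE,
    sign_match = sign(gr$log2fc_rma) == sign(g$true_log2fc),
    stringsAsFactors = FALSE)
  p <- truth$probeset[truth$probeset$event_type != "NONE", , drop = FALSE]
  pr <- res$splice_results[match(p$probeset_id, res$splice_results$probeset_id), ,
                           drop = FALSE]
  ps_rows <- data.frame(
    feature_id = p$probeset_id, level = rep("PROBESET", nrow(p)),
    event_type = p$event_type,
    true_effect = p$true_si, observed_effect = pr$si_rma,
    recovered = pr$consensus %in% TRUE,
    sign_match = sign(pr$si_rma) == sign(p$true_si),
    stringsAsFactors = FALSE)
  rbind(gene_rows, ps_rows)
}

#' Summary counts of a two-algorithm run
#'
#' Per-algorithm hit counts, consensus counts, up/down split with integer
#' percentages (rounded half away from zero), per-algorithm overlap
#' percentages (consensus / algorithm hits), and the consensus category
#' tally.
#'
#' @param gene_results,splice_results result tables from [splice_analysis()].
#' @return named list of counts and percentages.
#' @export
summarize_counts <- function(gene_results, splice_results) {
  up <- sum(gene_results$consensus & gene_results$direction %in% "UP")
  down <- sum(gene_results$consensus & gene_results$direction %in% "DOWN")
  cons_g <- sum(gene_results$consensus)
  rma_g <- sum(gene_results$hit_rma)
  plier_g <- sum(gene_results$hit_iterplier)
  cons_ps <- sum(splice_results$consensus)
  rma_ps <- sum(splice_results$hit_rma)
  plier_ps <- sum(splice_results$hit_iterplier)
  cats <- table(factor(splice_results$category[splice_results$consensus],
                       levels = event_categories))
  list(
    rma_gene_hits = rma_g, iterplier_gene_hits = plier_g,
    consensus_genes = cons_g, up = up, down = down,
    pct_up = pct_round(up, cons_g), pct_down = pct_round(down, cons_g),
    gene_overlap_pct_rma = pct_round(cons_g, rma_g),
    gene_overlap_pct_iterplier = pct_round(cons_g, plier_g),
    rma_probeset_hits = rma_ps, iterplier_probeset_hits = plier_ps,
    consensus_probesets = cons_ps,
    probeset_overlap_pct_rma = pct_round(cons_ps, rma_ps),
    probeset_overlap_pct_iterplier = pct_round(cons_ps, plier_ps),
    categories = as.list(cats), category_total = sum(cats))
}

#' Format a run summary as text lines
#' @param counts list from [summarize_counts()].
#' @param config optional `run_config` whose seed/thresholds are echoed.
#' @return character vector of lines.
#' @export
format_summary <- function(counts, config = NULL) {
  fmt <- function(x) ifelse(is.na(x), "NA", format(x))
  lines <- c("exonsplice run summary", "======================")
  if (!is.null(config)) {
    th <- config$thresholds
    lines <- c(lines, sprintf(
      "thresholds: fold>%g p<%g dabg_alpha=%g gene_fc_cap=%g ni_cap=%g",
      th$fold_threshold, th$p_threshold, th$dabg_alpha, th$gene_fc_cap,
      th$ni_cap))
    if (!is.null(config$sim))
      lines <- c(lines, sprintf("simulated input: n_tcs=%d seed=%d",
                                config$sim$n_tcs, config$sim$seed))
  }
  lines <- c(lines,
    sprintf("gene hits: RMA=%d Iter-PLIER=%d consensus=%d",
            counts$rma_gene_hits, counts$iterplier_gene_hits,
            counts$consensus_genes),
    sprintf("consensus genes: %d up (%s%%), %d down (%s%%)",
            counts$up, fmt(counts$pct_up), counts$down, fmt(counts$pct_down)),
    sprintf("gene-level overlap: %s%% of RMA, %s%% of Iter-PLIER",
            fmt(counts$gene_overlap_pct_rma),
            fmt(counts$gene_overlap_pct_iterplier)),
    sprintf("probe-set hits: RMA=%d Iter-PLIER=%d consensus=%d",
            counts$rma_probeset_hits, counts$iterplier_probeset_hits,
            counts$consensus_probesets),
    sprintf("probe-set overlap: %s%% of RMA, %s%% of Iter-PLIER",
            fmt(counts$probeset_overlap_pct_rma),
            fmt(counts$probeset_overlap_pct_iterplier)),
    "consensus probe-set categories:")
  for (nm in names(counts$categories))
    lines <- c(lines, sprintf("  %s: %d", nm, counts$categories[[nm]]))
  c(lines, sprintf("  total: %d", counts$category_total))
}
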
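# Fixtures are built in code; nothing is read from disk except round-trip
# temp files created by the tests themselves.

# Minimal hand-built annotation: two transcript clusters, one with three
# exons (middle probe set cassette-annotated), plus two background probes.
tiny_annotation <- function() {
  probesets <- data.frame(
    probeset_id = c("tcA_ps1", "tcA_ps2", "tcA_ps3", "tcB_ps1", "tcB_ps2"),
    tc_id = c("tcA", "tcA", "tcA", "tcB", "tcB"),
    exon_index = c(1L, 2L, 3L, 1L, 2L),
    n_exons = c(3L, 3L, 3L, 2L, 2L),
    rank_in_exon = 1L, n_probesets_in_exon = 1L,
    is_constitutive = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    known_event = c("NONE", "CASSETTE", "NONE", "NONE", "NONE"),
    crosshyb = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  probes <- data.frame(
    probe_id = c(paste0(rep(probesets$probeset_id, each = 2), "_p", 1:2),
                 "bg1", "bg2"),
    probeset_id = c(rep(probesets$probeset_id, each = 2), NA, NA),
    gc_count = c(rep(12L, 10), 8L, 15L),
    is_background = c(rep(FALSE, 10), TRUE, TRUE),
    stringsAsFactors = FALSE)
  list(probes = probes, probesets = probesets)
}

# Duplicate a simulated dataset with swapped group columns so that every
# sample column carries the same value multiset: quantile normalization is
# then exactly the identity, making noiseless pipeline results exact.
mirror_dataset <- function(ds) {
  pref <- function(x) if (length(x)) paste0("m_", x) else x
  probes2 <- ds$probes
  probes2$probe_id <- pref(probes2$probe_id)
  probes2$probeset_id[!probes2$is_background] <-
    pref(probes2$probeset_id[!probes2$is_background])
  probesets2 <- ds$probesets
  probesets2$probeset_id <- pref(probesets2$probeset_id)
  probesets2$tc_id <- pref(probesets2$tc_id)

  design <- ds$design
  groups <- unique(design$group)
  swap <- design$sample_id
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    other <- setdiff(groups, d$group)
    swap[i] <- design$sample_id[design$group == other &
                                  design$replicate == d$replicate]
  }
  int2 <- ds$intensities[, swap, drop = FALSE]
  colnames(int2) <- design$sample_id
  rownames(int2) <- pref(rownames(ds$intensities))

  probesets <- rbind(ds$probesets, probesets2)
  ev <- attr(ds$probesets, "planted_events")
  if (!is.null(ev)) {
    ev2 <- ev
    ev2$tc_id <- pref(ev2$tc_id)
    ev2$probeset_id <- pref(ev2$probeset_id)
    attr(probesets, "planted_events") <- rbind(ev, ev2)
  }
  truth <- ds$truth
  if (!is.null(truth)) {
    t2 <- truth
    t2$tc$tc_id <- pref(t2$tc$tc_id)
    t2$tc$true_log2fc <- -t2$tc$true_log2fc
    t2$probeset$probeset_id <- pref(t2$probeset$probeset_id)
    t2$probeset$true_si <- -t2$probeset$true_si
    truth <- list(tc = rbind(truth$tc, t2$tc),
                  probeset = rbind(truth$probeset, t2$probeset),
                  seed = truth$seed)
  }
  list(probes = rbind(ds$probes, probes2), probesets = probesets,
       design = design, intensities = rbind(ds$intensities, int2),
       truth = truth)
}

# Noiseless world: no residual or affinity noise, no additive background,
# every TC expressed. One planted cassette per `n_tcs` clusters when
# as_fraction is set accordingly.
noiseless_config <- function(n_tcs = 10L, as_fraction = 0, de_fraction = 0,
                             seed = 1L, ...) {
  sim_config(n_tcs = n_tcs, as_fraction = as_fraction,
             de_fraction = de_fraction,
             event_mix = c(CASSETTE = 1),
             probesets_per_exon = c(1L, 1L), probesets_per_exon_probs = 1,
             noise_sd = 0, affinity_sd = 0, bg_intercept = -Inf,
             bg_noise_sd = 0, n_background_probes = 0L,
             expressed_fraction = 1, crosshyb_fraction = 0, seed = seed, ...)
}

# Mirrored noiseless dataset with one planted cassette (and its +1 mirror
# image); quantile normalization is exactly neutral on it.
noiseless_cassette_fixture <- function(seed = 1L) {
  cfg <- noiseless_config(n_tcs = 10L, as_fraction = 0.1, seed = seed)
  mirror_dataset(simulate_dataset(cfg))
}

# Summarize a dataset with both algorithms at both levels (background
# correction only when the generating model had a background component).
summarize_both <- function(ds, background = TRUE,
                           rma_par = rma_params(background = background),
                           plier_par = plier_params()) {
  ann <- list(probes = ds$probes, probesets = ds$probesets)
  list(rma_gene = rma(ds$intensities, ann, "TRANSCRIPT_CLUSTER", rma_par),
       rma_ps = rma(ds$intensities, ann, "PROBESET", rma_par),
       plier_gene = iter_plier(ds$intensities, ann, "TRANSCRIPT_CLUSTER",
                               plier_par),
       plier_ps = iter_plier(ds$intensities, ann, "PROBESET", plier_par))
}

# Result tables carrying the published headline counts, used to exercise the
# run-summary arithmetic without array data: 296 / 650 / 294 genes with an
# 86 up / 208 down split, and 189 / 474 / 61 probe sets with consensus
# categories split 15 / 8 / 13 / 25.
paper_count_tables <- function() {
  n_rma_only <- 296 - 294     # 2
  n_plier_only <- 650 - 294   # 356
  n_gene <- 294 + n_rma_only + n_plier_only
  gene <- data.frame(
    tc_id = sprintf("g%04d", seq_len(n_gene)),
    hit_rma = c(rep(TRUE, 294), rep(TRUE, n_rma_only),
                rep(FALSE, n_plier_only)),
    hit_iterplier = c(rep(TRUE, 294), rep(FALSE, n_rma_only),
                      rep(TRUE, n_plier_only)),
    consensus = c(rep(TRUE, 294), rep(FALSE, n_rma_only + n_plier_only)),
    direction = c(rep("UP", 86), rep("DOWN", 208),
                  rep(NA, n_rma_only + n_plier_only)),
    stringsAsFactors = FALSE)
  cats <- c(rep("TERMINAL_UTR_PROBESET", 15), rep("TERMINAL_EXON_PROBESET", 8),
            rep("CONSTITUTIVE_EXON", 13), rep("KNOWN_AS_EVENT", 25))
  n_ps <- 189 + 474 - 61
  splice <- data.frame(
    probeset_id = sprintf("p%04d", 1:n_ps),
    hit_rma = c(rep(TRUE, 189), rep(FALSE, n_ps - 189)),
    hit_iterplier = c(rep(TRUE, 61), rep(FALSE, 189 - 61), rep(TRUE, 474 - 61),
                      rep(FALSE, n_ps - 189 - (474 - 61))),
    consensus = c(rep(TRUE, 61), rep(FALSE, n_ps - 61)),
    category = c(cats, rep(NA, n_ps - 61)),
    stringsAsFactors = FALSE)
  list(gene = gene, splice = splice)
}

.mat <- function(values, ids, design) {
  matrix(values, nrow = length(ids), ncol = nrow(design), byrow = TRUE,
         dimnames = list(ids, design$sample_id))
}

# Hand-built six-cluster scenario: five clusters violate exactly one filter
# each (on their middle probe set), the sixth is clean.
filter_toy <- function() {
  design <- sim_design(3L)
  tcs <- sprintf("t%d", 1:6)
  probesets <- do.call(rbind, lapply(tcs, function(t) data.frame(
    probeset_id = paste0(t, "_ps", 1:3), tc_id = t, exon_index = 1:3,
    n_exons = 3L, rank_in_exon = 1L, n_probesets_in_exon = 1L,
    is_constitutive = FALSE, known_event = "NONE", crosshyb = FALSE,
    stringsAsFactors = FALSE)))
  probes <- data.frame(probe_id = paste0(probesets$probeset_id, "_p1"),
                       probeset_id = probesets$probeset_id, gc_count = 12L,
                       is_background = FALSE, stringsAsFactors = FALSE)
  probesets$crosshyb[probesets$probeset_id == "t3_ps2"] <- TRUE

  ps_ids <- probesets$probeset_id
  gene <- .mat(rep(8, 6 * 6), tcs, design)
  gene["t4", design$group == "hypoxia"] <- 12   # 16-fold: filter (iv)
  ps <- gene[probesets$tc_id, ]
  rownames(ps) <- ps_ids
  ps["t5_ps2", 1] <- 8 + log2(6)                # |log2 NI| > log2 5: filter (v)

  dabg_tab <- matrix(0.001, length(ps_ids), 6,
                     dimnames = list(ps_ids, design$sample_id))
  hyp <- design$sample_id[design$group == "hypoxia"]
  dabg_tab["t1_ps2", hyp[1:2]] <- 0.5           # undetected 2/3: filter (i)
  dabg_tab["t2_ps1", hyp] <- 0.5                # two of three probe sets
  dabg_tab["t2_ps3", hyp] <- 0.5                #   undetected: filter (ii)
  list(design = design, annotation = list(probes = probes,
                                          probesets = probesets),
       gene = gene, ps = ps, dabg = dabg_tab)
}

# Independent brute-force median polish used as the oracle: plain R,
# translated directly from the textbook sweep, run to tight convergence.
oracle_medpolish <- function(y, eps = 1e-13, maxiter = 1000L) {
  fit <- stats::medpolish(y, eps = eps, maxiter = maxiter, trace.iter = FALSE)
  fit$overall + fit$col
}
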
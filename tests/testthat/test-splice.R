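test_that("differential expression handles degenerate inputs as documented", {
  design <- sim_design(3L)
  expr <- .mat(rep(5, 6), c("a", "b"), design)
  de <- differential_expression(expr, design)
  expect_equal(de$log2fc, c(0, 0))
  expect_equal(de$p_value, c(1, 1))

  # zero variance, unequal means: variance floor drives p toward 0
  expr2 <- expr
  expr2["a", design$group == "hypoxia"] <- 6
  de2 <- differential_expression(expr2, design)
  expect_equal(de2$log2fc[1], 1)
  expect_lt(de2$p_value[1], 1e-6)
})

test_that("Welch screen is calibrated near the nominal rate at n=3", {
  set.seed(41)
  expr <- matrix(rnorm(10000 * 6), 10000, 6,
                 dimnames = list(sprintf("f%05d", 1:10000),
                                 sim_design()$sample_id))
  de <- differential_expression(expr, sim_design())
  frac <- mean(de$p_value < 0.01)
  expect_gte(frac, 0.005)   # Welch at n=3 runs conservative
  expect_lte(frac, 0.015)
})

test_that("splice index follows the NI definition and sign convention", {
  design <- sim_design(3L)
  ann <- tiny_annotation()
  gene <- .mat(c(rep(8, 6), rep(6, 3), rep(7, 3)), c("tcA", "tcB"), design)
  # tcA_ps2 equals its TC in every sample -> SI 0, p 1;
  # tcB_ps1 constant while tcB rises 2-fold -> SI = -1
  ps <- rbind(tcA_ps2 = gene["tcA", ], tcB_ps1 = rep(6.5, 6))
  colnames(ps) <- design$sample_id
  si <- splice_index(ps, gene, ann, design)
  expect_equal(si$si[si$probeset_id == "tcA_ps2"], 0)
  expect_equal(si$p_value[si$probeset_id == "tcA_ps2"], 1)
  expect_equal(si$si[si$probeset_id == "tcB_ps1"], -1)
  expect_equal(si$tc_id, c("tcA", "tcB"))
  ni <- attr(si, "ni")
  expect_equal(unname(ni["tcA_ps2", ]), rep(0, 6))

  # missing transcript cluster -> consistency error
  expect_error(splice_index(ps, gene[1, , drop = FALSE], ann, design),
               class = "exonsplice_consistency_error")
})

test_that("SI is antisymmetric under group label swap", {
  ds <- simulate_dataset(huvec_like_config(seed = 43L, n_tcs = 60L))
  expr <- suppressWarnings(summarize_both(ds))
  si <- splice_index(expr$rma_ps, expr$rma_gene,
                     list(probes = ds$probes, probesets = ds$probesets),
                     ds$design)
  si2 <- splice_index(expr$rma_ps, expr$rma_gene,
                      list(probes = ds$probes, probesets = ds$probesets),
                      ds$design, groups = c("hypoxia", "normoxia"))
  expect_equal(si2$si, -si$si, tolerance = 1e-12)
  expect_equal(si2$p_value, si$p_value, tolerance = 1e-12)
})

test_that("each filter fires alone on its constructed violation", {
  toy <- filter_toy()
  fl <- apply_filters(toy$gene, toy$ps, toy$dabg, toy$annotation, toy$design)
  rownames(fl) <- fl$probeset_id
  flags <- c("f1", "f2", "f3", "f4", "f5")

  expect_equal(unlist(fl["t1_ps2", flags]) > 0,
               c(f1 = TRUE, f2 = FALSE, f3 = FALSE, f4 = FALSE, f5 = FALSE))
  # t2: the detected middle probe set is removed by the TC-level filter only
  expect_equal(unlist(fl["t2_ps2", flags]) > 0,
               c(f1 = FALSE, f2 = TRUE, f3 = FALSE, f4 = FALSE, f5 = FALSE))
  expect_equal(unlist(fl["t3_ps2", flags]) > 0,
               c(f1 = FALSE, f2 = FALSE, f3 = TRUE, f4 = FALSE, f5 = FALSE))
  expect_equal(unlist(fl["t4_ps2", flags]) > 0,
               c(f1 = FALSE, f2 = FALSE, f3 = FALSE, f4 = TRUE, f5 = FALSE))
  expect_equal(unlist(fl["t5_ps2", flags]) > 0,
               c(f1 = FALSE, f2 = FALSE, f3 = FALSE, f4 = FALSE, f5 = TRUE))
  # the clean family survives intact, and only it does among the "_ps2"
  expect_true(all(fl[paste0("t6_ps", 1:3), "pass"]))
  surviving_tcs <- unique(substr(fl$probeset_id[fl$pass], 1, 2))
  expect_false("t4" %in% surviving_tcs)
  expect_true(all(fl["t4_ps2", flags] == fl["t4_ps1", flags]))  # propagated
})

test_that("filter flags propagate and loosening thresholds is monotone", {
  ds <- simulate_dataset(huvec_like_config(seed = 44L, n_tcs = 150L))
  ann <- list(probes = ds$probes, probesets = ds$probesets)
  expr <- suppressWarnings(summarize_both(ds))
  dtab <- dabg(ds$intensities, ann, ds$design)
  tight <- si_thresholds(dabg_alpha = 0.01, gene_fc_cap = 4, ni_cap = 2)
  loose <- si_thresholds(dabg_alpha = 0.05, gene_fc_cap = 10, ni_cap = 5)
  f_tight <- apply_filters(expr$rma_gene, expr$rma_ps, dtab, ann, ds$design,
                           tight)
  f_loose <- apply_filters(expr$rma_gene, expr$rma_ps, dtab, ann, ds$design,
                           loose)
  expect_true(all(f_loose$pass[f_tight$pass]))   # pass set only grows
  # a probe set missing from the DABG table is a consistency error
  expect_error(apply_filters(expr$rma_gene, expr$rma_ps,
                             dtab[-1, , drop = FALSE], ann, ds$design),
               class = "exonsplice_consistency_error")
})

test_that("consensus is the sign-consistent thresholded intersection", {
  th <- si_thresholds()
  mk <- function(ids, effects, ps, pass = TRUE)
    data.frame(id = ids, effect = effects, p = ps, pass = pass)
  a <- mk(c("a", "b", "c", "d"), c(2, 1.5, -1.4, 0.2), c(1e-4, 1e-3, 1e-3, 0.5))
  b <- mk(c("a", "b", "c", "d"), c(0.1, 1.2, -2, -3), c(0.9, 1e-4, 1e-4, 1e-4))
  # a fails PLIER thresholds, d fails RMA thresholds: consensus = {b, c}
  expect_equal(consensus(a, b, th, "gene"), c("b", "c"))
  # disjoint hit sets -> empty
  expect_equal(consensus(mk("x", 2, 1e-4, TRUE), mk("y", 2, 1e-4, TRUE),
                         th, "gene"), character(0))
  # identical hit sets -> the set itself
  expect_equal(consensus(a, a, th, "gene"), c("a", "b", "c"))
  # disagreeing sign is excluded
  b2 <- b; b2$effect["b" == b2$id] <- -1.2
  expect_equal(consensus(a, b2, th, "gene"), "c")
  # probe-set level respects the filter pass flag
  a$pass <- c(TRUE, FALSE, TRUE, TRUE)
  expect_equal(consensus(a, b, th, "probeset"), "c")
})

test_that("event classification follows the positional precedence", {
  ann <- tiny_annotation()
  ps <- ann$probesets
  # add a terminal exon with several probe sets and an unannotated internal
  extra <- data.frame(
    probeset_id = c("tcC_ps1", "tcC_ps2", "tcC_ps3", "tcC_ps4"),
    tc_id = "tcC", exon_index = c(1L, 1L, 2L, 3L), n_exons = 4L,
    rank_in_exon = c(1L, 2L, 1L, 1L), n_probesets_in_exon = c(2L, 2L, 1L, 1L),
    is_constitutive = c(FALSE, FALSE, TRUE, FALSE),
    known_event = "NONE", crosshyb = FALSE,
    stringsAsFactors = FALSE)
  ann$probesets <- rbind(ps, extra)
  cl <- classify_events(c("tcA_ps2",   # known cassette
                          "tcA_ps1",   # sole probe set of first exon
                          "tcC_ps3",   # internal constitutive
                          "tcC_ps1",   # one of several on the first exon
                          "tcC_ps4"),  # internal, unflagged
                        ann)
  expect_equal(cl$category,
               c("KNOWN_AS_EVENT", "TERMINAL_UTR_PROBESET",
                 "CONSTITUTIVE_EXON", "TERMINAL_EXON_PROBESET",
                 "UNCLASSIFIED"))
  expect_equal(cl$event_type[1], "CASSETTE")
  expect_error(classify_events("nope", ann),
               class = "exonsplice_consistency_error")
})
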
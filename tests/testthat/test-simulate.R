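test_that("same seed gives byte-identical annotation and intensities", {
  cfg <- sim_config(n_tcs = 40L, seed = 9L)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)
  d <- sim_design()
  s1 <- simulate_intensities(a1, d, cfg)
  s2 <- simulate_intensities(a2, d, cfg)
  expect_identical(s1, s2)
})

test_that("event planting follows the configured mix and fractions", {
  # no events requested -> no known_event annotations
  ann0 <- simulate_annotation(sim_config(n_tcs = 10L, as_fraction = 0,
                                         seed = 2L))
  expect_true(all(ann0$probesets$known_event == "NONE"))

  # all mass on CASSETTE, every TC an event -> one cassette per TC
  cfg <- sim_config(n_tcs = 50L, as_fraction = 1,
                    event_mix = c(CASSETTE = 1), expressed_fraction = 1,
                    seed = 3L)
  ann <- simulate_annotation(cfg)
  cas <- ann$probesets[ann$probesets$known_event == "CASSETTE", ]
  expect_equal(nrow(cas), 50L)
  expect_equal(sort(unique(cas$tc_id)), sort(unique(ann$probesets$tc_id)))
  # cassettes are internal exons
  expect_true(all(cas$exon_index > 1 & cas$exon_index < cas$n_exons))

  # background probes span the documented GC range
  cfg2 <- sim_config(n_tcs = 5L, n_background_probes = 500L, seed = 4L)
  bg <- simulate_annotation(cfg2)$probes
  bg <- bg[bg$is_background, ]
  expect_equal(range(bg$gc_count), c(6L, 20L))
})

test_that("noiseless generator reproduces its own means exactly", {
  cfg <- noiseless_config(n_tcs = 5L, seed = 6L)
  ds <- simulate_dataset(cfg)
  # no noise, no effects: every probe constant across all samples
  expect_true(all(apply(ds$intensities, 1, function(x) diff(range(x))) == 0))

  # single planted gene effect Delta = 1: every probe of that TC doubles
  cfg2 <- noiseless_config(n_tcs = 5L, de_fraction = 0.2, seed = 6L)
  cfg2$de_log2fc <- 1
  ds2 <- simulate_dataset(cfg2)
  de_tc <- ds2$truth$tc$tc_id[ds2$truth$tc$true_log2fc != 0]
  expect_length(de_tc, 1L)
  ps <- ds2$probesets$probeset_id[ds2$probesets$tc_id == de_tc]
  pr <- ds2$probes$probe_id[ds2$probes$probeset_id %in% ps]
  g2 <- ds2$design$sample_id[ds2$design$group == "hypoxia"]
  g1 <- ds2$design$sample_id[ds2$design$group == "normoxia"]
  truth_fc <- ds2$truth$tc$true_log2fc[ds2$truth$tc$tc_id == de_tc]
  lfc <- rowMeans(log2(ds2$intensities[pr, g2])) -
    rowMeans(log2(ds2$intensities[pr, g1]))
  expect_equal(abs(truth_fc), 1)
  expect_equal(lfc, setNames(rep(truth_fc, length(pr)), pr),
               tolerance = 1e-12)
})

test_that("within-group spread matches the generating noise_sd", {
  # ~10,000 PM probe observations, pooled within-group SD ~ noise_sd (10%)
  cfg <- sim_config(n_tcs = 800L, exons_per_tc = c(3L, 4L),
                    probesets_per_exon = c(1L, 1L), probesets_per_exon_probs = 1,
                    de_fraction = 0, as_fraction = 0, noise_sd = 0.25,
                    bg_intercept = -Inf, bg_noise_sd = 0,
                    n_background_probes = 0L, expressed_fraction = 1,
                    seed = 8L)
  ds <- simulate_dataset(cfg)
  lmat <- log2(ds$intensities)
  g1 <- ds$design$group == unique(ds$design$group)[1]
  v <- c(apply(lmat[, g1], 1, stats::var), apply(lmat[, !g1], 1, stats::var))
  expect_gt(length(v), 2 * 2000)
  expect_equal(sqrt(mean(v)), 0.25, tolerance = 0.025)
})

test_that("planted truth follows the sign conventions", {
  cfg <- sim_config(n_tcs = 200L, as_fraction = 0.5, seed = 11L,
                    expressed_fraction = 1)
  ds <- simulate_dataset(cfg)
  tr <- ds$truth$probeset
  expect_equal(sum(tr$event_type != "NONE"), 100L)
  # unplanted probe sets have true SI 0
  expect_true(all(tr$true_si[tr$event_type == "NONE"] == 0))
  # cassette skipping in the numerator group has negative true SI
  expect_true(all(tr$true_si[tr$event_type == "CASSETTE"] ==
                    -cfg$event_delta))
  expect_true(all(tr$true_si[tr$event_type == "INTRON_RETENTION"] ==
                    cfg$event_delta))
  expect_true(all(abs(tr$true_si[tr$event_type != "NONE"]) ==
                    cfg$event_delta))
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(exons_per_tc = c(0L, 2L)),
               class = "exonsplice_config_error")
  expect_error(sim_config(de_fraction = 1.5),
               class = "exonsplice_config_error")
  expect_error(sim_config(probes_per_probeset = c(2L, 6L)),
               class = "exonsplice_config_error")
  expect_error(sim_config(bg_intercept = -Inf, n_background_probes = 10L),
               class = "exonsplice_config_error")
})
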
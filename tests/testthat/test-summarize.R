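test_that("normexp signal matches the closed-form posterior mean", {
  x <- c(50, 120, 300, 1000, 5000)
  mine <- normexp_signal(mu = 100, sigma = 10, alpha = 200, x)
  # independent implementation of the same closed form (limma)
  ref <- limma::normexp.signal(c(100, log(10), log(200)), x)
  expect_equal(mine, ref, tolerance = 1e-6)

  # strictly positive even far below background, monotone within an array
  set.seed(1)
  xs <- sort(c(1, rexp(500, 1 / 300) + rnorm(500, 100, 10)))
  out <- normexp_signal(100, 10, 200, xs)
  expect_true(all(out > 0))
  expect_true(all(diff(out) > 0))
})

test_that("background correction is monotone and errors on constant arrays", {
  set.seed(2)
  mat <- matrix(rexp(600, 1 / 400) + rnorm(600, 80, 15), 100, 6)
  mat <- pmax(mat, 1)
  dimnames(mat) <- list(sprintf("p%03d", 1:100), sprintf("s%d", 1:6))
  out <- rma_background_correct(mat)
  expect_true(all(out > 0))
  for (j in 1:6) {
    o <- order(mat[, j])
    expect_true(all(diff(out[o, j]) >= 0))
  }
  const <- matrix(5, 4, 2)
  expect_error(rma_background_correct(const),
               class = "exonsplice_config_error")
})

test_that("quantile normalization maps ranks onto mean order statistics", {
  m <- matrix(c(1, 5, 3, 7), 2, 2)
  expect_equal(unname(quantile_normalize(m)), matrix(c(2, 6, 2, 6), 2, 2))

  # identical columns unchanged
  m2 <- matrix(rep(c(4, 1, 9), 3), 3, 3)
  expect_equal(quantile_normalize(m2), m2)

  # defining property + idempotence (tie-free continuous data: with ties
  # the tie-averaging rule deliberately trades exact distribution equality
  # for a single value per tied group)
  set.seed(3)
  for (i in 1:5) {
    m3 <- matrix(rnorm(60), 20, 3)
    q1 <- quantile_normalize(m3)
    expect_equal(apply(q1, 2, sort), apply(q1, 2, sort)[, c(1, 1, 1)],
                 ignore_attr = TRUE)
    expect_equal(quantile_normalize(q1), q1)
  }
  # ties within a column receive the mean of the mapped reference values
  mt <- cbind(c(1, 1, 5, 9), c(2, 4, 6, 8))
  qt <- quantile_normalize(mt)
  ref <- rowMeans(cbind(sort(mt[, 1]), sort(mt[, 2])))
  expect_equal(qt[1:2, 1], rep(mean(ref[1:2]), 2))
  expect_equal(qt[3:4, 1], ref[3:4])
})

test_that("median polish matches the brute-force oracle", {
  # exact additive input: residuals vanish, sample effects returned exactly
  r <- c(-1, 0, 2); cvec <- c(3, 5, 1, 7)
  y <- outer(r, cvec, "+")
  expect_equal(unname(median_polish_summarize(y, max_iter = 50, tol = 1e-12)),
               cvec + median(r))

  # single probe: its own values
  expect_equal(unname(median_polish_summarize(matrix(1:4, 1))), as.numeric(1:4))

  # 100 random small matrices vs an independently run reference
  set.seed(4)
  for (i in 1:100) {
    nr <- sample(2:6, 1); nc <- sample(3:6, 1)
    y <- matrix(rnorm(nr * nc), nr, nc)
    if (i %% 3 == 0) y[sample(nr, 1), sample(nc, 1)] <- 10  # outlier cell
    mine <- median_polish_summarize(y, max_iter = 1000, tol = 1e-14)
    expect_equal(unname(mine), unname(oracle_medpolish(y)), tolerance = 1e-9)
  }
})

test_that("median polish is shift-equivariant in samples and label-blind", {
  set.seed(5)
  y <- matrix(rnorm(24), 4, 6)
  base <- median_polish_summarize(y, 100, 1e-12)
  y2 <- y; y2[, 3] <- y2[, 3] + 2.5
  shifted <- median_polish_summarize(y2, 100, 1e-12)
  # equivariance is exact only at a common fixed point; finite sweeps land
  # within a small numerical neighbourhood
  expect_equal(shifted[3] - base[3], 2.5, tolerance = 1e-3,
               ignore_attr = TRUE)
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(unname(median_polish_summarize(y[, perm], 100, 1e-12)),
               unname(base)[perm], tolerance = 1e-12)
})

test_that("rma recovers a noiseless planted gene effect exactly", {
  cfg <- noiseless_config(n_tcs = 8L, de_fraction = 1 / 8, seed = 21L)
  cfg$de_log2fc <- 1
  ds <- mirror_dataset(simulate_dataset(cfg))
  ann <- list(probes = ds$probes, probesets = ds$probesets)
  expr <- rma(ds$intensities, ann, "TRANSCRIPT_CLUSTER",
              rma_params(background = FALSE))
  de <- differential_expression(expr, ds$design)
  truth <- ds$truth$tc
  expect_equal(de$log2fc[match(truth$tc_id, de$feature_id)],
               truth$true_log2fc, tolerance = 1e-9)
  expect_equal(attr(expr, "algorithm"), "RMA")
  expect_equal(nrow(expr), length(unique(ds$probesets$tc_id)))
})

test_that("plier fits the multiplicative model and fixes the gauge", {
  # noiseless a = (1,2,4), c = (100,200): log2 c recovered up to a constant
  a <- c(1, 2, 4); conc <- c(100, 200)
  raw <- outer(a, conc)
  dimnames(raw) <- list(paste0("f1_p", 1:3), c("s1", "s2"))
  ann <- list(
    probes = data.frame(probe_id = rownames(raw), probeset_id = "f1",
                        gc_count = 12L, is_background = FALSE),
    probesets = data.frame(probeset_id = "f1", tc_id = "t1", exon_index = 1L,
                           n_exons = 1L, rank_in_exon = 1L,
                           n_probesets_in_exon = 1L, is_constitutive = FALSE,
                           known_event = "NONE", crosshyb = FALSE))
  fit <- plier_summarize(raw, ann, "PROBESET")
  d <- fit["f1", ] - log2(conc)
  expect_lt(diff(range(d)), 1e-6)

  # single-probe feature: log2 of its own intensities
  raw1 <- raw[1, , drop = FALSE]
  ann1 <- ann; ann1$probes <- ann$probes[1, ]
  expect_equal(unname(plier_summarize(raw1, ann1, "PROBESET")["f1", ]),
               unname(log2(raw[1, ])))

  # permutation of probe rows leaves the fit unchanged
  fit2 <- plier_summarize(raw[c(3, 1, 2), ], ann, "PROBESET")
  expect_equal(fit, fit2)
})

test_that("iter-PLIER drops the anti-correlated probe on reselection", {
  conc <- c(100, 150, 220, 330, 500, 750)
  good <- outer(c(1, 2, 4), conc)
  outlier <- 4 * rev(conc)   # anti-correlated by construction
  raw <- rbind(good, outlier)
  dimnames(raw) <- list(paste0("f1_p", 1:4), paste0("s", 1:6))
  ann <- list(
    probes = data.frame(probe_id = rownames(raw), probeset_id = "f1",
                        gc_count = 12L, is_background = FALSE),
    probesets = data.frame(probeset_id = "f1", tc_id = "t1", exon_index = 1L,
                           n_exons = 1L, rank_in_exon = 1L,
                           n_probesets_in_exon = 1L, is_constitutive = FALSE,
                           known_event = "NONE", crosshyb = FALSE))
  par3 <- plier_params(probes_kept = 3L, iter_rounds = 2L)
  refit <- iter_plier(raw, ann, "PROBESET", par3)
  # equals a single-round fit on the three concordant probes alone
  ann_good <- ann; ann_good$probes <- ann$probes[1:3, ]
  clean <- plier_summarize(raw[1:3, ], ann_good, "PROBESET", par3)
  expect_equal(refit, clean, tolerance = 1e-8)
  # true concentrations recovered up to gauge once the outlier is gone
  d <- refit["f1", ] - log2(conc)
  expect_lt(diff(range(d)), 1e-6)

  # with probes_kept >= n probes, selection is skipped entirely
  par_all <- plier_params(probes_kept = 11L, iter_rounds = 2L)
  expect_equal(iter_plier(raw, ann, "PROBESET", par_all),
               plier_summarize(raw, ann, "PROBESET", par_all))
})

test_that("summarizers are label-blind (column permutation equivariance)", {
  ds <- simulate_dataset(sim_config(n_tcs = 15L, seed = 13L))
  ann <- list(probes = ds$probes, probesets = ds$probesets)
  perm <- c(5, 3, 1, 6, 2, 4)
  raw_p <- ds$intensities[, perm]
  for (fun in list(function(x) rma(x, ann, "PROBESET"),
                   function(x) iter_plier(x, ann, "PROBESET"))) {
    a <- fun(ds$intensities)
    b <- fun(raw_p)
    expect_equal(unclass(b), unclass(a)[, perm], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})
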
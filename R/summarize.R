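# Probe summarization: RMA (normexp background correction, quantile
# normalization, median polish) and an Iter-PLIER-style robust multiplicative
# model. Neither claims bit-compatibility with Affymetrix Power Tools; the
# operative differences between the two algorithms (model form, probe
# reweighting) are what the dual-algorithm consensus exploits.

#' RMA parameters
#' @param bg_grid kernel-density grid size for the normexp mode estimate.
#' @param max_iter median-polish iteration cap.
#' @param tol median-polish tolerance on the relative change of the sum of
#'   absolute residuals.
#' @param background apply normexp background correction (disable for data
#'   generated without an additive background component).
#' @param normalize apply quantile normalization across arrays.
#' @return an `rma_params` list.
#' @export
rma_params <- function(bg_grid = 512L, max_iter = 10L, tol = 0.01,
                       background = TRUE, normalize = TRUE) {
  if (max_iter < 1L || tol <= 0) config_error("rma_params: positive iteration cap and tolerance required")
  structure(list(bg_grid = as.integer(bg_grid), max_iter = as.integer(max_iter),
                 tol = tol, background = isTRUE(background),
                 normalize = isTRUE(normalize)), class = "rma_params")
}

#' Iter-PLIER parameters
#' @param max_iter alternating-fit iteration cap.
#' @param tol convergence tolerance on the per-sample concentration change.
#' @param biweight_k Tukey biweight tuning constant.
#' @param iter_rounds fitting rounds; rounds after the first refit on the
#'   best-correlated probes.
#' @param probes_kept probes retained per reselection round (features with
#'   fewer probes skip selection).
#' @return a `plier_params` list.
#' @export
plier_params <- function(max_iter = 500L, tol = 1e-6, biweight_k = 4.685,
                         iter_rounds = 2L, probes_kept = 11L) {
  if (probes_kept < 1L || iter_rounds < 1L)
    config_error("plier_params: probes_kept and iter_rounds must be >= 1")
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 biweight_k = biweight_k, iter_rounds = as.integer(iter_rounds),
                 probes_kept = as.integer(probes_kept)),
            class = "plier_params")
}

# ---- normexp ----------------------------------------------------------------

#' Normexp posterior-mean signal
#'
#' Closed-form posterior mean of the true signal under the normal (background)
#' + exponential (signal) convolution model, evaluated at observed
#' intensities `x`.
#'
#' @param mu,sigma background mean and SD.
#' @param alpha exponential signal mean.
#' @param x observed intensities.
#' @return corrected (strictly positive) intensities.
#' @export
normexp_signal <- function(mu, sigma, alpha, x) {
  mu.sf <- x - mu - sigma^2 / alpha
  sig <- mu.sf + sigma^2 *
    exp(dnorm(0, mean = mu.sf, sd = sigma, log = TRUE) -
          pnorm(0, mean = mu.sf, sd = sigma, lower.tail = FALSE, log.p = TRUE))
  pmax(sig, .Machine$double.eps)
}

#' Estimate normexp parameters by the density mode
#'
#' Background mean = mode of a kernel density of the intensities; background
#' SD from the left-of-mode spread (doubled, as the left tail is assumed
#' background-only and symmetric); signal mean from the right-of-mode excess.
#'
#' @param x intensities of one array.
#' @param grid density grid size.
#' @return list(mu, sigma, alpha).
#' @export
normexp_fit_by_mode <- function(x, grid = 512L) {
  if (length(unique(x)) < 2L)
    config_error("normexp fit: array intensities are constant; cannot estimate background (check the input matrix)")
  d <- density(x, n = grid)
  mu <- d$x[which.max(d$y)]
  left <- x[x < mu]
  if (length(left) < 2L) left <- x - min(x) + mu   # pathological: no left tail
  sigma <- sqrt(sum((left - mu)^2) / max(1L, length(left) - 1L)) * sqrt(2)
  right <- x[x > mu]
  alpha <- if (length(right)) 1 / mean(right - mu) else 1 / mean(abs(x - mu))
  alpha <- max(alpha, .Machine$double.eps)
  list(mu = mu, sigma = max(sigma, .Machine$double.eps), alpha = 1 / alpha)
}

#' RMA background correction (normexp by mode)
#'
#' Per-array normexp posterior-mean transform; strictly positive and, within
#' an array, strictly increasing in the input.
#'
#' @param mat probes x samples matrix of strictly positive intensities.
#' @param params an [rma_params()].
#' @return corrected matrix, same shape.
#' @export
rma_background_correct <- function(mat, params = rma_params()) {
  if (any(mat <= 0)) format_error("background correction: intensities must be > 0")
  out <- mat
  for (j in seq_len(ncol(mat))) {
    est <- normexp_fit_by_mode(mat[, j], params$bg_grid)
    out[, j] <- normexp_signal(est$mu, est$sigma, est$alpha, mat[, j])
  }
  out
}

#' Quantile normalization
#'
#' Maps every column onto the cross-column mean of order statistics; ties
#' within a column receive the mean of the reference values their ranks span.
#' Idempotent, and exactly the identity when all columns already share one
#' value multiset.
#'
#' @param mat numeric matrix with >= 2 columns.
#' @return normalized matrix, same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  if (ncol(mat) < 2L) config_error("quantile_normalize: >= 2 columns required")
  ref <- rowMeans(apply(mat, 2L, sort, method = "radix"))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    v <- numeric(length(x))
    v[order(x, method = "radix")] <- ref
    # average the mapped reference values within tie groups
    out[, j] <- stats::ave(v, match(x, x), FUN = mean)
  }
  out
}

#' Median-polish summarization of one feature
#'
#' Fits `log2 y_ij ~ m + probe_i + sample_j` by alternating median sweeps
#' (rows first, then columns) and returns the per-sample fitted expression
#' `m + sample_j`. A single-probe feature returns its own values.
#'
#' @param log2_mat probes x samples log2 matrix for one feature.
#' @param max_iter,tol iteration cap and relative tolerance on the sum of
#'   absolute residual change.
#' @return numeric vector of per-sample log2 expression.
#' @export
median_polish_summarize <- function(log2_mat, max_iter = 10L, tol = 0.01) {
  log2_mat <- rbind(log2_mat)
  res <- cpp_medpolish_groups(log2_mat, rep(0L, nrow(log2_mat)), 1L,
                              as.integer(max_iter), tol)
  setNames(res[1L, ], colnames(log2_mat))
}

# probe -> feature map for a summarization level
.feature_map <- function(annotation, level) {
  level <- match.arg(level, c("PROBESET", "TRANSCRIPT_CLUSTER"))
  pm <- annotation$probes[!annotation$probes$is_background, , drop = FALSE]
  feat <- if (level == "PROBESET") pm$probeset_id else
    annotation$probesets$tc_id[match(pm$probeset_id,
                                     annotation$probesets$probeset_id)]
  all_feats <- if (level == "PROBESET") annotation$probesets$probeset_id else
    unique(annotation$probesets$tc_id)
  used <- sort(unique(feat))
  dropped <- setdiff(all_feats, used)
  if (length(dropped))
    warning(sprintf("%d %s feature(s) with zero probes excluded", length(dropped),
                    tolower(level)), call. = FALSE)
  list(probe_ids = pm$probe_id, feature = feat, features = used,
       index0 = match(feat, used) - 1L)
}

#' RMA summarization
#'
#' Background correct (normexp), quantile normalize, log2, median polish per
#' feature at the requested level.
#'
#' @param raw probes x samples matrix of raw linear intensities (background
#'   probes, if present, are ignored).
#' @param annotation list(probes, probesets).
#' @param level "PROBESET" or "TRANSCRIPT_CLUSTER".
#' @param params an [rma_params()].
#' @return log2 expression matrix tagged with level and algorithm "RMA".
#' @export
rma <- function(raw, annotation, level = c("PROBESET", "TRANSCRIPT_CLUSTER"),
                params = rma_params()) {
  level <- match.arg(level)
  fm <- .feature_map(annotation, level)
  mat <- raw[fm$probe_ids, , drop = FALSE]
  if (params$background) mat <- rma_background_correct(mat, params)
  if (params$normalize) mat <- quantile_normalize(mat)
  lmat <- log2(mat)
  res <- cpp_medpolish_groups(lmat, fm$index0, length(fm$features),
                              params$max_iter, params$tol)
  dimnames(res) <- list(fm$features, colnames(raw))
  expression_matrix(res, level, "RMA")
}

.plier_run <- function(raw, annotation, level, params, iter_rounds) {
  fm <- .feature_map(annotation, level)
  lmat <- log2(raw[fm$probe_ids, , drop = FALSE])
  res <- cpp_plier_groups(lmat, fm$index0, length(fm$features),
                          params$max_iter, params$tol, params$biweight_k,
                          iter_rounds, params$probes_kept)
  if (!all(res$converged))
    warning(sprintf("PLIER fit: %d feature(s) hit the iteration cap; last iterate returned",
                    sum(!res$converged)), call. = FALSE)
  m <- res$conc
  dimnames(m) <- list(fm$features, colnames(raw))
  expression_matrix(m, level, "ITERPLIER")
}

#' PLIER-style summarization (single round)
#'
#' Robust alternating fit of the multiplicative model
#' `intensity_ij ~ a_i * c_j` on the log2 scale with Tukey biweight weights;
#' identifiability is fixed by constraining the geometric mean of the probe
#' affinities `a_i` to 1. Returns log2 `c_j`.
#'
#' @inheritParams rma
#' @param params a [plier_params()].
#' @return log2 expression matrix tagged "ITERPLIER".
#' @export
plier_summarize <- function(raw, annotation,
                            level = c("PROBESET", "TRANSCRIPT_CLUSTER"),
                            params = plier_params()) {
  .plier_run(raw, annotation, match.arg(level), params, 1L)
}

#' Iter-PLIER summarization
#'
#' Round 1 fits all probes of a feature; each later round retains the
#' `probes_kept` probes whose log2 intensities correlate best with the
#' current fitted concentration, then refits. Features with at most
#' `probes_kept` probes skip selection.
#'
#' @inheritParams plier_summarize
#' @return log2 expression matrix tagged "ITERPLIER".
#' @export
iter_plier <- function(raw, annotation,
                       level = c("PROBESET", "TRANSCRIPT_CLUSTER"),
                       params = plier_params()) {
  .plier_run(raw, annotation, match.arg(level), params, params$iter_rounds)
}
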
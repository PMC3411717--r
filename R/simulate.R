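# Probe-level intensity simulator. Generative model (log2 scale), for PM
# probe i in probe set p of transcript cluster t, sample s in group g:
#
#   mu = beta_t + Delta_t * 1[g = group2] + a_i + b_p + delta_p * 1[g = group2] + eps
#   intensity = 2^mu + B,   B = 2^(bg_intercept + bg_gc_slope * gc + eps_b)
#
# with eps ~ N(0, noise_sd), eps_b ~ N(0, bg_noise_sd). Background probes
# receive B only. delta_p != 0 only for the single planted event of an
# event-carrying TC; b_p is a baseline offset used only by the planted
# intron-retention probe set (-1, keeping it detectable in both groups while
# its inclusion shift delta_p = +event_delta carries the splicing signal).

#' Simulation configuration
#'
#' Parameters of the synthetic exon-array world. Defaults are the desk-scale
#' "huvec-like" fixture: 2000 transcript clusters, 3 vs 3 arrays, 5% of genes
#' differentially expressed at |log2FC| = 1.5, 2% of genes carrying one
#' planted splicing event with a 1.0 log2 inclusion shift, residual noise
#' 0.25 log2 units.
#'
#' @param n_tcs number of transcript clusters.
#' @param exons_per_tc integer range (min, max) of exons per transcript.
#' @param probesets_per_exon integer range of probe sets per exon; counts are
#'   drawn with weights `probesets_per_exon_probs` (mostly 1, occasionally
#'   2-3 so terminal exons with several probe sets exist).
#' @param probesets_per_exon_probs sampling weights over the range above.
#' @param probes_per_probeset integer range of probes per probe set
#'   (within 1..4).
#' @param n_background_probes size of the antigenomic background pool.
#' @param expressed_fraction fraction of transcript clusters expressed in the
#'   assayed condition; unexpressed clusters emit background signal only
#'   (they are what the DABG filters exist to remove, and they give the
#'   normexp background estimator its background mode). Planted effects go
#'   on expressed clusters.
#' @param de_fraction fraction of TCs with a gene-level expression effect.
#' @param de_log2fc magnitude of the gene effect (log2 units).
#' @param de_up_fraction fraction of gene effects that are up (group2 high).
#' @param as_fraction fraction of TCs carrying one planted splicing event.
#' @param event_mix named weights over CASSETTE, INTRON_RETENTION, APA, APS,
#'   TERMINAL_UTR.
#' @param event_delta probe-set-level log2 inclusion shift of planted events.
#' @param affinity_sd probe affinity spread (log2).
#' @param noise_sd per-observation residual SD (log2).
#' @param bg_intercept,bg_gc_slope background model coefficients (log2 scale,
#'   slope per GC unit); `bg_intercept = -Inf` disables the additive
#'   background entirely (requires `n_background_probes = 0`).
#' @param bg_noise_sd background residual SD (log2).
#' @param constitutive_prob probability that an internal, event-free probe
#'   set is annotated constitutive.
#' @param crosshyb_fraction fraction of event-free probe sets flagged as
#'   cross-hybridization risks.
#' @param seed integer RNG seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_tcs = 2000L,
                       exons_per_tc = c(4L, 10L),
                       probesets_per_exon = c(1L, 3L),
                       probesets_per_exon_probs = c(0.85, 0.10, 0.05),
                       probes_per_probeset = c(2L, 4L),
                       n_background_probes = 1000L,
                       expressed_fraction = 0.65,
                       de_fraction = 0.05,
                       de_log2fc = 1.5,
                       de_up_fraction = 0.3,
                       as_fraction = 0.02,
                       event_mix = c(CASSETTE = 0.4, INTRON_RETENTION = 0.1,
                                     APA = 0.15, APS = 0.15,
                                     TERMINAL_UTR = 0.2),
                       event_delta = 1.0,
                       affinity_sd = 0.25,
                       noise_sd = 0.25,
                       bg_intercept = 3,
                       bg_gc_slope = 0.1,
                       bg_noise_sd = 0.25,
                       constitutive_prob = 0.8,
                       crosshyb_fraction = 0.01,
                       seed = 1L) {
  cfg <- list(n_tcs = as.integer(n_tcs), exons_per_tc = as.integer(exons_per_tc),
              probesets_per_exon = as.integer(probesets_per_exon),
              probesets_per_exon_probs = probesets_per_exon_probs,
              probes_per_probeset = as.integer(probes_per_probeset),
              n_background_probes = as.integer(n_background_probes),
              expressed_fraction = expressed_fraction,
              de_fraction = de_fraction, de_log2fc = de_log2fc,
              de_up_fraction = de_up_fraction, as_fraction = as_fraction,
              event_mix = event_mix, event_delta = event_delta,
              affinity_sd = affinity_sd, noise_sd = noise_sd,
              bg_intercept = bg_intercept, bg_gc_slope = bg_gc_slope,
              bg_noise_sd = bg_noise_sd,
              constitutive_prob = constitutive_prob,
              crosshyb_fraction = crosshyb_fraction, seed = as.integer(seed))
  fr <- c(cfg$de_fraction, cfg$as_fraction, cfg$de_up_fraction,
          cfg$crosshyb_fraction, cfg$constitutive_prob,
          cfg$expressed_fraction)
  if (any(fr < 0 | fr > 1)) config_error("sim_config: fractions must be in [0, 1]")
  if (any(c(cfg$affinity_sd, cfg$noise_sd, cfg$bg_noise_sd) < 0))
    config_error("sim_config: standard deviations must be >= 0")
  if (cfg$n_tcs < 1L) config_error("sim_config: n_tcs must be >= 1")
  if (cfg$exons_per_tc[1] < 1L || diff(cfg$exons_per_tc) < 0)
    config_error("sim_config: degenerate exons_per_tc range")
  if (cfg$as_fraction > 0 && cfg$exons_per_tc[1] < 3L)
    config_error("sim_config: splicing events need >= 3 exons per transcript")
  if (cfg$probes_per_probeset[1] < 1L || cfg$probes_per_probeset[2] > 4L)
    config_error("sim_config: probes_per_probeset must lie within 1..4")
  ps_vals <- seq(cfg$probesets_per_exon[1], cfg$probesets_per_exon[2])
  if (length(cfg$probesets_per_exon_probs) != length(ps_vals))
    config_error("sim_config: probesets_per_exon_probs length mismatch")
  if (abs(sum(cfg$event_mix)) == 0) config_error("sim_config: empty event_mix")
  bad <- setdiff(names(cfg$event_mix),
                 c("CASSETTE", "INTRON_RETENTION", "APA", "APS", "TERMINAL_UTR"))
  if (length(bad)) config_error(sprintf("sim_config: unknown event type '%s'", bad[1]))
  if (is.infinite(cfg$bg_intercept) && cfg$n_background_probes > 0L)
    config_error("sim_config: background disabled but n_background_probes > 0")
  if (is.infinite(cfg$bg_intercept) && cfg$expressed_fraction < 1)
    config_error("sim_config: unexpressed TCs need the background model enabled")
  class(cfg) <- "sim_config"
  cfg
}

# draw n integers uniformly (or with `prob`) from an inclusive range,
# immune to sample()'s scalar expansion when the range collapses
.sample_range <- function(range, n, prob = NULL) {
  vals <- seq(range[1], range[2])
  if (length(vals) == 1L) rep(vals, n)
  else sample(vals, n, replace = TRUE, prob = prob)
}

#' The default "huvec-like" fixture configuration
#' @param seed integer RNG seed.
#' @param ... overrides passed on to [sim_config()].
#' @return a `sim_config`.
#' @export
huvec_like_config <- function(seed = 1L, ...) {
  args <- list(n_tcs = 2000L, de_fraction = 0.05, de_log2fc = 1.5,
               as_fraction = 0.02, event_delta = 1.0, noise_sd = 0.25,
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

#' A two-group replicate design
#' @param n_per_group samples per group (>= 2).
#' @param groups two condition labels; the second is the contrast numerator.
#' @return a validated design data.frame.
#' @export
sim_design <- function(n_per_group = 3L, groups = c("normoxia", "hypoxia")) {
  validate_design(data.frame(
    sample_id = paste0(rep(groups, each = n_per_group), "_",
                       rep(seq_len(n_per_group), 2L)),
    group = rep(groups, each = n_per_group),
    replicate = rep(seq_len(n_per_group), 2L),
    stringsAsFactors = FALSE))
}

#' Simulate the probe / probe-set / transcript-cluster annotation
#'
#' Builds a hierarchy satisfying every annotation invariant and plants one
#' splicing event per selected transcript cluster. Known event types are
#' recorded in `known_event`; TERMINAL_UTR plantings are marked only by
#' their position (single probe set of a first/last exon) and are carried in
#' the `planted_events` attribute for the intensity generator.
#'
#' @param config a [sim_config()].
#' @return list(probes, probesets); `probesets` carries a `planted_events`
#'   attribute (tc_id, probeset_id, event_type).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_tcs <- config$n_tcs
  tc_ids <- sprintf("tc%05d", seq_len(n_tcs))
  n_exons <- .sample_range(config$exons_per_tc, n_tcs)

  ex_tc <- rep(seq_len(n_tcs), n_exons)
  ex_idx <- sequence(n_exons)
  nps <- .sample_range(config$probesets_per_exon, length(ex_tc),
                       prob = config$probesets_per_exon_probs)

  ps_tc <- rep(ex_tc, nps)
  ps_exon <- rep(ex_idx, nps)
  ps_rank <- sequence(nps)
  ps_nps <- rep(nps, nps)
  ps_num <- as.integer(stats::ave(ps_tc, ps_tc, FUN = seq_along))
  ps_id <- sprintf("%s_ps%02d", tc_ids[ps_tc], ps_num)
  ps_nexons <- n_exons[ps_tc]
  known_event <- rep("NONE", length(ps_id))

  # expressed status; planted events are restricted to expressed TCs
  expressed <- runif(n_tcs) < config$expressed_fraction

  # plant one event per selected TC
  as_n <- round(config$as_fraction * n_tcs)
  events <- data.frame(tc_id = character(0), probeset_id = character(0),
                       event_type = character(0), stringsAsFactors = FALSE)
  ir_rows <- NULL
  if (as_n > 0) {
    if (sum(expressed) < as_n)
      config_error("simulate_annotation: fewer expressed TCs than planted events")
    ev_tc <- which(expressed)[sample.int(sum(expressed), as_n)]
    mix <- config$event_mix[config$event_mix > 0]
    ev_type <- sample(names(mix), as_n, replace = TRUE, prob = mix)
    ev_ps <- character(as_n)
    for (j in seq_len(as_n)) {
      t <- ev_tc[j]
      idx <- which(ps_tc == t)
      first_ps <- idx[ps_exon[idx] == 1L & ps_rank[idx] == 1L]
      last_exon <- ps_nexons[idx][1L]
      last_idx <- idx[ps_exon[idx] == last_exon]
      last_ps <- last_idx[which.max(ps_rank[last_idx])]
      internal <- idx[ps_exon[idx] > 1L & ps_exon[idx] < last_exon]
      target <- switch(ev_type[j],
        CASSETTE = {
          solo <- internal[ps_nps[internal] == 1L]
          if (length(solo)) solo[sample.int(length(solo), 1L)]
          else internal[sample.int(length(internal), 1L)]
        },
        INTRON_RETENTION = internal[sample.int(length(internal), 1L)],
        APA = last_ps,
        APS = first_ps,
        TERMINAL_UTR = if (runif(1) < 0.5) first_ps else last_ps)
      if (ev_type[j] == "INTRON_RETENTION") {
        # append a probe set measuring the retained intron, placed as an
        # extra probe set of the chosen internal exon
        ir_rows <- rbind(ir_rows, data.frame(
          tc = t, exon = ps_exon[target], stringsAsFactors = FALSE))
        ev_ps[j] <- sprintf("%s_ir%02d", tc_ids[t], ps_exon[target])
      } else {
        if (ev_type[j] != "TERMINAL_UTR") known_event[target] <- ev_type[j]
        ev_ps[j] <- ps_id[target]
      }
    }
    events <- data.frame(tc_id = tc_ids[ev_tc], probeset_id = ev_ps,
                         event_type = ev_type, stringsAsFactors = FALSE)
  }

  probesets <- data.frame(
    probeset_id = ps_id, tc_id = tc_ids[ps_tc],
    exon_index = ps_exon, n_exons = ps_nexons,
    rank_in_exon = ps_rank, n_probesets_in_exon = ps_nps,
    is_constitutive = FALSE, known_event = known_event, crosshyb = FALSE,
    stringsAsFactors = FALSE)

  if (!is.null(ir_rows)) {
    for (j in seq_len(nrow(ir_rows))) {
      sib <- probesets$tc_id == tc_ids[ir_rows$tc[j]] &
        probesets$exon_index == ir_rows$exon[j]
      newn <- sum(sib) + 1L
      probesets$n_probesets_in_exon[sib] <- newn
      probesets <- rbind(probesets, data.frame(
        probeset_id = sprintf("%s_ir%02d", tc_ids[ir_rows$tc[j]],
                              ir_rows$exon[j]),
        tc_id = tc_ids[ir_rows$tc[j]], exon_index = ir_rows$exon[j],
        n_exons = n_exons[ir_rows$tc[j]], rank_in_exon = newn,
        n_probesets_in_exon = newn, is_constitutive = FALSE,
        known_event = "INTRON_RETENTION", crosshyb = FALSE,
        stringsAsFactors = FALSE))
    }
  }

  is_event_ps <- probesets$probeset_id %in% events$probeset_id
  internal_ps <- probesets$exon_index > 1L &
    probesets$exon_index < probesets$n_exons
  probesets$is_constitutive <- internal_ps & !is_event_ps &
    runif(nrow(probesets)) < config$constitutive_prob
  probesets$crosshyb <- !is_event_ps &
    runif(nrow(probesets)) < config$crosshyb_fraction

  # probes: PM per probe set, then the antigenomic background pool
  npr <- .sample_range(config$probes_per_probeset, nrow(probesets))
  pr_ps <- rep(seq_len(nrow(probesets)), npr)
  probe_id <- sprintf("%s_p%d", probesets$probeset_id[pr_ps], sequence(npr))
  gc_pm <- pmin(24L, pmax(1L, rbinom(length(probe_id), 25L, 0.5)))
  probes <- data.frame(probe_id = probe_id,
                       probeset_id = probesets$probeset_id[pr_ps],
                       gc_count = gc_pm, is_background = FALSE,
                       stringsAsFactors = FALSE)
  if (config$n_background_probes > 0L) {
    probes <- rbind(probes, data.frame(
      probe_id = sprintf("bg%05d", seq_len(config$n_background_probes)),
      probeset_id = NA_character_,
      gc_count = sample(6:20, config$n_background_probes, replace = TRUE),
      is_background = TRUE, stringsAsFactors = FALSE))
  }

  probesets <- validate_probesets(probesets)
  probes <- validate_probes(probes, probesets)
  attr(probesets, "planted_events") <- events
  attr(probesets, "expressed_tcs") <- tc_ids[expressed]
  list(probes = probes, probesets = probesets)
}

#' Simulate probe intensities with a ground-truth ledger
#'
#' Draws linear-scale intensities under the generative model documented in
#' the package vignette: log-normal signal with per-TC baselines, planted
#' gene effects `Delta_t`, probe affinities, planted inclusion shifts
#' `delta_p`, plus an additive GC-dependent background; background probes
#' receive background only.
#'
#' @param annotation list(probes, probesets) from [simulate_annotation()].
#' @param design validated two-group design; the second group is the
#'   contrast numerator (receives `Delta_t` and `delta_p`).
#' @param config the [sim_config()] used to build the annotation.
#' @return list(intensities = probes x samples matrix,
#'   truth = list(tc, probeset, seed)); `truth$tc` holds the true gene
#'   log2FC, `truth$probeset` the planted event type and true SI.
#' @export
simulate_intensities <- function(annotation, design, config) {
  stopifnot(inherits(config, "sim_config"))
  design <- validate_design(design)
  probes <- annotation$probes
  probesets <- annotation$probesets
  if (!all(probes$probeset_id[!probes$is_background] %in% probesets$probeset_id))
    consistency_error("simulate_intensities: annotation tables inconsistent")

  seed2 <- if (config$seed >= 2147483646L) 1L else config$seed + 1L
  set.seed(seed2)
  groups <- unique(design$group)
  g2 <- as.numeric(design$group == groups[2L])
  n_s <- nrow(design)

  tc_ids <- unique(probesets$tc_id)
  n_tcs <- length(tc_ids)
  beta <- runif(n_tcs, 7, 12)

  expressed_ids <- attr(probesets, "expressed_tcs")
  expressed <- if (is.null(expressed_ids)) rep(TRUE, n_tcs) else
    tc_ids %in% expressed_ids

  de_n <- round(config$de_fraction * n_tcs)
  Delta <- numeric(n_tcs)
  if (de_n > 0) {
    if (sum(expressed) < de_n)
      config_error("simulate_intensities: fewer expressed TCs than planted gene effects")
    de_idx <- which(expressed)[sample.int(sum(expressed), de_n)]
    sgn <- ifelse(runif(de_n) < config$de_up_fraction, 1, -1)
    Delta[de_idx] <- sgn * config$de_log2fc
  }

  events <- attr(probesets, "planted_events")
  if (is.null(events)) {
    ke <- probesets$known_event != "NONE"
    events <- data.frame(tc_id = probesets$tc_id[ke],
                         probeset_id = probesets$probeset_id[ke],
                         event_type = probesets$known_event[ke],
                         stringsAsFactors = FALSE)
  }
  delta <- setNames(numeric(nrow(probesets)), probesets$probeset_id)
  offset <- setNames(numeric(nrow(probesets)), probesets$probeset_id)
  if (nrow(events)) {
    for (j in seq_len(nrow(events))) {
      d <- switch(events$event_type[j],
                  CASSETTE = -config$event_delta,
                  INTRON_RETENTION = config$event_delta,
                  config$event_delta * sample(c(-1, 1), 1L))
      delta[events$probeset_id[j]] <- d
      if (events$event_type[j] == "INTRON_RETENTION")
        offset[events$probeset_id[j]] <- -1
    }
  }

  pm <- probes[!probes$is_background, , drop = FALSE]
  ps_of <- match(pm$probeset_id, probesets$probeset_id)
  tc_of <- match(probesets$tc_id[ps_of], tc_ids)
  a <- rnorm(nrow(pm), 0, config$affinity_sd)

  base <- beta[tc_of] + a + offset[ps_of]
  g2add <- Delta[tc_of] + delta[ps_of]
  eps <- matrix(rnorm(nrow(pm) * n_s, 0, config$noise_sd), nrow(pm), n_s)
  mu <- matrix(base, nrow(pm), n_s) + outer(g2add, g2) + eps
  signal <- 2^mu
  signal[!expressed[tc_of], ] <- 0   # unexpressed TCs emit background only

  n_all <- nrow(probes)
  intens <- matrix(0, n_all, n_s,
                   dimnames = list(probes$probe_id, design$sample_id))
  if (is.finite(config$bg_intercept)) {
    eb <- matrix(rnorm(n_all * n_s, 0, config$bg_noise_sd), n_all, n_s)
    B <- 2^(config$bg_intercept + config$bg_gc_slope * probes$gc_count + eb)
    intens[] <- B
  }
  intens[!probes$is_background, ] <- intens[!probes$is_background, ] + signal
  if (any(intens <= 0))
    consistency_error("simulate_intensities: non-positive intensity generated")

  truth <- list(
    tc = data.frame(tc_id = tc_ids, true_log2fc = Delta,
                    stringsAsFactors = FALSE),
    probeset = data.frame(
      probeset_id = probesets$probeset_id,
      event_type = ifelse(probesets$probeset_id %in% events$probeset_id,
                          events$event_type[match(probesets$probeset_id,
                                                  events$probeset_id)],
                          "NONE"),
      true_si = unname(delta), stringsAsFactors = FALSE),
    seed = config$seed)
  list(intensities = intens, truth = truth)
}

#' Simulate a full dataset (annotation, design, intensities, truth)
#' @param config a [sim_config()].
#' @param design optional design; defaults to the 3 vs 3 [sim_design()].
#' @return list(probes, probesets, design, intensities, truth).
#' @export
simulate_dataset <- function(config, design = sim_design()) {
  ann <- simulate_annotation(config)
  sim <- simulate_intensities(ann, design, config)
  list(probes = ann$probes, probesets = ann$probesets, design = design,
       intensities = sim$intensities, truth = sim$truth)
}

#' Write the simulated truth ledger
#' @param truth the `truth` element of [simulate_intensities()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  tc <- truth$tc
  ps <- truth$probeset
  df <- rbind(
    data.frame(feature_id = tc$tc_id, level = "TRANSCRIPT_CLUSTER",
               event_type = "NONE", true_effect = tc$true_log2fc,
               stringsAsFactors = FALSE),
    data.frame(feature_id = ps$probeset_id, level = "PROBESET",
               event_type = ps$event_type, true_effect = ps$true_si,
               stringsAsFactors = FALSE))
  .write_tsv(df, path)
}
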
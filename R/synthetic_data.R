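#' Synthetic ERP component description
#'
#' One stereotyped ERP component: a Gaussian-in-time waveform (truncated at
#' three standard deviations, so components have compact support) projected
#' onto the scalp through a smooth topography centered on a canonical 10-10
#' site.  Condition multipliers apply only to components flagged
#' `modulated` (the late positive potential in the default set).
#'
#' @param name component label.
#' @param latency_ms peak latency in ms post-onset.
#' @param sigma_ms temporal Gaussian width (SD) in ms.
#' @param amplitude base amplitude (signed).
#' @param center 10-10 label of the topography center (e.g. "Oz", "Pz").
#' @param modulated does the condition multiplier scale this component?
#' @return a component description list.
#' @export
erp_component <- function(name, latency_ms, sigma_ms, amplitude, center,
                          modulated = FALSE) {
  list(name = name, latency_ms = latency_ms, sigma_ms = sigma_ms,
       amplitude = amplitude, center = center, modulated = modulated)
}

default_components <- function() list(
  erp_component("P100", 100, 15, 1.0, "Oz"),
  erp_component("N200", 200, 20, -0.8, "Oz"),
  erp_component("P300", 300, 30, 1.2, "Pz"),
  erp_component("LPP", 600, 120, 1.0, "Pz", modulated = TRUE))

#' Synthetic ERP dataset specification
#'
#' Parameterizes the ground-truth simulator: epoched trials built as a sum of
#' Gaussian-windowed components (P100/N200/P300/LPP by default) times smooth
#' per-subject topographies, an LPP condition effect (emotional > neutral),
#' per-subject amplitude/latency jitter, and white observation noise.  The
#' desk-scale defaults (6 subjects, 32 channels, 150 samples at 100 Hz) keep
#' every downstream stage trainable on one CPU in minutes; the full-scale
#' geometry (88/129/750 at 500 Hz) is one configuration away.
#'
#' @param n_subjects,n_channels,n_samples,fs dataset geometry; `n_samples`
#'   must equal `round((post - t0) * fs)` for the 1.5 s epoch.
#' @param t0 epoch start in seconds (default -0.1).
#' @param components list of [erp_component()] entries; latencies must fall
#'   inside the epoch.
#' @param condition_effects named multipliers for the modulated component
#'   per condition.  The defaults put pleasant and unpleasant above neutral
#'   (the V-pattern), with unpleasant slightly above pleasant as typically
#'   observed, which also keeps the three categories mutually separable.
#' @param subject_effect_sd per-subject log-amplitude jitter SD; latency
#'   jitter uses `50 * subject_effect_sd` ms.
#' @param subject_topo_jitter SD of the per-subject displacement of each
#'   component's topography center (unit-sphere chord units).
#' @param topo_spread topography Gaussian width (chord units).
#' @param noise_sd white noise SD added to every sample.
#' @param seed integer seed; all draws derive from it.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 6L, n_channels = 32L,
                           n_samples = 150L, fs = 100,
                           t0 = -0.1,
                           components = default_components(),
                           condition_effects = c(pleasant = 1.5,
                                                 neutral = 1.0,
                                                 unpleasant = 1.8),
                           subject_effect_sd = 0.1,
                           subject_topo_jitter = 0.15,
                           topo_spread = 1.0,
                           noise_sd = 0.15,
                           seed = 1L) {
  assert_that(all(condition_effects > 0), "spec_error",
              "condition multipliers must be positive")
  t_end <- t0 + n_samples / fs
  for (cmp in components)
    assert_that(cmp$latency_ms / 1000 > t0 && cmp$latency_ms / 1000 < t_end,
                "spec_error", "component '%s' latency %g ms outside epoch",
                cmp$name, cmp$latency_ms)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples), fs = fs, t0 = t0,
                 components = components,
                 condition_effects = condition_effects,
                 subject_effect_sd = subject_effect_sd,
                 subject_topo_jitter = subject_topo_jitter,
                 topo_spread = topo_spread,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

spec_montage <- function(spec) {
  if (spec$n_channels == 129L) hydrocel_montage()
  else synthetic_montage(spec$n_channels)
}

# All deterministic per-(component, subject) structure: topography weights,
# amplitude factors, latency shifts.  Consumes only the "templates" child
# seed, so noise draws elsewhere cannot perturb it.
synth_templates <- function(spec, montage = spec_montage(spec)) {
  tt <- ten_ten_positions()
  pos <- montage$positions3d
  ncomp <- length(spec$components)
  with_seed(child_seed(spec$seed, "templates"), {
    topo <- array(NA_real_, c(ncomp, spec$n_subjects, spec$n_channels))
    ampf <- matrix(NA_real_, ncomp, spec$n_subjects)
    latshift <- matrix(NA_real_, ncomp, spec$n_subjects)
    for (ci in seq_len(ncomp)) {
      cmp <- spec$components[[ci]]
      center0 <- tt[cmp$center, ]
      for (s in seq_len(spec$n_subjects)) {
        ctr <- center0 + stats::rnorm(3, sd = spec$subject_topo_jitter)
        ctr <- ctr / sqrt(sum(ctr^2))
        d2 <- colSums((t(pos) - ctr)^2)
        topo[ci, s, ] <- exp(-d2 / (2 * spec$topo_spread^2))
        ampf[ci, s] <- exp(stats::rnorm(1, sd = spec$subject_effect_sd))
        latshift[ci, s] <- stats::rnorm(1, sd = 50 * spec$subject_effect_sd)
      }
    }
    list(topo = topo, ampf = ampf, latshift = latshift)
  })
}

# Truncated temporal Gaussian sampled on the epoch time base (ms).
component_waveform <- function(cmp, latshift_ms, spec) {
  t_ms <- (spec$t0 + (seq_len(spec$n_samples) - 1) / spec$fs) * 1000
  d <- t_ms - (cmp$latency_ms + latshift_ms)
  w <- exp(-d^2 / (2 * cmp$sigma_ms^2))
  w[abs(d) > 3 * cmp$sigma_ms] <- 0
  w
}

# Noiseless channel x samples matrix for one (subject, condition).
synth_clean_epoch <- function(spec, tpl, subject, condition,
                              only_component = NULL) {
  out <- matrix(0, spec$n_channels, spec$n_samples)
  for (ci in seq_along(spec$components)) {
    cmp <- spec$components[[ci]]
    if (!is.null(only_component) && cmp$name != only_component) next
    mult <- if (cmp$modulated)
      unname(spec$condition_effects[condition] %||% 1) else 1
    wave <- component_waveform(cmp, tpl$latshift[ci, subject], spec)
    out <- out + (cmp$amplitude * tpl$ampf[ci, subject] * mult) *
      outer(tpl$topo[ci, subject, ], wave)
  }
  out
}

#' Simulate an ERP dataset with known ground truth
#'
#' Generates one epoch per (subject, stimulus), subject-major: each epoch is
#' the sum of the spec's component templates (scaled by the subject factor
#' and, for modulated components, the condition multiplier) plus white
#' noise.  Deterministic for a fixed spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @param stimuli data.frame with columns `stimulus_id` and `condition`.
#' @return an `erp_dataset` of `n_subjects * nrow(stimuli)` epochs.
#' @export
simulate_dataset <- function(spec, stimuli) {
  stopifnot(inherits(spec, "synthetic_spec"))
  stimuli <- as.data.frame(stimuli)
  assert_that(nrow(stimuli) >= 1, "spec_error", "need at least one stimulus")
  assert_that(all(c("stimulus_id", "condition") %in% names(stimuli)),
              "spec_error", "stimuli needs stimulus_id and condition columns")
  mont <- spec_montage(spec)
  tpl <- synth_templates(spec, mont)
  nstim <- nrow(stimuli)
  n <- spec$n_subjects * nstim
  data <- array(NA_real_, c(n, spec$n_channels, spec$n_samples))
  meta <- data.frame(subject_id = integer(n), condition = character(n),
                     stimulus_id = character(n), modality = "synthetic",
                     stringsAsFactors = FALSE)
  # clean per-(subject, condition) fields are reused across stimuli
  conds <- unique(stimuli$condition)
  clean <- list()
  for (s in seq_len(spec$n_subjects))
    for (cond in conds)
      clean[[paste(s, cond)]] <- synth_clean_epoch(spec, tpl, s, cond)
  with_seed(child_seed(spec$seed, "noise"), {
    i <- 0L
    for (s in seq_len(spec$n_subjects)) {
      for (k in seq_len(nstim)) {
        i <- i + 1L
        e <- clean[[paste(s, stimuli$condition[k])]]
        if (spec$noise_sd > 0)
          e <- e + matrix(stats::rnorm(length(e), sd = spec$noise_sd),
                          nrow(e), ncol(e))
        data[i, , ] <- e
        meta$subject_id[i] <- s
        meta$condition[i] <- stimuli$condition[k]
        meta$stimulus_id[i] <- stimuli$stimulus_id[k]
      }
    }
  })
  reg <- subject_registry(sprintf("S%02d", seq_len(spec$n_subjects)))
  erp_dataset(data, meta, spec$fs, spec$t0, mont, reg,
              list(generator = "erpsynth::simulate_dataset",
                   seed = spec$seed, noise_sd = spec$noise_sd))
}

#' Analytic expected LPP score per subject and condition
#'
#' The noiseless mean amplitude of the simulated signal over the late
#' positive potential window at each subject's LPP-topography peak channel —
#' the oracle used by parameter-recovery tests.  `score` includes every
#' component active in the window (with the default compact-support
#' templates only the LPP reaches it); `lpp_only` is the LPP component's own
#' contribution.
#'
#' @param spec a [synthetic_spec()].
#' @param window_ms LPP scoring window, default `c(400, 800)` ms, half-open.
#' @return data.frame with `subject`, `condition`, `channel` (peak channel
#'   index), `score`, and `lpp_only`.
#' @export
ground_truth <- function(spec, window_ms = c(400, 800)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  mont <- spec_montage(spec)
  tpl <- synth_templates(spec, mont)
  li <- which(vapply(spec$components, function(c) isTRUE(c$modulated),
                     logical(1)))
  assert_that(length(li) >= 1, "spec_error", "no modulated (LPP) component")
  li <- li[1]
  win <- window_to_samples(window_ms, spec$fs, spec$t0, spec$n_samples)
  conds <- names(spec$condition_effects)
  out <- expand.grid(subject = seq_len(spec$n_subjects), condition = conds,
                     stringsAsFactors = FALSE)
  out$channel <- NA_integer_; out$score <- NA_real_; out$lpp_only <- NA_real_
  for (r in seq_len(nrow(out))) {
    s <- out$subject[r]
    ch <- which.max(tpl$topo[li, s, ])
    full <- synth_clean_epoch(spec, tpl, s, out$condition[r])
    lpp <- synth_clean_epoch(spec, tpl, s, out$condition[r],
                             only_component = spec$components[[li]]$name)
    out$channel[r] <- ch
    out$score[r] <- mean(full[ch, win])
    out$lpp_only[r] <- mean(lpp[ch, win])
  }
  out
}

#' Mock concept-embedding specification
#'
#' Stand-in for the external contrastive image-text encoder: embeddings are
#' class centroids on the 512-dimensional unit sphere plus isotropic
#' within-class jitter, deterministic per stimulus id.
#'
#' @param dim embedding dimensionality (contract: 512).
#' @param n_classes number of concept classes.
#' @param class_separation scale of the centroid relative to the jitter.
#' @param within_class_sd isotropic jitter SD.
#' @param seed integer seed.
#' @return a `mock_embedding_spec`.
#' @export
mock_embedding_spec <- function(dim = 512L, n_classes = 3L,
                                class_separation = 1,
                                within_class_sd = 0.05, seed = 1L) {
  structure(list(dim = as.integer(dim), n_classes = as.integer(n_classes),
                 class_separation = class_separation,
                 within_class_sd = within_class_sd, seed = as.integer(seed)),
            class = "mock_embedding_spec")
}

mock_centroids <- function(spec) {
  with_seed(child_seed(spec$seed, "centroids"), {
    ctr <- matrix(stats::rnorm(spec$dim * spec$n_classes), spec$dim)
    ctr / rep(sqrt(colSums(ctr^2)), each = spec$dim)
  })
}

#' Simulate concept embeddings for a stimulus list
#'
#' @param spec a [mock_embedding_spec()].
#' @param stimuli data.frame with columns `stimulus_id` and `class`
#'   (integer in `0..n_classes-1`).
#' @return list of `concept_embedding` objects (unit norm, modality
#'   `"mock"`).
#' @export
simulate_embeddings <- function(spec, stimuli) {
  stimuli <- as.data.frame(stimuli)
  lapply(seq_len(nrow(stimuli)), function(i)
    mock_encode(stimuli$stimulus_id[i], stimuli$class[i], spec))
}
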
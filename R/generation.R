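#' Mock encoder closure for generation requests
#'
#' Wraps a [mock_embedding_spec()] as an encoder function usable in the
#' generation pipeline.  Inputs may be a stimulus id string (class looked up
#' in `class_of`, if given) or a list with `stimulus_id` and `class`.
#'
#' @param spec a [mock_embedding_spec()].
#' @param class_of optional named integer vector mapping stimulus ids to
#'   classes.
#' @return function `(input) -> concept_embedding`.
#' @export
mock_encoder <- function(spec, class_of = NULL) {
  force(spec); force(class_of)
  function(input) {
    if (is.list(input))
      return(mock_encode(input$stimulus_id, input$class, spec))
    cls <- if (!is.null(class_of) && input %in% names(class_of))
      class_of[[input]] else NULL
    mock_encode(input, cls, spec)
  }
}

check_composition <- function(models) {
  assert_that(all(c("encoder", "bridge", "cvae") %in% names(models)),
              "composition_error",
              "models must contain encoder, bridge, and cvae")
  bc <- models$bridge$cfg; cc <- models$cvae$cfg
  assert_that(bc$latent_dim == cc$latent_dim, "composition_error",
              "bridge output (%d) does not match cvae latent (%d)",
              bc$latent_dim, cc$latent_dim)
  assert_that(bc$n_subjects == cc$n_subjects, "composition_error",
              "bridge n_subjects (%d) does not match cvae n_subjects (%d)",
              bc$n_subjects, cc$n_subjects)
  invisible(TRUE)
}

#' Generate one synthetic ERP from a concept input
#'
#' The full concept-to-ERP path: encode the input into the conceptual latent
#' space, map it (with the subject one-hot) into the electrophysiological
#' latent space with the bridge, and decode the latent mean deterministically
#' with the cVAE decoder.  Identical inputs always yield bit-identical
#' epochs.
#'
#' @param input encoder payload (stimulus id, text, or list with
#'   `stimulus_id`/`class` for the mock encoder).
#' @param subject subject index (into the model's registry) or a one-hot
#'   vector.
#' @param models list with `encoder` (function), `bridge` (`bridge_model`),
#'   and `cvae` (`cvae_model` trained via [train_cvae()], which records the
#'   signal geometry).
#' @param condition condition label to attach to the epoch metadata.
#' @return an `erp_epoch` (z-scored model units; see [zscore_invert()] and
#'   the model's stored normalization to return to input units).
#' @export
concept_to_erp <- function(input, subject, models, condition = "other") {
  check_composition(models)
  cvae <- models$cvae
  emb <- models$encoder(input)
  s <- if (length(subject) == 1)
    one_hot_vec(as.integer(subject), cvae$cfg$n_subjects) else subject
  z <- map_to_latent(emb, s, models$bridge)
  x <- decode(cvae, z, s)
  sig <- cvae$signal %||% list(fs = 1, t0 = 0)
  erp_epoch(x, sig$fs, sig$t0,
            subject_id = which.max(s), condition = condition,
            stimulus_id = emb$stimulus_id,
            modality = if (emb$modality == "mock") "synthetic" else
              emb$modality)
}

#' Generation request
#'
#' @param stimuli data.frame with `stimulus_id` and optionally `class` (for
#'   the mock encoder) and `condition` (metadata label).
#' @param subjects integer subject indices, or `"all"`.
#' @param output_path optional container path to write the result to.
#' @param tags named list of provenance tags.
#' @return a `generation_request`.
#' @export
generation_request <- function(stimuli, subjects = "all",
                               output_path = NULL, tags = list()) {
  stimuli <- as.data.frame(stimuli)
  assert_that(nrow(stimuli) >= 1, "parameter_error", "no stimuli requested")
  structure(list(stimuli = stimuli, subjects = subjects,
                 output_path = output_path, tags = tags),
            class = "generation_request")
}

#' Batch-generate a multi-subject synthetic ERP dataset
#'
#' Runs [concept_to_erp()] for every (subject, stimulus) pair in
#' subject-major order, so the output always holds exactly
#' `|subjects| * |stimuli|` epochs and a single-subject request reproduces
#' per-stimulus calls bit-exactly.
#'
#' @param req a [generation_request()].
#' @param models as in [concept_to_erp()].
#' @return an `erp_dataset`; also written to `req$output_path` if set.
#' @export
batch_generate <- function(req, models) {
  stopifnot(inherits(req, "generation_request"))
  check_composition(models)
  cvae <- models$cvae
  sig <- cvae$signal
  assert_that(!is.null(sig), "composition_error",
              "cvae model carries no signal geometry; train it on a dataset first")
  subjects <- req$subjects
  if (identical(subjects, "all")) subjects <- seq_len(cvae$cfg$n_subjects)
  assert_that(length(subjects) >= 1, "parameter_error", "no subjects requested")
  nstim <- nrow(req$stimuli)
  n <- length(subjects) * nstim
  data <- array(NA_real_, c(n, cvae$cfg$n_channels, cvae$cfg$n_samples))
  meta <- data.frame(subject_id = integer(n), condition = character(n),
                     stimulus_id = character(n), modality = character(n),
                     stringsAsFactors = FALSE)
  i <- 0L
  for (s in subjects) {
    for (k in seq_len(nstim)) {
      i <- i + 1L
      row <- req$stimuli[k, ]
      input <- if ("class" %in% names(req$stimuli))
        list(stimulus_id = row$stimulus_id, class = row$class)
        else row$stimulus_id
      cond <- if ("condition" %in% names(req$stimuli)) row$condition
        else "other"
      ep <- tryCatch(
        concept_to_erp(input, s, models, condition = cond),
        error = function(e) stop_fmt("generation_error",
          "generation failed for stimulus '%s', subject %d: %s",
          row$stimulus_id, s, conditionMessage(e)))
      data[i, , ] <- ep$data
      meta$subject_id[i] <- s
      meta$condition[i] <- ep$condition
      meta$stimulus_id[i] <- ep$stimulus_id
      meta$modality[i] <- ep$modality
    }
  }
  prov <- c(req$tags, list(
    generator = "erpsynth::batch_generate",
    encoder = "mock",
    bridge_hash = model_hash(models$bridge),
    cvae_hash = model_hash(cvae)))
  ds <- erp_dataset(data, meta, sig$fs, sig$t0, sig$montage, sig$subjects,
                    prov)
  if (!is.null(req$output_path)) write_container(ds, req$output_path)
  ds
}

# Stable short hash of a model's weights for provenance stamping.
model_hash <- function(model) {
  v <- unlist(model$params, use.names = FALSE)
  sprintf("%08x", sum(as.integer(
    abs(v[seq(1, length(v), length.out = min(1000, length(v)))]) * 1e4) %%
      97L) %% .Machine$integer.max)
}
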
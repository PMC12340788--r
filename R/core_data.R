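CONDITIONS <- c("pleasant", "neutral", "unpleasant", "other")
MODALITIES <- c("image", "text", "synthetic")

#' Single ERP epoch
#'
#' One channel-by-time trial of (typically z-scored) voltage with its
#' acquisition metadata.  Sample `k` (1-based) lies at time `t0 + (k-1)/fs`
#' seconds relative to stimulus onset.
#'
#' @param data numeric matrix `n_channels x n_samples`, all finite.
#' @param fs sampling rate in Hz.
#' @param t0 epoch start time in seconds (negative pre-event offset).
#' @param subject_id integer subject index.
#' @param condition one of `"pleasant"`, `"neutral"`, `"unpleasant"`,
#'   `"other"`.
#' @param stimulus_id stimulus identifier string.
#' @param modality one of `"image"`, `"text"`, `"synthetic"`.
#' @return an `erp_epoch` object.
#' @export
erp_epoch <- function(data, fs, t0 = -0.1, subject_id = 1L,
                      condition = "other", stimulus_id = "stim",
                      modality = "synthetic") {
  data <- as.matrix(data)
  assert_that(all(is.finite(data)), "epoch_error",
              "epoch data contains non-finite values")
  assert_that(is.numeric(fs) && fs > 0, "epoch_error", "fs must be > 0")
  condition <- match.arg(condition, CONDITIONS)
  modality <- match.arg(modality, MODALITIES)
  structure(list(data = data, fs = fs, t0 = t0,
                 subject_id = as.integer(subject_id),
                 condition = condition,
                 stimulus_id = as.character(stimulus_id),
                 modality = modality),
            class = "erp_epoch")
}

#' @export
print.erp_epoch <- function(x, ...) {
  cat(sprintf("<erp_epoch> %d ch x %d samples @ %g Hz, t0=%g s, subject %d, %s '%s'\n",
              nrow(x$data), ncol(x$data), x$fs, x$t0, x$subject_id,
              x$condition, x$stimulus_id))
  invisible(x)
}

#' Subject registry
#'
#' Fixes the ordered subject identity list used to build one-hot conditioning
#' vectors.  The ordering is explicit configuration: position `i` in the
#' registry is index `i` of the one-hot vector.
#'
#' @param ids ordered subject labels (coerced to character).
#' @param dataset_of optional character vector tagging each subject's source
#'   dataset.
#' @return a `subject_registry`.
#' @export
subject_registry <- function(ids, dataset_of = NULL) {
  ids <- as.character(ids)
  assert_that(!anyDuplicated(ids), "registry_error",
              "subject ids must be unique")
  if (is.null(dataset_of)) dataset_of <- rep("default", length(ids))
  assert_that(length(dataset_of) == length(ids), "registry_error",
              "dataset_of must match ids in length")
  structure(list(n_subjects = length(ids), ids = ids,
                 dataset_of = stats::setNames(as.character(dataset_of), ids)),
            class = "subject_registry")
}

#' One-hot subject vector
#'
#' @param registry a `subject_registry`.
#' @param i subject index (1-based position in the registry).
#' @return numeric vector of length `n_subjects` with a single 1 at `i`.
#' @export
one_hot <- function(registry, i) {
  assert_that(i >= 1 && i <= registry$n_subjects, "registry_error",
              "subject index %d outside registry of size %d", i,
              registry$n_subjects)
  v <- numeric(registry$n_subjects)
  v[i] <- 1
  v
}

#' ERP dataset container
#'
#' Stores all trials in a single `trials x channels x samples` array plus a
#' per-trial metadata frame, the montage, and the subject registry.  All
#' epochs share `(n_channels, n_samples, fs, t0)`.
#'
#' @param data numeric array `n_trials x n_channels x n_samples`.
#' @param meta data.frame with columns `subject_id`, `condition`,
#'   `stimulus_id`, `modality` (one row per trial).
#' @param fs sampling rate in Hz.
#' @param t0 epoch start time in seconds.
#' @param montage an `erp_montage` with `n_channels` channels.
#' @param subjects a `subject_registry`; every `subject_id` must be a valid
#'   registry index.
#' @param provenance free-form named list of metadata.
#' @return an `erp_dataset`.
#' @export
erp_dataset <- function(data, meta, fs, t0, montage, subjects,
                        provenance = list()) {
  assert_that(length(dim(data)) == 3, "dataset_error",
              "data must be a trials x channels x samples array")
  n <- dim(data)[1]
  assert_that(nrow(meta) == n, "dataset_error",
              "meta has %d rows for %d trials", nrow(meta), n)
  assert_that(dim(data)[2] == length(montage$names), "dataset_error",
              "data has %d channels but montage has %d",
              dim(data)[2], length(montage$names))
  assert_that(all(is.finite(data)), "dataset_error",
              "dataset contains non-finite values")
  meta$subject_id <- as.integer(meta$subject_id)
  assert_that(n == 0 || all(meta$subject_id >= 1 &
                            meta$subject_id <= subjects$n_subjects),
              "dataset_error", "subject_id outside the registry")
  assert_that(all(meta$condition %in% CONDITIONS), "dataset_error",
              "unknown condition label")
  meta$stimulus_id <- as.character(meta$stimulus_id)
  meta$modality <- as.character(meta$modality)
  rownames(meta) <- NULL
  structure(list(data = data, meta = meta, fs = fs, t0 = t0,
                 montage = montage, subjects = subjects,
                 provenance = provenance),
            class = "erp_dataset")
}

#' @export
print.erp_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<erp_dataset> %d trials x %d ch x %d samples @ %g Hz (t0=%g s), %d subjects\n",
    d[1], d[2], d[3], x$fs, x$t0, x$subjects$n_subjects))
  if (d[1] > 0)
    print(table(condition = x$meta$condition))
  invisible(x)
}

#' Number of trials in a dataset
#' @param ds an `erp_dataset`.
#' @return integer trial count.
#' @export
n_trials <- function(ds) dim(ds$data)[1]

#' Extract one trial as an `erp_epoch`
#' @param ds an `erp_dataset`.
#' @param i trial index.
#' @return an `erp_epoch`.
#' @export
get_epoch <- function(ds, i) {
  assert_that(i >= 1 && i <= n_trials(ds), "dataset_error",
              "trial index %d out of range", i)
  m <- ds$meta[i, ]
  erp_epoch(ds$data[i, , , drop = TRUE], ds$fs, ds$t0, m$subject_id,
            m$condition, m$stimulus_id, m$modality)
}

#' Subset a dataset by trial index
#' @param ds an `erp_dataset`.
#' @param idx integer trial indices.
#' @return an `erp_dataset` with the selected trials, in the given order.
#' @export
subset_trials <- function(ds, idx) {
  erp_dataset(ds$data[idx, , , drop = FALSE], ds$meta[idx, , drop = FALSE],
              ds$fs, ds$t0, ds$montage, ds$subjects, ds$provenance)
}

#' Average trials by subject and/or condition
#'
#' Computes the arithmetic mean over trials, per channel and sample, within
#' each group defined by the requested keys, mirroring the per-subject
#' per-condition averaging used before real-vs-synthetic comparison.
#'
#' @param ds an `erp_dataset`.
#' @param keys character subset of `c("subject", "condition")`.
#' @return an `erp_dataset` with one epoch per group, ordered by group key.
#'   The averaged epoch's `stimulus_id` is `"average"` and the metadata keeps
#'   the grouping values (ungrouped keys are collapsed to the first level
#'   present or `"other"`).
#' @export
average_by <- function(ds, keys = c("subject", "condition")) {
  keys <- match.arg(keys, c("subject", "condition"), several.ok = TRUE)
  assert_that(n_trials(ds) > 0, "empty_group_error", "dataset has no trials")
  fac <- list()
  if ("subject" %in% keys) fac$subject <- ds$meta$subject_id
  if ("condition" %in% keys) fac$condition <- ds$meta$condition
  key <- interaction(fac, drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(n_trials(ds)), key)
  nchan <- dim(ds$data)[2]; nsamp <- dim(ds$data)[3]
  out <- array(0, c(length(groups), nchan, nsamp))
  meta <- data.frame(subject_id = integer(length(groups)),
                     condition = character(length(groups)),
                     stimulus_id = "average",
                     modality = ds$meta$modality[1] %||% "synthetic",
                     stringsAsFactors = FALSE)
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    assert_that(length(idx) > 0, "empty_group_error",
                "empty group '%s'", names(groups)[g])
    sl <- ds$data[idx, , , drop = FALSE]
    out[g, , ] <- colMeans(sl, dims = 1)
    meta$subject_id[g] <- if ("subject" %in% keys)
      ds$meta$subject_id[idx[1]] else ds$meta$subject_id[idx[1]]
    meta$condition[g] <- if ("condition" %in% keys)
      ds$meta$condition[idx[1]] else "other"
  }
  erp_dataset(out, meta, ds$fs, ds$t0, ds$montage, ds$subjects,
              c(ds$provenance, list(averaged_by = paste(keys, collapse = "+"))))
}

#' Centered moving-average smoothing
#'
#' Smooths each channel with a centered moving-average window of the given
#' duration (the display smoothing applied to reported time series).  Window
#' edges shrink to the valid range, so no zero padding is introduced and a
#' constant signal is returned unchanged.
#'
#' @param e an `erp_epoch`.
#' @param window_ms window length in milliseconds; must round to at least one
#'   sample and at most the epoch length.
#' @return a smoothed `erp_epoch`.
#' @export
smooth_moving_average <- function(e, window_ms = 40) {
  stopifnot(inherits(e, "erp_epoch"))
  w <- round(window_ms / 1000 * e$fs)
  nsamp <- ncol(e$data)
  assert_that(w >= 1, "parameter_error",
              "window of %g ms is shorter than one sample at %g Hz",
              window_ms, e$fs)
  assert_that(w <= nsamp, "parameter_error",
              "window of %g ms exceeds the epoch length", window_ms)
  lo <- pmax(1L, seq_len(nsamp) - floor((w - 1) / 2))
  hi <- pmin(nsamp, seq_len(nsamp) + floor(w / 2))
  cs <- cbind(0, t(apply(e$data, 1, cumsum)))
  sm <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1L, each = nrow(e$data))
  out <- e
  out$data <- sm
  out
}
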
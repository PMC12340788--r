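#' Map a millisecond window to sample indices
#'
#' Windows are half-open `[start, end)` in milliseconds relative to stimulus
#' onset; sample `k` (1-based) lies at `t0 + (k-1)/fs` seconds.
#'
#' @param window_ms numeric `c(start, end)` in ms.
#' @param fs sampling rate in Hz.
#' @param t0 epoch start in seconds.
#' @param n_samples epoch length in samples.
#' @return 1-based integer sample indices covered by the window.
#' @export
window_to_samples <- function(window_ms, fs, t0, n_samples) {
  j0 <- ceiling((window_ms[1] / 1000 - t0) * fs - 1e-9)
  j1 <- ceiling((window_ms[2] / 1000 - t0) * fs - 1e-9) - 1
  assert_that(j0 >= 0 && j1 < n_samples && j1 >= j0, "parameter_error",
              "window [%g, %g) ms falls outside the epoch",
              window_ms[1], window_ms[2])
  (j0:j1) + 1L
}

#' Channel-by-time correlation map between paired datasets
#'
#' Pairs the averaged epochs of `a` and `b` on the given keys and computes,
#' at every (channel, sample), the Pearson correlation across pairs with a
#' two-sided p-value — the real-versus-synthetic reconstruction map.
#'
#' @param a,b `erp_dataset`s of averages with identical shapes; every
#'   pairing key of `a` must occur exactly once in each.
#' @param pairing character subset of `c("subject", "condition")` used to
#'   match epochs.
#' @return a `correlation_map` with matrices `r` and `p`
#'   (`n_channels x n_samples`), `n_pairs`, `fs`, `t0`.
#' @export
correlation_map <- function(a, b, pairing = c("subject", "condition")) {
  key <- function(ds) {
    parts <- list()
    if ("subject" %in% pairing) parts$s <- ds$meta$subject_id
    if ("condition" %in% pairing) parts$c <- ds$meta$condition
    do.call(paste, c(parts, sep = "|"))
  }
  ka <- key(a); kb <- key(b)
  assert_that(!anyDuplicated(ka) && !anyDuplicated(kb), "pairing_error",
              "pairing keys must be unique within each dataset")
  idx <- match(ka, kb)
  assert_that(!anyNA(idx), "pairing_error", "unpaired key(s): %s",
              paste(ka[is.na(idx)], collapse = ", "))
  assert_that(identical(dim(a$data)[2:3], dim(b$data)[2:3]),
              "dimension_error", "datasets have different epoch shapes")
  n <- length(ka)
  A <- matrix(a$data, n)                      # pairs x (chan*samples)
  B <- matrix(b$data[idx, , , drop = FALSE], n)
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  num <- colSums(Ac * Bc)
  den <- sqrt(colSums(Ac^2) * colSums(Bc^2))
  r <- ifelse(den > 0, num / den, NA_real_)
  r <- pmin(pmax(r, -1), 1)
  p <- rep(NA_real_, length(r))
  if (n > 2) {
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  nchan <- dim(a$data)[2]; nsamp <- dim(a$data)[3]
  structure(list(r = matrix(r, nchan, nsamp), p = matrix(p, nchan, nsamp),
                 n_pairs = n, fs = a$fs, t0 = a$t0,
                 pairing = pairing),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map> %d x %d over %d pairs; mean r = %.3f\n",
              nrow(x$r), ncol(x$r), x$n_pairs, mean(x$r, na.rm = TRUE)))
  invisible(x)
}

#' Windowed summary of a correlation map
#'
#' @param cm a `correlation_map`.
#' @param channels integer channel indices.
#' @param window_ms half-open window in ms.
#' @param label summary label.
#' @return one-row data.frame with `label` and `mean_r`.
#' @export
window_summary <- function(cm, channels, window_ms, label = "window") {
  win <- window_to_samples(window_ms, cm$fs, cm$t0, ncol(cm$r))
  data.frame(label = label,
             mean_r = mean(cm$r[channels, win], na.rm = TRUE))
}

#' Score an ERP component by windowed mean amplitude
#'
#' Mean amplitude over a channel and a half-open millisecond window (e.g.
#' the LPP at Pz over 400-800 ms), aggregated by the requested keys.
#'
#' @param ds an `erp_dataset`.
#' @param channel a 10-10 label resolved through the montage, or an integer
#'   channel index.
#' @param window_ms half-open scoring window in ms (default `c(400, 800)`).
#' @param by grouping columns: subset of
#'   `c("subject", "condition", "stimulus")`.
#' @return a `component_score`: data.frame with the grouping columns and
#'   `score`, with the channel index and window in attributes.
#' @export
score_component <- function(ds, channel = "Pz", window_ms = c(400, 800),
                            by = c("subject", "condition")) {
  ch <- if (is.character(channel)) channel_index(ds$montage, channel)
    else as.integer(channel)
  win <- window_to_samples(window_ms, ds$fs, ds$t0, dim(ds$data)[3])
  per_trial <- rowMeans(ds$data[, ch, win, drop = FALSE], dims = 1)
  cols <- list()
  if ("subject" %in% by) cols$subject <- ds$meta$subject_id
  if ("condition" %in% by) cols$condition <- ds$meta$condition
  if ("stimulus" %in% by) cols$stimulus_id <- ds$meta$stimulus_id
  assert_that(length(cols) > 0, "parameter_error", "no grouping keys")
  agg <- stats::aggregate(per_trial,
                          by = cols, FUN = mean)
  names(agg)[ncol(agg)] <- "score"
  structure(agg, class = c("component_score", "data.frame"),
            channel = ch, window_ms = window_ms)
}

#' Per-subject V-pattern statistic
#'
#' `(pleasant + unpleasant)/2 - neutral` on per-subject condition scores:
#' positive values mean emotional content evokes a larger response than
#' neutral content — the canonical V-shaped late-positive-potential effect.
#'
#' @param scores a `component_score` (or data.frame) with columns
#'   `subject`, `condition`, `score`; all three affective conditions must be
#'   present for every subject.
#' @return named numeric vector, one statistic per subject.
#' @export
v_pattern <- function(scores) {
  need <- c("pleasant", "neutral", "unpleasant")
  subjects <- sort(unique(scores$subject))
  vapply(subjects, function(s) {
    sub <- scores[scores$subject == s, ]
    for (cond in need)
      assert_that(cond %in% sub$condition, "missing_condition_error",
                  "subject %s lacks condition '%s'", s, cond)
    get1 <- function(cond) mean(sub$score[sub$condition == cond])
    (get1("pleasant") + get1("unpleasant")) / 2 - get1("neutral")
  }, numeric(1)) |> stats::setNames(subjects)
}

#' Correlation between component scores and stimulus ratings
#'
#' Pearson correlation of per-stimulus (subject-averaged) component scores
#' against a per-stimulus scalar rating such as normative arousal.
#'
#' @param scores data.frame with `stimulus_id` and `score` (e.g.
#'   `score_component(ds, by = "stimulus")`), or a named numeric vector.
#' @param ratings named numeric vector of ratings keyed by stimulus id.
#' @return list with `r`, `p`, and `n`.
#' @export
amplitude_rating_correlation <- function(scores, ratings) {
  if (is.data.frame(scores))
    scores <- stats::setNames(scores$score, scores$stimulus_id)
  common <- intersect(names(scores), names(ratings))
  assert_that(length(common) >= 3, "parameter_error",
              "need at least 3 paired stimuli, have %d", length(common))
  ct <- stats::cor.test(scores[common], ratings[common])
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common))
}

stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      ix <- sample(which(labels == cls))
      fold[ix] <- rep_len(seq_len(k), length(ix))
    }
  })
  fold
}

#' Cross-validated condition decoding from the latent space
#'
#' Stratified k-fold linear support-vector-machine classification of
#' condition labels from per-trial latent means, optionally per subject —
#' the latent-space separability analysis.
#'
#' @param latents numeric matrix `n_trials x latent_dim`.
#' @param labels condition label per trial.
#' @param subject_ids optional subject index per trial; if given, accuracy
#'   is computed within each subject.
#' @param folds number of folds (default 5).
#' @param seed integer seed for fold assignment.
#' @return named numeric vector of accuracies (one per subject, or
#'   `"all"`).
#' @export
latent_decode <- function(latents, labels, subject_ids = NULL, folds = 5L,
                          seed = 1L) {
  latents <- as.matrix(latents)
  labels <- factor(labels)
  groups <- if (is.null(subject_ids)) list(all = seq_len(nrow(latents)))
    else split(seq_len(nrow(latents)), subject_ids)
  vapply(groups, function(ix) {
    y <- droplevels(labels[ix])
    counts <- table(y)
    assert_that(length(counts) >= 2, "parameter_error",
                "need at least 2 classes to decode")
    assert_that(all(counts >= folds), "parameter_error",
                "class '%s' has fewer trials (%d) than folds (%d)",
                names(counts)[which.min(counts)], min(counts), folds)
    fold <- stratified_folds(as.character(y), folds, seed)
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- ix[fold != f]; te <- ix[fold == f]
      fit <- e1071::svm(latents[tr, , drop = FALSE],
                        droplevels(labels[tr]), kernel = "linear",
                        scale = FALSE)
      pred <- stats::predict(fit, latents[te, , drop = FALSE])
      correct <- correct + sum(as.character(pred) ==
                                 as.character(labels[te]))
    }
    correct / length(ix)
  }, numeric(1))
}

#' 2-D projection of latent vectors for visualization
#'
#' Centered principal-component projection onto the first two axes, with a
#' deterministic sign convention.  For display only; no quantitative claims
#' attach to the projection.
#'
#' @param latents numeric matrix `n x latent_dim` with `n >= 5`.
#' @param seed kept for interface stability; the projection is
#'   deterministic.
#' @return numeric matrix `n x 2`.
#' @export
project_2d <- function(latents, seed = 1L) {
  latents <- as.matrix(latents)
  assert_that(nrow(latents) >= 5, "parameter_error",
              "need at least 5 points, have %d", nrow(latents))
  pc <- stats::prcomp(latents, center = TRUE, scale. = FALSE, rank. = 2)
  rot <- pc$rotation
  for (j in seq_len(ncol(rot)))
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  out <- scale(latents, center = TRUE, scale = FALSE) %*% rot
  if (ncol(out) < 2) out <- cbind(out, 0)
  unname(out[, 1:2, drop = FALSE])
}
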
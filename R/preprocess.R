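#' Band filter specification
#'
#' Butterworth band filtering as used to condition the empirical recordings:
#' a gentle order-3 high-pass at 0.2 Hz paired with a steep order-9 low-pass
#' at 25 Hz, both applied zero-phase (forward-backward).
#'
#' @param hp_order,hp_cutoff high-pass order and cutoff (Hz).
#' @param lp_order,lp_cutoff low-pass order and cutoff (Hz).
#' @return a `filter_spec`.
#' @export
filter_spec <- function(hp_order = 3, hp_cutoff = 0.2,
                        lp_order = 9, lp_cutoff = 25) {
  assert_that(hp_cutoff > 0 && hp_cutoff < lp_cutoff, "parameter_error",
              "need 0 < high-pass cutoff < low-pass cutoff")
  structure(list(highpass = list(order = hp_order, cutoff = hp_cutoff),
                 lowpass = list(order = lp_order, cutoff = lp_cutoff),
                 design = "butterworth"),
            class = "filter_spec")
}

# Zero-phase filtering with odd (antisymmetric) edge extension, so slow
# components such as DC converge despite the long high-pass time constant.
filtfilt_padded <- function(b, a, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filtfilt(signal::Arma(b = b, a = a), ext)
  y[(pad + 1):(pad + n)]
}

#' Zero-phase Butterworth band filtering
#'
#' Applies the high-pass then the low-pass of `spec` forward-backward to each
#' channel.  The effective magnitude response is the squared filter response,
#' with zero phase distortion.
#'
#' @param x numeric matrix `channels x samples` (a vector is treated as one
#'   channel).
#' @param fs sampling rate in Hz.
#' @param spec a [filter_spec()].
#' @return filtered matrix of the same shape.
#' @export
bandpass <- function(x, fs, spec = filter_spec()) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  assert_that(spec$lowpass$cutoff < fs / 2, "parameter_error",
              "low-pass cutoff %g Hz is not below Nyquist (%g Hz)",
              spec$lowpass$cutoff, fs / 2)
  maxord <- max(spec$highpass$order, spec$lowpass$order)
  assert_that(ncol(x) > 3 * maxord, "parameter_error",
              "need more than %d samples for order-%d filtering",
              3 * maxord, maxord)
  hp <- signal::butter(spec$highpass$order, spec$highpass$cutoff / (fs / 2),
                       type = "high")
  lp <- signal::butter(spec$lowpass$order, spec$lowpass$cutoff / (fs / 2),
                       type = "low")
  # pad by several high-pass time constants, bounded by the record length
  pad <- min(ncol(x) - 1L, ceiling(3 * fs / spec$highpass$cutoff))
  out <- x
  for (ch in seq_len(nrow(x))) {
    y <- filtfilt_padded(hp$b, hp$a, x[ch, ], pad)
    out[ch, ] <- filtfilt_padded(lp$b, lp$a, y, pad)
  }
  out
}

#' Cut a continuous recording into stimulus-locked epochs
#'
#' Each event sample becomes epoch time 0; the epoch spans `pre_s` seconds
#' before to `post_s` seconds after, giving `round((pre_s + post_s) * fs)`
#' samples.  Events too close to the recording edges are skipped with a
#' warning.
#'
#' @param continuous numeric matrix `channels x samples`.
#' @param fs sampling rate in Hz.
#' @param event_samples integer vector of event sample indices (1-based).
#' @param pre_s,post_s pre/post event windows in seconds (default 0.1 / 1.4).
#' @param meta optional data.frame with one row per event (`subject_id`,
#'   `condition`, `stimulus_id`, `modality`).
#' @return list of `erp_epoch` objects (one per retained event), with the
#'   retained event indices in attribute `"events"`.
#' @export
segment <- function(continuous, fs, event_samples, pre_s = 0.1, post_s = 1.4,
                    meta = NULL) {
  if (is.null(dim(continuous))) continuous <- matrix(continuous, nrow = 1)
  npre <- round(pre_s * fs)
  nlen <- round((pre_s + post_s) * fs)
  nsamp <- ncol(continuous)
  epochs <- list()
  kept <- integer(0)
  for (i in seq_along(event_samples)) {
    ev <- event_samples[i]
    start <- ev - npre
    stop_ <- start + nlen - 1L
    if (start < 1L || stop_ > nsamp) {
      warning(sprintf("event %d at sample %d skipped: epoch window [%d, %d] outside recording",
                      i, ev, start, stop_))
      next
    }
    m <- if (!is.null(meta)) meta[i, ] else
      data.frame(subject_id = 1L, condition = "other",
                 stimulus_id = sprintf("event%d", i), modality = "synthetic")
    epochs[[length(epochs) + 1L]] <-
      erp_epoch(continuous[, start:stop_, drop = FALSE], fs, -pre_s,
                m$subject_id, m$condition, m$stimulus_id, m$modality)
    kept <- c(kept, i)
  }
  attr(epochs, "events") <- kept
  epochs
}

robust_z <- function(x) {
  med <- stats::median(x)
  s <- stats::mad(x)
  if (s == 0) return(rep(0, length(x)))
  (x - med) / s
}

#' Statistical artifact control: compound channel-quality index
#'
#' Computes per-channel median absolute voltage, standard deviation, and
#' maximum absolute first difference across all epochs; robust-z-scores each
#' metric across channels and averages them into a compound quality index.
#' Channels whose compound index exceeds the median of the index distribution
#' by more than `n_sd` standard deviations are flagged for interpolation.
#'
#' @param epochs list of `erp_epoch` objects or an `erp_dataset`.
#' @param n_sd flagging threshold in SD units above the median (default 2.5).
#' @return a `qc_report` with `metrics` (per-channel data.frame),
#'   `compound_index`, `threshold`, and `flagged` (integer channel indices).
#' @export
qc_flag <- function(epochs, n_sd = 2.5) {
  if (inherits(epochs, "erp_dataset"))
    epochs <- lapply(seq_len(n_trials(epochs)), get_epoch, ds = epochs)
  assert_that(length(epochs) > 0, "parameter_error", "no epochs supplied")
  nchan <- nrow(epochs[[1]]$data)
  assert_that(nchan >= 2, "parameter_error",
              "QC needs at least 2 channels, got %d", nchan)
  X <- do.call(cbind, lapply(epochs, function(e) e$data))  # chan x (samp*ep)
  med_abs <- apply(abs(X), 1, stats::median)
  sd_v <- apply(X, 1, stats::sd)
  max_d <- vapply(seq_len(nchan), function(ch) {
    max(vapply(epochs, function(e) max(abs(diff(e$data[ch, ]))), numeric(1)))
  }, numeric(1))
  compound <- (robust_z(med_abs) + robust_z(sd_v) + robust_z(max_d)) / 3
  thr <- stats::median(compound) + n_sd * stats::sd(compound)
  flagged <- which(compound > thr)
  if (stats::sd(compound) == 0) flagged <- integer(0)
  structure(list(
    metrics = data.frame(channel = seq_len(nchan), median_abs = med_abs,
                         sd = sd_v, max_diff = max_d),
    compound_index = compound, threshold = thr, flagged = flagged,
    n_sd = n_sd), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d channels, %d flagged (threshold %.3f)\n",
              nrow(x$metrics), length(x$flagged), x$threshold))
  if (length(x$flagged))
    cat("  flagged:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Reject trials dominated by flagged channels
#'
#' Runs [qc_flag()] per trial against the dataset-level channel statistics
#' and drops trials whose fraction of individually aberrant channels exceeds
#' `max_bad_fraction`.  The channel rule follows the stated median + 2.5 SD
#' criterion; the trial rule is a configurable stand-in for the full
#' statistical-control procedure.
#'
#' @param ds an `erp_dataset`.
#' @param max_bad_fraction maximum tolerated fraction of flagged channels per
#'   trial (default 0.1).
#' @param n_sd channel flagging threshold (default 2.5).
#' @return the dataset restricted to retained trials, with the drop list in
#'   `provenance$rejected_trials`.
#' @export
reject_trials <- function(ds, max_bad_fraction = 0.1, n_sd = 2.5) {
  nchan <- dim(ds$data)[2]
  bad_frac <- vapply(seq_len(n_trials(ds)), function(i) {
    e <- ds$data[i, , , drop = TRUE]
    compound <- (robust_z(apply(abs(e), 1, stats::median)) +
                 robust_z(apply(e, 1, stats::sd)) +
                 robust_z(apply(abs(t(diff(t(e)))), 1, max))) / 3
    s <- stats::sd(compound)
    if (s == 0) return(0)
    sum(compound > stats::median(compound) + n_sd * s) / nchan
  }, numeric(1))
  keep <- which(bad_frac <= max_bad_fraction)
  out <- subset_trials(ds, keep)
  out$provenance$rejected_trials <- setdiff(seq_len(n_trials(ds)), keep)
  out
}

# Perrin-style spherical spline basis: g(cos angle) as a truncated Legendre
# series, order m, degree <= deg.
spline_g <- function(cosang, m = 4, deg = 50) {
  n <- seq_len(deg)
  coef <- (2 * n + 1) / (n * (n + 1))^m
  P <- legendre_table(cosang, deg)
  as.vector(P %*% coef) / (4 * pi)
}

# Legendre polynomials P_1..P_deg evaluated at x (vector), via the
# three-term recurrence; returns length(x) x deg matrix.
legendre_table <- function(x, deg) {
  out <- matrix(0, length(x), deg)
  pm1 <- rep(1, length(x))  # P_0
  p <- x                    # P_1
  out[, 1] <- p
  for (n in 2:deg) {
    pn <- ((2 * n - 1) * x * p - (n - 1) * pm1) / n
    out[, n] <- pn
    pm1 <- p
    p <- pn
  }
  out
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces the flagged channels of an epoch with spherical-spline estimates
#' computed from the remaining channels (spline order `m = 4`, regularization
#' `lambda`, Legendre series truncated at degree `deg`).  Good channels are
#' returned untouched.
#'
#' @param epoch an `erp_epoch`.
#' @param montage an `erp_montage` matching the epoch's channels.
#' @param bad integer indices of channels to interpolate.
#' @param m spline order (default 4).
#' @param lambda diagonal regularization (default 1e-5).
#' @param deg Legendre truncation degree (default 50).
#' @return the epoch with interpolated bad channels.
#' @export
spline_interpolate <- function(epoch, montage, bad, m = 4, lambda = 1e-5,
                               deg = 50) {
  stopifnot(inherits(epoch, "erp_epoch"), inherits(montage, "erp_montage"))
  nchan <- nrow(epoch$data)
  bad <- sort(unique(as.integer(bad)))
  if (length(bad) == 0) return(epoch)
  assert_that(all(bad >= 1 & bad <= nchan), "parameter_error",
              "bad channel index outside 1..%d", nchan)
  good <- setdiff(seq_len(nchan), bad)
  assert_that(length(good) >= 4, "parameter_error",
              "spherical spline needs at least 4 good channels, have %d",
              length(good))
  P <- montage$positions3d
  cos_gg <- tcrossprod(P[good, , drop = FALSE])
  cos_bg <- P[bad, , drop = FALSE] %*% t(P[good, , drop = FALSE])
  cos_gg <- pmin(pmax(cos_gg, -1), 1)
  cos_bg <- pmin(pmax(cos_bg, -1), 1)
  ng <- length(good)
  G <- matrix(spline_g(as.vector(cos_gg), m, deg), ng, ng) +
    diag(lambda, ng)
  Gb <- matrix(spline_g(as.vector(cos_bg), m, deg), length(bad), ng)
  # solve [G 1; 1' 0] [c; c0] = [v; 0] per time sample
  A <- rbind(cbind(G, 1), c(rep(1, ng), 0))
  rhs <- rbind(epoch$data[good, , drop = FALSE],
               rep(0, ncol(epoch$data)))
  sol <- solve(A, rhs)
  est <- Gb %*% sol[seq_len(ng), , drop = FALSE] +
    matrix(sol[ng + 1, ], length(bad), ncol(epoch$data), byrow = TRUE)
  out <- epoch
  out$data[bad, ] <- est
  out
}

#' Fit per-channel z-score normalization
#'
#' Computes per-channel mean and standard deviation over all trials and
#' samples of the (training) dataset; the parameters are retained so that
#' generated output can be mapped back to the original scale.
#'
#' @param ds an `erp_dataset` (the fit/training set).
#' @return a `zscore_params` object with `mean` and `sd` per channel.
#' @export
zscore_fit <- function(ds) {
  nchan <- dim(ds$data)[2]
  mu <- vapply(seq_len(nchan), function(c) mean(ds$data[, c, ]), numeric(1))
  sd_ <- vapply(seq_len(nchan), function(c) stats::sd(as.vector(ds$data[, c, ])),
                numeric(1))
  zero <- which(sd_ == 0 | !is.finite(sd_))
  assert_that(length(zero) == 0, "parameter_error",
              "zero-variance channel(s): %s", paste(zero, collapse = ", "))
  structure(list(mean = mu, sd = sd_, scope = "per_channel_over_fit_set"),
            class = "zscore_params")
}

#' Apply / invert z-score normalization
#'
#' @param ds an `erp_dataset`.
#' @param params a `zscore_params` from [zscore_fit()].
#' @return the transformed dataset.
#' @export
zscore_apply <- function(ds, params) {
  nchan <- dim(ds$data)[2]
  assert_that(length(params$mean) == nchan, "dimension_error",
              "normalization has %d channels, data has %d",
              length(params$mean), nchan)
  out <- ds
  for (c in seq_len(nchan))
    out$data[, c, ] <- (ds$data[, c, ] - params$mean[c]) / params$sd[c]
  out$provenance$zscore <- "applied"
  out
}

#' @rdname zscore_apply
#' @export
zscore_invert <- function(ds, params) {
  out <- ds
  for (c in seq_len(dim(ds$data)[2]))
    out$data[, c, ] <- ds$data[, c, ] * params$sd[c] + params$mean[c]
  out$provenance$zscore <- "inverted"
  out
}

#' Z-score a dataset
#'
#' Convenience wrapper fitting and applying per-channel normalization in one
#' step.
#'
#' @param ds an `erp_dataset`.
#' @return list with elements `dataset` (normalized) and `params`.
#' @export
zscore <- function(ds) {
  params <- zscore_fit(ds)
  list(dataset = zscore_apply(ds, params), params = params)
}

#' Random train/holdout split
#'
#' Draws `round(fraction * n)` trials (round-half-even, so 80% of 13,640
#' trials gives exactly 10,912) into the training set; the rest form the
#' holdout.  Reproducible for a fixed seed.
#'
#' @param ds an `erp_dataset`.
#' @param fraction training fraction in (0, 1) (default 0.8).
#' @param seed integer seed.
#' @return list with `train` and `holdout` datasets partitioning `ds`.
#' @export
train_split <- function(ds, fraction = 0.8, seed = 1L) {
  n <- n_trials(ds)
  assert_that(n > 0, "parameter_error", "cannot split an empty dataset")
  assert_that(fraction > 0 && fraction < 1, "parameter_error",
              "fraction must be in (0, 1)")
  ntrain <- round(fraction * n)
  idx <- with_seed(seed, sample.int(n, ntrain))
  list(train = subset_trials(ds, sort(idx)),
       holdout = subset_trials(ds, setdiff(seq_len(n), idx)))
}
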
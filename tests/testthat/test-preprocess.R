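test_that("bandpass keeps the passband and removes DC", {
  fs <- 500
  t <- seq(0, 120, by = 1 / fs)
  # 10 Hz unit sinusoid: passband gain within 5% of unity
  x <- sin(2 * pi * 10 * t)
  y <- bandpass(matrix(x, 1), fs)
  mid <- seq(10 * fs, 110 * fs)   # away from edges
  gain <- sqrt(mean(y[mid]^2) / mean(x[mid]^2))
  expect_gt(gain, 0.95); expect_lt(gain, 1.05)
  # DC offset of 5 is suppressed
  yd <- bandpass(matrix(5, 1, length(t)), fs)
  expect_lt(abs(mean(yd)), 0.05)
  # all-zero input stays zero
  expect_equal(max(abs(bandpass(matrix(0, 2, 5000), fs))), 0)
  # cutoff above Nyquist is rejected
  expect_error(bandpass(matrix(rnorm(1000), 1), fs = 40), "Nyquist")
})

test_that("bandpass response matches the theoretical Butterworth gain", {
  # oracle: |H_hp|^2 * |H_lp|^2 (forward-backward squares each response)
  fs <- 500
  t <- seq(0, 60, by = 1 / fs)
  mid <- seq(10 * fs, 50 * fs)
  for (f0 in c(5, 25, 40)) {
    x <- sin(2 * pi * f0 * t)
    y <- bandpass(matrix(x, 1), fs)
    g_lp <- 1 / (1 + (f0 / 25)^(2 * 9))   # order-9 low-pass power response
    g_hp <- (f0 / 0.2)^(2 * 3) / (1 + (f0 / 0.2)^(2 * 3))
    expected <- g_lp * g_hp               # filtfilt squares the magnitude
    gain <- sqrt(mean(y[mid]^2) / mean(x[mid]^2))
    expect_equal(gain, expected, tolerance = 0.05)
  }
})

test_that("bandpass is linear", {
  fs <- 250
  set.seed(5)
  x <- matrix(rnorm(2000), 1); y <- matrix(rnorm(2000), 1)
  a <- 2.5; b <- -1.2
  lhs <- bandpass(a * x + b * y, fs)
  rhs <- a * bandpass(x, fs) + b * bandpass(y, fs)
  expect_lt(max(abs(lhs - rhs)), 1e-8)
})

test_that("segmentation produces 750-sample epochs at 500 Hz", {
  fs <- 500
  cont <- matrix(rnorm(3 * 5000), 3)
  eps <- segment(cont, fs, event_samples = c(300, 1500, 3000))
  expect_length(eps, 3)
  expect_equal(ncol(eps[[1]]$data), 750)
  expect_equal(eps[[1]]$t0, -0.1)
  # the epoch is an exact slice of the continuous record
  expect_equal(eps[[2]]$data, cont[, (1500 - 50):(1500 + 699)])
  # event at sample 1 lacks the pre-window and is skipped with a warning
  expect_warning(e2 <- segment(cont, fs, event_samples = c(1, 1500)),
                 "skipped")
  expect_length(e2, 1)
  expect_equal(attr(e2, "events"), 2L)
})

test_that("qc_flag isolates a grossly aberrant channel", {
  set.seed(42)
  eps <- lapply(1:6, function(i) {
    m <- matrix(rnorm(16 * 100), 16)
    m[5, ] <- m[5, ] * 50
    erp_epoch(m, fs = 100)
  })
  rep <- qc_flag(eps)
  expect_true(5 %in% rep$flagged)
  expect_lte(length(rep$flagged), 2)
  expect_true(all(is.finite(rep$compound_index)))
})

test_that("qc_flag handles degenerate and undersized input", {
  eps <- list(erp_epoch(matrix(1:200 * 0 + 3, 10, 20), fs = 100))
  expect_length(qc_flag(eps)$flagged, 0)     # identical channels: none
  expect_error(qc_flag(list(erp_epoch(matrix(rnorm(30), 1), fs = 10))),
               "2 channels")
})

test_that("qc false-positive rate under an i.i.d. Gaussian null is <= 5%", {
  set.seed(2024)
  nchan <- 24
  rates <- replicate(200, {
    eps <- list(erp_epoch(matrix(rnorm(nchan * 60), nchan), fs = 100))
    length(qc_flag(eps)$flagged) / nchan
  })
  expect_lte(mean(rates), 0.05)
})

test_that("trial rejection drops trials dominated by aberrant channels", {
  set.seed(6)
  ds <- tiny_dataset(n_trials = 6, n_channels = 16, n_samples = 40,
                     seed = 6)
  ds$data[3, 1:2, ] <- ds$data[3, 1:2, ] * 80   # 12.5% of channels corrupted
  kept <- reject_trials(ds, max_bad_fraction = 0.1)
  expect_false(3 %in% setdiff(seq_len(6), kept$provenance$rejected_trials))
  expect_true(3 %in% kept$provenance$rejected_trials)
  expect_lt(n_trials(kept), 6)
})

test_that("spherical splines reproduce constants and leave good channels alone", {
  m <- hydrocel_montage()
  e <- erp_epoch(matrix(3.7, 129, 10), fs = 500)
  bad <- c(7, 45, 100)
  out <- spline_interpolate(e, m, bad)
  expect_lt(max(abs(out$data[bad, ] - 3.7)), 1e-6)
  # empty bad set is the identity
  expect_identical(spline_interpolate(e, m, integer(0)), e)
  # good channels are bit-identical
  set.seed(1)
  e2 <- erp_epoch(matrix(rnorm(129 * 5), 129), fs = 500)
  out2 <- spline_interpolate(e2, m, bad)
  expect_identical(out2$data[-bad, ], e2$data[-bad, ])
})

test_that("spherical splines recover a smooth field at a held-out channel", {
  m <- hydrocel_montage()
  pos <- m$positions3d
  # low-order harmonic field: linear in z plus a gentle xy term
  field <- 1.5 * pos[, "z"] + 0.5 * pos[, "x"] * pos[, "y"] + 2
  e <- erp_epoch(matrix(field, 129, 3), fs = 500)
  for (hold in c(62, 75, 96)) {
    out <- spline_interpolate(e, m, hold)
    rel <- abs(out$data[hold, 1] - field[hold]) / abs(field[hold])
    expect_lt(rel, 0.05)
  }
})

test_that("spline interpolation refuses too few good channels", {
  m <- synthetic_montage(6)
  e <- erp_epoch(matrix(rnorm(6 * 4), 6), fs = 100)
  expect_error(spline_interpolate(e, m, 1:3), "good channels")
})

test_that("z-scoring normalizes per channel and round-trips", {
  ds <- tiny_dataset(n_trials = 6, seed = 3)
  ds$data[, 2, ] <- ds$data[, 2, ] * 2 + 10   # mean 10, SD 2 channel
  z <- zscore(ds)
  for (ch in 1:8) {
    expect_equal(mean(z$dataset$data[, ch, ]), 0, tolerance = 1e-10)
    expect_equal(sd(as.vector(z$dataset$data[, ch, ])), 1,
                 tolerance = 1e-10)
  }
  back <- zscore_invert(z$dataset, z$params)
  expect_lt(max(abs(back$data - ds$data)), 1e-6)
  # already standardized data: parameters ~ (0, 1), data unchanged
  z2 <- zscore(z$dataset)
  expect_equal(z2$params$mean, rep(0, 8), tolerance = 1e-10)
  expect_equal(z2$params$sd, rep(1, 8), tolerance = 1e-10)
  expect_lt(max(abs(z2$dataset$data - z$dataset$data)), 1e-6)
  # zero-variance channel is named in the error
  ds$data[, 3, ] <- 0
  err <- tryCatch(zscore_fit(ds), error = identity)
  expect_s3_class(err, "parameter_error")
  expect_match(conditionMessage(err), "3")
})

test_that("train_split partitions reproducibly with round-half-even size", {
  ds <- tiny_dataset(n_trials = 10)
  sp <- train_split(ds, 0.8, seed = 9)
  expect_equal(n_trials(sp$train), 8)
  expect_equal(n_trials(sp$holdout), 2)
  ids <- c(sp$train$meta$stimulus_id, sp$holdout$meta$stimulus_id)
  expect_setequal(ids, ds$meta$stimulus_id)
  sp2 <- train_split(ds, 0.8, seed = 9)
  expect_identical(sp$train$meta, sp2$train$meta)
})
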
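test_that("window-to-sample mapping follows the half-open convention", {
  # 400-800 ms at 500 Hz, t0 = -0.1 s: 0-based samples 250..449
  idx <- window_to_samples(c(400, 800), 500, -0.1, 750)
  expect_equal(idx, (250:449) + 1L)
  expect_length(idx, 200)
  # 0.1 s pre + 1.4 s post at 500 Hz spans exactly 750 samples
  expect_equal(window_to_samples(c(-100, 1400), 500, -0.1, 750),
               1:750)
  expect_error(window_to_samples(c(1300, 1600), 500, -0.1, 750),
               "outside")
})

test_that("correlation maps hit the self- and anti-correlation anchors", {
  ds <- tiny_dataset(n_trials = 6, n_subjects = 3, seed = 21)
  avg <- average_by(ds)
  cm <- correlation_map(avg, avg)
  expect_true(all(abs(cm$r - 1) < 1e-12, na.rm = TRUE))
  neg <- avg; neg$data <- -avg$data
  cmn <- correlation_map(avg, neg)
  expect_true(all(abs(cmn$r + 1) < 1e-12, na.rm = TRUE))
  expect_true(all(cm$p >= 0 & cm$p <= 1, na.rm = TRUE))
  # symmetry of r in the arguments
  b <- avg; b$data <- avg$data + array(rnorm(length(avg$data), sd = 0.3),
                                       dim(avg$data))
  expect_equal(correlation_map(avg, b)$r, correlation_map(b, avg)$r)
})

test_that("correlation decays monotonically with added noise", {
  set.seed(33)
  ds <- tiny_dataset(n_trials = 40, n_channels = 4, n_samples = 10,
                     n_subjects = 20, seed = 33)
  avg <- average_by(ds, "subject")
  means <- sapply(c(0.2, 1, 5), function(sd_) {
    noisy <- avg
    noisy$data <- avg$data + array(rnorm(length(avg$data), sd = sd_),
                                   dim(avg$data))
    mean(correlation_map(avg, noisy, "subject")$r, na.rm = TRUE)
  })
  expect_true(all(diff(means) < 0))
})

test_that("pairing failures raise a pairing error", {
  ds <- tiny_dataset(n_trials = 6, n_subjects = 3, seed = 2)
  avg <- average_by(ds)
  other <- subset_trials(avg, 1:(n_trials(avg) - 1))
  expect_s3_class(tryCatch(correlation_map(avg, other), error = identity),
                  "pairing_error")
})

test_that("component scores are windowed means with linearity", {
  ds <- tiny_dataset(n_trials = 4, n_channels = 8, n_samples = 30,
                     fs = 20, seed = 5)
  ds$data[] <- 2.5   # constant epochs score the constant, any window
  sc <- score_component(ds, channel = 3, window_ms = c(400, 800))
  expect_true(all(sc$score == 2.5))
  # linearity: score(a + b) = score(a) + score(b)
  a <- tiny_dataset(n_trials = 4, seed = 6)
  b <- tiny_dataset(n_trials = 4, seed = 7)
  ab <- a; ab$data <- a$data + b$data
  sa <- score_component(a, 2, c(200, 600))
  sb <- score_component(b, 2, c(200, 600))
  sab <- score_component(ab, 2, c(200, 600))
  expect_equal(sab$score, sa$score + sb$score)
  expect_error(score_component(a, 2, c(5000, 6000)), "outside")
})

test_that("scores on a simulated fixture match the analytic ground truth", {
  spec <- synthetic_spec(n_subjects = 3, noise_sd = 0.05, seed = 11)
  ds <- simulate_dataset(spec, desk_stimuli(10))
  gt <- ground_truth(spec)
  for (s in 1:3) {
    ch <- gt$channel[gt$subject == s][1]
    sc <- score_component(ds, ch, c(400, 800))
    for (cond in c("pleasant", "neutral", "unpleasant")) {
      got <- sc$score[sc$subject == s & sc$condition == cond]
      want <- gt$score[gt$subject == s & gt$condition == cond]
      # noise SD 0.05 over 40 window samples x 10 trials
      expect_equal(got, want, tolerance = 0.02)
    }
  }
})

test_that("v_pattern computes the emotional-minus-neutral contrast", {
  sc <- data.frame(subject = rep(1:2, each = 3),
                   condition = rep(c("pleasant", "neutral", "unpleasant"),
                                   2),
                   score = c(1.5, 1.0, 1.5, 2, 2, 2))
  v <- v_pattern(sc)
  expect_equal(unname(v), c(0.5, 0))
  # shift invariance
  sc2 <- sc; sc2$score <- sc$score + 7
  expect_equal(v_pattern(sc2), v)
  err <- tryCatch(v_pattern(sc[-2, ]), error = identity)
  expect_s3_class(err, "missing_condition_error")
  expect_match(conditionMessage(err), "neutral")
})

test_that("score-rating correlation recovers known relationships", {
  set.seed(17)
  scores <- stats::setNames(rnorm(50), sprintf("s%02d", 1:50))
  self <- amplitude_rating_correlation(scores, scores)
  expect_equal(self$r, 1)
  # permutation null: independent ratings give |r| near 0
  null_r <- replicate(200, {
    amplitude_rating_correlation(scores,
                                 stats::setNames(sample(scores),
                                                 names(scores)))$r
  })
  expect_lt(mean(abs(null_r) < 2 / sqrt(50)), 1.01)  # sanity on scale
  expect_gt(mean(abs(null_r) < 0.28), 0.9)
  # injected linear relation with noise recovers the population r
  n <- 500
  ratings <- stats::setNames(rnorm(n), sprintf("r%03d", 1:n))
  pop_r <- 0.6
  y <- pop_r * ratings + sqrt(1 - pop_r^2) * rnorm(n)
  got <- amplitude_rating_correlation(stats::setNames(y, names(ratings)),
                                      ratings)
  expect_equal(got$r, pop_r, tolerance = 0.1)
  expect_error(amplitude_rating_correlation(scores[1:2], scores[1:2]),
               "3 paired")
})

test_that("latent decoding separates separable clusters and respects the null", {
  set.seed(23)
  n_per <- 40
  centers <- rbind(c(5, 0, 0), c(0, 5, 0), c(0, 0, 5))
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(n_per * 3, sd = 0.3), n_per), 2, centers[k, ], "+")))
  y <- rep(c("pleasant", "neutral", "unpleasant"), each = n_per)
  acc <- latent_decode(X, y, seed = 3)
  expect_equal(unname(acc), 1.0)
  # permuted labels: inside the binomial null band around 1/3 (n = 120)
  accp <- latent_decode(X, sample(y), seed = 3)
  expect_gte(unname(accp), 0.2)
  expect_lte(unname(accp), 0.47)
  expect_lte(max(acc), 1.0)
  expect_error(latent_decode(X[1:7, ], y[c(1:4, 41:43)], folds = 5),
               "fewer trials")
})

test_that("2-D projection is deterministic with matching row count", {
  set.seed(29)
  X <- matrix(rnorm(40 * 6), 40)
  p1 <- project_2d(X, seed = 1)
  expect_equal(dim(p1), c(40, 2))
  expect_identical(project_2d(X, seed = 1), p1)
  # duplicated points land on coincident coordinates
  Xd <- rbind(X[1:5, ], X[1:5, ])
  pd <- project_2d(Xd)
  expect_lt(max(abs(pd[1:5, ] - pd[6:10, ])), 1e-10)
  expect_error(project_2d(X[1:3, ]), "at least 5")
})
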
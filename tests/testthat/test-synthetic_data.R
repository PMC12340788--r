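test_that("the simulator produces one epoch per (subject, stimulus)", {
  spec <- synthetic_spec(n_subjects = 3, n_channels = 8, n_samples = 30,
                         fs = 20, noise_sd = 0.1, seed = 2)
  stim <- data.frame(stimulus_id = c("a", "b", "c", "d"),
                     condition = c("pleasant", "neutral", "unpleasant",
                                   "neutral"))
  ds <- simulate_dataset(spec, stim)
  expect_equal(n_trials(ds), 12)
  expect_equal(ds$meta$subject_id, rep(1:3, each = 4))  # subject-major
  expect_equal(unique(ds$meta$stimulus_id), c("a", "b", "c", "d"))
  # same seed, bit-identical; different seed, different noise
  ds2 <- simulate_dataset(spec, stim)
  expect_identical(ds$data, ds2$data)
  spec3 <- synthetic_spec(n_subjects = 3, n_channels = 8, n_samples = 30,
                          fs = 20, noise_sd = 0.1, seed = 3)
  expect_false(identical(simulate_dataset(spec3, stim)$data, ds$data))
})

test_that("without condition effects or noise, conditions are identical", {
  spec <- synthetic_spec(n_subjects = 1, n_channels = 8, n_samples = 30,
                         fs = 20, noise_sd = 0,
                         condition_effects = c(pleasant = 1, neutral = 1,
                                               unpleasant = 1))
  ds <- simulate_dataset(spec, data.frame(
    stimulus_id = c("p", "n", "u"),
    condition = c("pleasant", "neutral", "unpleasant")))
  expect_equal(ds$data[1, , ], ds$data[2, , ])
  expect_equal(ds$data[1, , ], ds$data[3, , ])
})

test_that("the LPP window mean scales exactly with the condition multiplier", {
  spec <- synthetic_spec(n_subjects = 2, noise_sd = 0, subject_effect_sd = 0,
                         condition_effects = c(pleasant = 1.5, neutral = 1.0,
                                               unpleasant = 1.5))
  ds <- simulate_dataset(spec, data.frame(
    stimulus_id = c("p", "n"), condition = c("pleasant", "neutral")))
  gt <- ground_truth(spec)
  for (s in 1:2) {
    ch <- gt$channel[gt$subject == s][1]
    win <- window_to_samples(c(400, 800), spec$fs, spec$t0, spec$n_samples)
    pleasant <- mean(ds$data[ds$meta$subject_id == s &
                               ds$meta$condition == "pleasant", ch, ][win])
    neutral <- mean(ds$data[ds$meta$subject_id == s &
                              ds$meta$condition == "neutral", ch, ][win])
    expect_equal(pleasant, 1.5 * neutral, tolerance = 1e-12)
  }
})

test_that("empirical LPP window means match ground truth as noise vanishes", {
  spec <- synthetic_spec(n_subjects = 3, noise_sd = 0)
  ds <- simulate_dataset(spec, data.frame(
    stimulus_id = c("p", "n", "u"),
    condition = c("pleasant", "neutral", "unpleasant")))
  gt <- ground_truth(spec)
  win <- window_to_samples(c(400, 800), spec$fs, spec$t0, spec$n_samples)
  for (r in seq_len(nrow(gt))) {
    sel <- ds$meta$subject_id == gt$subject[r] &
      ds$meta$condition == gt$condition[r]
    emp <- mean(ds$data[sel, gt$channel[r], ][win])
    expect_lt(abs(emp - gt$score[r]), 1e-6)
  }
})

test_that("ground truth encodes the V-pattern algebra", {
  spec <- synthetic_spec(n_subjects = 4, noise_sd = 0,
                         condition_effects = c(pleasant = 1.5, neutral = 1.0,
                                               unpleasant = 1.5))
  gt <- ground_truth(spec)
  for (s in 1:4) {
    g <- gt[gt$subject == s, ]
    v <- (g$score[g$condition == "pleasant"] +
            g$score[g$condition == "unpleasant"]) / 2 -
      g$score[g$condition == "neutral"]
    expect_equal(v, 0.5 * g$lpp_only[g$condition == "neutral"],
                 tolerance = 1e-10)
  }
  # no subject effect: identical truth across subjects
  spec0 <- synthetic_spec(n_subjects = 3, subject_effect_sd = 0,
                          subject_topo_jitter = 0, noise_sd = 0)
  gt0 <- ground_truth(spec0)
  neutral <- gt0$score[gt0$condition == "neutral"]
  expect_equal(max(neutral) - min(neutral), 0, tolerance = 1e-12)
  # zero-amplitude LPP: all scores 0 (other components never reach 400 ms)
  specz <- synthetic_spec(components = list(
    erp_component("P100", 100, 15, 1, "Oz"),
    erp_component("LPP", 600, 120, 0, "Pz", modulated = TRUE)),
    noise_sd = 0)
  expect_equal(max(abs(ground_truth(specz)$score)), 0)
})

test_that("component latencies outside the epoch are rejected", {
  expect_error(synthetic_spec(components = list(
    erp_component("late", 2000, 50, 1, "Pz", TRUE))), "outside epoch")
  expect_error(synthetic_spec(condition_effects = c(pleasant = -1,
                                                    neutral = 1,
                                                    unpleasant = 1)),
               "positive")
})

test_that("mock embeddings are unit-norm, class-structured, deterministic", {
  spec <- mock_embedding_spec(n_classes = 2, within_class_sd = 0,
                              seed = 5)
  stim <- data.frame(stimulus_id = c("a", "b", "c"), class = c(0, 0, 1))
  embs <- simulate_embeddings(spec, stim)
  expect_length(embs[[1]]$vector, 512)
  norms <- sapply(embs, function(e) sqrt(sum(e$vector^2)))
  expect_lt(max(abs(norms - 1)), 1e-6)
  # zero within-class spread: same-class embeddings identical
  expect_equal(embs[[1]]$vector, embs[[2]]$vector)
  expect_false(isTRUE(all.equal(embs[[1]]$vector, embs[[3]]$vector)))
  # determinism of the encoder
  expect_identical(mock_encode("a", 0, spec)$vector, embs[[1]]$vector)
})

test_that("well-separated mock classes are perfectly classifiable", {
  spec <- mock_embedding_spec(n_classes = 2, class_separation = 1,
                              within_class_sd = 0.01, seed = 6)
  stim <- data.frame(stimulus_id = sprintf("s%02d", 1:40),
                     class = rep(0:1, 20))
  embs <- simulate_embeddings(spec, stim)
  X <- do.call(rbind, lapply(embs, function(e) e$vector))
  ctr <- rbind(colMeans(X[stim$class == 0, ]), colMeans(X[stim$class == 1, ]))
  pred <- apply(X, 1, function(v)
    which.min(colSums((t(ctr) - v)^2)) - 1L)
  expect_equal(mean(pred == stim$class), 1.0)   # brute-force oracle
  expect_error(mock_encode("a", 7, spec), "outside")
})
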
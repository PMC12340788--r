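# Heavy shared fixtures for the acceptance blocks: the desk-profile
# parameter-recovery benchmark (minutes of training) and a miniature
# 88-subject pipeline for full-scale trial counts.  Each is computed once
# per test session.

.recovery_cache <- new.env(parent = emptyenv())

recovery_fixture <- function() {
  if (is.null(.recovery_cache$run))
    .recovery_cache$run <- recovery_benchmark(seed = 20260901)
  .recovery_cache$run
}

# Miniature (8 ch x 15 samples) trained pipeline with an 88-subject
# registry, for exercising full-scale trial counts at desk cost.
tiny88_models <- function(seed = 5) {
  spec <- synthetic_spec(n_subjects = 88, n_channels = 8, n_samples = 15,
                         fs = 10,
                         components = list(
                           erp_component("P1", 200, 120, 1, "Oz"),
                           erp_component("LPP", 600, 200, 1, "Pz",
                                         modulated = TRUE)),
                         noise_sd = 0.1, seed = seed)
  ds <- simulate_dataset(spec, data.frame(
    stimulus_id = c("w1", "w2"), condition = c("pleasant", "neutral")))
  z <- zscore(ds)
  cfg <- cvae_config(8, 15, 88, latent_dim = 4, conv_channels = c(2, 3, 4),
                     decoder_hidden = 8, beta = 1e-3, anneal_midpoint = 2,
                     lr = 1e-3, batch_size = 64, epochs = 2)
  cvae <- train_cvae(z$dataset, cfg, seed = seed, norm = z$params)
  cvae$signal <- list(fs = ds$fs, t0 = ds$t0, montage = ds$montage,
                      subjects = ds$subjects)
  espec <- mock_embedding_spec(seed = seed)
  mu <- encode_dataset(cvae, z$dataset)
  embs <- lapply(seq_len(n_trials(ds)), function(i)
    mock_encode(ds$meta$stimulus_id[i], NULL, espec))
  bcfg <- bridge_config(88, 4, hidden = c(16, 8), max_epochs = 2)
  bridge <- train_bridge(embs, ds$meta$subject_id, mu, bcfg, seed = seed)
  list(encoder = mock_encoder(espec), bridge = bridge, cvae = cvae)
}

.tiny88_cache <- new.env(parent = emptyenv())

tiny88_fixture <- function() {
  if (is.null(.tiny88_cache$models))
    .tiny88_cache$models <- tiny88_models()
  .tiny88_cache$models
}
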
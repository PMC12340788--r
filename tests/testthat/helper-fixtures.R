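# Shared fixture builders.  Everything is generated in code; sizes are kept
# small so the whole suite runs quickly on one CPU.

tiny_montage <- function(n = 8) synthetic_montage(n)

tiny_dataset <- function(n_trials = 4, n_channels = 8, n_samples = 30,
                         fs = 20, n_subjects = 2, seed = 1) {
  set.seed(seed)
  data <- array(rnorm(n_trials * n_channels * n_samples),
                c(n_trials, n_channels, n_samples))
  meta <- data.frame(
    subject_id = rep_len(seq_len(n_subjects), n_trials),
    condition = rep_len(c("pleasant", "neutral", "unpleasant"), n_trials),
    stimulus_id = sprintf("stim%02d", seq_len(n_trials)),
    modality = "synthetic", stringsAsFactors = FALSE)
  erp_dataset(data, meta, fs, -0.1, tiny_montage(n_channels),
              subject_registry(sprintf("S%d", seq_len(n_subjects))))
}

# Standard desk-profile stimulus set: n_per_cond per affective category,
# classes 0/1/2 for the mock encoder.
desk_stimuli <- function(n_per_cond = 20) {
  conds <- c("pleasant", "neutral", "unpleasant")
  data.frame(
    stimulus_id = sprintf("%s%03d", rep(substr(conds, 1, 1),
                                        each = n_per_cond),
                          seq_len(n_per_cond)),
    condition = rep(conds, each = n_per_cond),
    class = rep(0:2, each = n_per_cond),
    stringsAsFactors = FALSE)
}

tiny_cvae_config <- function(...) {
  args <- utils::modifyList(
    list(n_channels = 8, n_samples = 20, n_subjects = 2,
         latent_dim = 4, conv_channels = c(2, 3, 4),
         decoder_hidden = 8, beta = 1e-3, anneal_midpoint = 5,
         lr = 1e-3, batch_size = 4, epochs = 3),
    list(...))
  do.call(cvae_config, args)
}
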
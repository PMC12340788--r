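test_that("encoder flatten length follows the conv shape arithmetic", {
  # desk: 32x150 with channels 8/16/32 -> 32 * 4 * 19 = 2432
  desk <- cvae_config(32, 150, 6, latent_dim = 32,
                      conv_channels = c(8, 16, 32))
  expect_equal(encoder_flatten_length(desk), 32 * 4 * 19)
  # per-stage oracle: floor((n + 2p - k)/s) + 1 applied three times
  oracle <- function(n) { for (i in 1:3) n <- floor((n + 2 - 3) / 2) + 1; n }
  expect_equal(encoder_flatten_length(desk), 32 * oracle(32) * oracle(150))
  expect_error(cvae_config(32, 150, 6, latent_dim = 0), "latent_dim")
  expect_error(cvae_config(32, 150, 6, latent_dim = 4, beta = 0), "beta")
})

test_that("kl_loss matches closed form and numerical integration", {
  # prior == posterior
  expect_equal(kl_loss(latent_code(0, 0)), 0)
  # hand-evaluated cases
  expect_equal(kl_loss(latent_code(1, 0)), 0.5)
  expect_equal(kl_loss(latent_code(0, log(2))), (1 - log(2)) / 2,
               tolerance = 1e-12)
  # numerical integration oracle over 50 random (mu, sigma)
  set.seed(8)
  for (i in 1:50) {
    mu <- rnorm(1); sigma <- runif(1, 0.3, 3)
    num <- integrate(function(x) {
      q <- dnorm(x, mu, sigma)
      ifelse(q > 0, q * (dnorm(x, mu, sigma, log = TRUE) -
                           dnorm(x, log = TRUE)), 0)
    }, -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(kl_loss(latent_code(mu, log(sigma^2))), num,
                 tolerance = 1e-6)
  }
  # batch averaging over columns
  mu <- cbind(c(1, 0), c(0, 0)); lv <- matrix(0, 2, 2)
  expect_equal(kl_loss(mu, lv), 0.25)
  expect_error(kl_loss(latent_code(c(1, Inf), c(0, 0))), "non-finite")
})

test_that("recon_loss equals a brute-force accumulator", {
  set.seed(9)
  x <- matrix(rnorm(40), 5); y <- matrix(rnorm(40), 5)
  acc <- 0
  for (i in seq_along(x)) acc <- acc + (x[i] - y[i])^2
  expect_equal(recon_loss(x, y), acc / length(x))
  expect_equal(recon_loss(x, x), 0)
  expect_equal(recon_loss(x, x + 3), 9)
  expect_error(recon_loss(x, matrix(0, 2, 2)), "shapes differ")
})

test_that("anneal weight follows the sigmoid schedule and saturates", {
  cfg <- cvae_config(129, 750, 88)   # beta 1e-5, slope 0.5, midpoint 100
  expect_equal(anneal_weight(100, cfg), 5e-6)
  expect_equal(anneal_weight(0, cfg), 1e-5 / (1 + exp(50)))
  expect_lt(abs(anneal_weight(1300, cfg) - 1e-5), 1e-12)
  w <- sapply(0:2000, anneal_weight, cfg = cfg)
  expect_true(all(diff(w) >= 0))
  expect_true(all(w <= cfg$beta + 1e-15))
})

test_that("reparameterization reproduces z = mu + sigma * epsilon", {
  code <- latent_code(mu = c(1, -2), logvar = c(0, log(4)))
  r <- reparameterize(code, seed = 11)
  expect_equal(r$z, r$mu + exp(r$logvar / 2) * r$epsilon)
  # degenerate variance collapses to the mean
  tiny <- reparameterize(latent_code(c(3, 3), c(-50, -50)), seed = 1)
  expect_lt(max(abs(tiny$z - 3)), 1e-10)
  # same seed, same draw
  expect_identical(reparameterize(code, seed = 11)$z, r$z)
  # standard-normal statistics at mu = 0, logvar = 0
  big <- reparameterize(latent_code(numeric(1e4), numeric(1e4)), seed = 2)
  expect_lt(abs(mean(big$z)), 0.05)
  expect_lt(abs(sd(big$z) - 1), 0.05)
})

test_that("encode/decode respect the shape contract and determinism", {
  cfg <- tiny_cvae_config()
  model <- cvae_init(cfg, seed = 21)
  x <- matrix(rnorm(8 * 20), 8)
  s <- one_hot(subject_registry(c("a", "b")), 2)
  code <- encode(model, x, s)
  expect_length(code$mu, 4)
  expect_length(code$logvar, 4)
  expect_identical(encode(model, x, s)$mu, code$mu)
  out <- decode(model, code$mu, s)
  expect_equal(dim(out), c(8, 20))
  expect_identical(decode(model, code$mu, s), out)
  err <- tryCatch(encode(model, matrix(0, 3, 3), s), error = identity)
  expect_s3_class(err, "dimension_error")
  expect_match(conditionMessage(err), "8 x 20")
  expect_s3_class(tryCatch(decode(model, numeric(3), s), error = identity),
                  "dimension_error")
})

test_that("decode inverts encode shapes across a randomized config sweep", {
  set.seed(13)
  for (i in 1:6) {
    nch <- sample(10:40, 1); nsm <- sample(20:80, 1)
    cfg <- cvae_config(nch, nsm, 3, latent_dim = 5,
                       conv_channels = c(2, 3, 4), decoder_hidden = 8)
    model <- cvae_init(cfg, seed = i)
    x <- matrix(rnorm(nch * nsm), nch)
    s <- c(1, 0, 0)
    out <- decode(model, encode(model, x, s)$mu, s)
    expect_equal(dim(out), dim(x))
  }
})

test_that("a short training run reduces loss, is seeded, and anneals KL", {
  ds <- tiny_dataset(n_trials = 24, n_channels = 8, n_samples = 20,
                     n_subjects = 2, seed = 31)
  cfg <- tiny_cvae_config(epochs = 8)
  m1 <- train_cvae(ds, cfg, seed = 5)
  m2 <- train_cvae(ds, cfg, seed = 5)
  expect_identical(m1$params, m2$params)         # bit-reproducible
  expect_identical(m1$report, m2$report)
  m3 <- train_cvae(ds, cfg, seed = 6)
  expect_false(identical(m1$params, m3$params))  # seed matters
  expect_lt(m1$report$recon[8], m1$report$recon[1])
  # KL weight sequence nondecreasing and bounded by beta
  expect_true(all(diff(m1$report$kl_weight) >= 0))
  expect_true(all(m1$report$kl_weight <= cfg$beta))
  expect_true(all(is.finite(m1$report$total)))
})

test_that("training on low-noise data cuts reconstruction loss below 25%", {
  spec <- synthetic_spec(n_subjects = 2, n_channels = 8, n_samples = 20,
                         fs = 20,
                         components = list(
                           erp_component("P1", 150, 60, 1, "Oz"),
                           erp_component("LPP", 600, 150, 1, "Pz",
                                         modulated = TRUE)),
                         noise_sd = 0.02, seed = 3)
  stim <- data.frame(stimulus_id = sprintf("s%02d", 1:12),
                     condition = rep(c("pleasant", "neutral", "unpleasant"),
                                     4))
  z <- zscore(simulate_dataset(spec, stim))
  cfg <- cvae_config(8, 20, 2, latent_dim = 8, conv_channels = c(4, 6, 8),
                     decoder_hidden = 32, beta = 1e-4,
                     anneal_midpoint = 50, lr = 2e-3, batch_size = 8,
                     epochs = 200)
  m <- train_cvae(z$dataset, cfg, seed = 2)
  expect_lt(m$report$recon[cfg$epochs], 0.25 * m$report$recon[1])
  # annealing disabled contributes nothing: with beta ~ 0 the weighted KL
  # term is numerically zero in the total
  expect_equal(m$report$total, m$report$recon + m$report$kl_weight *
                 m$report$kl)
})

test_that("checkpoints round-trip through save_model/load_model", {
  ds <- tiny_dataset(n_trials = 8, seed = 41)
  ds2 <- tiny_dataset(n_trials = 8, n_channels = 8, n_samples = 20,
                      seed = 41)
  cfg <- tiny_cvae_config(epochs = 2)
  m <- train_cvae(ds2, cfg, seed = 1)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$cfg, m$cfg)
  expect_error(load_model(tempfile()), "not found")
})
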
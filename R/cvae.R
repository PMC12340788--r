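#' Conditioned VAE configuration
#'
#' Architecture and training hyperparameters of the convolutional cVAE.
#' Three stride-2, kernel-3, pad-1 convolution stages run over the
#' channel-by-time grid; the flattened features are concatenated with the
#' subject one-hot and mapped by two parallel dense heads to the latent mean
#' and log-variance.  The decoder mirrors this with two dense layers and
#' three transposed convolutions whose per-axis output padding is computed
#' automatically so decoder output exactly matches the input shape.  At full
#' scale (129 channels x 750 samples, conv channels 32/64/128) the flattened
#' feature length is 204,544.
#'
#' @param n_channels,n_samples input ERP matrix shape.
#' @param n_subjects length of the subject one-hot conditioning vector.
#' @param latent_dim latent dimensionality (256 at full scale).
#' @param conv_channels output channels of the three conv stages.
#' @param decoder_hidden width of the first decoder dense layer.
#' @param beta KL scale (1e-5 at full scale).
#' @param anneal_slope,anneal_midpoint sigmoid annealing schedule parameters
#'   (0.5 and 100).
#' @param lr Adam learning rate (1e-6 at full scale).
#' @param batch_size minibatch size (64).
#' @param epochs training epochs.
#' @param kernel,stride,pad convolution geometry (3 / 2 / 1).
#' @return a `cvae_config`.
#' @export
cvae_config <- function(n_channels, n_samples, n_subjects,
                        latent_dim = 256L,
                        conv_channels = c(32L, 64L, 128L),
                        decoder_hidden = 1024L,
                        beta = 1e-5, anneal_slope = 0.5,
                        anneal_midpoint = 100,
                        lr = 1e-6, batch_size = 64L, epochs = 1300L,
                        kernel = 3L, stride = 2L, pad = 1L) {
  assert_that(latent_dim >= 1, "config_error", "latent_dim must be >= 1")
  assert_that(beta > 0, "config_error", "beta must be > 0")
  assert_that(length(conv_channels) == 3, "config_error",
              "exactly three convolution stages are supported")
  cfg <- structure(list(
    n_channels = as.integer(n_channels), n_samples = as.integer(n_samples),
    n_subjects = as.integer(n_subjects), latent_dim = as.integer(latent_dim),
    conv_channels = as.integer(conv_channels),
    decoder_hidden = as.integer(decoder_hidden),
    beta = beta, anneal_slope = anneal_slope,
    anneal_midpoint = anneal_midpoint, lr = lr,
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    kernel = as.integer(kernel), stride = as.integer(stride),
    pad = as.integer(pad)), class = "cvae_config")
  sh <- cvae_shapes(cfg)
  assert_that(all(unlist(sh) >= 1), "config_error",
              "convolution stages collapse the input below 1 sample")
  cfg
}

# Spatial shape after each encoder stage, and the flatten length.
cvae_shapes <- function(cfg) {
  h <- cfg$n_channels; w <- cfg$n_samples
  hs <- integer(3); ws <- integer(3)
  for (i in 1:3) {
    h <- conv_out_len(h, cfg$kernel, cfg$stride, cfg$pad)
    w <- conv_out_len(w, cfg$kernel, cfg$stride, cfg$pad)
    hs[i] <- h; ws[i] <- w
  }
  list(h = hs, w = ws,
       flatten = as.integer(cfg$conv_channels[3] * hs[3] * ws[3]))
}

#' Encoder flatten length
#'
#' Pure shape arithmetic: the length of the flattened feature vector after
#' the three stride-2 convolution stages.
#'
#' @param cfg a [cvae_config()].
#' @return integer flatten length (204,544 for the full-scale configuration).
#' @export
encoder_flatten_length <- function(cfg) cvae_shapes(cfg)$flatten

#' KL annealing weight
#'
#' Sigmoid schedule `beta / (1 + exp(-slope * (epoch - midpoint)))`: near 0
#' for early epochs, `beta/2` at the midpoint epoch, saturating at `beta`.
#' Gradually admitting the KL term lets reconstruction organize the latent
#' space before the Gaussian prior is enforced, protecting against posterior
#' collapse.
#'
#' @param epoch epoch number (>= 0).
#' @param cfg a [cvae_config()] providing `beta`, `anneal_slope`,
#'   `anneal_midpoint`.
#' @return scalar KL weight.
#' @export
anneal_weight <- function(epoch, cfg) {
  cfg$beta / (1 + exp(-cfg$anneal_slope * (epoch - cfg$anneal_midpoint)))
}

#' Gaussian KL divergence loss
#'
#' `-1/2 * sum(1 + log sigma^2 - mu^2 - sigma^2)` over latent dimensions,
#' averaged over the batch: the divergence of the approximate posterior
#' `N(mu, sigma^2)` from the standard-normal prior.
#'
#' @param code a `latent_code`, or a numeric matrix/vector of means.
#' @param logvar log-variances matching `code` when `code` is numeric.
#' @return scalar KL loss (always >= 0).
#' @export
kl_loss <- function(code, logvar = NULL) {
  if (inherits(code, "latent_code")) {
    mu <- code$mu; logvar <- code$logvar
  } else mu <- code
  assert_that(all(is.finite(mu)) && all(is.finite(logvar)), "numeric_error",
              "non-finite latent parameters")
  mu <- as.matrix(mu); logvar <- as.matrix(logvar)
  mean(colSums(-0.5 * (1 + logvar - mu^2 - exp(logvar))))
}

#' Mean-squared-error reconstruction loss
#'
#' @param x,x_hat numeric arrays of identical shape.
#' @return mean of squared elementwise differences.
#' @export
recon_loss <- function(x, x_hat) {
  assert_that(identical(dim(x) %||% length(x), dim(x_hat) %||% length(x_hat)),
              "dimension_error", "x and x_hat shapes differ")
  mean((x - x_hat)^2)
}

#' Latent code
#'
#' Mean and log-variance of the electrophysiological latent posterior; the
#' paper-level standard deviation is `exp(logvar / 2)`.  `z` and `epsilon`
#' are populated by [reparameterize()].
#'
#' @param mu,logvar numeric vectors of latent dimension.
#' @param z,epsilon optional sampled draw and its standard-normal noise.
#' @return a `latent_code`.
#' @export
latent_code <- function(mu, logvar, z = NULL, epsilon = NULL) {
  assert_that(length(mu) == length(logvar), "dimension_error",
              "mu and logvar lengths differ")
  structure(list(mu = mu, logvar = logvar, z = z, epsilon = epsilon),
            class = "latent_code")
}

#' Reparameterization trick
#'
#' Samples `z = mu + exp(logvar/2) * epsilon` with `epsilon ~ N(0, I)`,
#' recording `epsilon` so the draw is fully reproducible.
#'
#' @param code a `latent_code` with `mu` and `logvar` set.
#' @param seed optional integer seed for the standard-normal draw.
#' @return the code with `z` and `epsilon` filled in.
#' @export
reparameterize <- function(code, seed = NULL) {
  stopifnot(inherits(code, "latent_code"))
  eps <- if (is.null(seed)) stats::rnorm(length(code$mu))
    else with_seed(seed, stats::rnorm(length(code$mu)))
  code$epsilon <- eps
  code$z <- code$mu + exp(code$logvar / 2) * eps
  code
}

# ---- model construction -------------------------------------------------

cvae_geoms <- function(cfg) {
  sh <- cvae_shapes(cfg)
  k <- cfg$kernel; s <- cfg$stride; p <- cfg$pad
  enc <- list(
    conv_geom(1L, cfg$n_channels, cfg$n_samples, k, s, c(p, p), c(p, p)),
    conv_geom(cfg$conv_channels[1], sh$h[1], sh$w[1], k, s, c(p, p), c(p, p)),
    conv_geom(cfg$conv_channels[2], sh$h[2], sh$w[2], k, s, c(p, p), c(p, p)))
  # transposed stages are exact adjoints of the encoder stages, so decoder
  # output shapes invert encoder shapes by construction
  dec <- list(
    tconv_geom(cfg$conv_channels[3], cfg$conv_channels[2], sh$h[3], sh$w[3],
               k, s, p, sh$h[2], sh$w[2]),
    tconv_geom(cfg$conv_channels[2], cfg$conv_channels[1], sh$h[2], sh$w[2],
               k, s, p, sh$h[1], sh$w[1]),
    tconv_geom(cfg$conv_channels[1], 1L, sh$h[1], sh$w[1],
               k, s, p, cfg$n_channels, cfg$n_samples))
  list(enc = enc, dec = dec, shapes = sh)
}

#' Initialize an untrained cVAE model
#'
#' @param cfg a [cvae_config()].
#' @param seed integer seed for weight initialization.
#' @return a `cvae_model` (config, geometry, named weight arrays).
#' @export
cvae_init <- function(cfg, seed = 1L) {
  g <- cvae_geoms(cfg)
  cc <- cfg$conv_channels
  k2 <- cfg$kernel^2
  flat <- g$shapes$flatten
  params <- with_seed(seed, {
    p <- list(
      enc_conv1_W = init_weight(cc[1], 1 * k2),
      enc_conv1_b = numeric(cc[1]),
      enc_conv2_W = init_weight(cc[2], cc[1] * k2),
      enc_conv2_b = numeric(cc[2]),
      enc_conv3_W = init_weight(cc[3], cc[2] * k2),
      enc_conv3_b = numeric(cc[3]),
      enc_mu_W = init_weight(cfg$latent_dim, flat + cfg$n_subjects),
      enc_mu_b = numeric(cfg$latent_dim),
      enc_lv_W = init_weight(cfg$latent_dim, flat + cfg$n_subjects) * 0.01,
      enc_lv_b = numeric(cfg$latent_dim),
      dec_fc1_W = init_weight(cfg$decoder_hidden,
                              cfg$latent_dim + cfg$n_subjects),
      dec_fc1_b = numeric(cfg$decoder_hidden),
      dec_fc2_W = init_weight(flat, cfg$decoder_hidden),
      dec_fc2_b = numeric(flat),
      dec_tconv1_W = init_weight(cc[3], cc[2] * k2),
      dec_tconv1_b = numeric(cc[2]),
      dec_tconv2_W = init_weight(cc[2], cc[1] * k2),
      dec_tconv2_b = numeric(cc[1]),
      dec_tconv3_W = init_weight(cc[1], 1L * k2),
      dec_tconv3_b = numeric(1L))
    p
  })
  structure(list(cfg = cfg, geoms = g, params = params, report = NULL,
                 norm = NULL, seed = as.integer(seed)),
            class = "cvae_model")
}

#' @export
print.cvae_model <- function(x, ...) {
  cat(sprintf(
    "<cvae_model> %d ch x %d samples, latent %d, %d subjects, flatten %d%s\n",
    x$cfg$n_channels, x$cfg$n_samples, x$cfg$latent_dim, x$cfg$n_subjects,
    encoder_flatten_length(x$cfg),
    if (is.null(x$report)) " (untrained)" else
      sprintf(", trained %d epochs", nrow(x$report))))
  invisible(x)
}

# Batched encoder forward; x4 is (1, C, S, N), s is (n_subjects x N).
cvae_enc_forward <- function(model, x4, s, keep_cache = FALSE) {
  p <- model$params; g <- model$geoms
  c1 <- conv_forward(x4, p$enc_conv1_W, p$enc_conv1_b, g$enc[[1]])
  r1 <- relu(c1$y)
  c2 <- conv_forward(r1, p$enc_conv2_W, p$enc_conv2_b, g$enc[[2]])
  r2 <- relu(c2$y)
  c3 <- conv_forward(r2, p$enc_conv3_W, p$enc_conv3_b, g$enc[[3]])
  r3 <- relu(c3$y)
  N <- dim(x4)[4]
  f <- rbind(matrix(r3, ncol = N), s)
  mu <- dense_forward(f, p$enc_mu_W, p$enc_mu_b)
  lv <- dense_forward(f, p$enc_lv_W, p$enc_lv_b)
  out <- list(mu = mu, logvar = lv)
  if (keep_cache)
    out$cache <- list(c1 = c1, r1 = r1, c2 = c2, r2 = r2, c3 = c3, r3 = r3,
                      f = f)
  out
}

# Batched decoder forward; z is (latent x N), s is (n_subjects x N).
cvae_dec_forward <- function(model, z, s, keep_cache = FALSE) {
  p <- model$params; g <- model$geoms
  N <- ncol(z)
  d0 <- rbind(z, s)
  a1 <- dense_forward(d0, p$dec_fc1_W, p$dec_fc1_b)
  h1 <- relu(a1)
  a2 <- dense_forward(h1, p$dec_fc2_W, p$dec_fc2_b)
  h2 <- relu(a2)
  sh <- g$shapes
  x3 <- array(h2, c(model$cfg$conv_channels[3], sh$h[3], sh$w[3], N))
  t1 <- tconv_forward(x3, p$dec_tconv1_W, p$dec_tconv1_b, g$dec[[1]])
  u1 <- relu(t1$y)
  t2 <- tconv_forward(u1, p$dec_tconv2_W, p$dec_tconv2_b, g$dec[[2]])
  u2 <- relu(t2$y)
  t3 <- tconv_forward(u2, p$dec_tconv3_W, p$dec_tconv3_b, g$dec[[3]])
  out <- list(xhat = t3$y)
  if (keep_cache)
    out$cache <- list(d0 = d0, a1 = a1, h1 = h1, a2 = a2, x3dim = dim(x3),
                      t1 = t1, u1 = u1, t2 = t2, u2 = u2, t3 = t3)
  out
}

#' Encode an ERP matrix into the latent space
#'
#' Three ReLU convolution stages, flattening, concatenation of the subject
#' one-hot, and the two parallel dense heads.
#'
#' @param model a `cvae_model`.
#' @param x numeric matrix `n_channels x n_samples`.
#' @param s subject one-hot vector of length `n_subjects`.
#' @return a `latent_code` with `mu` and `logvar`.
#' @export
encode <- function(model, x, s) {
  stopifnot(inherits(model, "cvae_model"))
  x <- as.matrix(x)
  assert_that(nrow(x) == model$cfg$n_channels &&
              ncol(x) == model$cfg$n_samples, "dimension_error",
              "expected %d x %d input, received %d x %d",
              model$cfg$n_channels, model$cfg$n_samples, nrow(x), ncol(x))
  assert_that(length(s) == model$cfg$n_subjects, "dimension_error",
              "subject vector has length %d, expected %d", length(s),
              model$cfg$n_subjects)
  fw <- cvae_enc_forward(model, array(x, c(1, dim(x), 1)),
                         matrix(s, ncol = 1))
  latent_code(as.vector(fw$mu), as.vector(fw$logvar))
}

#' Decode a latent vector into an ERP matrix
#'
#' Concatenates the subject one-hot, expands through two dense layers, and
#' applies three transposed-convolution stages; the final activation is
#' linear.  Generation-time decoding uses the latent mean deterministically.
#'
#' @param model a `cvae_model`.
#' @param z_or_mu latent vector of length `latent_dim` (a sampled `z` or a
#'   mean `mu`).
#' @param s subject one-hot vector.
#' @return numeric matrix `n_channels x n_samples`.
#' @export
decode <- function(model, z_or_mu, s) {
  stopifnot(inherits(model, "cvae_model"))
  if (inherits(z_or_mu, "latent_code")) z_or_mu <- z_or_mu$z %||% z_or_mu$mu
  assert_that(length(z_or_mu) == model$cfg$latent_dim, "dimension_error",
              "latent vector has length %d, expected %d", length(z_or_mu),
              model$cfg$latent_dim)
  assert_that(length(s) == model$cfg$n_subjects, "dimension_error",
              "subject vector has length %d, expected %d", length(s),
              model$cfg$n_subjects)
  fw <- cvae_dec_forward(model, matrix(z_or_mu, ncol = 1),
                         matrix(s, ncol = 1))
  matrix(fw$xhat, model$cfg$n_channels, model$cfg$n_samples)
}

# Full backward pass for one minibatch.  Returns gradients for every
# parameter.  dmu/dlv are (latent x N) gradients of the loss w.r.t. the
# encoder heads; dxhat is the gradient w.r.t. the decoder output.
cvae_backward <- function(model, x4, s, enc, dec, eps, dxhat, klw, N) {
  p <- model$params; g <- model$geoms
  gr <- list()
  # decoder
  dy <- dxhat
  bk3 <- tconv_backward(dy, dec$cache$t3$xf, p$dec_tconv3_W, g$dec[[3]])
  gr$dec_tconv3_W <- bk3$dW; gr$dec_tconv3_b <- bk3$db
  dy <- relu_grad(bk3$dx, dec$cache$t2$y)
  bk2 <- tconv_backward(dy, dec$cache$t2$xf, p$dec_tconv2_W, g$dec[[2]])
  gr$dec_tconv2_W <- bk2$dW; gr$dec_tconv2_b <- bk2$db
  dy <- relu_grad(bk2$dx, dec$cache$t1$y)
  bk1 <- tconv_backward(dy, dec$cache$t1$xf, p$dec_tconv1_W, g$dec[[1]])
  gr$dec_tconv1_W <- bk1$dW; gr$dec_tconv1_b <- bk1$db
  dh2 <- relu_grad(matrix(bk1$dx, ncol = N), dec$cache$a2)
  bkf2 <- dense_backward(dh2, dec$cache$h1, p$dec_fc2_W)
  gr$dec_fc2_W <- bkf2$dW; gr$dec_fc2_b <- bkf2$db
  dh1 <- relu_grad(bkf2$dx, dec$cache$a1)
  bkf1 <- dense_backward(dh1, dec$cache$d0, p$dec_fc1_W)
  gr$dec_fc1_W <- bkf1$dW; gr$dec_fc1_b <- bkf1$db
  dz <- bkf1$dx[seq_len(model$cfg$latent_dim), , drop = FALSE]
  # reparameterization + KL
  mu <- enc$mu; lv <- enc$logvar
  dmu <- dz + klw * mu / N
  dlv <- dz * eps * 0.5 * exp(lv / 2) - klw * 0.5 * (1 - exp(lv)) / N
  # encoder heads
  bmu <- dense_backward(dmu, enc$cache$f, p$enc_mu_W)
  gr$enc_mu_W <- bmu$dW; gr$enc_mu_b <- bmu$db
  blv <- dense_backward(dlv, enc$cache$f, p$enc_lv_W)
  gr$enc_lv_W <- blv$dW; gr$enc_lv_b <- blv$db
  df <- bmu$dx + blv$dx
  flat <- model$geoms$shapes$flatten
  dr3 <- array(df[seq_len(flat), , drop = FALSE],
               dim(enc$cache$r3))
  dy <- relu_grad(dr3, enc$cache$c3$y)
  bc3 <- conv_backward(dy, enc$cache$c3$cols, p$enc_conv3_W, g$enc[[3]])
  gr$enc_conv3_W <- bc3$dW; gr$enc_conv3_b <- bc3$db
  dy <- relu_grad(bc3$dx, enc$cache$c2$y)
  bc2 <- conv_backward(dy, enc$cache$c2$cols, p$enc_conv2_W, g$enc[[2]])
  gr$enc_conv2_W <- bc2$dW; gr$enc_conv2_b <- bc2$db
  dy <- relu_grad(bc2$dx, enc$cache$c1$y)
  bc1 <- conv_backward(dy, enc$cache$c1$cols, p$enc_conv1_W, g$enc[[1]])
  gr$enc_conv1_W <- bc1$dW; gr$enc_conv1_b <- bc1$db
  gr
}

subject_onehots <- function(ids, n_subjects) {
  s <- matrix(0, n_subjects, length(ids))
  s[cbind(ids, seq_along(ids))] <- 1
  s
}

#' Train the conditioned VAE
#'
#' Minimizes `recon_loss + anneal_weight(epoch) * kl_loss` over minibatches
#' with Adam.  Fully reproducible for a fixed seed: weight initialization,
#' epoch shuffling, and the reparameterization noise all derive from `seed`.
#'
#' @param ds an `erp_dataset` whose epochs match the configured input shape
#'   (typically the z-scored training split).
#' @param cfg a [cvae_config()].
#' @param seed integer seed.
#' @param norm optional `zscore_params` to store with the model so generated
#'   output can be de-normalized.
#' @param verbose print per-epoch losses every `verbose` epochs (0 = quiet).
#' @return a trained `cvae_model`; `$report` holds the per-epoch
#'   reconstruction loss, KL loss, KL weight, and total loss.
#' @export
train_cvae <- function(ds, cfg, seed = 1L, norm = NULL, verbose = 0) {
  stopifnot(inherits(ds, "erp_dataset"), inherits(cfg, "cvae_config"))
  n <- n_trials(ds)
  assert_that(n > 0, "parameter_error", "training set is empty")
  assert_that(dim(ds$data)[2] == cfg$n_channels &&
              dim(ds$data)[3] == cfg$n_samples, "dimension_error",
              "dataset epochs are %d x %d but config expects %d x %d",
              dim(ds$data)[2], dim(ds$data)[3], cfg$n_channels,
              cfg$n_samples)
  assert_that(max(ds$meta$subject_id) <= cfg$n_subjects, "parameter_error",
              "dataset subject index exceeds configured n_subjects")
  model <- cvae_init(cfg, child_seed(seed, "init"))
  model$norm <- norm
  X <- aperm(ds$data, c(2, 3, 1))            # C x S x N
  dim(X) <- c(1, dim(X))                     # 1 x C x S x N
  S <- subject_onehots(ds$meta$subject_id, cfg$n_subjects)
  state <- adam_init(model$params)
  report <- data.frame(epoch = seq_len(cfg$epochs), recon = NA_real_,
                       kl = NA_real_, kl_weight = NA_real_,
                       total = NA_real_)
  with_seed(child_seed(seed, "train"), {
    for (ep in seq_len(cfg$epochs)) {
      klw <- anneal_weight(ep, cfg)
      ord <- sample.int(n)
      ep_rec <- 0; ep_kl <- 0
      nb <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        xb <- X[, , , idx, drop = FALSE]
        sb <- S[, idx, drop = FALSE]
        N <- length(idx)
        enc <- cvae_enc_forward(model, xb, sb, keep_cache = TRUE)
        eps <- matrix(stats::rnorm(cfg$latent_dim * N), cfg$latent_dim, N)
        z <- enc$mu + exp(enc$logvar / 2) * eps
        dec <- cvae_dec_forward(model, z, sb, keep_cache = TRUE)
        rec <- mean((dec$cache$t3$y - xb)^2)
        kl <- mean(colSums(-0.5 * (1 + enc$logvar - enc$mu^2 -
                                     exp(enc$logvar))))
        if (!is.finite(rec) || !is.finite(kl))
          stop_fmt("training_error", paste(
            "non-finite loss at epoch %d (recon=%g, kl=%g);",
            "reduce the learning rate or beta"), ep, rec, kl)
        dxhat <- 2 * (dec$cache$t3$y - xb) / length(xb)
        gr <- cvae_backward(model, xb, sb, enc, dec, eps, dxhat, klw, N)
        upd <- adam_step(model$params, gr, state, cfg$lr)
        model$params <- upd$params
        state <- upd$state
        ep_rec <- ep_rec + rec; ep_kl <- ep_kl + kl; nb <- nb + 1L
      }
      report$recon[ep] <- ep_rec / nb
      report$kl[ep] <- ep_kl / nb
      report$kl_weight[ep] <- klw
      report$total[ep] <- report$recon[ep] + klw * report$kl[ep]
      if (verbose > 0 && ep %% verbose == 0)
        message(sprintf("epoch %4d  recon %.5f  kl %.3f  w %.2e", ep,
                        report$recon[ep], report$kl[ep], klw))
    }
  })
  model$report <- report
  model$seed <- as.integer(seed)
  model
}

#' Encode every trial of a dataset to latent means
#'
#' @param ds an `erp_dataset` matching the model input shape.
#' @param model a `cvae_model`.
#' @param batch_size forward batch size.
#' @return numeric matrix `n_trials x latent_dim` of posterior means.
#' @export
encode_dataset <- function(model, ds, batch_size = 256L) {
  n <- n_trials(ds)
  S <- subject_onehots(ds$meta$subject_id, model$cfg$n_subjects)
  out <- matrix(NA_real_, n, model$cfg$latent_dim)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- aperm(ds$data[idx, , , drop = FALSE], c(2, 3, 1))
    dim(xb) <- c(1, dim(xb))
    fw <- cvae_enc_forward(model, xb, S[, idx, drop = FALSE])
    out[idx, ] <- t(fw$mu)
  }
  out
}

#' Deterministically reconstruct a dataset through the bottleneck
#'
#' Encodes each trial, takes the posterior mean, and decodes it with the
#' trial's subject one-hot (no sampling).
#'
#' @param model a `cvae_model`.
#' @param ds an `erp_dataset`.
#' @param batch_size forward batch size.
#' @return array `n_trials x n_channels x n_samples` of reconstructions.
#' @export
reconstruct_dataset <- function(model, ds, batch_size = 256L) {
  n <- n_trials(ds)
  S <- subject_onehots(ds$meta$subject_id, model$cfg$n_subjects)
  out <- array(NA_real_, dim(ds$data))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- aperm(ds$data[idx, , , drop = FALSE], c(2, 3, 1))
    dim(xb) <- c(1, dim(xb))
    enc <- cvae_enc_forward(model, xb, S[, idx, drop = FALSE])
    dec <- cvae_dec_forward(model, enc$mu, S[, idx, drop = FALSE])
    out[idx, , ] <- aperm(array(dec$xhat,
                                c(model$cfg$n_channels, model$cfg$n_samples,
                                  length(idx))), c(3, 1, 2))
  }
  out
}

#' Save / load model checkpoints
#'
#' Checkpoints are self-describing: a format tag, the configuration snapshot,
#' and the named weight arrays.
#'
#' @param model a `cvae_model` or `bridge_model`.
#' @param path checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` the restored
#'   model.
#' @export
save_model <- function(model, path) {
  kind <- class(model)[1]
  saveRDS(list(format = paste0("erpsynth_", kind), version = 1L,
               model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  assert_that(file.exists(path), "io_error", "checkpoint '%s' not found",
              path)
  obj <- readRDS(path)
  assert_that(is.list(obj) && startsWith(obj$format %||% "", "erpsynth_"),
              "format_error", "'%s' is not an erpsynth checkpoint", path)
  obj$model
}
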
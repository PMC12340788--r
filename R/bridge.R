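#' Concept embedding
#'
#' A 512-dimensional multimodal vector locating a picture or text in the
#' conceptual latent space, with its modality tag.
#'
#' @param vector numeric vector (finite; conventionally length 512).
#' @param modality `"image"`, `"text"`, or `"mock"`.
#' @param stimulus_id identifier of the encoded stimulus.
#' @return a `concept_embedding`.
#' @export
concept_embedding <- function(vector, modality = "mock",
                              stimulus_id = "stim") {
  assert_that(all(is.finite(vector)), "embedding_error",
              "embedding contains non-finite values")
  modality <- match.arg(modality, c("image", "text", "mock"))
  structure(list(vector = as.numeric(vector), modality = modality,
                 stimulus_id = as.character(stimulus_id)),
            class = "concept_embedding")
}

#' Deterministic mock concept encoder
#'
#' Offline stand-in for the external contrastive image-text encoder: maps a
#' stimulus id and class to a unit-norm embedding, `class centroid +
#' within-class jitter`, where the jitter is a pure function of
#' `(stimulus_id, seed)`.  Identical inputs always produce identical
#' embeddings.
#'
#' @param stimulus_id stimulus identifier string.
#' @param class integer class label in `0..n_classes-1`, or `NULL` for an
#'   unclassed id-specific embedding.
#' @param spec a [mock_embedding_spec()].
#' @return a `concept_embedding` with modality `"mock"`.
#' @export
mock_encode <- function(stimulus_id, class = NULL, spec) {
  stopifnot(inherits(spec, "mock_embedding_spec"))
  base <- numeric(spec$dim)
  if (!is.null(class) && !is.na(class)) {
    class <- as.integer(class)
    assert_that(class >= 0 && class < spec$n_classes, "spec_error",
                "class %d outside 0..%d", class, spec$n_classes - 1L)
    base <- spec$class_separation * mock_centroids(spec)[, class + 1L]
  }
  jitter <- with_seed(child_seed(spec$seed, paste0("stim:", stimulus_id)),
                      stats::rnorm(spec$dim))
  v <- base + spec$within_class_sd * jitter
  if (sqrt(sum(v^2)) == 0) v <- rep(1 / sqrt(spec$dim), spec$dim)
  concept_embedding(v / sqrt(sum(v^2)), "mock", stimulus_id)
}

#' External encoder adapter
#'
#' Hook for a real pretrained contrastive image-text encoder.  No such
#' encoder ships with this package, so calling this without a configured
#' adapter raises a capability error directing to [mock_encode()]; there is
#' never a silent fallback.
#'
#' @param input image path or text string.
#' @param adapter optional adapter: a function `(input) -> numeric(512)`.
#' @param modality `"image"` or `"text"`.
#' @return a `concept_embedding` (unit norm).
#' @export
clip_encode <- function(input, adapter = NULL, modality = "text") {
  if (is.null(adapter))
    stop_fmt("capability_error", paste(
      "no external concept encoder is configured;",
      "use mock_encode() for offline operation"))
  v <- adapter(input)
  assert_that(length(v) == 512, "dimension_error",
              "adapter returned %d values, expected 512", length(v))
  concept_embedding(v / sqrt(sum(v^2)), modality, as.character(input))
}

#' Cross-domain bridge configuration
#'
#' The dense network mapping `embedding (512) + subject one-hot` into the
#' cVAE latent space: three fully connected layers, exponential-linear
#' activation on the first two, linear output, trained with Adam (learning
#' rate 1e-3) on mean squared error, stopping at the best validation loss.
#'
#' @param n_subjects subject one-hot length.
#' @param latent_dim output width (= cVAE latent dimension).
#' @param embedding_dim concept embedding width (512).
#' @param hidden widths of the two hidden layers.
#' @param lr Adam learning rate.
#' @param max_epochs training epoch cap (the full-scale run converged in
#'   10).
#' @param val_fraction validation fraction for early stopping.
#' @param normalize_embeddings L2-normalize inputs before training/mapping.
#' @return a `bridge_config`.
#' @export
bridge_config <- function(n_subjects, latent_dim, embedding_dim = 512L,
                          hidden = c(512L, 384L), lr = 1e-3,
                          max_epochs = 10L, val_fraction = 0.1,
                          batch_size = 64L,
                          normalize_embeddings = TRUE) {
  assert_that(length(hidden) == 2, "config_error",
              "bridge has exactly two hidden layers")
  structure(list(n_subjects = as.integer(n_subjects),
                 latent_dim = as.integer(latent_dim),
                 embedding_dim = as.integer(embedding_dim),
                 hidden = as.integer(hidden), lr = lr,
                 max_epochs = as.integer(max_epochs),
                 val_fraction = val_fraction,
                 batch_size = as.integer(batch_size),
                 normalize_embeddings = normalize_embeddings),
            class = "bridge_config")
}

bridge_init <- function(cfg, seed = 1L) {
  nin <- cfg$embedding_dim + cfg$n_subjects
  params <- with_seed(seed, list(
    W1 = init_weight(cfg$hidden[1], nin), b1 = numeric(cfg$hidden[1]),
    W2 = init_weight(cfg$hidden[2], cfg$hidden[1]),
    b2 = numeric(cfg$hidden[2]),
    W3 = init_weight(cfg$latent_dim, cfg$hidden[2]),
    b3 = numeric(cfg$latent_dim)))
  structure(list(cfg = cfg, params = params, report = NULL),
            class = "bridge_model")
}

#' @export
print.bridge_model <- function(x, ...) {
  cat(sprintf("<bridge_model> %d+%d -> %d -> %d -> %d%s\n",
              x$cfg$embedding_dim, x$cfg$n_subjects, x$cfg$hidden[1],
              x$cfg$hidden[2], x$cfg$latent_dim,
              if (is.null(x$report)) " (untrained)" else " (trained)"))
  invisible(x)
}

bridge_forward <- function(model, X, keep_cache = FALSE) {
  p <- model$params
  a1 <- dense_forward(X, p$W1, p$b1); h1 <- elu(a1)
  a2 <- dense_forward(h1, p$W2, p$b2); h2 <- elu(a2)
  y <- dense_forward(h2, p$W3, p$b3)
  out <- list(y = y)
  if (keep_cache) out$cache <- list(X = X, a1 = a1, h1 = h1, a2 = a2,
                                    h2 = h2)
  out
}

bridge_input <- function(emb, s, cfg) {
  v <- if (inherits(emb, "concept_embedding")) emb$vector else as.numeric(emb)
  assert_that(length(v) == cfg$embedding_dim, "dimension_error",
              "embedding has length %d, bridge expects %d", length(v),
              cfg$embedding_dim)
  if (cfg$normalize_embeddings && sqrt(sum(v^2)) > 0)
    v <- v / sqrt(sum(v^2))
  assert_that(length(s) == cfg$n_subjects, "dimension_error",
              "subject vector has length %d, bridge expects %d", length(s),
              cfg$n_subjects)
  c(v, s)
}

#' Map a concept embedding into the electrophysiological latent space
#'
#' Deterministic forward pass of the trained bridge on
#' `[embedding; subject one-hot]`, estimating the cVAE latent mean.
#'
#' @param emb a `concept_embedding` or numeric embedding vector.
#' @param s subject one-hot vector.
#' @param bridge a trained `bridge_model`.
#' @return numeric latent vector of length `latent_dim`.
#' @export
map_to_latent <- function(emb, s, bridge) {
  stopifnot(inherits(bridge, "bridge_model"))
  x <- bridge_input(emb, s, bridge$cfg)
  as.vector(bridge_forward(bridge, matrix(x, ncol = 1))$y)
}

#' Train the cross-domain bridge
#'
#' Minimizes mean squared error from `[embedding; one-hot]` inputs to cVAE
#' latent-mean targets with Adam, holding out a validation fraction
#' (stratified by subject) and returning the weights from the epoch with the
#' best validation loss.
#'
#' @param embeddings list of `concept_embedding` (or numeric matrix
#'   `n x embedding_dim`).
#' @param subject_ids integer subject index per pair.
#' @param targets numeric matrix `n x latent_dim` of latent means.
#' @param cfg a [bridge_config()].
#' @param seed integer seed.
#' @return a trained `bridge_model`; `$report` holds per-epoch train and
#'   validation MSE and the selected epoch.
#' @export
train_bridge <- function(embeddings, subject_ids, targets, cfg, seed = 1L) {
  if (is.list(embeddings))
    embeddings <- do.call(rbind, lapply(embeddings, function(e) e$vector))
  embeddings <- as.matrix(embeddings)
  targets <- as.matrix(targets)
  n <- nrow(embeddings)
  assert_that(n == length(subject_ids) && n == nrow(targets),
              "dimension_error", "pair components differ in length")
  assert_that(ncol(targets) == cfg$latent_dim, "dimension_error",
              "targets have %d columns, config expects %d", ncol(targets),
              cfg$latent_dim)
  assert_that(n >= 2, "parameter_error",
              "need at least 2 pairs for a validation split")
  X <- matrix(NA_real_, cfg$embedding_dim + cfg$n_subjects, n)
  for (i in seq_len(n))
    X[, i] <- bridge_input(embeddings[i, ], one_hot_vec(subject_ids[i],
                                                        cfg$n_subjects), cfg)
  Y <- t(targets)
  # subject-stratified validation split
  val <- with_seed(child_seed(seed, "split"), {
    unlist(lapply(split(seq_len(n), subject_ids), function(ix) {
      k <- max(1L, round(cfg$val_fraction * length(ix)))
      if (length(ix) == 1) ix else sample(ix, k)
    }), use.names = FALSE)
  })
  if (length(val) >= n) val <- val[-1]
  assert_that(length(val) >= 1 && length(val) < n, "parameter_error",
              "degenerate validation split")
  tr <- setdiff(seq_len(n), val)
  model <- bridge_init(cfg, child_seed(seed, "init"))
  state <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  report <- data.frame(epoch = seq_len(cfg$max_epochs), train = NA_real_,
                       val = NA_real_)
  with_seed(child_seed(seed, "train"), {
    for (ep in seq_len(cfg$max_epochs)) {
      ord <- sample(tr)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        xb <- X[, idx, drop = FALSE]; yb <- Y[, idx, drop = FALSE]
        fw <- bridge_forward(model, xb, keep_cache = TRUE)
        err <- fw$y - yb
        loss <- mean(err^2)
        dy <- 2 * err / length(err)
        p <- model$params
        bk3 <- dense_backward(dy, fw$cache$h2, p$W3)
        dh2 <- elu_grad(bk3$dx, fw$cache$a2)
        bk2 <- dense_backward(dh2, fw$cache$h1, p$W2)
        dh1 <- elu_grad(bk2$dx, fw$cache$a1)
        bk1 <- dense_backward(dh1, fw$cache$X, p$W1)
        gr <- list(W1 = bk1$dW, b1 = bk1$db, W2 = bk2$dW, b2 = bk2$db,
                   W3 = bk3$dW, b3 = bk3$db)
        upd <- adam_step(model$params, gr, state, cfg$lr)
        model$params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + loss; nb <- nb + 1L
      }
      fwv <- bridge_forward(model, X[, val, drop = FALSE])
      vloss <- mean((fwv$y - Y[, val, drop = FALSE])^2)
      report$train[ep] <- ep_loss / nb
      report$val[ep] <- vloss
      if (vloss < best$loss)
        best <- list(loss = vloss, params = model$params, epoch = ep)
    }
  })
  model$params <- best$params
  model$report <- report
  model$best_epoch <- best$epoch
  model$val_loss <- best$loss
  model
}

one_hot_vec <- function(i, n) {
  v <- numeric(n); v[i] <- 1; v
}
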
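# Minimal neural-network engine: 2-D convolutions over the channel x time
# grid (im2col + matrix multiply), transposed convolutions (zero dilation +
# stride-1 convolution), dense layers, ReLU/ELU, and Adam.  Feature maps are
# stored as arrays dim (C, H, W, N); weights as (C_out, C_in*k*k) matrices.
# Backprop is explicit; a finite-difference oracle in the test suite checks
# the gradients.

#' Convolution stage output length
#'
#' `floor((n + pad_lo + pad_hi - k) / stride) + 1` for one axis.
#' @keywords internal
conv_out_len <- function(n, k, stride, pad_lo, pad_hi = pad_lo) {
  as.integer((n + pad_lo + pad_hi - k) %/% stride + 1L)
}

# Precompute im2col gather indices and the transposed scatter matrix for a
# conv stage.  padH/padW are c(lo, hi) pads per axis.
conv_geom <- function(Cin, H, W, k, stride, padH = c(1L, 1L),
                      padW = c(1L, 1L)) {
  Hp <- H + sum(padH); Wp <- W + sum(padW)
  Ho <- conv_out_len(H, k, stride, padH[1], padH[2])
  Wo <- conv_out_len(W, k, stride, padW[1], padW[2])
  stopifnot(Ho >= 1, Wo >= 1)
  taps <- expand.grid(ci = seq_len(Cin), kh = seq_len(k), kw = seq_len(k))
  pos <- expand.grid(ho = seq_len(Ho), wo = seq_len(Wo))
  hmat <- outer(taps$kh, (pos$ho - 1L) * stride, "+")      # ntap x npos
  wmat <- outer(taps$kw, (pos$wo - 1L) * stride, "+")
  idx <- taps$ci + Cin * (hmat - 1L) + (Cin * Hp) * (wmat - 1L)
  idx <- as.integer(idx)
  S <- Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                            dims = c(Cin * Hp * Wp, length(idx)))
  list(Cin = Cin, H = H, W = W, k = k, stride = stride,
       padH = padH, padW = padW, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo,
       ntap = nrow(taps), npos = nrow(pos), idx = idx, S = S,
       cache = new.env(parent = emptyenv()))
}

# Batch gather index, memoized per batch size (hot path).
batch_index <- function(g, N) {
  key <- as.character(N)
  if (!is.null(g$cache[[key]])) return(g$cache[[key]])
  per <- g$Cin * g$Hp * g$Wp
  bigidx <- rep(g$idx, N) + rep((seq_len(N) - 1L) * per,
                                each = length(g$idx))
  g$cache[[key]] <- bigidx
  bigidx
}

pad_input <- function(x, g) {
  d <- dim(x)
  xp <- array(0, c(g$Cin, g$Hp, g$Wp, d[4]))
  xp[, g$padH[1] + seq_len(g$H), g$padW[1] + seq_len(g$W), ] <- x
  xp
}

# im2col gather; columns ordered (position within sample, then sample).
conv_cols <- function(x, g) {
  N <- dim(x)[4]
  xp <- pad_input(x, g)
  cols <- xp[batch_index(g, N)]
  dim(cols) <- c(g$ntap, g$npos * N)
  cols
}

conv_forward <- function(x, Wm, b, g) {
  cols <- conv_cols(x, g)
  y <- Wm %*% cols + b
  dim(y) <- c(nrow(Wm), g$Ho, g$Wo, dim(x)[4])
  list(y = y, cols = cols)
}

conv_backward <- function(dy, cols, Wm, g) {
  N <- dim(dy)[4]
  dym <- matrix(dy, nrow = dim(dy)[1])
  dW <- tcrossprod(dym, cols)
  db <- rowSums(dym)
  dcols <- crossprod(Wm, dym)
  dim(dcols) <- c(g$ntap * g$npos, N)
  dxp <- as.matrix(g$S %*% dcols)
  dim(dxp) <- c(g$Cin, g$Hp, g$Wp, N)
  dx <- dxp[, g$padH[1] + seq_len(g$H), g$padW[1] + seq_len(g$W), ,
            drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# Transposed convolution as the exact adjoint of the mirrored convolution:
# the geometry is the conv that maps the tconv OUTPUT shape back to its
# input shape, so decoder stages invert encoder shapes by construction.
# Weight shape: (C_in, C_out * k * k) — the mirror conv's weight matrix.
tconv_geom <- function(Cin, Cout, Hin, Win, k, stride, pad,
                       target_h, target_w) {
  g <- conv_geom(Cout, target_h, target_w, k, stride,
                 padH = c(pad, pad), padW = c(pad, pad))
  stopifnot(g$Ho == Hin, g$Wo == Win)
  list(conv = g, Cin = Cin, Cout = Cout, Hin = Hin, Win = Win,
       Hout = target_h, Wout = target_w)
}

tconv_forward <- function(x, Wm, b, tg) {
  g <- tg$conv
  N <- dim(x)[4]
  xf <- x
  dim(xf) <- c(tg$Cin, tg$Hin * tg$Win * N)      # Cin x (Hin*Win*N)
  dcols <- crossprod(Wm, xf)                     # ntap x (npos*N)
  dim(dcols) <- c(g$ntap * g$npos, N)
  yp <- as.matrix(g$S %*% dcols)
  dim(yp) <- c(tg$Cout, g$Hp, g$Wp, N)
  y <- yp[, g$padH[1] + seq_len(tg$Hout), g$padW[1] + seq_len(tg$Wout), ,
          drop = FALSE] + b
  list(y = y, xf = xf)
}

tconv_backward <- function(dy, xf, Wm, tg) {
  g <- tg$conv
  N <- dim(dy)[4]
  cols <- conv_cols(dy, g)
  dx <- Wm %*% cols
  dim(dx) <- c(tg$Cin, tg$Hin, tg$Win, N)
  dW <- tcrossprod(xf, cols)
  dym <- dy
  dim(dym) <- c(tg$Cout, length(dy) / tg$Cout)
  db <- rowSums(dym)
  list(dx = dx, dW = dW, db = db)
}

dense_forward <- function(x, Wm, b) Wm %*% x + b

dense_backward <- function(dy, x, Wm) {
  list(dx = crossprod(Wm, dy), dW = dy %*% t(x), db = rowSums(dy))
}

relu <- function(x) pmax(x, 0)
relu_grad <- function(dy, x) dy * (x > 0)

elu <- function(x, alpha = 1) ifelse(x > 0, x, alpha * (exp(x) - 1))
elu_grad <- function(dy, x, alpha = 1) {
  dy * ifelse(x > 0, 1, alpha * exp(x))
}

# He-scaled Gaussian initialization for a (fan_out x fan_in) weight matrix.
init_weight <- function(fan_out, fan_in) {
  matrix(stats::rnorm(fan_out * fan_in, sd = sqrt(2 / fan_in)),
         fan_out, fan_in)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
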
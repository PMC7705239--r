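# The two multi-scale layers. User-facing functions operate on one feature
# map, a (w x c) matrix (w = length, c = channels); the batched *_forward /
# *_backward internals used in training operate on (n*w) x c blocks.

as_feature_map <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (!all(is.finite(x))) stop("feature map must be finite-valued")
  x
}

#' Pooling-branch geometry
#'
#' For an input of length `w`, a pooling window `p` and stride `d = 1`, the
#' branch output length is `o = (w - p)/d + 1`; zero padding back to length
#' `w` uses `l = ceiling((w - o)/4)` leading and `r = w - o - l` trailing
#' zeros, so `o + l + r = w` exactly.
#'
#' @param w Input length.
#' @param p Pool window size.
#' @param d Stride (must be 1).
#' @return List with `p`, `d`, `o`, `l`, `r`.
#' @export
pool_branch_spec <- function(w, p, d = 1L) {
  if (d != 1L) stop("stride must be 1 for signal-pooling branches")
  if (p < 1L || p > w) stop(sprintf("pool window %d outside 1..%d", p, w))
  o_real <- (w - p) / d + 1
  if (o_real != round(o_real)) stop("non-integer branch output length")
  o <- as.integer(o_real)
  l <- as.integer(ceiling((w - o) / 4))
  r <- w - o - l
  stopifnot(l >= 0L, r >= 0L, o + l + r == w)
  list(p = as.integer(p), d = 1L, o = o, l = l, r = r)
}

#' Sliding-window channelwise max pooling (stride 1)
#'
#' Output position t holds the per-channel maximum of input window
#' `[t, t + p)`; output length is `w - p + 1`.
#'
#' @param x Feature map: numeric vector or `(w x c)` matrix.
#' @param p Window size, `1 <= p <= w`.
#' @param d Stride; only 1 is supported.
#' @return `(o x c)` matrix.
#' @examples
#' multi_pool(c(1, 3, 2, 5), 2)  # [3, 3, 5]
#' @export
multi_pool <- function(x, p, d = 1L) {
  x <- as_feature_map(x)
  spec <- pool_branch_spec(nrow(x), p, d)
  out <- maxpool_forward(x, n = 1L, w = nrow(x), k = spec$p, s = 1L)
  out$Y
}

#' Asymmetric zero-padding to a target length
#'
#' Pads a pooled branch back to the common length `w_target` with
#' `l = ceiling((w_target - o)/4)` leading and `r = w_target - o - l`
#' trailing zero rows.
#'
#' @param x Feature map (vector or `o x c` matrix) with `o <= w_target`.
#' @param w_target Target length.
#' @return `(w_target x c)` matrix with `x` at row offset `l`.
#' @examples
#' pad_to_length(c(3, 3, 5), 4)  # [0, 3, 3, 5]
#' @export
pad_to_length <- function(x, w_target) {
  x <- as_feature_map(x)
  o <- nrow(x)
  if (o > w_target) stop("feature map longer than target length")
  l <- as.integer(ceiling((w_target - o) / 4))
  out <- matrix(0, w_target, ncol(x))
  if (o > 0L) out[(l + 1L):(l + o), ] <- x
  out
}

#' Multi-branch concatenation of the signal pooling layer
#'
#' The three parallel branches: max pooling at windows 1 (identity), 2 and
#' 4, each zero-padded back to the input length and concatenated along the
#' channel axis, giving `(w x 3c)`.
#'
#' @param x Feature map (vector or `w x c` matrix), `w >= 4`.
#' @return `(w x 3c)` matrix; branch order is window 1, 2, 4.
#' @export
signal_pool_concat <- function(x) {
  x <- as_feature_map(x)
  w <- nrow(x)
  if (w < 4L) stop("input length must be >= 4 (largest pooling window)")
  branches <- lapply(c(1L, 2L, 4L), function(p)
    pad_to_length(multi_pool(x, p), w))
  do.call(cbind, branches)
}

#' Initialize signal-pooling layer parameters
#'
#' The trainable part is the pointwise reduction convolution mapping the
#' 3c-channel concatenation back to c channels so the layer is
#' shape-preserving.
#'
#' @param c_in Input channel count c.
#' @return List with weight matrix `W` (`3c x c`) and bias `b` (length c).
#' @export
init_signal_pooling <- function(c_in) {
  list(W = glorot(3L * c_in, c_in, 3L * c_in, c_in), b = numeric(c_in))
}

#' Signal pooling layer (single feature map)
#'
#' Runs the three pooling branches, pads and concatenates them
#' ([signal_pool_concat()]), then applies the pointwise reduction
#' convolution so the output shape equals the input shape. With
#' `reduce = "none"` the raw `(w x 3c)` concatenation is returned instead.
#'
#' @param x Feature map (vector or `w x c` matrix), `w >= 4`.
#' @param params Parameters from [init_signal_pooling()]; required for
#'   `reduce = "conv"`.
#' @param reduce `"conv"` (default, shape-preserving) or `"none"`.
#' @return `(w x c)` matrix (or `(w x 3c)` when `reduce = "none"`).
#' @export
signal_pooling_layer <- function(x, params = NULL,
                                 reduce = c("conv", "none")) {
  reduce <- match.arg(reduce)
  concat <- signal_pool_concat(x)
  if (reduce == "none") return(concat)
  if (is.null(params)) stop("reduce = 'conv' needs params; see init_signal_pooling()")
  dense_forward(concat, params$W, params$b)
}

# Batched forward/backward. X is (n*w) x c.
sp_forward <- function(X, n, w, params, reduce = "conv") {
  c_in <- ncol(X)
  spec2 <- pool_branch_spec(w, 2L)
  spec4 <- pool_branch_spec(w, 4L)
  mp2 <- maxpool_forward(X, n, w, 2L, 1L)
  mp4 <- maxpool_forward(X, n, w, 4L, 1L)
  pad_branch <- function(Y, o, l) {
    out <- matrix(0, n * w, c_in)
    out[pad_rows_branch(n, w, o, l), ] <- Y
    out
  }
  concat <- cbind(X, pad_branch(mp2$Y, spec2$o, spec2$l),
                  pad_branch(mp4$Y, spec4$o, spec4$l))
  cache <- list(mp2 = mp2$cache, mp4 = mp4$cache, spec2 = spec2,
                spec4 = spec4, n = n, w = w, c_in = c_in, concat = concat,
                reduce = reduce)
  Y <- if (reduce == "conv") dense_forward(concat, params$W, params$b)
       else concat
  list(Y = Y, cache = cache)
}

# Rows of the padded (length-w) block occupied by a branch of length o.
pad_rows_branch <- function(n, w, o, l) {
  rep((seq_len(n) - 1L) * w, each = o) + l + seq_len(o)
}

sp_backward <- function(dY, params, cache) {
  n <- cache$n; w <- cache$w; c_in <- cache$c_in
  if (cache$reduce == "conv") {
    d <- dense_backward(dY, cache$concat, params$W)
    dconcat <- d$dX; dW <- d$dW; db <- d$db
  } else {
    dconcat <- dY; dW <- NULL; db <- NULL
  }
  d1 <- dconcat[, 1:c_in, drop = FALSE]
  d2p <- dconcat[, (c_in + 1L):(2L * c_in), drop = FALSE]
  d4p <- dconcat[, (2L * c_in + 1L):(3L * c_in), drop = FALSE]
  unpad <- function(dpad, o, l) dpad[pad_rows_branch(n, w, o, l), , drop = FALSE]
  dX <- d1 +
    maxpool_backward(unpad(d2p, cache$spec2$o, cache$spec2$l), cache$mp2) +
    maxpool_backward(unpad(d4p, cache$spec4$o, cache$spec4$l), cache$mp4)
  list(dX = dX, dW = dW, db = db)
}

# ---- multi-scale non-local layer --------------------------------------

#' Initialize non-local layer parameters
#'
#' Five trainable pointwise convolutions: the three embeddings phi, delta,
#' rho (`c -> c_hat`), the inner fusion conv (`c_hat -> c`, applied before
#' the residual addition) and the outer fusion conv (`c -> c`).
#'
#' @param c_in Input channel count c.
#' @param c_hat Embedding channel count (default `c/2`).
#' @return Named list of weight matrices and bias vectors.
#' @export
init_nonlocal <- function(c_in, c_hat = max(1L, c_in %/% 2L)) {
  if (c_hat < 1L) stop("c_hat must be >= 1")
  list(Wphi = glorot(c_in, c_hat, c_in, c_hat), bphi = numeric(c_hat),
       Wdelta = glorot(c_in, c_hat, c_in, c_hat), bdelta = numeric(c_hat),
       Wrho = glorot(c_in, c_hat, c_in, c_hat), brho = numeric(c_hat),
       Winner = glorot(c_hat, c_in, c_hat, c_in), binner = numeric(c_in),
       Wouter = glorot(c_in, c_in, c_in, c_in), bouter = numeric(c_in))
}

#' Pointwise embeddings of the non-local layer
#'
#' Three independent window-1 convolutions (no nonlinearity) mapping a
#' `(w x c)` feature map to the `(w x c_hat)` embeddings phi, delta, rho.
#'
#' @param x_ms Feature map (vector or `w x c` matrix).
#' @param params Parameters from [init_nonlocal()].
#' @return List with matrices `phi`, `delta`, `rho`.
#' @export
nonlocal_embed <- function(x_ms, params) {
  x_ms <- as_feature_map(x_ms)
  list(phi = dense_forward(x_ms, params$Wphi, params$bphi),
       delta = dense_forward(x_ms, params$Wdelta, params$bdelta),
       rho = dense_forward(x_ms, params$Wrho, params$brho))
}

#' Channel-affinity similarity matrix
#'
#' The raw similarity `R = phi^T delta`: entry (i, j) is the inner product
#' over positions of embedding channel i of phi with channel j of delta,
#' a `(c_hat x c_hat)` matrix correlating the multi-scale feature channels.
#'
#' @param phi,delta `(w x c_hat)` embedding matrices of equal shape.
#' @return `(c_hat x c_hat)` matrix.
#' @export
similarity <- function(phi, delta) {
  phi <- as_feature_map(phi); delta <- as_feature_map(delta)
  if (!all(dim(phi) == dim(delta))) stop("phi and delta shapes differ")
  crossprod(phi, delta)
}

#' Softmax-normalize a similarity matrix into attention weights
#'
#' Row-wise softmax: each row of the result is strictly positive and sums
#' to 1.
#'
#' @param R Finite numeric matrix.
#' @return Matrix of the same shape.
#' @export
attention_normalize <- function(R) {
  if (!all(is.finite(R))) stop("similarity matrix must be finite")
  softmax_rows(as_feature_map(R))
}

#' Multi-scale non-local layer (single feature map)
#'
#' Full attention block: pointwise embeddings, channel-affinity similarity
#' `R = phi^T delta`, row-softmax attention weights, attended features
#' `rho %*% t(R_hat)` (shape `w x c_hat`), inner pointwise convolution back
#' to c channels, residual addition with the input, and an outer pointwise
#' convolution. Output shape equals input shape.
#'
#' With `affinity = "position"` the attention is computed between positions
#' instead (`R = phi delta^T`, a `w x w` matrix, attended `R_hat %*% rho`),
#' the standard non-local-block orientation, for comparison.
#'
#' @param x_ms Feature map (vector or `w x c` matrix).
#' @param params Parameters from [init_nonlocal()].
#' @param affinity `"channel"` (default) or `"position"`.
#' @return `(w x c)` matrix.
#' @export
multi_scale_nonlocal_layer <- function(x_ms, params,
                                       affinity = c("channel", "position")) {
  affinity <- match.arg(affinity)
  x_ms <- as_feature_map(x_ms)
  emb <- nonlocal_embed(x_ms, params)
  if (affinity == "channel") {
    R <- similarity(emb$phi, emb$delta)
    Rhat <- attention_normalize(R)
    att <- emb$rho %*% t(Rhat)
  } else {
    R <- tcrossprod(emb$phi, emb$delta)
    Rhat <- attention_normalize(R)
    att <- Rhat %*% emb$rho
  }
  z <- dense_forward(att, params$Winner, params$binner)
  dense_forward(z + x_ms, params$Wouter, params$bouter)
}

# Batched forward: loops over examples for the per-example attention
# algebra (w and c_hat are small where this layer sits).
nl_forward <- function(X, n, w, params, affinity = "channel") {
  phi <- dense_forward(X, params$Wphi, params$bphi)
  delta <- dense_forward(X, params$Wdelta, params$bdelta)
  rho <- dense_forward(X, params$Wrho, params$brho)
  att <- matrix(0, nrow(phi), ncol(phi))
  Rhats <- vector("list", n)
  for (ex in seq_len(n)) {
    rows <- ((ex - 1L) * w + 1L):(ex * w)
    if (affinity == "channel") {
      Rhat <- softmax_rows(crossprod(phi[rows, , drop = FALSE],
                                     delta[rows, , drop = FALSE]))
      att[rows, ] <- rho[rows, , drop = FALSE] %*% t(Rhat)
    } else {
      Rhat <- softmax_rows(tcrossprod(phi[rows, , drop = FALSE],
                                      delta[rows, , drop = FALSE]))
      att[rows, ] <- Rhat %*% rho[rows, , drop = FALSE]
    }
    Rhats[[ex]] <- Rhat
  }
  z <- dense_forward(att, params$Winner, params$binner)
  s <- z + X
  Y <- dense_forward(s, params$Wouter, params$bouter)
  list(Y = Y, cache = list(X = X, phi = phi, delta = delta, rho = rho,
                           att = att, s = s, Rhats = Rhats, n = n, w = w,
                           affinity = affinity))
}

nl_backward <- function(dY, params, cache) {
  n <- cache$n; w <- cache$w
  douter <- dense_backward(dY, cache$s, params$Wouter)
  ds <- douter$dX
  dinner <- dense_backward(ds, cache$att, params$Winner)
  datt <- dinner$dX
  dphi <- matrix(0, nrow(datt), ncol(datt))
  ddelta <- dphi
  drho <- dphi
  for (ex in seq_len(n)) {
    rows <- ((ex - 1L) * w + 1L):(ex * w)
    Rhat <- cache$Rhats[[ex]]
    da <- datt[rows, , drop = FALSE]
    P <- cache$phi[rows, , drop = FALSE]
    D <- cache$delta[rows, , drop = FALSE]
    Rho <- cache$rho[rows, , drop = FALSE]
    if (cache$affinity == "channel") {
      drho[rows, ] <- da %*% Rhat
      dRhat <- crossprod(da, Rho)           # t(att' ) %*% rho -> (chat x chat)
      dR <- (dRhat - rowSums(dRhat * Rhat)) * Rhat
      dphi[rows, ] <- D %*% t(dR)
      ddelta[rows, ] <- P %*% dR
    } else {
      drho[rows, ] <- crossprod(Rhat, da)
      dRhat <- tcrossprod(da, Rho)
      dR <- (dRhat - rowSums(dRhat * Rhat)) * Rhat
      dphi[rows, ] <- dR %*% D
      ddelta[rows, ] <- crossprod(dR, P)
    }
  }
  X <- cache$X
  gphi <- dense_backward(dphi, X, params$Wphi)
  gdelta <- dense_backward(ddelta, X, params$Wdelta)
  grho <- dense_backward(drho, X, params$Wrho)
  dX <- ds + gphi$dX + gdelta$dX + grho$dX
  list(dX = dX,
       dWphi = gphi$dW, dbphi = gphi$db,
       dWdelta = gdelta$dW, dbdelta = gdelta$db,
       dWrho = grho$dW, dbrho = grho$db,
       dWinner = dinner$dW, dbinner = dinner$db,
       dWouter = douter$dW, dbouter = douter$db)
}
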
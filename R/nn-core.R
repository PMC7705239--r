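# Neural-network primitives on base R matrix algebra.
#
# Batched feature maps are stored as a single (n*w) x c matrix in
# example-major blocks: row (ex-1)*w + t holds position t of example ex,
# columns are channels. Convolutions become one BLAS matrix product via
# im2col; all backward passes are exact analytic gradients.

# Fast column-wise broadcasts (avoid sweep()/aperm overhead): add or
# multiply b[j] into column j of a matrix.
col_add <- function(Y, b) Y + rep(b, rep.int(nrow(Y), length(b)))
col_mul <- function(Y, b) Y * rep(b, rep.int(nrow(Y), length(b)))

# Row indices of window offset j (1-based) for every (example, position):
# a vector ordered position-fastest, example-major, into the padded matrix.
conv_rows <- function(n, wp, o, stride, j) {
  starts <- (seq_len(o) - 1L) * stride + j
  as.vector(outer(starts, (seq_len(n) - 1L) * wp, `+`))
}

# im2col geometry cache: the gather index (into the padded matrix seen as a
# vector) and the scatter targets are pure functions of the layer geometry
# and batch size, so they are computed once and reused across batches.
.im2col_cache <- new.env(parent = emptyenv())

im2col_plan <- function(n, wp, o, stride, k, cin) {
  key <- paste(n, wp, o, stride, k, cin, sep = "_")
  plan <- .im2col_cache[[key]]
  if (!is.null(plan)) return(plan)
  rows_mat <- vapply(seq_len(k), function(j) conv_rows(n, wp, o, stride, j),
                     integer(n * o))
  # channel-major column order: column (ch-1)*k + j, so the backward
  # regroup of dXcol to (n*o*k) x cin is a plain dim change
  idx <- unlist(lapply(seq_len(cin), function(ch)
    rows_mat + (ch - 1L) * (n * wp)), use.names = FALSE)
  targets <- as.vector(rows_mat)
  S <- Matrix::sparseMatrix(i = seq_along(targets), j = targets, x = 1,
                            dims = c(n * o * k, n * wp))
  plan <- list(idx = idx, S = S)
  .im2col_cache[[key]] <- plan
  plan
}

# Zero-pad each example block from length w to pl + w + pr.
pad_rows_map <- function(n, w, pl, pr) {
  wp <- w + pl + pr
  rep((seq_len(n) - 1L) * wp, each = w) + pl + seq_len(w)
}

#' 1D convolution forward pass (im2col)
#'
#' @param X Feature-map matrix `(n*w) x cin`.
#' @param W Weight matrix `(k*cin) x f`; rows are ordered channel-major
#'   (channel 1 offsets 1..k, channel 2 offsets 1..k, ...).
#' @param b Bias vector length `f`.
#' @param n,w Batch size and input length.
#' @param k,stride Kernel size and stride.
#' @param pl,pr Left/right zero padding.
#' @return List with `Y` (`(n*o) x f`), `o`, and a `cache` for
#'   [conv1d_backward()].
#' @keywords internal
conv1d_forward <- function(X, W, b, n, w, k, stride, pl = 0L, pr = 0L) {
  cin <- ncol(X)
  wp <- w + pl + pr
  if (pl > 0L || pr > 0L) {
    Xp <- matrix(0, n * wp, cin)
    Xp[pad_rows_map(n, w, pl, pr), ] <- X
  } else Xp <- X
  o <- (wp - k) %/% stride + 1L
  if (o < 1L) stop(sprintf("kernel %d does not fit input of length %d", k, wp))
  plan <- im2col_plan(n, wp, o, stride, k, cin)
  Xcol <- Xp[plan$idx]
  dim(Xcol) <- c(n * o, k * cin)
  Y <- col_add(Xcol %*% W, b)
  list(Y = Y, o = o,
       cache = list(Xcol = Xcol, plan = plan, o = o, n = n, w = w, wp = wp,
                    cin = cin, k = k, pl = pl, pr = pr))
}

#' 1D convolution backward pass
#' @param dY Gradient `(n*o) x f`.
#' @param W Weight matrix used in the forward pass.
#' @param cache Cache from [conv1d_forward()].
#' @return List `dX`, `dW`, `db`.
#' @keywords internal
conv1d_backward <- function(dY, W, cache) {
  cin <- cache$cin; k <- cache$k
  no <- cache$n * cache$o
  dW <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dXcol <- tcrossprod(dY, W)
  # scatter-add back to the padded input: with channel-major columns the
  # regroup to (n*o*k) x cin is a dim change, and the overlapping-window
  # reduction is one precomputed sparse crossprod
  dim(dXcol) <- c(no * k, cin)
  dXp <- as.matrix(Matrix::crossprod(cache$plan$S, dXcol))
  dX <- if (cache$pl > 0L || cache$pr > 0L)
    dXp[pad_rows_map(cache$n, cache$w, cache$pl, cache$pr), , drop = FALSE]
  else dXp
  list(dX = dX, dW = dW, db = db)
}

# Max pooling, window k, stride s, no padding. Forward keeps the argmax
# offset for the backward scatter; ties go to the earliest position.
maxpool_forward <- function(X, n, w, k, s) {
  o <- (w - k) %/% s + 1L
  if (o < 1L) stop(sprintf("pool window %d does not fit length %d", k, w))
  rows <- lapply(seq_len(k), function(j) conv_rows(n, w, o, s, j))
  Y <- X[rows[[1]], , drop = FALSE]
  arg <- matrix(1L, nrow(Y), ncol(Y))
  if (k > 1L) for (j in 2:k) {
    cand <- X[rows[[j]], , drop = FALSE]
    upd <- cand > Y
    Y[upd] <- cand[upd]
    arg[upd] <- j
  }
  list(Y = Y, o = o, cache = list(rows = rows, arg = arg, n = n, w = w,
                                  k = k, cols = ncol(X)))
}

maxpool_backward <- function(dY, cache) {
  dX <- matrix(0, cache$n * cache$w, cache$cols)
  for (j in seq_len(cache$k)) {
    rj <- cache$rows[[j]]
    dX[rj, ] <- dX[rj, ] + dY * (cache$arg == j)
  }
  dX
}

# Batch normalization over all rows (batch x position) per channel.
batchnorm_forward <- function(X, gamma, beta, run_mean, run_var,
                              training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- .colMeans(X, nrow(X), ncol(X))
    xc <- col_add(X, -mu)
    v <- .colMeans(xc^2, nrow(xc), ncol(xc))
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
    xc <- col_add(X, -mu)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- col_mul(xc, invstd)
  Y <- col_add(col_mul(xhat, gamma), beta)
  list(Y = Y, run_mean = run_mean, run_var = run_var,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma))
}

batchnorm_backward <- function(dY, cache) {
  m <- nrow(dY)
  nc <- ncol(dY)
  xhat <- cache$xhat
  dgamma <- .colSums(dY * xhat, m, nc)
  dbeta <- .colSums(dY, m, nc)
  dxhat <- col_mul(dY, cache$gamma)
  t1 <- col_add(dxhat, -.colSums(dxhat, m, nc) / m)
  t2 <- col_mul(xhat, .colSums(dxhat * xhat, m, nc) / m)
  dX <- col_mul(t1 - t2, cache$invstd)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

#' Rectified linear activation
#'
#' Elementwise `max(0, a)`.
#' @param a Numeric vector, matrix or array.
#' @return Same shape as `a`.
#' @export
relu <- function(a) pmax(a, 0)

relu_backward <- function(dY, X) dY * (X > 0)

dense_forward <- function(X, W, b) col_add(X %*% W, b)

dense_backward <- function(dY, X, W) {
  list(dX = tcrossprod(dY, W), dW = crossprod(X, dY),
       db = .colSums(dY, nrow(dY), ncol(dY)))
}

#' Softmax over the rows of a matrix
#'
#' Numerically stabilized (row max subtracted); each row of the result is
#' positive and sums to 1.
#' @param logits Numeric matrix (or vector, treated as one row).
#' @return Matrix of the same shape with row-wise softmax applied.
#' @export
softmax_rows <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  rmax <- logits[cbind(seq_len(nrow(logits)), max.col(logits, "first"))]
  e <- exp(logits - rmax)
  e / .rowSums(e, nrow(e), ncol(e))
}

#' Softmax classification head
#'
#' Converts a logit vector into class probabilities.
#' @param logits Numeric vector of length `C >= 2`.
#' @return Probability vector: positive entries summing to 1, invariant to
#'   adding a constant to all logits.
#' @export
softmax_head <- function(logits) {
  if (length(logits) < 2L) stop("need at least 2 classes")
  as.vector(softmax_rows(logits))
}

# Mean cross-entropy over a batch; y is 0-based. Returns loss and dlogits.
cross_entropy <- function(probs, y) {
  n <- nrow(probs)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n)
}

# Reshape (n*w) x c feature maps to n x (w*c) and back (flatten layer).
flatten_forward <- function(X, n, w) {
  c_ <- ncol(X)
  t(matrix(aperm(array(X, c(w, n, c_)), c(1, 3, 2)), nrow = w * c_))
}

flatten_backward <- function(dY, n, w) {
  c_ <- ncol(dY) / w
  matrix(aperm(array(t(dY), c(w, c_, n)), c(1, 3, 2)), nrow = n * w)
}

# ---- Adam optimizer ---------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(m = zeros, v = zeros, t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Glorot-uniform initialization for a (fan_in x fan_out)-shaped matrix.
glorot <- function(nrow_, ncol_, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow_ * ncol_, -lim, lim), nrow_, ncol_)
}
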
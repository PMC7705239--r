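# Full network: three conv/BN/ReLU stages (max pooling after the first
# two), signal pooling layer, multi-scale non-local layer, flatten, and a
# three-layer fully connected head with softmax output.

#' Network architecture specification
#'
#' The backbone follows the reference parameter table for 178-sample
#' inputs: conv(20 filters, kernel 40, stride 1, length-preserving
#' padding) -> BN -> ReLU -> maxpool(2/2) -> conv(40, 20, stride 2, no
#' padding) -> BN -> ReLU -> maxpool(2/2) -> conv(80, 10, stride 2, no
#' padding) -> BN -> ReLU -> signal pooling layer -> multi-scale non-local
#' layer -> flatten -> FC(64) -> ReLU -> FC(32) -> ReLU -> FC(n_classes)
#' -> softmax. The first conv uses "same" padding (the only reading under
#' which 178 stays 178 with kernel 40); the later convs are unpadded with
#' floor division.
#'
#' @param input_length Segment length (default 178).
#' @param n_classes Number of task classes (>= 2).
#' @param c_hat Non-local embedding channels (default half the final
#'   feature channels, i.e. 40).
#' @param conv_stages List of stages, each
#'   `list(filters, kernel, stride, pool)` (`pool` logical).
#' @param fc_widths Hidden fully connected widths.
#' @param pooling_reduce `"conv"` (shape-preserving reduction after the
#'   branch concatenation) or `"none"` (literal 3c-channel concatenation).
#' @param affinity `"channel"` or `"position"` non-local orientation.
#' @return An object of class `mnl_arch` including the computed per-stage
#'   shape trace (`$trace`).
#' @export
mnl_architecture <- function(input_length = 178L, n_classes = 2L,
                             c_hat = NULL,
                             conv_stages = list(
                               list(filters = 20L, kernel = 40L,
                                    stride = 1L, pool = TRUE),
                               list(filters = 40L, kernel = 20L,
                                    stride = 2L, pool = TRUE),
                               list(filters = 80L, kernel = 10L,
                                    stride = 2L, pool = FALSE)),
                             fc_widths = c(64L, 32L),
                             pooling_reduce = c("conv", "none"),
                             affinity = c("channel", "position")) {
  pooling_reduce <- match.arg(pooling_reduce)
  affinity <- match.arg(affinity)
  if (n_classes < 2L) stop("n_classes must be >= 2")
  w <- as.integer(input_length)
  c_in <- 1L
  trace <- list(list(layer = "input", w = w, c = c_in))
  for (i in seq_along(conv_stages)) {
    st <- conv_stages[[i]]
    if (st$stride == 1L) {                 # length-preserving padding
      pad_total <- st$kernel - 1L
      pl <- pad_total %/% 2L
      pr <- pad_total - pl
      o <- w
    } else {
      pl <- 0L; pr <- 0L
      o <- (w - st$kernel) %/% st$stride + 1L
    }
    if (o < 1L) stop("conv stage ", i, " output collapses to zero length")
    conv_stages[[i]]$pl <- pl
    conv_stages[[i]]$pr <- pr
    w <- o; c_in <- st$filters
    trace[[length(trace) + 1L]] <- list(layer = paste0("conv", i), w = w,
                                        c = c_in)
    if (isTRUE(st$pool)) {
      w <- (w - 2L) %/% 2L + 1L
      trace[[length(trace) + 1L]] <- list(layer = paste0("pool", i), w = w,
                                          c = c_in)
    }
  }
  if (w < 4L) stop("final feature length < 4: signal pooling cannot run")
  c_feat <- c_in
  c_pool <- if (pooling_reduce == "conv") c_feat else 3L * c_feat
  trace[[length(trace) + 1L]] <- list(layer = "signal_pooling", w = w,
                                      c = c_pool)
  if (is.null(c_hat)) c_hat <- max(1L, c_pool %/% 2L)
  trace[[length(trace) + 1L]] <- list(layer = "nonlocal", w = w, c = c_pool)
  flat <- w * c_pool
  trace[[length(trace) + 1L]] <- list(layer = "flatten", w = flat, c = 1L)
  structure(
    list(input_length = as.integer(input_length),
         n_classes = as.integer(n_classes),
         conv_stages = conv_stages, fc_widths = as.integer(fc_widths),
         c_hat = as.integer(c_hat), pooling_reduce = pooling_reduce,
         affinity = affinity, feat_w = w, feat_c = c_feat,
         pool_c = c_pool, flat = flat, trace = trace),
    class = "mnl_arch")
}

#' Per-layer shape trace of an architecture
#'
#' @param arch An [mnl_architecture()].
#' @return Data frame with columns `layer`, `length`, `channels`.
#' @export
shape_trace <- function(arch) {
  stopifnot(inherits(arch, "mnl_arch"))
  data.frame(layer = vapply(arch$trace, `[[`, "", "layer"),
             length = vapply(arch$trace, function(t) as.integer(t$w),
                             integer(1)),
             channels = vapply(arch$trace, function(t) as.integer(t$c),
                               integer(1)))
}

#' @export
print.mnl_arch <- function(x, ...) {
  cat(sprintf("<mnl_arch> input %d -> %d classes, c_hat = %d\n",
              x$input_length, x$n_classes, x$c_hat))
  print(shape_trace(x), row.names = FALSE)
  invisible(x)
}

# Initialize all trainable parameters (Glorot uniform, biases zero, BN
# gamma 1 / beta 0) plus the BN running statistics ("state"). Uses the
# current RNG state; callers seed for reproducibility.
init_network <- function(arch) {
  params <- list()
  state <- list()
  c_in <- 1L
  for (i in seq_along(arch$conv_stages)) {
    st <- arch$conv_stages[[i]]
    k <- st$kernel; f <- st$filters
    params[[paste0("conv", i, ".W")]] <- glorot(k * c_in, f, k * c_in, k * f)
    params[[paste0("conv", i, ".b")]] <- numeric(f)
    params[[paste0("bn", i, ".gamma")]] <- rep(1, f)
    params[[paste0("bn", i, ".beta")]] <- numeric(f)
    state[[paste0("bn", i, ".mean")]] <- numeric(f)
    state[[paste0("bn", i, ".var")]] <- rep(1, f)
    c_in <- f
  }
  if (arch$pooling_reduce == "conv") {
    sp <- init_signal_pooling(arch$feat_c)
    params[["sp.W"]] <- sp$W
    params[["sp.b"]] <- sp$b
  }
  nl <- init_nonlocal(arch$pool_c, arch$c_hat)
  for (nm in names(nl)) params[[paste0("nl.", nm)]] <- nl[[nm]]
  widths <- c(arch$flat, arch$fc_widths, arch$n_classes)
  for (i in seq_len(length(widths) - 1L)) {
    params[[paste0("fc", i, ".W")]] <- glorot(widths[i], widths[i + 1L],
                                              widths[i], widths[i + 1L])
    params[[paste0("fc", i, ".b")]] <- numeric(widths[i + 1L])
  }
  list(params = params, state = state)
}

nl_params <- function(params) {
  nms <- c("Wphi", "bphi", "Wdelta", "bdelta", "Wrho", "brho",
           "Winner", "binner", "Wouter", "bouter")
  out <- lapply(nms, function(nm) params[[paste0("nl.", nm)]])
  names(out) <- nms
  out
}

# Forward pass over a batch. X: n x input_length matrix of segments.
# Returns probs (n x n_classes) and, when training, the caches needed for
# the backward pass plus updated BN running stats.
network_forward <- function(params, state, X, arch, training = FALSE) {
  n <- nrow(X)
  w <- arch$input_length
  H <- matrix(t(X), ncol = 1L)            # (n*w) x 1, example-major
  caches <- list()
  for (i in seq_along(arch$conv_stages)) {
    st <- arch$conv_stages[[i]]
    cv <- conv1d_forward(H, params[[paste0("conv", i, ".W")]],
                         params[[paste0("conv", i, ".b")]],
                         n, w, st$kernel, st$stride, st$pl, st$pr)
    w <- cv$o
    bn <- batchnorm_forward(cv$Y, params[[paste0("bn", i, ".gamma")]],
                            params[[paste0("bn", i, ".beta")]],
                            state[[paste0("bn", i, ".mean")]],
                            state[[paste0("bn", i, ".var")]], training)
    if (training) {
      state[[paste0("bn", i, ".mean")]] <- bn$run_mean
      state[[paste0("bn", i, ".var")]] <- bn$run_var
    }
    A <- relu(bn$Y)
    stage_cache <- list(conv = cv$cache, bn = bn$cache, pre_relu = bn$Y)
    H <- A
    if (isTRUE(st$pool)) {
      mp <- maxpool_forward(H, n, w, 2L, 2L)
      H <- mp$Y
      w <- mp$o
      stage_cache$pool <- mp$cache
    }
    caches[[paste0("stage", i)]] <- stage_cache
  }
  sp <- sp_forward(H, n, w, list(W = params[["sp.W"]], b = params[["sp.b"]]),
                   arch$pooling_reduce)
  caches$sp <- sp$cache
  H <- sp$Y
  nl <- nl_forward(H, n, w, nl_params(params), arch$affinity)
  caches$nl <- nl$cache
  H <- nl$Y
  Fl <- flatten_forward(H, n, w)
  caches$flat_w <- w
  n_fc <- length(arch$fc_widths) + 1L
  A <- Fl
  for (i in seq_len(n_fc)) {
    Z <- dense_forward(A, params[[paste0("fc", i, ".W")]],
                       params[[paste0("fc", i, ".b")]])
    caches[[paste0("fc", i)]] <- list(X = A, pre = Z)
    A <- if (i < n_fc) relu(Z) else Z
  }
  probs <- softmax_rows(A)
  list(probs = probs, logits = A, caches = caches, state = state, n = n)
}

# Backward pass from dlogits; returns gradients named like params.
network_backward <- function(params, arch, fwd, dlogits) {
  caches <- fwd$caches
  n <- fwd$n
  grads <- list()
  n_fc <- length(arch$fc_widths) + 1L
  dA <- dlogits
  for (i in rev(seq_len(n_fc))) {
    cc <- caches[[paste0("fc", i)]]
    if (i < n_fc) dA <- relu_backward(dA, cc$pre)
    d <- dense_backward(dA, cc$X, params[[paste0("fc", i, ".W")]])
    grads[[paste0("fc", i, ".W")]] <- d$dW
    grads[[paste0("fc", i, ".b")]] <- d$db
    dA <- d$dX
  }
  w <- caches$flat_w
  dH <- flatten_backward(dA, n, w)
  dnl <- nl_backward(dH, nl_params(params), caches$nl)
  for (nm in c("Wphi", "bphi", "Wdelta", "bdelta", "Wrho", "brho",
               "Winner", "binner", "Wouter", "bouter"))
    grads[[paste0("nl.", nm)]] <- dnl[[paste0("d", nm)]]
  dH <- dnl$dX
  dsp <- sp_backward(dH, list(W = params[["sp.W"]], b = params[["sp.b"]]),
                     caches$sp)
  if (!is.null(dsp$dW)) {
    grads[["sp.W"]] <- dsp$dW
    grads[["sp.b"]] <- dsp$db
  }
  dH <- dsp$dX
  for (i in rev(seq_along(arch$conv_stages))) {
    st <- arch$conv_stages[[i]]
    cc <- caches[[paste0("stage", i)]]
    if (isTRUE(st$pool)) dH <- maxpool_backward(dH, cc$pool)
    dH <- relu_backward(dH, cc$pre_relu)
    bn <- batchnorm_backward(dH, cc$bn)
    grads[[paste0("bn", i, ".gamma")]] <- bn$dgamma
    grads[[paste0("bn", i, ".beta")]] <- bn$dbeta
    cv <- conv1d_backward(bn$dX, params[[paste0("conv", i, ".W")]], cc$conv)
    grads[[paste0("conv", i, ".W")]] <- cv$dW
    grads[[paste0("conv", i, ".b")]] <- cv$db
    dH <- cv$dX
  }
  grads
}

#' Total trainable parameter count
#' @param model A fitted [mnlnet()] model (or a raw parameter list).
#' @return Integer number of scalar parameters.
#' @export
n_parameters <- function(model) {
  params <- if (inherits(model, "mnlnet")) model$params else model
  sum(vapply(params, length, integer(1)))
}
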
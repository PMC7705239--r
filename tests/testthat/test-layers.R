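# The signal pooling layer and the multi-scale non-local layer.

test_that("sliding max pooling matches hand-computed windows", {
  expect_equal(as.vector(multi_pool(c(1, 3, 2, 5), 2)), c(3, 3, 5))
  expect_equal(as.vector(multi_pool(c(1, 3, 2, 5), 4)), 5)
  x <- matrix(rnorm(12), 6, 2)
  expect_equal(multi_pool(x, 1), x)          # window 1 is the identity
  expect_error(multi_pool(c(1, 2), 5), "outside")
})

test_that("branch geometry conserves length: o + l + r = w", {
  for (w in 4:40) for (p in c(1L, 2L, 4L)) {
    sp <- pool_branch_spec(w, p)
    expect_equal(sp$o, w - p + 1L)
    expect_equal(sp$l, as.integer(ceiling((w - sp$o) / 4)))
    expect_gte(sp$r, 0L)
    expect_identical(sp$o + sp$l + sp$r, w)
  }
})

test_that("asymmetric zero padding places values at the computed offset", {
  expect_equal(as.vector(pad_to_length(c(3, 3, 5), 4)), c(0, 3, 3, 5))
  expect_equal(as.vector(pad_to_length(5, 4)), c(0, 5, 0, 0))
  x <- matrix(1:6, 3, 2)
  expect_equal(pad_to_length(x, 3), x)       # no padding when o = w
  expect_error(pad_to_length(1:5, 4), "longer")
})

test_that("pooling-branch concatenation matches the composed oracles", {
  concat <- signal_pool_concat(c(1, 3, 2, 5))
  expect_equal(dim(concat), c(4L, 3L))
  expect_equal(concat[, 1], c(1, 3, 2, 5))
  expect_equal(concat[, 2], c(0, 3, 3, 5))
  expect_equal(concat[, 3], c(0, 5, 0, 0))

  # zero in, zero out: max pooling and padding preserve zero
  z <- matrix(0, 6, 3)
  expect_true(all(signal_pool_concat(z) == 0))
})

test_that("signal pooling layer is shape-preserving with the reduction conv", {
  set.seed(2)
  x <- matrix(rnorm(4 * 80), 4, 80)
  params <- init_signal_pooling(80)
  y <- signal_pooling_layer(x, params)
  expect_equal(dim(y), c(4L, 80L))
  expect_equal(dim(signal_pooling_layer(x, reduce = "none")), c(4L, 240L))
  expect_error(signal_pooling_layer(matrix(1, 3, 2), params), ">= 4")
})

test_that("similarity is the literal channel-affinity matrix product", {
  expect_equal(similarity(diag(2), diag(2)), diag(2))
  expect_equal(similarity(matrix(c(1, 2), 2, 1), matrix(c(3, 4), 2, 1)),
               matrix(11, 1, 1))
  # brute-force double-loop oracle on random 5 x 3 inputs
  set.seed(31)
  phi <- matrix(rnorm(15), 5, 3)
  delta <- matrix(rnorm(15), 5, 3)
  R <- similarity(phi, delta)
  for (i in 1:3) for (j in 1:3)
    expect_equal(R[i, j], sum(phi[, i] * delta[, j]), tolerance = 1e-12)
  expect_error(similarity(phi, delta[, 1:2]), "differ")
})

test_that("similarity is bilinear in its arguments", {
  set.seed(8)
  phi <- matrix(rnorm(12), 4, 3)
  delta <- matrix(rnorm(12), 4, 3)
  expect_equal(similarity(2.5 * phi, delta), 2.5 * similarity(phi, delta))
  phi2 <- matrix(rnorm(12), 4, 3)
  expect_equal(similarity(phi + phi2, delta),
               similarity(phi, delta) + similarity(phi2, delta))
})

test_that("attention normalization is a row softmax", {
  Rhat <- attention_normalize(matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))
  e <- exp(1)
  expect_equal(Rhat[1, ], c(e / (e + 1), 1 / (e + 1)), tolerance = 1e-6)
  # constant matrix gives uniform rows
  expect_true(all(abs(attention_normalize(matrix(3, 4, 4)) - 0.25) < 1e-12))
  # rows always sum to 1, entries strictly in (0, 1)
  set.seed(19)
  for (i in 1:10) {
    R <- matrix(rnorm(36, sd = 5), 6, 6)
    Rh <- attention_normalize(R)
    expect_equal(unname(rowSums(Rh)), rep(1, 6), tolerance = 1e-6)
    expect_true(all(Rh > 0 & Rh < 1))
  }
})

test_that("embeddings with identity or zero weights behave as expected", {
  set.seed(4)
  x <- matrix(rnorm(4 * 6), 4, 6)
  params <- fixed_nonlocal_params(6, 6)
  for (nm in c("Wphi", "Wdelta", "Wrho")) params[[nm]] <- diag(6)
  emb <- nonlocal_embed(x, params)
  expect_equal(emb$phi, x)
  expect_equal(emb$delta, x)
  expect_equal(emb$rho, x)
  for (nm in c("Wphi", "Wdelta", "Wrho")) params[[nm]] <- matrix(0, 6, 6)
  emb0 <- nonlocal_embed(x, params)
  expect_true(all(emb0$phi == 0) && all(emb0$rho == 0))
  # shape contract with c_hat = c/2
  p2 <- fixed_nonlocal_params(80, 40)
  e2 <- nonlocal_embed(matrix(rnorm(4 * 80), 4, 80), p2)
  expect_equal(dim(e2$phi), c(4L, 40L))
})

test_that("zeroed attention branch reduces the layer to a residual pass-through", {
  set.seed(6)
  x <- matrix(rnorm(4 * 8), 4, 8)
  params <- fixed_nonlocal_params(8, 4)
  params$Winner <- matrix(0, 4, 8); params$binner <- numeric(8)
  params$Wouter <- diag(8); params$bouter <- numeric(8)
  expect_equal(multi_scale_nonlocal_layer(x, params), x, tolerance = 1e-12)
})

test_that("full non-local layer matches an explicit-loop oracle", {
  # oracle: every matrix product written as scalar double loops
  nl_oracle <- function(x, p) {
    w <- nrow(x); c_in <- ncol(x); ch <- ncol(p$Wphi)
    embed <- function(W, b) {
      out <- matrix(0, w, ch)
      for (t in 1:w) for (j in 1:ch) {
        acc <- b[j]
        for (q in 1:c_in) acc <- acc + x[t, q] * W[q, j]
        out[t, j] <- acc
      }
      out
    }
    phi <- embed(p$Wphi, p$bphi); delta <- embed(p$Wdelta, p$bdelta)
    rho <- embed(p$Wrho, p$brho)
    R <- matrix(0, ch, ch)
    for (i in 1:ch) for (j in 1:ch)
      for (t in 1:w) R[i, j] <- R[i, j] + phi[t, i] * delta[t, j]
    Rhat <- matrix(0, ch, ch)
    for (i in 1:ch) {
      m <- max(R[i, ]); den <- sum(exp(R[i, ] - m))
      for (j in 1:ch) Rhat[i, j] <- exp(R[i, j] - m) / den
    }
    att <- matrix(0, w, ch)
    for (t in 1:w) for (i in 1:ch)
      for (j in 1:ch) att[t, i] <- att[t, i] + rho[t, j] * Rhat[i, j]
    z <- matrix(0, w, c_in)
    for (t in 1:w) for (q in 1:c_in) {
      acc <- p$binner[q]
      for (j in 1:ch) acc <- acc + att[t, j] * p$Winner[j, q]
      z[t, q] <- acc + x[t, q]
    }
    out <- matrix(0, w, c_in)
    for (t in 1:w) for (q in 1:c_in) {
      acc <- p$bouter[q]
      for (r in 1:c_in) acc <- acc + z[t, r] * p$Wouter[r, q]
      out[t, q] <- acc
    }
    out
  }
  set.seed(77)
  x <- matrix(rnorm(4 * 8), 4, 8)
  params <- fixed_nonlocal_params(8, 4, seed = 55)
  expect_equal(multi_scale_nonlocal_layer(x, params), nl_oracle(x, params),
               tolerance = 1e-5)
})

test_that("layer forwards are deterministic and shape-preserving", {
  set.seed(90)
  x <- matrix(rnorm(4 * 80), 4, 80)
  sp <- init_signal_pooling(80)
  nl <- init_nonlocal(80, 40)
  y1 <- multi_scale_nonlocal_layer(signal_pooling_layer(x, sp), nl)
  y2 <- multi_scale_nonlocal_layer(signal_pooling_layer(x, sp), nl)
  expect_identical(y1, y2)
  expect_equal(dim(y1), dim(x))
  # position-affinity variant is also shape-preserving
  y3 <- multi_scale_nonlocal_layer(x, nl, affinity = "position")
  expect_equal(dim(y3), dim(x))
})

test_that("batched layer paths agree with the single-example functions", {
  set.seed(14)
  n <- 3; w <- 5; c_in <- 6
  X <- matrix(rnorm(n * w * c_in), n * w, c_in)
  spp <- init_signal_pooling(c_in)
  nlp <- init_nonlocal(c_in, 3)
  spb <- mnlnet:::sp_forward(X, n, w, spp)$Y
  nlb <- mnlnet:::nl_forward(X, n, w, nlp)$Y
  for (ex in 1:n) {
    rows <- ((ex - 1) * w + 1):(ex * w)
    expect_equal(spb[rows, ], signal_pooling_layer(X[rows, ], spp),
                 tolerance = 1e-12)
    expect_equal(nlb[rows, ], multi_scale_nonlocal_layer(X[rows, ], nlp),
                 tolerance = 1e-12)
  }
})
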
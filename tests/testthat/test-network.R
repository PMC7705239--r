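# Architecture assembly, shape trace, forward-pass contracts.

test_that("relu and the softmax head follow their closed forms", {
  expect_equal(relu(-2), 0)
  expect_equal(relu(3), 3)
  expect_equal(relu(0), 0)
  expect_equal(relu(c(-1, 0.5)), c(0, 0.5))

  expect_equal(softmax_head(rep(1, 5)), rep(0.2, 5))
  expect_equal(softmax_head(c(log(2), log(1))), c(2 / 3, 1 / 3))
  set.seed(3)
  for (i in 1:10) {
    p <- softmax_head(rnorm(4, sd = 10))
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(all(p > 0))
  }
  # shift invariance
  z <- rnorm(5)
  expect_equal(softmax_head(z), softmax_head(z + 100), tolerance = 1e-12)
  expect_error(softmax_head(1), "at least 2")
})

test_that("the standard architecture reproduces the reference shape trace", {
  arch <- mnl_architecture(178, 2)
  tr <- shape_trace(arch)
  expect_equal(tr$length[tr$layer == "conv1"], 178L)
  expect_equal(tr$length[tr$layer == "pool1"], 89L)
  expect_equal(tr$length[tr$layer == "conv2"], 35L)
  expect_equal(tr$length[tr$layer == "pool2"], 17L)
  expect_equal(tr$length[tr$layer == "conv3"], 4L)
  expect_equal(tr$channels[tr$layer == "conv3"], 80L)
  # the two multi-scale layers are shape-preserving at 4 x 80
  expect_equal(tr[tr$layer == "signal_pooling", c("length", "channels")],
               tr[tr$layer == "conv3", c("length", "channels")],
               ignore_attr = TRUE)
  expect_equal(tr[tr$layer == "nonlocal", c("length", "channels")],
               tr[tr$layer == "conv3", c("length", "channels")],
               ignore_attr = TRUE)
  expect_equal(arch$flat, 320L)
  expect_equal(arch$c_hat, 40L)
})

test_that("head width follows the task's class count", {
  set.seed(10)
  X <- matrix(rnorm(3 * 178), 3)
  for (nc in c(2L, 5L)) {
    arch <- mnl_architecture(178, nc)
    net <- mnlnet:::init_network(arch)
    probs <- mnlnet:::network_forward(net$params, net$state, X, arch)$probs
    expect_equal(dim(probs), c(3L, nc))
    expect_equal(unname(rowSums(probs)), rep(1, 3), tolerance = 1e-6)
  }
})

test_that("forward pass is deterministic and numerically stable", {
  set.seed(21)
  arch <- mnl_architecture(178, 2)
  net <- mnlnet:::init_network(arch)
  X <- matrix(rnorm(7 * 178), 7)
  p1 <- mnlnet:::network_forward(net$params, net$state, X, arch)$probs
  p2 <- mnlnet:::network_forward(net$params, net$state, X, arch)$probs
  expect_identical(p1, p2)
  # inputs scaled by 1e3 still give finite probabilities
  p3 <- mnlnet:::network_forward(net$params, net$state, X * 1e3, arch)$probs
  expect_true(all(is.finite(p3)))
  expect_equal(unname(rowSums(p3)), rep(1, 7), tolerance = 1e-6)
  expect_error(
    mnlnet:::network_forward(net$params, net$state, X[, 1:100], arch),
    "fit|length")
})

test_that("parameter count is a pure function of the architecture", {
  arch <- mnl_architecture(178, 2)
  set.seed(1); n1 <- n_parameters(mnlnet:::init_network(arch)$params)
  set.seed(99); n2 <- n_parameters(mnlnet:::init_network(arch)$params)
  expect_identical(n1, n2)
})

test_that("analytic gradients match finite differences on a small network", {
  set.seed(42)
  arch <- mnl_architecture(24, 3, c_hat = 2,
    conv_stages = list(
      list(filters = 3L, kernel = 5L, stride = 1L, pool = TRUE),
      list(filters = 4L, kernel = 3L, stride = 2L, pool = FALSE),
      list(filters = 4L, kernel = 2L, stride = 1L, pool = FALSE)),
    fc_widths = c(6L, 4L))
  net <- mnlnet:::init_network(arch)
  X <- matrix(rnorm(5 * 24), 5)
  y <- c(0L, 1L, 2L, 1L, 0L)
  fwd <- mnlnet:::network_forward(net$params, net$state, X, arch,
                                  training = TRUE)
  ce <- mnlnet:::cross_entropy(fwd$probs, y)
  g <- mnlnet:::network_backward(net$params, arch, fwd, ce$dlogits)
  eps <- 1e-6
  loss_at <- function(params) {
    f <- mnlnet:::network_forward(params, net$state, X, arch,
                                  training = TRUE)
    mnlnet:::cross_entropy(f$probs, y)$loss
  }
  for (nm in names(net$params)) {
    idx <- sample.int(length(net$params[[nm]]),
                      min(length(net$params[[nm]]), 3))
    for (i in idx) {
      pp <- net$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- net$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      ana <- g[[nm]][i]
      # conv biases feeding batch norm have an exactly-zero gradient;
      # finite differences only see rounding noise there
      if (abs(num) + abs(ana) > 1e-8)
        expect_lt(abs(num - ana) / (abs(num) + abs(ana)), 1e-4)
    }
  }
})
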
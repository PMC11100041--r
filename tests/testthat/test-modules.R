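# Core engine correctness: convolution/pooling against naive oracles,
# finite-difference gradient checks through every layer type, and the fused
# batch-norm + ReLU against its two-step counterpart.

test_that("convolution matches the naive direct-convolution oracle", {
  set.seed(11)
  for (cfg in list(list(k = 3L, s = 1L, p = 1L, bias = TRUE),
                   list(k = 1L, s = 1L, p = 0L, bias = FALSE),
                   list(k = 3L, s = 2L, p = 1L, bias = FALSE),
                   list(k = 7L, s = 2L, p = 3L, bias = TRUE))) {
    x <- array(rnorm(10 * 10 * 2 * 2), c(10, 10, 2, 2))
    w <- array(rnorm(cfg$k * cfg$k * 2 * 3), c(cfg$k, cfg$k, 2, 3))
    b <- if (cfg$bias) rnorm(3) else NULL
    got <- resmini:::conv2d_forward_cpp(x, w, b, cfg$s, cfg$p)
    want <- naive_conv(x, w, b, cfg$s, cfg$p)
    expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("max pooling matches a naive implementation and routes gradients", {
  set.seed(12)
  x <- array(rnorm(9 * 9 * 2 * 2), c(9, 9, 2, 2))
  r <- resmini:::maxpool_forward_cpp(x, 3L, 2L, 1L)
  # naive: pad with -Inf, take window max
  xp <- array(-Inf, c(11, 11, 2, 2))
  xp[2:10, 2:10, , ] <- x
  for (n in 1:2) for (c_ in 1:2) for (ho in 1:5) for (wo in 1:5) {
    win <- xp[(ho - 1) * 2 + 1:3, (wo - 1) * 2 + 1:3, c_, n]
    expect_equal(r$out[ho, wo, c_, n], max(win))
  }
  # backward distributes each output gradient to its argmax location
  dout <- array(1, dim(r$out))
  dx <- resmini:::maxpool_backward_cpp(r$argmax, dout, dim(x))
  expect_equal(sum(dx), sum(dout))
  expect_true(all(dx >= 0))
})

test_that("backpropagation matches finite differences through all layer kinds", {
  set.seed(13)
  net <- resmini:::nn_seq(
    resmini:::nn_conv(2, 3, 3, 1, 1, TRUE),
    resmini:::nn_bnrelu(3),
    resmini:::nn_maxpool(3, 2, 1),
    resmini:::nn_residual(
      main = resmini:::nn_seq(resmini:::nn_conv(3, 4, 3, 2, 1, FALSE),
                              resmini:::nn_bn(4), resmini:::nn_relu(),
                              resmini:::nn_conv(4, 4, 3, 1, 1, FALSE),
                              resmini:::nn_bnrelu(4)),
      shortcut = resmini:::nn_seq(resmini:::nn_conv(3, 4, 3, 2, 1, FALSE))),
    resmini:::nn_gap(), resmini:::nn_dense(4, 2))
  x <- array(rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  y <- c(1L, 0L, 1L)
  lossfun <- function(m) {
    r <- resmini:::nn_forward(m, x, training = TRUE)
    cross_entropy(softmax(r$out), y)
  }
  fw <- resmini:::nn_forward(net, x, training = TRUE)
  p <- softmax(fw$out)
  Y <- matrix(0, 2, 3); Y[cbind(y + 1L, 1:3)] <- 1
  bk <- resmini:::nn_backward(net, fw$cache, (p - Y) / 3)
  par <- resmini:::nn_params(net)
  expect_setequal(names(par), names(bk$grads))
  eps <- 1e-5
  set.seed(14)
  for (nm in names(par)) {
    for (i in sample(length(par[[nm]]), min(3, length(par[[nm]])))) {
      p2 <- par; p2[[nm]][i] <- p2[[nm]][i] + eps
      lp <- lossfun(resmini:::nn_set_params(net, p2))
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      lm <- lossfun(resmini:::nn_set_params(net, p2))
      fd <- (lp - lm) / (2 * eps)
      g <- bk$grads[[nm]][i]
      # a conv bias feeding straight into BN has an exactly-zero gradient
      expect_lt(abs(fd - g), 1e-4 * max(1, abs(fd) + abs(g)))
    }
  }
})

test_that("fused batch-norm + ReLU equals batch norm followed by ReLU", {
  set.seed(15)
  x <- array(rnorm(6 * 6 * 3 * 4, sd = 2), c(6, 6, 3, 4))
  fused <- resmini:::nn_bnrelu(3)
  two <- resmini:::nn_seq(resmini:::nn_bn(3), resmini:::nn_relu())
  # give them identical (non-trivial) affine parameters
  pars <- list(gamma = c(0.5, 1.5, 2), beta = c(-0.2, 0.1, 0.4))
  fused$gamma <- pars$gamma; fused$beta <- pars$beta
  two$modules[[1]]$gamma <- pars$gamma; two$modules[[1]]$beta <- pars$beta
  for (training in c(TRUE, FALSE)) {
    rf <- resmini:::nn_forward(fused, x, training)
    rt <- resmini:::nn_forward(two, x, training)
    expect_equal(rf$out, rt$out, tolerance = 1e-12)
    dout <- array(rnorm(length(rf$out)), dim(rf$out))
    bf <- resmini:::nn_backward(fused, rf$cache, dout)
    bt <- resmini:::nn_backward(two, rt$cache, dout)
    expect_equal(bf$dx, bt$dx, tolerance = 1e-10)
    expect_equal(unname(bf$grads[["gamma"]]), unname(bt$grads[["l1.gamma"]]),
                 tolerance = 1e-10)
  }
})

test_that("softmax columns are probability vectors and handle extreme logits", {
  set.seed(16)
  z <- matrix(rnorm(2 * 50, sd = 30), 2, 50)
  p <- softmax(z)
  expect_true(all(p >= 0))
  expect_equal(colSums(p), rep(1, 50), tolerance = 1e-12)
  expect_equal(softmax(matrix(c(1000, -1000)))[, 1], c(1, 0))
})
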
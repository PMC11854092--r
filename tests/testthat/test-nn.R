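# The convolution engine is the substrate of every neural component, so it
# is pinned directly: forward against a naive R convolution, gradients
# against central differences (double-precision kernel path), and the
# single-precision training path against the double path.

naive_conv <- function(x, Wm, b, k, stride, pt, pb, pl, pr) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  Ho <- (H + pt + pb - k) %/% stride + 1
  Wo <- (W + pl + pr - k) %/% stride + 1
  Cout <- nrow(Wm)
  xp <- array(0, dim = c(H + pt + pb, W + pl + pr, C))
  xp[pt + seq_len(H), pl + seq_len(W), ] <- x
  out <- array(0, dim = c(Ho, Wo, Cout))
  for (co in seq_len(Cout)) for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    acc <- b[co]
    for (c in seq_len(C)) for (ki in seq_len(k)) for (kj in seq_len(k)) {
      wgt <- Wm[co, ((c - 1) * k + (ki - 1)) * k + kj]
      acc <- acc + wgt * xp[(i - 1) * stride + ki, (j - 1) * stride + kj, c]
    }
    out[i, j, co] <- acc
  }
  out
}

test_that("convolution forward matches a naive direct implementation", {
  withr::with_seed(1, {
    for (case in list(c(3, 1, 1), c(4, 2, 1), c(1, 1, 0))) {
      k <- case[1]; s <- case[2]; p <- case[3]
      x <- array(rnorm(6 * 6 * 2), dim = c(6, 6, 2))
      Wm <- matrix(rnorm(3 * k^2 * 2), nrow = 3)
      b <- rnorm(3)
      got <- surgiview:::cpp_conv2d_forward(x, Wm, b, k, s, p, p, p, p)
      want <- naive_conv(x, Wm, b, k, s, p, p, p, p)
      expect_equal(got, want, tolerance = 1e-12)
    }
    # asymmetric "same" padding for the even 4x4 kernel, stride 1
    x <- array(rnorm(5 * 5 * 1), dim = c(5, 5, 1))
    Wm <- matrix(rnorm(16), nrow = 1); b <- 0.3
    got <- surgiview:::cpp_conv2d_forward(x, Wm, b, 4, 1, 1, 2, 1, 2)
    expect_equal(dim(got), c(5, 5, 1))
    expect_equal(got, naive_conv(x, Wm, b, 4, 1, 1, 2, 1, 2),
                 tolerance = 1e-12)
  })
})

test_that("convolution gradients match central differences", {
  withr::with_seed(2, {
    x <- array(rnorm(7 * 7 * 2), dim = c(7, 7, 2))
    Wm <- matrix(rnorm(3 * 16 * 2), nrow = 3)
    b <- rnorm(3)
    fwd <- function(xx, ww, bb)
      surgiview:::cpp_conv2d_forward(xx, ww, bb, 4, 2, 1, 1, 1, 1)
    dout <- array(rnorm(length(fwd(x, Wm, b))), dim = dim(fwd(x, Wm, b)))
    g <- surgiview:::cpp_conv2d_backward(x, Wm, dout, 4, 2, 1, 1, 1, 1,
                                         TRUE, TRUE, FALSE)
    eps <- 1e-6
    for (i in sample(length(Wm), 10)) {
      W1 <- Wm; W1[i] <- W1[i] + eps
      W2 <- Wm; W2[i] <- W2[i] - eps
      num <- sum((fwd(x, W1, b) - fwd(x, W2, b)) * dout) / (2 * eps)
      expect_equal(g$dW[i], num, tolerance = 1e-6)
    }
    for (i in sample(length(x), 10)) {
      x1 <- x; x1[i] <- x1[i] + eps
      x2 <- x; x2[i] <- x2[i] - eps
      num <- sum((fwd(x1, Wm, b) - fwd(x2, Wm, b)) * dout) / (2 * eps)
      expect_equal(g$dx[i], num, tolerance = 1e-6)
    }
    expect_equal(g$db, as.matrix(apply(dout, 3, sum)), tolerance = 1e-9)
  })
})

test_that("the single-precision training path tracks the double path", {
  withr::with_seed(3, {
    x <- array(rnorm(16 * 16 * 8), dim = c(16, 16, 8))
    Wm <- matrix(rnorm(16 * 16 * 8) * 0.1, nrow = 16)
    b <- rnorm(16) * 0.1
    fd <- surgiview:::cpp_conv2d_forward(x, Wm, b, 4, 2, 1, 1, 1, 1, FALSE)
    fs <- surgiview:::cpp_conv2d_forward(x, Wm, b, 4, 2, 1, 1, 1, 1, TRUE)
    expect_equal(fs, fd, tolerance = 1e-5)
  })
})

test_that("upsampling and max pooling are exact adjoint pairs", {
  withr::with_seed(4, {
    x <- array(rnorm(6 * 6 * 3), dim = c(6, 6, 3))
    y <- array(rnorm(12 * 12 * 3), dim = c(12, 12, 3))
    up <- surgiview:::cpp_upsample2x(x)
    expect_equal(up[1:2, 1:2, 1], matrix(x[1, 1, 1], 2, 2))
    expect_equal(sum(up * y),
                 sum(x * surgiview:::cpp_upsample2x_backward(y)),
                 tolerance = 1e-12)
    mp <- surgiview:::cpp_maxpool_forward(x, 3, 2, 1, 1, 1, 1)
    # every pooled value is the max of its (clipped) 3x3 window
    expect_equal(mp$out[1, 1, 2], max(x[1:2, 1:2, 2]))
    expect_equal(mp$out[2, 2, 1], max(x[2:4, 2:4, 1]))
    d <- array(rnorm(length(mp$out)), dim = dim(mp$out))
    dx <- surgiview:::cpp_maxpool_backward(d, mp$arg, 6, 6, 3)
    expect_equal(sum(dx), sum(d), tolerance = 1e-12)
  })
})

test_that("Adam drives a quadratic to its minimum deterministically", {
  target <- list(W = matrix(c(2, -1, 0.5, 3), 2), b = c(-2, 1))
  run <- function() {
    p <- list(W = matrix(0, 2, 2), b = c(0, 0))
    st <- surgiview:::adam_init(p)
    for (i in 1:400) {
      g <- surgiview:::tree_map2(p, target, function(a, t) 2 * (a - t))
      up <- surgiview:::adam_step(p, g, st, lr = 0.05)
      p <- up$params; st <- up$state
    }
    p
  }
  p1 <- run(); p2 <- run()
  expect_identical(p1, p2)
  expect_equal(p1$W, target$W, tolerance = 1e-3)
  expect_equal(p1$b, target$b, tolerance = 1e-3)
})
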
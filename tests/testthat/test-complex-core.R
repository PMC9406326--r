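test_that("complex convolution equals native complex arithmetic", {
  # multiplicative identity: 1x1 kernel of 1 + 0i
  set.seed(5)
  x <- rand_ct(c(4, 4, 1))
  w_id <- complex_tensor(array(1, c(1, 1, 1, 1)), array(0, c(1, 1, 1, 1)))
  y <- complex_conv2d(x, w_id)
  expect_equal(y$re, x$re, tolerance = 1e-12)
  expect_equal(y$im, x$im, tolerance = 1e-12)

  # purely imaginary 1x1 kernel rotates a real input by i
  xr <- complex_tensor(array(rnorm(16), c(4, 4, 1)))
  w_i <- complex_tensor(array(0, c(1, 1, 1, 1)), array(1, c(1, 1, 1, 1)))
  yi <- complex_conv2d(xr, w_i)
  expect_equal(max(abs(yi$re)), 0)
  expect_equal(yi$im, xr$re, tolerance = 1e-12)

  # randomised brute-force oracle
  set.seed(17)
  for (trial in 1:20) {
    kh <- sample(1:3, 1); kw <- sample(1:3, 1)
    cin <- sample(1:3, 1); cout <- sample(1:3, 1)
    H <- kh + sample(1:4, 1); W <- kw + sample(1:4, 1)
    x <- rand_ct(c(H, W, cin))
    w <- rand_ct(c(kh, kw, cin, cout))
    got <- as_complex_array(complex_conv2d(x, w))
    expect_lt(max(Mod(got - brute_conv(x, w))), 1e-10)
  }
})

test_that("complex convolution is linear and embeds real convolution", {
  set.seed(23)
  x <- rand_ct(c(6, 6, 2)); y <- rand_ct(c(6, 6, 2))
  w <- rand_ct(c(3, 3, 2, 2))
  alpha <- 1.7
  lhs <- complex_conv2d(complex_tensor(alpha * x$re + y$re,
                                       alpha * x$im + y$im), w)
  rx <- complex_conv2d(x, w); ry <- complex_conv2d(y, w)
  expect_equal(lhs$re, alpha * rx$re + ry$re, tolerance = 1e-10)
  expect_equal(lhs$im, alpha * rx$im + ry$im, tolerance = 1e-10)

  # zero imaginary parts everywhere -> exactly a real convolution
  xr <- complex_tensor(array(rnorm(72), c(6, 6, 2)))
  wr <- complex_tensor(array(rnorm(36), c(3, 3, 2, 2)))
  out <- complex_conv2d(xr, wr)
  expect_equal(max(abs(out$im)), 0)
  ref <- Re(brute_conv(xr, wr))
  expect_lt(max(abs(out$re - ref)), 1e-10)
})

test_that("zReLU gates on both components strictly and is idempotent", {
  z <- complex_tensor(c(3, -1, 3, 0.5), c(2, 2, 0, -0.1))
  g <- complex_relu(z)
  expect_equal(g$re, c(3, 0, 0, 0))
  expect_equal(g$im, c(2, 0, 0, 0))
  gg <- complex_relu(g)
  expect_equal(gg$re, g$re)
  expect_equal(gg$im, g$im)
  # pass-through set has both components > 0, blocked set exactly 0
  set.seed(3)
  zr <- rand_ct(c(50))
  gr <- complex_relu(zr)
  passed <- gr$re != 0 | gr$im != 0
  expect_true(all(gr$re[passed] > 0 & gr$im[passed] > 0))
  expect_true(all(gr$re[!passed] == 0 & gr$im[!passed] == 0))

  # crelu rectifies components independently (reduces to ReLU on reals)
  cr <- complex_relu(zr, mode = "crelu")
  expect_equal(cr$re, pmax(zr$re, 0))
  expect_equal(cr$im, pmax(zr$im, 0))
})

test_that("complex average pooling is the complex mean over windows", {
  const <- complex_tensor(array(2.5, c(4, 4, 1)), array(-1, c(4, 4, 1)))
  p <- complex_avg_pool(const, window = 2)
  expect_equal(unique(as.vector(p$re)), 2.5)
  expect_equal(unique(as.vector(p$im)), -1)

  vals <- complex_tensor(array(c(1, 3, 1, 3), c(2, 2, 1)),
                         array(c(1, 3, 1, 3), c(2, 2, 1)))
  pv <- complex_avg_pool(vals, window = 2)
  expect_equal(as.vector(pv$re), 2)
  expect_equal(as.vector(pv$im), 2)

  # zero imaginary part: real component equals a plain real average pool
  set.seed(9)
  xr <- complex_tensor(array(rnorm(36), c(6, 6, 1)))
  pr <- complex_avg_pool(xr, window = 3)
  ref <- sapply(0:1, function(j) sapply(0:1, function(i) {
    mean(xr$re[i * 3 + 1:3, j * 3 + 1:3, 1])
  }))
  expect_equal(matrix(pr$re[, , 1], 2, 2), ref, tolerance = 1e-12)
  expect_equal(max(abs(pr$im)), 0)

  expect_error(complex_avg_pool(vals, window = 5), "geometry")
})

test_that("complex dense layer matches the native complex matrix product", {
  x <- complex_tensor(c(1), c(1))
  W <- complex_tensor(matrix(0, 1, 1), matrix(1, 1, 1))
  y <- complex_linear(x, W)
  expect_equal(y$re, -1)
  expect_equal(y$im, 1)

  # identity weights
  xi <- rand_ct(c(3))
  Wi <- complex_tensor(diag(3), matrix(0, 3, 3))
  yid <- complex_linear(xi, Wi)
  expect_equal(yid$re, as.vector(xi$re), tolerance = 1e-12)
  expect_equal(yid$im, as.vector(xi$im), tolerance = 1e-12)

  set.seed(31)
  xv <- rand_ct(c(3))
  Wm <- rand_ct(c(2, 3))
  b <- rand_ct(c(2))
  got <- as_complex_array(complex_linear(xv, Wm, b))
  ref <- as.vector(as_complex_array(Wm) %*% as.vector(as_complex_array(xv))) +
    as.vector(as_complex_array(b))
  expect_lt(max(Mod(got - ref)), 1e-12)

  # conjugating variant
  gotc <- as_complex_array(complex_linear(xv, Wm, conjugate_weights = TRUE))
  refc <- Conj(as_complex_array(Wm)) %*% as_complex_array(xv)
  expect_lt(max(Mod(gotc - as.vector(refc))), 1e-12)

  expect_error(complex_linear(rand_ct(c(4)), Wm), "dimension mismatch")
})

test_that("magnitude readout is the elementwise modulus", {
  expect_equal(magnitude_readout(complex_tensor(3, 4)), 5)
  expect_equal(magnitude_readout(complex_tensor(0, 0)), 0)
  expect_equal(magnitude_readout(complex_tensor(c(1, 2), c(1, 0))),
               c(sqrt(2), 2))
})

test_that("parameter counting follows the complex-unit convention", {
  conv <- list(kind = "conv", domain = "complex", kernel = c(3, 3),
               n_in = 2, n_out = 4, bias = TRUE)
  expect_identical(count_parameters(conv, "complex"), 76L)
  expect_identical(count_parameters(conv, "real_scalar"), 152L)
  expect_identical(count_parameters(list(kind = "pool", domain = "real")), 0L)
  expect_identical(count_parameters(list(kind = "activation",
                                         domain = "complex")), 0L)
  dense <- list(kind = "dense", domain = "real", n_in = 10, n_out = 5,
                bias = TRUE)
  expect_identical(count_parameters(dense, "real_scalar"), 55L)
  expect_error(count_parameters(list(kind = "conv", domain = "real")),
               "unresolved")
})

test_that("analytic gradients of every layer match finite differences", {
  pair <- default_architecture_pair(input_size = 16)
  expect_lt(grad_check_network(pair$complex, seed = 3), 1e-4)
  expect_lt(grad_check_network(pair$real, seed = 4), 1e-4)
  # and for the crelu / real-readout variant used in embedding checks
  alt <- architecture_spec("complex", input_size = 16, activation = "crelu",
                           readout = "real")
  expect_lt(grad_check_network(alt, seed = 5), 1e-4)
})
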
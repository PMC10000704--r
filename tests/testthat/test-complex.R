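test_that("Cartesian ReLU acts independently on both parts", {
  expect_equal(crelu(complex(real = -1, imaginary = 2)), 0 + 2i)
  expect_equal(crelu(complex(real = 3, imaginary = -4)), 3 + 0i)
  set.seed(31)
  z <- complex(real = rnorm(50), imaginary = rnorm(50))
  expect_equal(crelu(crelu(z)), crelu(z))
  zt <- complex_tensor(matrix(rnorm(4), 2), matrix(rnorm(4), 2))
  r <- crelu(zt)
  expect_true(all(r$re >= 0) && all(r$im >= 0))
})

test_that("split complex sigmoid amplitude has the stated value and range", {
  expect_equal(complex_sigmoid_magnitude(0 + 0i), sqrt(0.5))
  expect_equal(complex_sigmoid_magnitude(0 + 0i), 0.70711, tolerance = 1e-5)
  expect_equal(complex_sigmoid_magnitude(complex(real = 50, imaginary = -50)),
               1, tolerance = 1e-9)
  set.seed(32)
  z <- complex(real = rnorm(200, sd = 4), imaginary = rnorm(200, sd = 4))
  v <- complex_sigmoid_magnitude(z)
  expect_true(all(v > 0 & v < sqrt(2)))
  # monotone in the real part at fixed imaginary part
  vs <- complex_sigmoid_magnitude(complex(real = seq(-5, 5, 0.5),
                                          imaginary = 0.7))
  expect_true(all(diff(vs) > 0))
})

test_that("complex dense layer performs a true complex product", {
  set.seed(33)
  n <- 3; fin <- 4; u <- 2
  xr <- matrix(rnorm(n * fin), n); xi <- matrix(rnorm(n * fin), n)
  Wr <- matrix(rnorm(fin * u), fin); Wi <- matrix(rnorm(fin * u), fin)
  out <- complex_dense_forward(list(re = xr, im = xi),
                               list(re = Wr, im = Wi))
  zc <- (xr + 1i * xi) %*% (Wr + 1i * Wi)
  expect_equal(out$re, Re(zc), tolerance = 1e-12)
  expect_equal(out$im, Im(zc), tolerance = 1e-12)
  # real weights on real input embed the real layer
  out2 <- complex_dense_forward(list(re = xr, im = xi * 0),
                                list(re = Wr, im = Wi * 0))
  expect_equal(out2$re, xr %*% Wr, tolerance = 1e-12)
  expect_equal(out2$im, xr %*% Wr * 0)
  # multiplication by i swaps parts and negates one
  outj <- complex_dense_forward(list(re = xr[, 1:2], im = xi[, 1:2]),
                                list(re = diag(2) * 0, im = diag(2)))
  expect_equal(outj$re, -xi[, 1:2])
  expect_equal(outj$im, xr[, 1:2])
})

test_that("complex convolution matches complex-number arithmetic", {
  set.seed(34)
  xr <- array(rnorm(5 * 5), c(5, 5, 1, 1)); xi <- array(rnorm(25), c(5, 5, 1, 1))
  wr <- array(rnorm(9), c(3, 3, 1, 1)); wi <- array(rnorm(9), c(3, 3, 1, 1))
  out <- complex_conv2d_forward(list(re = xr, im = xi),
                                list(re = wr, im = wi))
  orc <- conv_oracle(xr[, , , 1, drop = FALSE], wr) -
         conv_oracle(xi[, , , 1, drop = FALSE], wi)
  oic <- conv_oracle(xr[, , , 1, drop = FALSE], wi) +
         conv_oracle(xi[, , , 1, drop = FALSE], wr)
  expect_equal(out$re[, , 1, 1], orc[, , 1], tolerance = 1e-12)
  expect_equal(out$im[, , 1, 1], oic[, , 1], tolerance = 1e-12)
})

test_that("CACE is the average of the per-part cross-entropies", {
  y <- matrix(c(1, 0, 0, 1), 2)
  p <- list(re = matrix(c(0.9, 0.2, 0.3, 0.7), 2),
            im = matrix(c(0.6, 0.4, 0.1, 0.8), 2))
  # hand-summed oracle
  ce <- function(q) -mean(y * log(q) + (1 - y) * log(1 - q))
  expect_equal(cace_loss(p, y), 0.5 * (ce(p$re) + ce(p$im)), tolerance = 1e-10)
  # equal parts reduce to the plain cross-entropy
  expect_equal(cace_loss(list(re = p$re, im = p$re), y), ce(p$re),
               tolerance = 1e-12)
  # perfect (clamped) prediction attains the clamp floor
  expect_lt(cace_loss(list(re = y, im = y), y), 1e-5)
  expect_error(cace_loss(p, matrix(0.5, 2, 2)), "binary")
})

test_that("complex layer gradients agree with finite differences", {
  b <- mwisar:::node_builder()
  b$add("conv2d", filters = 2L, kernel = c(3L, 3L), padding = "same",
        activation = "relu", bias = TRUE)
  b$add("conv2d", filters = 1L, kernel = c(1L, 1L), padding = "same",
        activation = "sigmoid", bias = TRUE)
  m <- new_model("ctoy", c(2L, 2L, 1L), b$nodes, "complex", seed = 5)
  set.seed(35)
  x <- list(re = array(rnorm(8), c(2, 2, 1, 2)),
            im = array(rnorm(8), c(2, 2, 1, 2)))
  y <- array(rbinom(8, 1, 0.4), c(2, 2, 1, 2))
  lf <- mwisar:::loss_fun("cace")
  fw <- model_forward(m, x, training = TRUE, keep_cache = TRUE)
  # the cross-entropy losses differentiate through the output sigmoid
  bw <- model_backward(m, fw$caches, lf(fw$out, y)$grad, skip_out_act = TRUE)
  p <- model_params(m)
  for (nm in names(bw$grads)) for (part in c("re", "im")) {
    f <- function(v) {
      p2 <- p
      p2[[nm]][[part]] <- if (is.null(dim(p[[nm]][[part]]))) v
                          else array(v, dim(p[[nm]][[part]]))
      lf(model_forward(model_set_params(m, p2), x, training = TRUE)$out,
         y)$value
    }
    ng <- num_grad(f, as.vector(p[[nm]][[part]]))
    expect_lt(max(abs(ng - as.vector(bw$grads[[nm]][[part]]))),
              1e-4 * max(1, max(abs(ng))))
  }
})

test_that("zero imaginary weights on real input reproduce the real model", {
  spec <- function() {
    b <- mwisar:::node_builder()
    b$add("conv2d", filters = 3L, kernel = c(3L, 3L), padding = "same",
          activation = "relu", bias = TRUE)
    b$add("maxpool", size = 2L)
    b$add("flatten")
    b$add("dense", units = 5L, activation = "relu")
    b$nodes
  }
  mr <- new_model("re", c(4L, 4L, 1L), spec(), "real", seed = 8)
  mc <- new_model("cx", c(4L, 4L, 1L), spec(), "complex", seed = 9)
  # copy the real parameters into the complex model's real parts
  pr <- model_params(mr); pc <- model_params(mc)
  for (nm in names(pc)) {
    pc[[nm]]$re <- pr[[nm]]
    pc[[nm]]$im <- pr[[nm]] * 0
  }
  mc <- model_set_params(mc, pc)
  set.seed(36)
  x <- array(rnorm(16 * 2), c(4, 4, 1, 2))
  yr <- model_forward(mr, x)$out
  yc <- model_forward(mc, list(re = x, im = x * 0))$out
  expect_equal(yc$re, yr, tolerance = 1e-12)
  expect_equal(yc$im, yr * 0)
})
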
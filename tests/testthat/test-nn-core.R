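test_that("elementary activations behave as defined", {
  expect_equal(nn_relu(-1), 0)
  expect_equal(nn_relu(0), 0)
  expect_equal(nn_relu(2.5), 2.5)
  expect_equal(nn_relu(c(-3, 0.5)), c(0, 0.5))
})

test_that("dense forward matches the explicit loop oracle", {
  expect_equal(nn_dense_forward(matrix(1:2, 1), matrix(0, 2, 3), rep(0, 3)),
               matrix(0, 1, 3))
  expect_equal(nn_dense_forward(matrix(c(1, -2), 1), diag(2), rep(0, 2),
                                activation = "relu"),
               matrix(c(1, 0), 1))
  set.seed(21)
  x <- matrix(rnorm(12), 4, 3); W <- matrix(rnorm(9), 3, 3); b <- rnorm(3)
  expect_equal(nn_dense_forward(x, W, b), dense_oracle(x, W, b),
               tolerance = 1e-12)
  expect_error(nn_dense_forward(x, matrix(0, 4, 2)), "mismatch")
})

test_that("valid convolution matches the quadruple-loop oracle", {
  set.seed(22)
  x <- array(rnorm(25), c(5, 5, 1, 1))
  w <- array(rnorm(9), c(3, 3, 1, 1))
  y <- nn_conv2d_forward(x, w)
  expect_equal(dim(y), c(3L, 3L, 1L, 1L))
  expect_equal(y[, , 1, 1], conv_oracle(x[, , , 1, drop = FALSE], w)[, , 1],
               tolerance = 1e-12)
  # multi-channel multi-filter case
  x2 <- array(rnorm(6 * 7 * 3), c(6, 7, 3, 1))
  w2 <- array(rnorm(3 * 2 * 3 * 4), c(3, 2, 3, 4))
  y2 <- nn_conv2d_forward(x2, w2)
  expect_equal(dim(y2), c(4L, 6L, 4L, 1L))
  expect_equal(y2[, , , 1], conv_oracle(x2[, , , 1, drop = FALSE], w2),
               tolerance = 1e-12)
  # 1x1 identity kernel reproduces the map
  w1 <- array(1, c(1, 1, 1, 1))
  expect_equal(nn_conv2d_forward(x, w1), x)
  # output dims follow the no-padding rule (301x90 -> 299x88 for 3x3)
  xb <- array(0, c(301, 90, 1, 1))
  expect_equal(dim(nn_conv2d_forward(xb, w))[1:2], c(299L, 88L))
  expect_error(nn_conv2d_forward(array(0, c(2, 2, 1, 1)), w), "larger")
})

test_that("same-padded convolution preserves spatial size", {
  set.seed(23)
  x <- array(rnorm(36), c(6, 6, 1, 1))
  w <- array(rnorm(9), c(3, 3, 1, 1))
  y <- nn_conv2d_forward(x, w, padding = "same")
  expect_equal(dim(y)[1:2], c(6L, 6L))
  # interior pixels agree with the valid convolution
  yv <- nn_conv2d_forward(x, w)
  expect_equal(y[2:5, 2:5, 1, 1], yv[, , 1, 1], tolerance = 1e-12)
})

test_that("every layer's analytic gradient matches finite differences", {
  b <- mwisar:::node_builder()
  b$add("conv2d", filters = 3L, kernel = c(3L, 3L), padding = "same",
        activation = "relu", bias = TRUE)
  b$add("batchnorm", activation = "relu")
  b$add("maxpool", size = 2L)
  b$add("conv2d", filters = 2L, kernel = c(2L, 2L), activation = "linear",
        bias = FALSE)
  b$add("upsample", factor = 2L)
  b$add("flatten")
  b$add("dense", units = 4L, activation = "sigmoid")
  m <- new_model("toy", c(6L, 6L, 2L), b$nodes, "real", seed = 3)
  set.seed(9)
  x <- array(rnorm(6 * 6 * 2 * 3), c(6, 6, 2, 3))
  y <- matrix(runif(12), 3, 4)
  lf <- mwisar:::loss_fun("mse")
  fw <- model_forward(m, x, training = TRUE, keep_cache = TRUE)
  l <- lf(fw$out, y)
  bw <- model_backward(fw$model, fw$caches, l$grad)
  p <- model_params(m)
  for (nm in names(bw$grads)) {
    f <- function(v) {
      p2 <- p
      p2[[nm]] <- if (is.null(dim(p[[nm]]))) v else array(v, dim(p[[nm]]))
      lf(model_forward(model_set_params(m, p2), x, training = TRUE)$out,
         y)$value
    }
    ng <- num_grad(f, as.vector(p[[nm]]))
    expect_lt(max(abs(ng - as.vector(bw$grads[[nm]]))) / max(1e-8, max(abs(ng))),
              1e-6)
  }
  # gradient w.r.t. the input
  fx <- function(v) lf(model_forward(m, array(v, dim(x)),
                                     training = TRUE)$out, y)$value
  ngx <- num_grad(fx, as.vector(x))
  expect_lt(max(abs(ngx - as.vector(bw$dinput))) / max(abs(ngx)), 1e-6)
})

test_that("max pooling uses floor division and exact argmax routing", {
  x <- array(0, c(7, 5, 1, 1))
  x[2, 2, 1, 1] <- 5; x[5, 3, 1, 1] <- 7
  r <- mwisar:::maxpool_fwd_cpp(x, 3)
  expect_equal(dim(r$y), c(2L, 1L, 1L, 1L))   # floor(7/3) x floor(5/3)
  expect_equal(r$y[1, 1, 1, 1], 5)
  expect_equal(r$y[2, 1, 1, 1], 7)
  dy <- r$y * 0 + 1
  dx <- mwisar:::maxpool_bwd_cpp(r$idx, dy, dim(x))
  expect_equal(sum(dx), 2)
  expect_equal(dx[2, 2, 1, 1], 1)
  expect_equal(dx[5, 3, 1, 1], 1)
})

test_that("an Adam step on a singleton batch decreases its loss", {
  b <- mwisar:::node_builder()
  b$add("dense", units = 8L, activation = "relu")
  b$add("dense", units = 2L, activation = "linear")
  m <- new_model("opt", 5L, b$nodes, "real", seed = 1)
  set.seed(5)
  x <- matrix(rnorm(5), 1); y <- matrix(c(1, -1), 1)
  lf <- mwisar:::loss_fun("mse")
  p <- model_params(m)
  st <- mwisar:::adam_init(p)
  l0 <- lf(model_forward(m, x)$out, y)$value
  for (k in 1:5) {
    fw <- model_forward(model_set_params(m, p), x, keep_cache = TRUE)
    l <- lf(fw$out, y)
    g <- model_backward(model_set_params(m, p), fw$caches, l$grad)$grads
    r <- mwisar:::adam_step(p, g, st, lr = 1e-2)
    p <- r$params; st <- r$state
  }
  l1 <- lf(model_forward(model_set_params(m, p), x)$out, y)$value
  expect_lt(l1, l0)
})

test_that("batchnorm normalizes batch statistics in training mode", {
  b <- mwisar:::node_builder()
  b$add("batchnorm", activation = "linear")
  m <- new_model("bn", 3L, b$nodes, "real", seed = 1)
  set.seed(6)
  x <- matrix(rnorm(300, mean = 4, sd = 3), 100, 3)
  out <- model_forward(m, x, training = TRUE)$out
  expect_equal(colMeans(out), rep(0, 3), tolerance = 1e-8)
  expect_equal(apply(out, 2, sd), rep(1, 3), tolerance = 0.05)
})
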
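test_that("RV-DNN has the published input/output sizes and parameter total", {
  m <- build_rv_dnn()
  expect_equal(m$input_shape, 27090)
  expect_equal(m$shapes[[length(m$shapes)]], 16384)
  expect_equal(16384, 128 * 128)
  # closed-form sum over the dense stack
  expected <- (27090 * 128 + 128) + 4 * (128 * 128 + 128) +
    (128 * 16384 + 16384)
  expect_equal(sum(model_param_counts(m)$params), expected)
})

test_that("RV-CNN per-layer parameter counts reproduce the reference table", {
  m <- build_rv_cnn()
  cnt <- model_param_counts(m, bn = "all")
  expect_equal(cnt$params[cnt$op == "conv2d"],
               c(288, 9216, 18432, 36864, 73728, 147456, 147456))
  expect_equal(cnt$params[cnt$op == "batchnorm"],
               c(128, 128, 256, 256, 512, 512, 512, 8192))
  expect_equal(cnt$params[cnt$op == "dense"],
               c(13107200, 4196352, 33570816))
  # flatten feeds 6400 units into the first dense layer
  expect_equal(m$shapes[[which(cnt$op == "flatten")]], 6400)
  # trainable convention halves only the batchnorm rows
  tr <- model_param_counts(m, bn = "trainable")
  expect_equal(tr$params[tr$op == "batchnorm"],
               c(128, 128, 256, 256, 512, 512, 512, 8192) / 2)
  expect_equal(tr$params[tr$op == "conv2d"], cnt$params[cnt$op == "conv2d"])
})

test_that("models map a field matrix to a 128x128 image worth of outputs", {
  cfg <- acquisition_config()
  set.seed(41)
  x <- matrix(abs(rnorm(2 * 27090)), 2)
  dnn <- build_rv_dnn(cfg)
  expect_equal(dim(model_predict(dnn, x)), c(2L, 16384L))
  # width-scaled CNN still consumes (301, 90) and emits out_side^2
  cnn <- build_rv_cnn(cfg, out_side = 32, width = 0.1)
  xc <- array(abs(rnorm(301 * 90 * 2)), c(301, 90, 1, 2))
  expect_equal(dim(model_predict(cnn, xc)), c(2L, 1024L))
})

test_that("the MWINet hybrids emit sigmoid-bounded maps with aligned skips", {
  cfg <- acquisition_config()
  mw <- build_rv_mwinet(cfg, out_side = 32, width = 0.1)
  expect_equal(mw$shapes[[length(mw$shapes)]], c(32, 32, 1))
  # encoder levels and their decoder concat partners share spatial shapes
  for (nd in mw$nodes[vapply(mw$nodes, function(n) n$op == "concat",
                             logical(1))]) {
    s1 <- mw$shapes[[nd$input[1]]]; s2 <- mw$shapes[[nd$input[2]]]
    expect_equal(s1[1:2], s2[1:2])
  }
  set.seed(42)
  xc <- array(abs(rnorm(301 * 90 * 2)), c(301, 90, 1, 2))
  out <- model_predict(mw, xc)
  expect_equal(dim(out), c(32L, 32L, 1L, 2L))
  expect_true(all(out > 0 & out < 1))
})

test_that("CV-MWINet takes complex input and yields a real bounded image", {
  cfg <- acquisition_config()
  mc <- build_cv_mwinet(cfg, out_side = 32, width = 0.1)
  expect_equal(mc$field, "complex")
  set.seed(43)
  z <- list(re = array(rnorm(301 * 90), c(301, 90, 1, 1)),
            im = array(rnorm(301 * 90), c(301, 90, 1, 1)))
  raw <- model_forward(mc, z)$out
  expect_true(is.list(raw) && !is.null(raw$re))    # complex pipeline inside
  img <- model_predict(mc, z)
  expect_true(is.numeric(img))
  expect_equal(dim(img), c(32L, 32L, 1L, 1L))
  expect_true(all(img > 0 & img < sqrt(2)))        # split-sigmoid amplitude
})

test_that("one optimizer step decreases a singleton-batch loss on each model", {
  cfg <- acquisition_config(n_freq = 95, angle_step = 4)
  set.seed(44)
  check_decreases <- function(m, x, y, loss) {
    lf <- mwisar:::loss_fun(loss)
    p <- model_params(m); st <- mwisar:::adam_init(p)
    fw <- model_forward(m, x, training = TRUE, keep_cache = TRUE)
    l0 <- lf(fw$out, y)
    g <- model_backward(fw$model, fw$caches, l0$grad,
                        skip_out_act = isTRUE(attr(lf, "logit_grad")))$grads
    r <- mwisar:::adam_step(p, g, st, lr = 1e-3)
    m2 <- model_set_params(m, r$params)
    l1 <- lf(model_forward(m2, x, training = TRUE)$out, y)
    expect_lt(l1$value, l0$value)
  }
  xm <- array(abs(rnorm(95 * 90)), c(95, 90, 1, 1))
  yb <- array(rbinom(16 * 16, 1, 0.05), c(16, 16, 1, 1))
  check_decreases(build_rv_mwinet(cfg, 16, width = 0.06, seed = 2),
                  xm, yb, "bce")
  check_decreases(build_cv_mwinet(cfg, 16, width = 0.06, seed = 2),
                  list(re = xm, im = xm * 0.5), yb, "cace")
  xd <- matrix(abs(rnorm(95 * 90)), 1)
  yd <- matrix(rnorm(256) * 50, 1)
  check_decreases(build_rv_dnn(cfg, 16, seed = 2), xd, yd, "mse")
})
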
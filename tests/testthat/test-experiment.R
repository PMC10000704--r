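test_that("k-fold splits are disjoint, exhaustive, balanced and seeded", {
  f <- kfold_split(1000, 10, seed = 3)
  expect_length(f, 10)
  tests <- lapply(f, `[[`, "test")
  expect_true(all(lengths(tests) == 100))
  expect_equal(sort(unlist(tests)), 1:1000)
  for (k in 1:10) {
    expect_length(intersect(f[[k]]$train, f[[k]]$test), 0)
    expect_equal(sort(c(f[[k]]$train, f[[k]]$test)), 1:1000)
  }
  expect_identical(kfold_split(1000, 10, seed = 3), f)
  expect_false(identical(kfold_split(1000, 10, seed = 4), f))
  # uneven n: fold sizes differ by at most one
  f2 <- kfold_split(25, 4, seed = 1)
  expect_true(diff(range(lengths(lapply(f2, `[[`, "test")))) <= 1)
  expect_error(kfold_split(5, 6), "folds")
  expect_error(kfold_split(10, 1), "at least 2")
})

test_that("holdout split gives the rounded test fraction", {
  s <- holdout_split(1000, 0.1, seed = 9)
  expect_length(s$test, 100)
  expect_length(s$train, 900)
  expect_equal(sort(c(s$train, s$test)), 1:1000)
  expect_identical(holdout_split(1000, 0.1, 9), s)
  expect_error(holdout_split(10, 0), "fraction")
  expect_length(holdout_split(37, 0.25, 1)$test, round(37 * 0.25))
})

# one tiny shared dataset for the harness tests
harness_env <- new.env()
harness_data <- function() {
  if (is.null(harness_env$ds)) {
    cfg <- acquisition_config(n_freq = 95)
    ds <- build_dataset(20, global_seed = 31, cfg = cfg, image_size = 16,
                        n_skin_points = 24, tumor_spacing = 0.3)
    harness_env$cfg <- cfg
    harness_env$ds <- ds
    harness_env$x <- prepare_inputs(ds$fields, "dense")$x
    harness_env$y <- prepare_targets(ds$images_float, "dense")
  }
  harness_env
}

test_that("the training loop records history and keeps the best checkpoint", {
  h <- harness_data()
  m <- build_rv_dnn(h$cfg, 16, hidden = rep(32L, 2), seed = 1)
  fit <- train_model(m, h$x[1:16, ], h$y[1:16, ], h$x[17:20, ], h$y[17:20, ],
                     loss = "mse", epochs = 5, batch_size = 8, seed = 1)
  expect_s3_class(fit, "mwi_trained")
  expect_equal(nrow(fit$history), 5L)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_true(fit$best_epoch %in% 1:5)
  expect_equal(fit$history$val_loss[fit$best_epoch],
               min(fit$history$val_loss))
})

test_that("training is deterministic under a fixed seed", {
  h <- harness_data()
  m <- build_rv_dnn(h$cfg, 16, hidden = rep(32L, 2), seed = 1)
  f1 <- train_model(m, h$x[1:16, ], h$y[1:16, ], loss = "mse", epochs = 2,
                    batch_size = 8, seed = 5)
  f2 <- train_model(m, h$x[1:16, ], h$y[1:16, ], loss = "mse", epochs = 2,
                    batch_size = 8, seed = 5)
  expect_identical(f1$history$train_loss[1], f2$history$train_loss[1])
  expect_identical(model_params(f1$model), model_params(f2$model))
})

test_that("a dense model memorizes a handful of scenarios", {
  h <- harness_data()
  m <- build_rv_dnn(h$cfg, 16, seed = 2)
  fit <- train_model(m, h$x[1:8, ], h$y[1:8, ], loss = "mse", epochs = 200,
                     batch_size = 2, lr = 5e-3, seed = 2)
  tl <- fit$history$train_loss
  expect_lt(tl[length(tl)], 0.01 * tl[1])
})

test_that("reconstruction reshapes checkpoint output into images", {
  h <- harness_data()
  m <- build_rv_dnn(h$cfg, 16, hidden = rep(32L, 2), seed = 3)
  fit <- train_model(m, h$x[1:16, ], h$y[1:16, ], loss = "mse", epochs = 2,
                     batch_size = 8, seed = 3)
  fit$scale <- prepare_inputs(h$ds$fields, "dense")$scale
  imgs <- reconstruct(fit, h$ds$fields[17:19, , ])
  expect_equal(dim(imgs), c(3L, 16L, 16L))
  expect_identical(imgs, reconstruct(fit, h$ds$fields[17:19, , ]))
  # single field matrix and PNG export
  d <- file.path(tempdir(), "recon")
  one <- reconstruct(fit, h$ds$fields[20, , ], out_dir = d)
  expect_equal(dim(one), c(1L, 16L, 16L))
  expect_true(file.exists(file.path(d, "recon_0001.png")))
  expect_error(reconstruct(fit, matrix(0 + 0i, 5, 5)), "does not match")
})

test_that("cross-validation tabulates per-fold metrics plus the average row", {
  h <- harness_data()
  cv <- cross_validate(function(seed) build_rv_dnn(h$cfg, 16,
                                                   hidden = rep(16L, 2),
                                                   seed = seed),
                       h$x, h$y, k = 3, seed = 4, loss = "mse", epochs = 2,
                       batch_size = 8, metric_value = "mse")
  expect_equal(nrow(cv), 4L)
  expect_equal(cv$fold, c("1", "2", "3", "average"))
  expect_equal(cv$test_mean[4], mean(cv$test_mean[1:3]), tolerance = 1e-12)
  expect_equal(cv$train_mean[4], mean(cv$train_mean[1:3]), tolerance = 1e-12)
  expect_equal(sum(cv$n_test[1:3]), 20)
})

test_that("aborts with a diagnostic on non-finite loss", {
  h <- harness_data()
  m <- build_rv_dnn(h$cfg, 16, hidden = rep(16L, 1), seed = 1)
  p <- model_params(m)
  p[[1]][1, 1] <- NaN
  m <- model_set_params(m, p)
  expect_error(train_model(m, h$x[1:8, ], h$y[1:8, ], loss = "mse",
                           epochs = 1, seed = 1), "non-finite loss")
})
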
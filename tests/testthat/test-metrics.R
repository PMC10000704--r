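test_that("MSE follows the pixel-mean definition and is symmetric", {
  x <- matrix(0, 1, 2); y <- matrix(255, 1, 2)
  expect_equal(img_mse(x, y), 65025)
  expect_equal(img_mse(x, x), 0)
  set.seed(2)
  a <- matrix(rnorm(64), 8); b <- matrix(rnorm(64), 8)
  expect_equal(img_mse(a, b), img_mse(b, a))
  expect_equal(img_mse(a, b), sum((a - b)^2) / 64)
  expect_error(img_mse(a, matrix(0, 4, 4)), "mismatch")
})

test_that("PSNR matches its closed form with the standard dynamic range", {
  x <- matrix(0, 1, 2); y <- matrix(255, 1, 2)
  expect_equal(img_psnr(x, y, 255), 0)
  # MSE = 1 against the 255 ceiling
  x1 <- matrix(c(0, 0), 1); y1 <- matrix(c(1, 1), 1)
  expect_equal(img_psnr(x1, y1, 255), 48.1308, tolerance = 1e-4)
  expect_equal(img_psnr(x1, x1, 255), Inf)
})

test_that("UQI matches a hand-computed oracle and its stated range", {
  set.seed(11)
  for (k in 1:25) {
    a <- matrix(runif(9, 0, 255), 3)
    b <- matrix(runif(9, 0, 255), 3)
    expect_equal(img_uqi(a, b), uqi_oracle(a, b), tolerance = 1e-12)
    expect_gte(img_uqi(a, b), -1 - 1e-12)
    expect_lte(img_uqi(a, b), 1 + 1e-12)
  }
  a <- matrix(runif(16, 1, 10), 4)
  expect_equal(img_uqi(a, a), 1)
  # perfect anticorrelation with sign-flipped means: both luminance and
  # correlation factors are -1, so the product returns +1
  expect_equal(img_uqi(a, -a), 1, tolerance = 1e-12)
  # anticorrelation at matched positive means is negative
  refl <- max(a) + min(a) - a
  expect_lt(img_uqi(a, refl), 0)
  # degenerate constant-zero pair is defined, not NaN
  z <- matrix(0, 3, 3)
  expect_equal(img_uqi(z, z), 1)
  expect_equal(img_uqi(z, z + 0:8 * 0), 1)
})

test_that("SSIM reduces to UQI at zero constants and is exact on oracles", {
  set.seed(12)
  for (k in 1:1000) {
    a <- matrix(runif(16), 4); b <- matrix(runif(16), 4)
    expect_equal(img_ssim(a, b, C1 = 0, C2 = 0), img_uqi(a, b),
                 tolerance = 1e-10)
  }
  a <- matrix(runif(9, 0, 255), 3); b <- matrix(runif(9, 0, 255), 3)
  mx <- mean(a); my <- mean(b)
  vx <- sum((a - mx)^2) / 8; vy <- sum((b - my)^2) / 8
  cxy <- sum((a - mx) * (b - my)) / 8
  C1 <- (0.01 * 255)^2; C2 <- (0.03 * 255)^2
  hand <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  expect_equal(img_ssim(a, b), hand, tolerance = 1e-12)
  expect_equal(img_ssim(a, a), 1, tolerance = 1e-9)
})

test_that("UQI and zero-constant SSIM are scale invariant, PSNR is not", {
  set.seed(13)
  a <- matrix(runif(25, 1, 5), 5); b <- matrix(runif(25, 1, 5), 5)
  expect_equal(img_uqi(2.7 * a, 2.7 * b), img_uqi(a, b), tolerance = 1e-12)
  expect_equal(img_ssim(3 * a, 3 * b, C1 = 0, C2 = 0),
               img_ssim(a, b, C1 = 0, C2 = 0), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(img_psnr(2 * a, 2 * b), img_psnr(a, b))))
})

test_that("pixel accuracy counts threshold agreements", {
  t <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(pixel_accuracy(t, t), 1)
  expect_equal(pixel_accuracy(1 - t, t), 0)
  p <- matrix(c(0.9, 0.1, 0.8, 0.2), 2)   # two pixels flipped
  expect_equal(pixel_accuracy(p, t), 0.5)
  expect_error(pixel_accuracy(p, p), "binary")
})

test_that("metric reports aggregate per-image values with mean and sd", {
  set.seed(3)
  pred <- array(runif(5 * 8 * 8), c(5, 8, 8))
  truth <- array(runif(5 * 8 * 8), c(5, 8, 8))
  rep <- metric_report(pred, truth, max_value = 1, model = "toy")
  expect_equal(nrow(rep), 5L)
  s <- attr(rep, "summary")
  expect_equal(s$mean[s$metric == "mse"], mean(rep$mse))
  expect_equal(s$sd[s$metric == "ssim"], sd(rep$ssim))
  d <- tempfile(); paths <- write_report(rep, d, "r1", meta = list(seed = 3))
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths[1])
  expect_equal(back$mse, rep$mse, tolerance = 1e-12)
  js <- jsonlite::read_json(paths[2])
  expect_equal(js$summary$mse$mean, mean(rep$mse), tolerance = 1e-12)
  expect_match(js$summary$mse$formatted, "±")
})
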
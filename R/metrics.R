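#' Mean squared error between two images
#' @param x,y numeric arrays of identical shape.
#' @return Scalar mean of squared pixel differences.
#' @export
img_mse <- function(x, y) {
  if (length(x) != length(y)) stop("shape mismatch")
  mean((x - y)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 log10(M_I^2 / MSE)`; identical images give `Inf`.
#'
#' @param x,y images of identical shape.
#' @param max_value `M_I`, the maximum possible pixel value (default 255).
#' @return PSNR in dB (`Inf` when `MSE = 0`).
#' @export
img_psnr <- function(x, y, max_value = 255) {
  m <- img_mse(x, y)
  if (m == 0) return(Inf)
  10 * log10(max_value^2 / m)
}

uqi_stats <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / (n - 1)
  vy <- sum((y - my)^2) / (n - 1)
  cxy <- sum((x - mx) * (y - my)) / (n - 1)
  list(mx = mx, my = my, vx = vx, vy = vy, cxy = cxy)
}

#' Universal quality index (UQI)
#'
#' `4 sxy mx my / ((sx2 + sy2)(mx2 + my2))`, computed from global
#' whole-image statistics with the unbiased (N-1) variance/covariance.
#' Range [-1, 1]; equals 1 only for identical images. The degenerate
#' constant-zero denominator is defined as 1 for identical inputs and 0
#' otherwise so reports never hold NaN.
#'
#' @param x,y images of identical shape.
#' @return Scalar in [-1, 1].
#' @export
img_uqi <- function(x, y) {
  if (length(x) != length(y)) stop("shape mismatch")
  s <- uqi_stats(x, y)
  den <- (s$vx + s$vy) * (s$mx^2 + s$my^2)
  if (den == 0) return(if (isTRUE(all.equal(as.vector(x), as.vector(y)))) 1 else 0)
  4 * s$cxy * s$mx * s$my / den
}

#' Global structural similarity (SSIM)
#'
#' Single-window SSIM from global image statistics:
#' `(2 mx my + C1)(2 sxy + C2) / ((mx2 + my2 + C1)(sx2 + sy2 + C2))`.
#' With `C1 = C2 = 0` this reduces exactly to [img_uqi()]. Defaults follow
#' the standard stabilizing constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`
#' with `L = max_value`.
#'
#' @param x,y images of identical shape.
#' @param max_value dynamic range `L` (default 255).
#' @param C1,C2 stabilizing constants; override the defaults.
#' @return Scalar SSIM.
#' @export
img_ssim <- function(x, y, max_value = 255, C1 = (0.01 * max_value)^2,
                     C2 = (0.03 * max_value)^2) {
  if (length(x) != length(y)) stop("shape mismatch")
  s <- uqi_stats(x, y)
  if (C1 == 0 && C2 == 0) return(img_uqi(x, y))
  ((2 * s$mx * s$my + C1) * (2 * s$cxy + C2)) /
    ((s$mx^2 + s$my^2 + C1) * (s$vx + s$vy + C2))
}

#' Pixel accuracy of a thresholded prediction against a binary mask
#'
#' @param pred predicted image (any real values).
#' @param truth binary ground-truth mask.
#' @param threshold decision threshold on `pred` (default 0.5).
#' @return Fraction of pixels where `(pred > threshold)` matches `truth`.
#' @export
pixel_accuracy <- function(pred, truth, threshold = 0.5) {
  if (length(pred) != length(truth)) stop("shape mismatch")
  if (!all(truth %in% c(0, 1))) stop("truth must be binary")
  mean((pred > threshold) == (truth > 0.5))
}

#' Per-image metric report over a stack of reconstructions
#'
#' @param pred array `(n, H, W)` of reconstructed images (or `(H, W, 1, n)`).
#' @param truth matching ground-truth stack.
#' @param max_value dynamic range for PSNR/SSIM.
#' @param binary also compute pixel accuracy against binary truth.
#' @param model,split identifiers recorded in the report.
#' @return Object of class `mwi_report`: data.frame of per-image metrics
#'   with a `summary` attribute of mean and sd per metric.
#' @export
metric_report <- function(pred, truth, max_value = 255, binary = FALSE,
                          model = "model", split = "test") {
  pred <- as_image_stack(pred); truth <- as_image_stack(truth)
  n <- dim(pred)[1]
  rows <- lapply(seq_len(n), function(i) {
    p <- pred[i, , ]; t <- truth[i, , ]
    r <- data.frame(image = i, mse = img_mse(p, t),
                    psnr = img_psnr(p, t, max_value),
                    uqi = img_uqi(p, t),
                    ssim = img_ssim(p, t, max_value))
    if (binary) r$accuracy <- pixel_accuracy(p, t)
    r
  })
  df <- do.call(rbind, rows)
  df$model <- model; df$split <- split
  met <- setdiff(names(df), c("image", "model", "split"))
  smry <- data.frame(metric = met,
                     mean = vapply(met, function(m) mean(df[[m]][is.finite(df[[m]])]), numeric(1)),
                     sd = vapply(met, function(m) stats::sd(df[[m]][is.finite(df[[m]])]), numeric(1)))
  structure(df, summary = smry, class = c("mwi_report", "data.frame"))
}

#' @export
print.mwi_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("Metric report: %s / %s, %d images\n",
              x$model[1], x$split[1], nrow(x)))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s %s\n", s$metric[i],
                format_pm(s$mean[i], s$sd[i])))
  invisible(x)
}

format_pm <- function(m, s) sprintf("%.5f ± %.5f", m, s)

# accepts (n, H, W) stacks or (H, W, 1, n) model-output arrays
as_image_stack <- function(x) {
  d <- dim(x)
  if (length(d) == 2) return(array(x, c(1, d)))
  if (length(d) == 4) return(aperm(array(x, c(d[1], d[2], d[4])), c(3, 1, 2)))
  x
}
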
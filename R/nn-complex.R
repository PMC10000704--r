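# Complex-valued network components. A complex activation is carried as a
# list(re, im) pair; the split (Cartesian) nonlinearities act on each part.

#' Complex tensor constructor
#' @param re,im real and imaginary parts (identical shapes).
#' @return A `list(re, im)` complex tensor.
#' @export
complex_tensor <- function(re, im = re * 0) {
  stopifnot(identical(dim(re), dim(im)) || length(re) == length(im))
  list(re = re, im = im)
}

#' Cartesian ReLU
#'
#' `max(0, Re z) + i max(0, Im z)`, applied elementwise.
#'
#' @param z complex vector/array, or a `list(re, im)` tensor.
#' @return Same type as the input.
#' @export
crelu <- function(z) {
  if (is.complex(z)) return(complex(real = pmax(Re(z), 0),
                                    imaginary = pmax(Im(z), 0)))
  list(re = pmax(z$re, 0), im = pmax(z$im, 0))
}

#' Amplitude of the split complex sigmoid
#'
#' Applies the logistic function independently to real and imaginary parts
#' and returns the modulus `|sigma(Re z) + i sigma(Im z)|`, a real value in
#' `(0, sqrt(2))`.
#'
#' @param z complex vector/array or `list(re, im)` tensor.
#' @return Real array of the same shape.
#' @export
complex_sigmoid_magnitude <- function(z) {
  if (is.complex(z)) z <- list(re = Re(z), im = Im(z))
  sr <- 1 / (1 + exp(-z$re)); si <- 1 / (1 + exp(-z$im))
  sqrt(sr^2 + si^2)
}

#' Complex dense layer forward pass
#'
#' True complex product via four real products:
#' `(Wr xr - Wi xi) + i (Wi xr + Wr xi)`.
#'
#' @param x `list(re, im)` input, parts `(N, in)` matrices (a real matrix is
#'   promoted with zero imaginary part).
#' @param W `list(re, im)` weights, parts `(in, out)`.
#' @param b optional `list(re, im)` biases.
#' @param activation `"linear"`, `"relu"` (Cartesian) or `"sigmoid"` (split).
#' @return `list(re, im)` output.
#' @export
complex_dense_forward <- function(x, W, b = NULL, activation = "linear") {
  if (!is_cplx(x)) x <- complex_tensor(as.matrix(x))
  if (ncol(x$re) != nrow(W$re)) stop("shape mismatch")
  fw_dense(x, list(W = W, b = b), activation)
}

#' Complex 2-D convolution forward pass
#'
#' @param x `list(re, im)` input, parts `(H, W, C, N)` arrays.
#' @param W `list(re, im)` kernels, parts `(kh, kw, C, F)`.
#' @param activation split activation.
#' @param padding `"valid"` or `"same"`.
#' @return `list(re, im)` output.
#' @export
complex_conv2d_forward <- function(x, W, activation = "linear",
                                   padding = c("valid", "same")) {
  padding <- match.arg(padding)
  k <- dim(W$re)
  pad <- if (padding == "same") c((k[1] - 1) %/% 2, (k[2] - 1) %/% 2) else c(0L, 0L)
  fw_conv(x, list(W = W), activation, pad)
}

clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

bce_mean <- function(p, t, eps = 1e-7) {
  p <- clamp_prob(p, eps)
  -mean(t * log(p) + (1 - t) * log(1 - p))
}

#' Complex average cross-entropy (CACE) loss
#'
#' Mean of the binary cross-entropies of the prediction's real and imaginary
#' parts against a real binary target:
#' `0.5 * (CE(Re y, t) + CE(Im y, t))`. Probabilities are clamped to
#' `[eps, 1 - eps]` to keep the loss finite.
#'
#' @param y_pred `list(re, im)` prediction with parts in `(0, 1)`
#'   (post-sigmoid per component), or a complex array.
#' @param y_true binary target of the same shape.
#' @param eps clamping floor (default 1e-7).
#' @return Scalar loss.
#' @export
cace_loss <- function(y_pred, y_true, eps = 1e-7) {
  if (is.complex(y_pred)) y_pred <- list(re = Re(y_pred), im = Im(y_pred))
  if (!all(y_true %in% c(0, 1))) stop("y_true must be binary")
  0.5 * (bce_mean(y_pred$re, y_true, eps) + bce_mean(y_pred$im, y_true, eps))
}

# Loss functions used by the training loop: value plus gradient. For the
# cross-entropy losses the gradient is taken with respect to the output
# layer's pre-activation (sigmoid and cross-entropy fused, (p - t)/n), which
# is numerically stable where the sigmoid saturates; the training loop skips
# the output activation derivative for these. The mse gradient is the plain
# output-space gradient.
loss_fun <- function(kind) {
  f <- switch(kind,
    mse = function(p, t) {
      d <- p - t
      list(value = mean(d * d), grad = 2 * d / length(d))
    },
    bce = function(p, t, eps = 1e-7) {
      pc <- clamp_prob(p, eps)
      list(value = -mean(t * log(pc) + (1 - t) * log(1 - pc)),
           grad = (p - t) / length(p))
    },
    cace = function(p, t, eps = 1e-7) {
      pr <- clamp_prob(p$re, eps); pi_ <- clamp_prob(p$im, eps)
      v <- 0.5 * (-mean(t * log(pr) + (1 - t) * log(1 - pr)) -
                  mean(t * log(pi_) + (1 - t) * log(1 - pi_)))
      list(value = v,
           grad = list(re = 0.5 * (p$re - t) / length(pr),
                       im = 0.5 * (p$im - t) / length(pi_)))
    },
    stop("unknown loss: ", kind))
  attr(f, "logit_grad") <- kind %in% c("bce", "cace")
  f
}
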
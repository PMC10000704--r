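# The four reconstruction architectures. Default sizes are the full-scale
# ones; `width` scales the filter/unit counts and `out_side` the generated
# image, so the same topologies can be trained at reduced scale.

scale_w <- function(x, width) max(1L, as.integer(round(x * width)))

#' Build the real-valued dense reconstruction network (RV-DNN)
#'
#' Flattened field-magnitude input (301 x 90 = 27,090 by default), five
#' ReLU hidden layers of 128 units, and a linear output of `out_side^2`
#' pixels (16,384 by default) trained under MSE against 0--255 float
#' targets.
#'
#' @param cfg an [acquisition_config()] fixing the input size.
#' @param out_side output image side (default 128).
#' @param hidden hidden layer widths.
#' @param seed initialization seed.
#' @return An `mwi_model`.
#' @export
build_rv_dnn <- function(cfg = acquisition_config(), out_side = 128,
                         hidden = rep(128L, 5), seed = 1L) {
  b <- node_builder()
  for (h in hidden) b$add("dense", units = h, activation = "relu")
  b$add("dense", units = out_side^2, activation = "linear")
  m <- new_model("RV-DNN", cfg$n_freq * cfg$n_angles, b$nodes, "real", seed)
  m$out_side <- out_side
  m$input_kind <- "dense"
  m
}

# shared CNN front end: 7 bias-free 3x3 valid convolutions with batchnorm,
# two 3x3 max poolings, then dense 2048 (+bn) / 2048 / out
cnn_front <- function(b, width, out_units, final_act) {
  f <- vapply(c(32, 32, 64, 64, 128, 128, 128), scale_w, integer(1), width)
  u <- scale_w(2048, width)
  cv <- function(filters) {
    b$add("conv2d", filters = filters, kernel = c(3L, 3L), bias = FALSE,
          activation = "linear")
    b$add("batchnorm", activation = "relu")
  }
  cv(f[1]); cv(f[2]); b$add("maxpool", size = 3L)
  cv(f[3]); cv(f[4]); b$add("maxpool", size = 3L)
  cv(f[5]); cv(f[6]); cv(f[7])
  b$add("flatten")
  # bias-free: the following batchnorm absorbs the shift
  b$add("dense", units = u, activation = "linear", bias = FALSE)
  b$add("batchnorm", activation = "relu")
  b$add("dense", units = u, activation = "relu")
  b$add("dense", units = out_units, activation = final_act)
}

#' Build the real-valued convolutional reconstruction network (RV-CNN)
#'
#' Seven bias-free 3 x 3 valid convolutions (32, 32, 64, 64, 128, 128, 128
#' filters), each followed by batch normalization and ReLU, two 3 x 3 max
#' poolings, a 6400-unit flatten and three fully connected layers
#' (2048 + batchnorm, 2048, `out_side^2` linear). At the default width the
#' per-layer trainable-parameter counts reproduce the reference layer table
#' (first convolution 288, dense layers 13,107,200 / 4,196,352 /
#' 33,570,816).
#'
#' @inheritParams build_rv_dnn
#' @param width width multiplier applied to filter/unit counts (default 1).
#' @return An `mwi_model`.
#' @export
build_rv_cnn <- function(cfg = acquisition_config(), out_side = 128,
                         width = 1, seed = 1L) {
  b <- node_builder()
  cnn_front(b, width, out_side^2, "linear")
  m <- new_model("RV-CNN", c(cfg$n_freq, cfg$n_angles, 1L), b$nodes, "real", seed)
  m$out_side <- out_side
  m$input_kind <- "conv"
  m
}

# U-Net on an (s, s, 1) map: 4-level encoder, symmetric decoder with skip
# concatenations, 3x3 same-padded convolutions, final 1x1 sigmoid.
unet_tail <- function(b, start_id, base_filters) {
  f <- vapply(base_filters * c(1, 2, 4, 8, 16), function(x)
    max(1L, as.integer(round(x))), integer(1))
  cv <- function(filters, input = NULL)
    b$add("conv2d", filters = filters, kernel = c(3L, 3L), padding = "same",
          activation = "relu", bias = TRUE, input = input)
  enc <- integer(4)
  prev <- start_id
  for (k in 1:4) {
    cv(f[k], input = prev); enc[k] <- cv(f[k])
    prev <- b$add("maxpool", size = 2L)
  }
  cv(f[5], input = prev); prev <- cv(f[5])
  for (k in 4:1) {
    up <- b$add("upsample", factor = 2L, input = prev)
    upc <- cv(f[k], input = up)
    cat_id <- b$add("concat", input = c(upc, enc[k]))
    cv(f[k], input = cat_id); prev <- cv(f[k])
  }
  # output bias starts at the background log-odds of sparse tumor masks so
  # optimization spends its steps on discrimination, not on the class prior
  b$add("conv2d", filters = 1L, kernel = c(1L, 1L), padding = "same",
        activation = "sigmoid", bias = TRUE, bias_init = -4, input = prev)
}

build_mwinet <- function(cfg, out_side, width, unet_base, field, seed) {
  b <- node_builder()
  cnn_front(b, width, out_side^2, "linear")
  mid <- b$add("reshape", dim = c(out_side, out_side, 1L))
  unet_tail(b, mid, unet_base)
  m <- new_model(if (field == "real") "RV-MWINet" else "CV-MWINet",
                 c(cfg$n_freq, cfg$n_angles, 1L), b$nodes, field, seed)
  m$out_side <- out_side
  m$input_kind <- "conv"
  m
}

#' Build the real-valued CNN + U-Net hybrid (RV-MWINet)
#'
#' The RV-CNN front end produces a coarse `out_side x out_side` map
#' (linear, "general imaging"); a 4-level U-Net (encoder filters
#' 16/32/64/128, bottleneck 256, symmetric decoder with skip
#' concatenations) cleans it, ending in a 1-channel sigmoid, trained with
#' binary cross-entropy against binary tumor masks.
#'
#' @inheritParams build_rv_cnn
#' @param unet_base encoder base filter count (default 16; levels are
#'   base * 1/2/4/8, bottleneck base * 16). Scaled by `width`.
#' @return An `mwi_model`.
#' @export
build_rv_mwinet <- function(cfg = acquisition_config(), out_side = 128,
                            width = 1, unet_base = 16 * width, seed = 1L) {
  build_mwinet(cfg, out_side, width, unet_base, "real", seed)
}

#' Build the complex-valued CNN + U-Net hybrid (CV-MWINet)
#'
#' Mirrors the RV-MWINet topology with complex-valued layers throughout:
#' complex weights, Cartesian ReLU activations inside, and a split sigmoid
#' at the output. The input is the raw complex field matrix (not its
#' magnitude); the predicted image is the amplitude of the complex sigmoid
#' output, a real value in `(0, sqrt(2))`. Trained with the complex average
#' cross-entropy ([cace_loss()]).
#'
#' @inheritParams build_rv_mwinet
#' @return An `mwi_model` with `field = "complex"`.
#' @export
build_cv_mwinet <- function(cfg = acquisition_config(), out_side = 128,
                            width = 1, unet_base = 16 * width, seed = 1L) {
  build_mwinet(cfg, out_side, width, unet_base, "complex", seed)
}

#' Model predictions
#'
#' Runs the model in inference mode, batched. For complex models the
#' returned image is the amplitude of the split sigmoid output.
#'
#' @param model an `mwi_model`.
#' @param x input batch (see [model_forward()]).
#' @param batch_size forward batch size.
#' @return Real output: `(N, F)` matrix for dense output, `(H, W, 1, N)`
#'   array for image output.
#' @export
model_predict <- function(model, x, batch_size = 32) {
  n <- batch_n(x)
  outs <- NULL
  for (ix in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    o <- model_forward(model, batch_take(x, ix), training = FALSE)$out
    if (is_cplx(o)) o <- sqrt(o$re^2 + o$im^2)
    outs <- if (is.null(outs)) o else bind_batches(outs, o)
  }
  outs
}

#' Batch utilities
#'
#' `batch_n` returns the number of samples of a batch container (matrix
#' rows, array 4th dimension, or a complex pair); `batch_take` subsets it by
#' sample index.
#'
#' @param x batch container: `(N, F)` matrix, `(H, W, C, N)` array, or
#'   `list(re, im)`.
#' @return `batch_n`: integer count; `batch_take`: same container type.
#' @export
batch_n <- function(x) {
  if (is_cplx(x)) return(batch_n(x$re))
  if (is.matrix(x)) nrow(x) else dim(x)[4]
}

#' @rdname batch_n
#' @param ix 1-based sample indices.
#' @export
batch_take <- function(x, ix) {
  if (is_cplx(x)) return(list(re = batch_take(x$re, ix), im = batch_take(x$im, ix)))
  if (is.matrix(x)) x[ix, , drop = FALSE] else x[, , , ix, drop = FALSE]
}

bind_batches <- function(a, b) {
  if (is.matrix(a)) return(rbind(a, b))
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}
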
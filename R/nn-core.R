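# Minimal neural-network engine backing the reconstruction models.
#
# Tensors: feature maps are (H, W, C, N) arrays, dense activations (N, F)
# matrices. Complex tensors are lists with `re` and `im` parts of identical
# shape; complex products expand into four real products. A model is a DAG of
# nodes evaluated in index order; node inputs reference earlier nodes (0 = the
# model input), which admits U-Net skip connections. Backward accumulates
# fan-out gradients and returns parameter gradients in a flat named list,
# which the Adam optimizer consumes.

is_cplx <- function(x) is.list(x) && !is.null(x$re)

act_apply <- function(x, act) {
  switch(act,
         linear = x,
         relu = pmax(x, 0),
         sigmoid = 1 / (1 + exp(-x)),
         stop("unknown activation: ", act))
}

act_grad <- function(out, dout, act) {
  switch(act,
         linear = dout,
         relu = dout * (out > 0),
         sigmoid = dout * out * (1 - out),
         stop("unknown activation: ", act))
}

# activation on a complex value: relu -> Cartesian ReLU, sigmoid -> per-part
# logistic (the amplitude is taken only at prediction time).
cact_apply <- function(z, act) list(re = act_apply(z$re, act),
                                    im = act_apply(z$im, act))

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

#' Rectified linear unit
#' @param u numeric vector/array.
#' @return `max(0, u)` elementwise.
#' @export
nn_relu <- function(u) pmax(u, 0)

#' Dense (fully connected) layer forward pass
#'
#' `h = act(x W + b)` with `x` an `(N, in)` matrix and `W` an `(in, out)`
#' weight matrix.
#'
#' @param x input matrix `(N, in)`.
#' @param W weight matrix `(in, out)`.
#' @param b bias vector length `out` (or NULL).
#' @param activation `"linear"`, `"relu"` or `"sigmoid"`.
#' @return Output matrix `(N, out)`.
#' @export
nn_dense_forward <- function(x, W, b = NULL, activation = "linear") {
  x <- as.matrix(x)
  if (ncol(x) != nrow(W)) stop("shape mismatch: ncol(x) != nrow(W)")
  y <- x %*% W
  if (!is.null(b)) y <- sweep(y, 2, b, "+")
  act_apply(y, activation)
}

#' 2-D convolution layer forward pass
#'
#' Valid (no padding) cross-correlation of a `(H, W, C, N)` input stack with
#' a `(kh, kw, C, F)` kernel, output dims `H - kh + 1` by `W - kw + 1`;
#' `padding = "same"` zero-pads to preserve the spatial size (odd kernels).
#'
#' @param x input array `(H, W, C, N)`; a matrix is treated as `(H, W, 1, 1)`.
#' @param w kernel array `(kh, kw, C, F)`; a matrix as `(kh, kw, 1, 1)`.
#' @param activation elementwise activation.
#' @param padding `"valid"` or `"same"`.
#' @return Array `(oH, oW, F, N)`.
#' @export
nn_conv2d_forward <- function(x, w, activation = "linear",
                              padding = c("valid", "same")) {
  padding <- match.arg(padding)
  if (is.matrix(x)) dim(x) <- c(dim(x), 1, 1)
  if (is.matrix(w)) dim(w) <- c(dim(w), 1, 1)
  p <- if (padding == "same") c((dim(w)[1] - 1) %/% 2, (dim(w)[2] - 1) %/% 2)
       else c(0L, 0L)
  act_apply(conv2d_fwd_cpp(x, w, p[1], p[2]), activation)
}

# ---- op implementations -----------------------------------------------------
# Each op provides init (shape inference + parameter creation), forward
# (returns out + cache) and backward (returns dinputs + dparams).

shape_str <- function(s) paste(s, collapse = "x")

op_init <- function(op, args, in_shape, field) {
  cplx <- field == "complex"
  mk <- function(dims, fan_in, fan_out) {
    if (cplx) list(re = glorot(fan_in, fan_out, dims),
                   im = glorot(fan_in, fan_out, dims))
    else glorot(fan_in, fan_out, dims)
  }
  zeros <- function(n, init = NULL) {
    v <- rep(if (is.null(init)) 0 else init, n)
    if (cplx) list(re = v, im = v) else v
  }
  switch(op,
    dense = {
      fin <- if (length(in_shape) == 1) in_shape else prod(in_shape)
      u <- args$units
      p <- list(W = mk(c(fin, u), fin, u))
      if (!identical(args$bias, FALSE)) p$b <- zeros(u, args$bias_init)
      list(params = p, out_shape = u)
    },
    conv2d = {
      stopifnot(length(in_shape) == 3)
      k <- args$kernel; f <- args$filters; C <- in_shape[3]
      p <- list(W = mk(c(k[1], k[2], C, f), k[1] * k[2] * C, k[1] * k[2] * f))
      if (isTRUE(args$bias)) p$b <- zeros(f, args$bias_init)
      if (identical(args$padding, "same")) {
        os <- c(in_shape[1], in_shape[2], f)
      } else {
        os <- c(in_shape[1] - k[1] + 1, in_shape[2] - k[2] + 1, f)
        if (any(os[1:2] < 1)) stop("kernel larger than input")
      }
      list(params = p, out_shape = os)
    },
    batchnorm = {
      C <- in_shape[length(in_shape)]
      g1 <- function() if (cplx) list(re = rep(1, C), im = rep(1, C)) else rep(1, C)
      z1 <- function() zeros(C)
      list(params = list(gamma = g1(), beta = z1()),
           state = list(mean = z1(),
                        var = if (cplx) list(re = rep(1, C), im = rep(1, C)) else rep(1, C)),
           out_shape = in_shape)
    },
    maxpool = {
      s <- args$size
      os <- c(in_shape[1] %/% s, in_shape[2] %/% s, in_shape[3])
      if (any(os[1:2] < 1)) stop("pool size larger than input")
      list(params = list(), out_shape = os)
    },
    flatten = list(params = list(), out_shape = prod(in_shape)),
    reshape = list(params = list(), out_shape = args$dim),
    upsample = {
      f <- args$factor
      list(params = list(), out_shape = c(in_shape[1] * f, in_shape[2] * f, in_shape[3]))
    },
    concat = {
      s1 <- in_shape[[1]]; s2 <- in_shape[[2]]
      if (!all(s1[1:2] == s2[1:2])) stop("concat spatial shapes differ")
      list(params = list(), out_shape = c(s1[1], s1[2], s1[3] + s2[3]))
    },
    stop("unknown op: ", op))
}

# dense/conv forward shared between real and complex paths
fw_dense <- function(x, p, act) {
  if (is_cplx(x)) {
    yr <- x$re %*% p$W$re - x$im %*% p$W$im
    yi <- x$re %*% p$W$im + x$im %*% p$W$re
    if (!is.null(p$b)) {
      yr <- sweep(yr, 2, p$b$re, "+"); yi <- sweep(yi, 2, p$b$im, "+")
    }
    cact_apply(list(re = yr, im = yi), act)
  } else {
    y <- x %*% p$W
    if (!is.null(p$b)) y <- sweep(y, 2, p$b, "+")
    act_apply(y, act)
  }
}

act_code <- function(act) switch(act, linear = 0L, relu = 1L, sigmoid = 2L)

fw_conv <- function(x, p, act, pad) {
  if (is_cplx(x)) {
    cconv2d_fwd_cpp(x$re, x$im, p$W$re, p$W$im, pad[1], pad[2],
                    p$b$re, p$b$im, act_code(act))
  } else {
    conv2d_fwd_cpp(x, p$W, pad[1], pad[2], p$b, act_code(act))
  }
}

# batchnorm over all axes but the channel axis; data is viewed as
# (inner, C, outer): an (N, F) matrix as (N, F, 1), an (H, W, C, N) map as
# (H*W, C, N). The loops live in C++.
bn_geom <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2)
    c(nrow(x), ncol(x), 1L)
  else c(d[1] * d[2], d[3], d[4])
}

fw_bn_part <- function(x, gamma, beta, st_mean, st_var, training, eps,
                       momentum, act) {
  g <- bn_geom(x)
  r <- bn_fwd_cpp(x, g[1], g[2], g[3], gamma, beta, st_mean, st_var,
                  training, eps, momentum, act_code(act))
  y <- r$y
  if (is.null(dim(y))) dim(y) <- dim(x)
  list(y = y,
       cache = list(x = x, y = y, mu = r$mu, invstd = r$invstd, g = g,
                    d = dim(x)),
       mean = r$mean, var = r$var)
}

bw_bn_part <- function(dy, cache, gamma, act) {
  r <- bn_bwd_cpp(dy, cache$y, cache$x, cache$mu, cache$invstd, gamma,
                  cache$g[1], cache$g[2], cache$g[3], act_code(act))
  dx <- r$dx
  if (is.null(dim(dx))) dim(dx) <- cache$d
  list(dx = dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

flatten_fw <- function(x) t(matrix(x, prod(dim(x)[1:3]), dim(x)[4]))
flatten_bw <- function(dy, d) array(t(dy), d)
reshape_fw <- function(x, s) array(t(x), c(s, nrow(x)))
reshape_bw <- function(dy, n) t(matrix(dy, length(dy) / n, n))

upsample_fw <- function(x, f) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), , , drop = FALSE]
}
upsample_bw <- function(dy, f, d) {
  s1 <- array(colSums(array(dy, c(f, length(dy) / f))),
              c(d[1], f, d[2], d[3], d[4]))
  array(colSums(aperm(s1, c(2, 1, 3, 4, 5))), d)
}

op_forward <- function(node, x, training) {
  p <- node$params; a <- node$args
  switch(node$op,
    dense = {
      out <- fw_dense(x, p, a$activation)
      list(out = out, cache = list(x = x, out = out))
    },
    conv2d = {
      out <- fw_conv(x, p, a$activation, node$pad)
      list(out = out, cache = list(x = x, out = out))
    },
    batchnorm = {
      eps <- 1e-3; mom <- 0.99
      if (is_cplx(x)) {
        r <- fw_bn_part(x$re, p$gamma$re, p$beta$re, node$state$mean$re,
                        node$state$var$re, training, eps, mom, a$activation)
        i <- fw_bn_part(x$im, p$gamma$im, p$beta$im, node$state$mean$im,
                        node$state$var$im, training, eps, mom, a$activation)
        list(out = list(re = r$y, im = i$y),
             cache = list(re = r$cache, im = i$cache),
             state = list(mean = list(re = r$mean, im = i$mean),
                          var = list(re = r$var, im = i$var)))
      } else {
        r <- fw_bn_part(x, p$gamma, p$beta, node$state$mean, node$state$var,
                        training, eps, mom, a$activation)
        list(out = r$y, cache = list(re = r$cache),
             state = list(mean = r$mean, var = r$var))
      }
    },
    maxpool = {
      if (is_cplx(x)) {
        r <- maxpool_fwd_cpp(x$re, a$size); i <- maxpool_fwd_cpp(x$im, a$size)
        list(out = list(re = r$y, im = i$y),
             cache = list(ir = r$idx, ii = i$idx, d = dim(x$re)))
      } else {
        r <- maxpool_fwd_cpp(x, a$size)
        list(out = r$y, cache = list(ir = r$idx, d = dim(x)))
      }
    },
    flatten = {
      if (is_cplx(x))
        list(out = list(re = flatten_fw(x$re), im = flatten_fw(x$im)),
             cache = dim(x$re))
      else list(out = flatten_fw(x), cache = dim(x))
    },
    reshape = {
      if (is_cplx(x))
        list(out = list(re = reshape_fw(x$re, a$dim), im = reshape_fw(x$im, a$dim)),
             cache = nrow(x$re))
      else list(out = reshape_fw(x, a$dim), cache = nrow(x))
    },
    upsample = {
      if (is_cplx(x))
        list(out = list(re = upsample_fw(x$re, a$factor),
                        im = upsample_fw(x$im, a$factor)), cache = dim(x$re))
      else list(out = upsample_fw(x, a$factor), cache = dim(x))
    },
    concat = {
      x1 <- x[[1]]; x2 <- x[[2]]
      cat1 <- function(u, v) {
        d1 <- dim(u); d2 <- dim(v)
        out <- array(0, c(d1[1], d1[2], d1[3] + d2[3], d1[4]))
        out[, , seq_len(d1[3]), ] <- u
        out[, , d1[3] + seq_len(d2[3]), ] <- v
        out
      }
      if (is_cplx(x1))
        list(out = list(re = cat1(x1$re, x2$re), im = cat1(x1$im, x2$im)),
             cache = c(dim(x1$re)[3], dim(x2$re)[3]))
      else list(out = cat1(x1, x2), cache = c(dim(x1)[3], dim(x2)[3]))
    },
    stop("unknown op: ", node$op))
}

bw_dense <- function(dy, cache, p, act) {
  x <- cache$x; out <- cache$out
  if (is_cplx(x)) {
    dr <- act_grad(out$re, dy$re, act); di <- act_grad(out$im, dy$im, act)
    g <- list(W = list(re = crossprod(x$re, dr) + crossprod(x$im, di),
                       im = crossprod(x$re, di) - crossprod(x$im, dr)))
    if (!is.null(p$b)) g$b <- list(re = colSums(dr), im = colSums(di))
    dx <- list(re = tcrossprod(dr, p$W$re) + tcrossprod(di, p$W$im),
               im = tcrossprod(di, p$W$re) - tcrossprod(dr, p$W$im))
    list(dx = dx, dp = g)
  } else {
    dpre <- act_grad(out, dy, act)
    g <- list(W = crossprod(x, dpre))
    if (!is.null(p$b)) g$b <- colSums(dpre)
    list(dx = tcrossprod(dpre, p$W), dp = g)
  }
}

bw_conv <- function(dy, cache, p, act, pad) {
  x <- cache$x; out <- cache$out
  if (is_cplx(x)) {
    b <- cconv2d_bwd_cpp(x$re, x$im, p$W$re, p$W$im, dy$re, dy$im,
                         pad[1], pad[2], out$re, out$im, act_code(act),
                         want_db = !is.null(p$b))
    g <- list(W = list(re = b$dwr, im = b$dwi))
    if (!is.null(p$b)) g$b <- list(re = b$dbr, im = b$dbi)
    list(dx = list(re = b$dxr, im = b$dxi), dp = g)
  } else {
    b <- conv2d_bwd_cpp(x, p$W, dy, pad[1], pad[2], out, act_code(act),
                        want_db = !is.null(p$b))
    g <- list(W = b$dw)
    if (!is.null(p$b)) g$b <- b$db
    list(dx = b$dx, dp = g)
  }
}

op_backward <- function(node, cache, dy) {
  p <- node$params; a <- node$args
  switch(node$op,
    dense = bw_dense(dy, cache, p, a$activation),
    conv2d = bw_conv(dy, cache, p, a$activation, node$pad),
    batchnorm = {
      if (is_cplx(dy)) {
        br <- bw_bn_part(dy$re, cache$re, p$gamma$re, a$activation)
        bi <- bw_bn_part(dy$im, cache$im, p$gamma$im, a$activation)
        list(dx = list(re = br$dx, im = bi$dx),
             dp = list(gamma = list(re = br$dgamma, im = bi$dgamma),
                       beta = list(re = br$dbeta, im = bi$dbeta)))
      } else {
        b <- bw_bn_part(dy, cache$re, p$gamma, a$activation)
        list(dx = b$dx, dp = list(gamma = b$dgamma, beta = b$dbeta))
      }
    },
    maxpool = {
      if (is_cplx(dy))
        list(dx = list(re = maxpool_bwd_cpp(cache$ir, dy$re, cache$d),
                       im = maxpool_bwd_cpp(cache$ii, dy$im, cache$d)), dp = list())
      else list(dx = maxpool_bwd_cpp(cache$ir, dy, cache$d), dp = list())
    },
    flatten = {
      if (is_cplx(dy))
        list(dx = list(re = flatten_bw(dy$re, cache), im = flatten_bw(dy$im, cache)),
             dp = list())
      else list(dx = flatten_bw(dy, cache), dp = list())
    },
    reshape = {
      if (is_cplx(dy))
        list(dx = list(re = reshape_bw(dy$re, cache), im = reshape_bw(dy$im, cache)),
             dp = list())
      else list(dx = reshape_bw(dy, cache), dp = list())
    },
    upsample = {
      f <- a$factor
      if (is_cplx(dy))
        list(dx = list(re = upsample_bw(dy$re, f, cache), im = upsample_bw(dy$im, f, cache)),
             dp = list())
      else list(dx = upsample_bw(dy, f, cache), dp = list())
    },
    concat = {
      sp <- function(u) list(u[, , seq_len(cache[1]), , drop = FALSE],
                             u[, , cache[1] + seq_len(cache[2]), , drop = FALSE])
      if (is_cplx(dy)) {
        r <- sp(dy$re); i <- sp(dy$im)
        list(dx = list(list(re = r[[1]], im = i[[1]]),
                       list(re = r[[2]], im = i[[2]])), dp = list())
      } else {
        r <- sp(dy)
        list(dx = list(r[[1]], r[[2]]), dp = list())
      }
    },
    stop("unknown op: ", node$op))
}

# ---- model construction -----------------------------------------------------

#' Create a layer-graph builder
#'
#' Accumulates layer specifications; each `add()` returns the node id so
#' skip connections can reference earlier layers.
#'
#' @return Environment with an `add(op, ..., input)` function and the
#'   accumulated layer definitions in `$nodes`.
#' @keywords internal
node_builder <- function() {
  env <- new.env()
  env$nodes <- list()
  env$add <- function(op, ..., input = NULL) {
    id <- length(env$nodes) + 1L
    if (is.null(input)) input <- id - 1L   # 0 = model input
    env$nodes[[id]] <- list(op = op, input = as.integer(input), args = list(...))
    id
  }
  env
}

#' Assemble and initialize a model from a node specification
#'
#' @param name model name.
#' @param input_shape integer vector: a single length for dense input, or
#'   `(H, W, C)` for image input.
#' @param nodes list of node specs (`op`, `input`, `args`), as produced by
#'   [node_builder()].
#' @param field `"real"` or `"complex"`; complex models carry paired
#'   real/imaginary weights.
#' @param seed initialization seed.
#' @return Object of class `mwi_model`.
#' @export
new_model <- function(name, input_shape, nodes, field = c("real", "complex"),
                      seed = 1L) {
  field <- match.arg(field)
  set.seed(as.integer(seed %% 2147483647))
  shapes <- list()
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    ins <- lapply(nd$input, function(j) if (j == 0) input_shape else shapes[[j]])
    in_shape <- if (length(ins) == 1) ins[[1]] else ins
    if (nd$op == "conv2d") {
      if (is.null(nd$args$padding)) nd$args$padding <- "valid"
      k <- nd$args$kernel
      nd$pad <- if (nd$args$padding == "same")
        as.integer(c((k[1] - 1) %/% 2, (k[2] - 1) %/% 2)) else c(0L, 0L)
    }
    if (nd$op %in% c("dense", "conv2d", "batchnorm") &&
        is.null(nd$args$activation)) nd$args$activation <- "linear"
    ini <- op_init(nd$op, nd$args, in_shape, field)
    nd$params <- ini$params
    nd$state <- ini$state
    shapes[[i]] <- ini$out_shape
    nodes[[i]] <- nd
  }
  structure(list(name = name, field = field, input_shape = input_shape,
                 nodes = nodes, shapes = shapes, seed = seed),
            class = "mwi_model")
}

#' @export
print.mwi_model <- function(x, ...) {
  cnt <- model_param_counts(x)
  cat(sprintf("%s (%s-valued): input %s -> output %s, %s parameters\n",
              x$name, x$field, shape_str(x$input_shape),
              shape_str(x$shapes[[length(x$shapes)]]),
              format(sum(cnt$params), big.mark = ",")))
  invisible(x)
}

#' @export
summary.mwi_model <- function(object, ...) {
  df <- model_param_counts(object)
  print(df, row.names = FALSE)
  cat(sprintf("Total parameters: %s\n", format(sum(df$params), big.mark = ",")))
  invisible(df)
}

#' Per-layer parameter counts
#'
#' Counts follow the usual bookkeeping of deep-learning frameworks: dense
#' layers `in*out + out`, bias-free convolutions `kh*kw*C*F`, batch
#' normalization 4 numbers per channel (scale, shift, moving mean, moving
#' variance) when `bn = "all"`, or the 2 trainable ones when
#' `bn = "trainable"`. Complex layers count each complex parameter as its
#' two real components.
#'
#' @param model an `mwi_model`.
#' @param bn batchnorm accounting convention.
#' @return `data.frame` with layer, op, output shape and parameter count.
#' @export
model_param_counts <- function(model, bn = c("all", "trainable")) {
  bn <- match.arg(bn)
  rows <- lapply(seq_along(model$nodes), function(i) {
    nd <- model$nodes[[i]]
    n <- sum(vapply(nd$params, function(p)
      if (is_cplx(p)) length(p$re) + length(p$im) else length(p), numeric(1)))
    if (nd$op == "batchnorm" && bn == "all") n <- 2 * n
    data.frame(layer = i, op = nd$op,
               output_shape = shape_str(model$shapes[[i]]),
               params = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Forward pass of a model
#'
#' @param model an `mwi_model`.
#' @param x input batch: `(N, F)` matrix for dense input, `(H, W, C, N)`
#'   array for image input, or a `list(re, im)` pair for complex models.
#' @param training TRUE uses batch statistics in normalization layers and
#'   updates their moving averages.
#' @param keep_cache retain per-node caches for [model_backward()].
#' @return List with `out`, `caches` and (possibly updated) `model`.
#' @export
model_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  n <- length(model$nodes)
  acts <- vector("list", n)
  caches <- if (keep_cache) vector("list", n) else NULL
  for (i in seq_len(n)) {
    nd <- model$nodes[[i]]
    ins <- lapply(nd$input, function(j) if (j == 0) x else acts[[j]])
    xi <- if (length(ins) == 1) ins[[1]] else ins
    r <- op_forward(nd, xi, training)
    acts[[i]] <- r$out
    if (keep_cache) caches[[i]] <- r$cache
    if (training && !is.null(r$state)) model$nodes[[i]]$state <- r$state
  }
  list(out = acts[[n]], caches = caches, model = model)
}

#' Backward pass: gradients of a scalar loss w.r.t. all parameters
#'
#' @param model an `mwi_model`.
#' @param caches caches from `model_forward(..., keep_cache = TRUE)`.
#' @param grad_out gradient of the loss w.r.t. the model output (same
#'   structure as the output), or, with `skip_out_act = TRUE`, w.r.t. the
#'   output node's pre-activation (fused sigmoid + cross-entropy).
#' @param skip_out_act treat the output node's activation as already
#'   differentiated through.
#' @return List with `grads` (flat named list aligned with
#'   [model_params()]) and `dinput`, the gradient w.r.t. the model input.
#' @export
model_backward <- function(model, caches, grad_out, skip_out_act = FALSE) {
  n <- length(model$nodes)
  douts <- vector("list", n)
  dinput <- NULL
  douts[[n]] <- if (is_cplx(grad_out))
    list(re = grad_out$re + 0, im = grad_out$im + 0) else grad_out + 0
  acc <- function(a, b) {
    if (is.null(a)) return(b)
    if (is_cplx(a)) list(re = a$re + b$re, im = a$im + b$im) else a + b
  }
  grads <- list()
  for (i in rev(seq_len(n))) {
    nd <- model$nodes[[i]]
    if (is.null(douts[[i]])) next
    if (i == n && skip_out_act && !is.null(nd$args$activation))
      nd$args$activation <- "linear"
    r <- op_backward(nd, caches[[i]], douts[[i]])
    for (pn in names(r$dp))
      grads[[sprintf("n%03d.%s", i, pn)]] <- r$dp[[pn]]
    dxs <- if (length(nd$input) == 1) list(r$dx) else r$dx
    for (k in seq_along(nd$input)) {
      j <- nd$input[k]
      if (j == 0) dinput <- acc(dinput, dxs[[k]])
      else douts[[j]] <- acc(douts[[j]], dxs[[k]])
    }
    douts[i] <- list(NULL)
  }
  list(grads = grads, dinput = dinput)
}

#' Flat named parameter list of a model
#' @param model an `mwi_model`.
#' @return Named list `n<idx>.<name>` of parameter arrays.
#' @export
model_params <- function(model) {
  out <- list()
  for (i in seq_along(model$nodes))
    for (pn in names(model$nodes[[i]]$params))
      out[[sprintf("n%03d.%s", i, pn)]] <- model$nodes[[i]]$params[[pn]]
  out
}

#' Replace model parameters from a flat named list
#' @param model an `mwi_model`.
#' @param params list as returned by [model_params()].
#' @return The updated model.
#' @export
model_set_params <- function(model, params) {
  for (nm in names(params)) {
    i <- as.integer(substr(nm, 2, 4))
    pn <- substring(nm, 6)
    model$nodes[[i]]$params[[pn]] <- params[[nm]]
  }
  model
}

# ---- Adam optimizer ---------------------------------------------------------

adam_init <- function(params) {
  z <- rapply(params, function(x) x * 0, how = "replace")
  list(m = z, v = z, t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / c1) / (sqrt(v / c2) + eps)
    list(p, m, v)
  }
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is_cplx(params[[nm]])) {
      for (part in c("re", "im")) {
        r <- upd(params[[nm]][[part]], g[[part]],
                 state$m[[nm]][[part]], state$v[[nm]][[part]])
        params[[nm]][[part]] <- r[[1]]
        state$m[[nm]][[part]] <- r[[2]]
        state$v[[nm]][[part]] <- r[[3]]
      }
    } else {
      r <- upd(params[[nm]], g, state$m[[nm]], state$v[[nm]])
      params[[nm]] <- r[[1]]; state$m[[nm]] <- r[[2]]; state$v[[nm]] <- r[[3]]
    }
  }
  list(params = params, state = state)
}
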
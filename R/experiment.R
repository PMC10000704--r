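# Training / evaluation harness: splits, the Adam training loop with
# best-checkpoint keeping, k-fold cross-validation, reconstruction and
# report writing.

#' k-fold cross-validation split
#'
#' @param n number of items.
#' @param k number of folds (>= 2).
#' @param seed shuffle seed.
#' @return List of `k` lists with disjoint, exhaustive `train`/`test`
#'   1-based index vectors; fold sizes differ by at most one.
#' @export
kfold_split <- function(n, k = 10, seed = 1L) {
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("more folds than items")
  set.seed(as.integer(seed %% 2147483647))
  idx <- sample.int(n)
  fold <- rep(seq_len(k), length.out = 0)
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  fold <- rep(seq_len(k), times = sizes)
  lapply(seq_len(k), function(f)
    list(train = sort(idx[fold != f]), test = sort(idx[fold == f])))
}

#' Shuffled holdout split
#'
#' @param n number of items.
#' @param fraction test fraction in (0, 1) (default 0.1).
#' @param seed shuffle seed.
#' @return List with `train` and `test` index vectors;
#'   `length(test) = round(n * fraction)`.
#' @export
holdout_split <- function(n, fraction = 0.1, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  set.seed(as.integer(seed %% 2147483647))
  idx <- sample.int(n)
  nt <- round(n * fraction)
  list(train = sort(idx[seq_len(n - nt)]), test = sort(idx[n - nt + seq_len(nt)]))
}

eval_metric <- function(pred, y, metric) {
  if (metric == "accuracy") pixel_accuracy(pred, y) else img_mse(pred, y)
}

#' Train a model with Adam and best-checkpoint keeping
#'
#' Mini-batch Adam training with per-epoch validation; the parameters at the
#' best validation metric (lowest loss, or highest accuracy for binary
#' targets) are kept as the returned checkpoint. Runs are a pure function of
#' `seed` on one device.
#'
#' @param model an `mwi_model`.
#' @param x,y training inputs/targets (see [model_forward()] for formats).
#' @param val_x,val_y validation set (optional; without it the final
#'   parameters are kept).
#' @param loss `"mse"`, `"bce"` or `"cace"`.
#' @param metric `"loss"` or `"accuracy"` (binary targets).
#' @param epochs,batch_size,lr training protocol (Adam, beta 0.9/0.999).
#' @param seed shuffling seed.
#' @param verbose print one line per `verbose` epochs (0 = silent).
#' @return Object of class `mwi_trained`: the best `model`, `history`
#'   data.frame (per-epoch train loss, validation loss/metric), and
#'   `best_epoch`.
#' @export
train_model <- function(model, x, y, val_x = NULL, val_y = NULL,
                        loss = c("mse", "bce", "cace"),
                        metric = c("loss", "accuracy"),
                        epochs = 10, batch_size = 32, lr = 1e-3,
                        seed = 1L, verbose = 0) {
  loss <- match.arg(loss); metric <- match.arg(metric)
  lf <- loss_fun(loss)
  n <- batch_n(x)
  params <- model_params(model)
  opt <- adam_init(params)
  set.seed(as.integer(seed %% 2147483647))
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_metric = numeric())
  best <- list(value = if (metric == "accuracy") -Inf else Inf, vl = Inf,
               params = params, epoch = 0L, state = lapply(model$nodes, `[[`, "state"))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    bl <- 0; nb <- 0
    for (ix in split(ord, ceiling(seq_along(ord) / batch_size))) {
      xb <- batch_take(x, ix); yb <- batch_take(y, ix)
      model <- model_set_params(model, params)
      fw <- model_forward(model, xb, training = TRUE, keep_cache = TRUE)
      model <- fw$model            # updated batchnorm moving stats
      l <- lf(fw$out, yb)
      if (!is.finite(l$value)) stop(sprintf(
        "non-finite loss at epoch %d (model %s); aborting", ep, model$name))
      bw <- model_backward(model, fw$caches, l$grad,
                           skip_out_act = isTRUE(attr(lf, "logit_grad")))
      st <- adam_step(params, bw$grads, opt, lr = lr)
      params <- st$params; opt <- st$state
      bl <- bl + l$value; nb <- nb + 1
    }
    model <- model_set_params(model, params)
    vl <- NA_real_; vm <- NA_real_
    if (!is.null(val_x)) {
      pv_raw <- model_forward_batched(model, val_x, batch_size)
      vl <- lf(pv_raw, val_y)$value
      pv <- if (is_cplx(pv_raw)) sqrt(pv_raw$re^2 + pv_raw$im^2) else pv_raw
      yv <- val_y
      vm <- if (metric == "accuracy") pixel_accuracy(pv, yv) else vl
      # ties on the metric (common early in accuracy tracking) resolve to
      # the epoch with the lower validation loss
      better <- if (metric == "accuracy")
        vm > best$value || (vm == best$value && vl < best$vl)
      else vm < best$value
      if (better) best <- list(value = vm, vl = vl, params = params,
                               epoch = ep,
                               state = lapply(model$nodes, `[[`, "state"))
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = bl / nb,
                                   val_loss = vl, val_metric = vm))
    if (verbose > 0 && ep %% verbose == 0)
      cat(sprintf("[%s] epoch %d/%d train %.5g val %.5g metric %.5g\n",
                  model$name, ep, epochs, bl / nb, vl, vm))
  }
  if (is.null(val_x)) best <- list(value = NA_real_, params = params,
                                   epoch = epochs,
                                   state = lapply(model$nodes, `[[`, "state"))
  model <- model_set_params(model, best$params)
  for (i in seq_along(model$nodes))
    if (!is.null(best$state[[i]])) model$nodes[[i]]$state <- best$state[[i]]
  structure(list(model = model, history = hist, best_epoch = best$epoch,
                 loss = loss, metric = metric, seed = seed),
            class = "mwi_trained")
}

model_forward_batched <- function(model, x, batch_size = 32) {
  n <- batch_n(x)
  out <- NULL
  for (ix in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    o <- model_forward(model, batch_take(x, ix), training = FALSE)$out
    out <- if (is.null(out)) o
           else if (is_cplx(o)) list(re = bind_batches(out$re, o$re),
                                     im = bind_batches(out$im, o$im))
           else bind_batches(out, o)
  }
  out
}

#' @export
print.mwi_trained <- function(x, ...) {
  h <- x$history
  cat(sprintf("Trained %s: %d epochs, best epoch %d (val %s %.5g)\n",
              x$model$name, nrow(h), x$best_epoch, x$metric,
              if (nrow(h)) h$val_metric[x$best_epoch] else NA))
  invisible(x)
}

#' Normalize field matrices into model inputs
#'
#' Real-valued models consume the field magnitude scaled by the training-set
#' maximum to `[0, 1]`; the complex model consumes the raw complex field
#' scaled by the same maximum magnitude. The scale is estimated on the
#' training indices only and reused verbatim at inference time.
#'
#' @param fields complex array `(n, n_freq, n_angles)`.
#' @param kind `"dense"` (flattened magnitude), `"conv"` (magnitude map) or
#'   `"complex"` (raw field map).
#' @param train_idx indices used to estimate the scale (default: all).
#' @param scale known scale to reuse (overrides estimation).
#' @return List with the model input `x` and the `scale`.
#' @export
prepare_inputs <- function(fields, kind = c("dense", "conv", "complex"),
                           train_idx = NULL, scale = NULL) {
  kind <- match.arg(kind)
  d <- dim(fields)
  if (is.null(scale)) {
    sub <- if (is.null(train_idx)) fields else fields[train_idx, , , drop = FALSE]
    scale <- max(Mod(sub))
  }
  mag <- Mod(fields) / scale
  x <- switch(kind,
    dense = matrix(mag, d[1], d[2] * d[3]),
    conv = array(aperm(mag, c(2, 3, 1)), c(d[2], d[3], 1, d[1])),
    complex = list(re = array(aperm(Re(fields) / scale, c(2, 3, 1)),
                              c(d[2], d[3], 1, d[1])),
                   im = array(aperm(Im(fields) / scale, c(2, 3, 1)),
                              c(d[2], d[3], 1, d[1]))))
  list(x = x, scale = scale)
}

#' Image stacks as training targets
#'
#' @param images array `(n, s, s)`.
#' @param kind `"dense"` (flattened `(n, s*s)`) or `"conv"` (`(s, s, 1, n)`).
#' @return Target array.
#' @export
prepare_targets <- function(images, kind = c("dense", "conv")) {
  kind <- match.arg(kind)
  d <- dim(images)
  m <- aperm(images, c(2, 3, 1))                     # (s, s, n)
  if (kind == "dense") t(matrix(m, d[2] * d[3], d[1]))
  else array(m, c(d[2], d[3], 1, d[1]))
}

#' Reconstruct images from field matrices with a trained model
#'
#' @param trained an `mwi_trained` (or bare `mwi_model` plus `scale`).
#' @param fields complex array `(n, n_freq, n_angles)`, an `mwi_field`, or a
#'   single complex matrix.
#' @param scale input normalization scale (taken from `trained$scale` if
#'   present).
#' @param out_dir optional directory for PNG export (one file per image).
#' @param max_value white level for PNG export.
#' @return Array `(n, s, s)` of reconstructed images.
#' @export
reconstruct <- function(trained, fields, scale = trained$scale, out_dir = NULL,
                        max_value = NULL) {
  model <- if (inherits(trained, "mwi_trained")) trained$model else trained
  if (inherits(fields, "mwi_field")) fields <- fields$values
  if (is.matrix(fields)) fields <- array(fields, c(1, dim(fields)))
  d <- dim(fields)
  ok <- if (model$input_kind == "dense") d[2] * d[3] == model$input_shape
        else all(d[2:3] == model$input_shape[1:2])
  if (!ok) stop("field shape does not match the model input")
  kind <- if (model$field == "complex") "complex" else model$input_kind
  x <- prepare_inputs(fields, kind, scale = scale)$x
  pred <- model_predict(model, x)
  s <- model$out_side
  n <- d[1]
  imgs <- array(0, c(n, s, s))
  if (is.matrix(pred)) for (i in seq_len(n)) imgs[i, , ] <- matrix(pred[i, ], s, s)
  else imgs <- aperm(array(pred, c(s, s, n)), c(3, 1, 2))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    mv <- if (is.null(max_value)) max(imgs, 1) else max_value
    for (i in seq_len(n))
      write_image_png(imgs[i, , ], file.path(out_dir, sprintf("recon_%04d.png", i)), mv)
  }
  imgs
}

#' Cross-validate a model builder
#'
#' Trains a freshly built model on each fold's training part and evaluates
#' the metric report on both parts, mirroring the usual per-fold
#' mean-and-spread tables.
#'
#' @param builder function `(seed) -> mwi_model`.
#' @param x,y full inputs/targets.
#' @param k number of folds.
#' @param seed split/init seed.
#' @param ... passed to [train_model()] (epochs, loss, metric, ...).
#' @param metric_value which per-image metric to tabulate (`"mse"`,
#'   `"accuracy"`, `"ssim"`, ...).
#' @param max_value dynamic range for image metrics.
#' @param binary targets are binary masks.
#' @return data.frame with one row per fold plus an `"average"` row of
#'   columnwise means; attribute `reports` holds the per-fold test reports.
#' @export
cross_validate <- function(builder, x, y, k = 10, seed = 1L, ...,
                           metric_value = "mse", max_value = 255,
                           binary = FALSE) {
  n <- batch_n(x)
  folds <- kfold_split(n, k, seed)
  rows <- list(); reports <- list()
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    fit <- train_model(builder(seed + f), batch_take(x, tr), batch_take(y, tr),
                       batch_take(x, te), batch_take(y, te),
                       seed = seed + f, ...)
    ev <- function(ix, split) {
      pred <- stack_from_targets(model_predict(fit$model, batch_take(x, ix)))
      metric_report(pred, stack_from_targets(batch_take(y, ix)),
                    max_value = max_value, binary = binary,
                    model = fit$model$name, split = split)
    }
    rte <- ev(te, "test"); rtr <- ev(tr, "train")
    reports[[f]] <- rte
    pick <- function(r) {
      v <- r[[metric_value]]; v <- v[is.finite(v)]
      c(mean(v), stats::sd(v))
    }
    a <- pick(rtr); b <- pick(rte)
    rows[[f]] <- data.frame(fold = as.character(f), n_train = length(tr),
                            n_test = length(te),
                            train_mean = a[1], train_sd = a[2],
                            test_mean = b[1], test_sd = b[2])
  }
  df <- do.call(rbind, rows)
  avg <- df[1, ]
  avg$fold <- "average"; avg$n_train <- mean(df$n_train); avg$n_test <- mean(df$n_test)
  for (cn in c("train_mean", "train_sd", "test_mean", "test_sd"))
    avg[[cn]] <- mean(df[[cn]])
  out <- rbind(df, avg)
  attr(out, "metric") <- metric_value
  attr(out, "reports") <- reports
  out
}

# (H,W,1,n) arrays or (n,F) matrices back to (n,s,s) stacks
stack_from_targets <- function(y) {
  if (is.matrix(y)) {
    s <- as.integer(sqrt(ncol(y)))
    aperm(array(t(y), c(s, s, nrow(y))), c(3, 1, 2))
  } else as_image_stack(y)
}

#' Write a metric table to CSV and JSON
#'
#' @param df data.frame (e.g. an `mwi_report` or [cross_validate()] table).
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @param meta named list of provenance (seed, config, ...) stored in the
#'   JSON summary.
#' @return Paths of the written files, invisibly.
#' @export
write_report <- function(df, dir, name = "report", meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  ok <- tryCatch({ utils::write.csv(as.data.frame(df), csv, row.names = FALSE); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) stop(sprintf("failed to write '%s': %s", csv,
                                conditionMessage(ok)))
  js <- file.path(dir, paste0(name, ".json"))
  smry <- attr(df, "summary")
  payload <- list(meta = meta)
  if (!is.null(smry))
    payload$summary <- stats::setNames(
      lapply(seq_len(nrow(smry)), function(i)
        list(mean = smry$mean[i], sd = smry$sd[i],
             formatted = format_pm(smry$mean[i], smry$sd[i]))),
      smry$metric)
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, js))
}
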
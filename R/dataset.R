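#' Build a reproducible simulated dataset
#'
#' Samples `n` random scenarios (per-item seeds derived from `global_seed`
#' via [item_seed()]), synthesizes their backscattered field matrices and
#' renders paired float and binary ground-truth images. Regeneration with the
#' same seed and configuration is bit-identical.
#'
#' @param n number of scenarios.
#' @param global_seed integer global seed.
#' @param cfg an [acquisition_config()].
#' @param image_size ground-truth image side (default 128).
#' @param hires rasterization side before downscaling.
#' @param n_tumors candidate tumor counts per scenario (default 1:3).
#' @param n_skin_points,tumor_spacing scene discretization, see [scenario()].
#' @param progress print a dot every 25 scenarios.
#' @return Object of class `mwi_dataset`: complex array `fields`
#'   `(n, n_freq, n_angles)`, numeric arrays `images_float` and
#'   `images_binary` `(n, image_size, image_size)`, the scenario list, the
#'   seed and the configuration.
#' @export
build_dataset <- function(n, global_seed = 42L, cfg = acquisition_config(),
                          image_size = 128, hires = 4 * image_size,
                          n_tumors = 1:3, n_skin_points = 360,
                          tumor_spacing = 0.1, progress = FALSE) {
  stopifnot(n >= 1)
  fields <- array(complex(real = 0), c(n, cfg$n_freq, cfg$n_angles))
  imf <- array(0, c(n, image_size, image_size))
  imb <- array(0, c(n, image_size, image_size))
  scens <- vector("list", n)
  seeds <- item_seed(global_seed, seq_len(n))
  for (i in seq_len(n)) {
    sc <- sample_scenario(cfg, seed = seeds[i], n_tumors = n_tumors,
                          n_skin_points = n_skin_points,
                          tumor_spacing = tumor_spacing)
    fd <- backscattered_field(sc, cfg)
    gt <- ground_truth_images(sc, image_size, hires)
    fields[i, , ] <- fd$values
    imf[i, , ] <- gt$float
    imb[i, , ] <- gt$binary
    scens[[i]] <- sc
    if (progress && i %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  structure(list(fields = fields, images_float = imf, images_binary = imb,
                 scenarios = scens, global_seed = global_seed, cfg = cfg,
                 image_size = image_size),
            class = "mwi_dataset")
}

#' @export
print.mwi_dataset <- function(x, ...) {
  d <- dim(x$fields)
  cat(sprintf("mwi_dataset: %d scenarios, fields (%d x %d x %d), images %dx%d, seed %s\n",
              d[1], d[1], d[2], d[3], x$image_size, x$image_size,
              format(x$global_seed)))
  invisible(x)
}

#' Save / load a dataset container
#'
#' Serializes the full dataset (field stack, image stacks, scenario geometry
#' and configuration provenance) to a single file using R's native
#' serialization.
#'
#' @param ds an `mwi_dataset`.
#' @param path file path.
#' @return `save_dataset` returns the path invisibly; `load_dataset` returns
#'   the `mwi_dataset`.
#' @export
save_dataset <- function(ds, path) {
  ok <- tryCatch(suppressWarnings({ saveRDS(ds, path); TRUE }),
                 error = function(e) e)
  if (!isTRUE(ok)) stop(sprintf("failed to write dataset to '%s': %s",
                                path, conditionMessage(ok)))
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop(sprintf("dataset file '%s' not found", path))
  readRDS(path)
}
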
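#' @useDynLib mwisar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# 32-bit mixer for per-item seeds (splitmix-style finalizer). Arithmetic is
# done on 16-bit limbs so every intermediate stays exactly representable in
# doubles; the result is reduced mod 2^31 for set.seed().
mix32 <- function(a, b) {
  mul32 <- function(x, y) {
    xl <- x %% 65536; xh <- (x - xl) / 65536
    yl <- y %% 65536; yh <- (y - yl) / 65536
    (xl * yl + ((xl * yh + xh * yl) %% 65536) * 65536) %% 4294967296
  }
  xor32 <- function(x, y) {
    r <- 0; p <- 1
    for (k in 1:32) {
      xb <- x %% 2; yb <- y %% 2
      r <- r + ((xb + yb) %% 2) * p
      x <- (x - xb) / 2; y <- (y - yb) / 2; p <- p * 2
    }
    r
  }
  z <- (a %% 4294967296 + mul32(b %% 4294967296, 2654435769)) %% 4294967296
  z <- mul32(xor32(z, floor(z / 65536)), 2246822519)
  z <- mul32(xor32(z, floor(z / 8192)), 3266489917)
  z <- xor32(z, floor(z / 65536))
  z %% 2147483647
}

#' Per-item seed derivation
#'
#' Deterministically derives the seed of dataset item `i` from a global seed,
#' so items can be regenerated independently and in any order.
#'
#' @param global_seed integer global seed.
#' @param index 1-based item index (vectorized).
#' @return Integer seed(s) in `[0, 2^31)`.
#' @export
item_seed <- function(global_seed, index) {
  vapply(index, function(i) mix32(global_seed, i), numeric(1))
}

#' Construct a tumor scatterer
#'
#' A circular tumor inclusion, optionally already discretized to scatter
#' points. Validity: radius in a configurable range and the disk strictly
#' inside the skin circle.
#'
#' @param center_x,center_y disk center in cm.
#' @param radius disk radius in cm.
#' @param skin_radius enclosing skin circle radius in cm (for validation).
#' @param points optional n x 2 matrix of scatter-point coordinates (cm).
#' @return Object of class `mwi_tumor`.
#' @export
tumor_scatterer <- function(center_x, center_y, radius, skin_radius = 7,
                            points = NULL) {
  if (radius <= 0) stop("radius must be positive")
  if (sqrt(center_x^2 + center_y^2) + radius >= skin_radius)
    stop("tumor must lie strictly inside the skin circle")
  if (!is.null(points)) {
    d <- sqrt((points[, 1] - center_x)^2 + (points[, 2] - center_y)^2)
    if (any(d > radius + 1e-9)) stop("scatter points outside the tumor disk")
  }
  structure(list(center_x = center_x, center_y = center_y, radius = radius,
                 points = points), class = "mwi_tumor")
}

#' Discretize a tumor disk into point scatterers
#'
#' Lays a square grid of pitch `spacing` centred on the disk center and keeps
#' grid points inside the disk; the center itself is always included, so even
#' a vanishing disk yields one point.
#'
#' @param tumor an `mwi_tumor`, or a list with `center_x`, `center_y`,
#'   `radius`.
#' @param spacing grid pitch in cm (default 0.1).
#' @return n x 2 matrix of point coordinates (cm).
#' @export
discretize_tumor <- function(tumor, spacing = 0.1) {
  stopifnot(spacing > 0)
  r <- tumor$radius
  k <- floor(r / spacing)
  g <- spacing * (-k:k)
  pts <- as.matrix(expand.grid(x = tumor$center_x + g, y = tumor$center_y + g))
  keep <- (pts[, 1] - tumor$center_x)^2 + (pts[, 2] - tumor$center_y)^2 <= r^2 + 1e-12
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) == 0L) pts <- matrix(c(tumor$center_x, tumor$center_y), 1, 2)
  dimnames(pts) <- NULL
  pts
}

#' Equally spaced scatter points on the skin circle
#'
#' @param cfg an [acquisition_config()].
#' @param n_points number of points on the circle (default 360).
#' @return n x 2 matrix of coordinates (cm).
#' @export
discretize_skin <- function(cfg, n_points = 360) {
  a <- 2 * pi * (seq_len(n_points) - 1) / n_points
  cbind(cfg$skin_radius * cos(a), cfg$skin_radius * sin(a))
}

#' Construct a scenario
#'
#' A scenario bundles 1--3 non-overlapping tumor disks with the skin circle
#' discretization that together form the scattering scene.
#'
#' @param tumors list of [tumor_scatterer()] objects (length 1--3).
#' @param cfg an [acquisition_config()].
#' @param n_skin_points skin circle discretization count.
#' @param tumor_spacing scatter-point grid pitch for tumors, in cm.
#' @param seed optional provenance seed.
#' @param id optional identifier.
#' @param check_overlap reject overlapping tumor disks (default TRUE).
#' @return Object of class `mwi_scenario`.
#' @export
scenario <- function(tumors, cfg = acquisition_config(), n_skin_points = 360,
                     tumor_spacing = 0.1, seed = NA_integer_, id = NA_character_,
                     check_overlap = TRUE) {
  if (length(tumors) < 1 || length(tumors) > 3)
    stop("a scenario holds between one and three tumors")
  if (check_overlap && length(tumors) > 1) {
    for (i in seq_along(tumors)) for (j in seq_len(i - 1)) {
      d <- sqrt((tumors[[i]]$center_x - tumors[[j]]$center_x)^2 +
                (tumors[[i]]$center_y - tumors[[j]]$center_y)^2)
      if (d <= tumors[[i]]$radius + tumors[[j]]$radius)
        stop("tumor disks overlap")
    }
  }
  tumors <- lapply(tumors, function(t) {
    if (is.null(t$points)) t$points <- discretize_tumor(t, tumor_spacing)
    t
  })
  structure(list(tumors = tumors,
                 skin_points = discretize_skin(cfg, n_skin_points),
                 seed = seed, id = id, cfg = cfg),
            class = "mwi_scenario")
}

#' @export
print.mwi_scenario <- function(x, ...) {
  cat(sprintf("Scenario%s: %d tumor(s), %d skin points\n",
              if (is.na(x$id)) "" else paste0(" ", x$id),
              length(x$tumors), nrow(x$skin_points)))
  for (t in x$tumors)
    cat(sprintf("  tumor at (%.3f, %.3f) cm, radius %.3f cm, %d points\n",
                t$center_x, t$center_y, t$radius, nrow(t$points)))
  invisible(x)
}

#' Sample a random tumor scenario
#'
#' Draws the tumor count uniformly from `n_tumors`, each radius uniformly
#' from `radius_range`, and each center uniformly over the disk that keeps
#' the tumor fully inside the skin. Disks are kept pairwise disjoint by
#' rejection re-sampling (up to `max_tries` draws per tumor).
#'
#' @param cfg an [acquisition_config()].
#' @param seed integer seed; the draw is a pure function of it.
#' @param n_tumors candidate tumor counts (default 1:3).
#' @param radius_range tumor radius range in cm (default `c(0.2, 0.9)`).
#' @param n_skin_points,tumor_spacing discretization, see [scenario()].
#' @param max_tries rejection cap per tumor.
#' @return An `mwi_scenario`.
#' @export
sample_scenario <- function(cfg = acquisition_config(), seed = 1L,
                            n_tumors = 1:3, radius_range = c(0.2, 0.9),
                            n_skin_points = 360, tumor_spacing = 0.1,
                            max_tries = 1000) {
  set.seed(as.integer(seed %% 2147483647))
  k <- if (length(n_tumors) == 1L) n_tumors else sample(n_tumors, 1L)
  tumors <- list()
  for (i in seq_len(k)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      r <- stats::runif(1, radius_range[1], radius_range[2])
      rho <- (cfg$skin_radius - r) * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      cx <- rho * cos(th); cy <- rho * sin(th)
      ok <- TRUE
      for (t in tumors) {
        d <- sqrt((cx - t$center_x)^2 + (cy - t$center_y)^2)
        if (d <= r + t$radius) { ok <- FALSE; break }
      }
      if (ok) {
        tumors[[i]] <- tumor_scatterer(cx, cy, r, cfg$skin_radius)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("rejection cap exceeded while placing tumors")
  }
  scenario(tumors, cfg, n_skin_points, tumor_spacing, seed = seed,
           id = sprintf("s%d", seed))
}
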
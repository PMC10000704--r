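#' Synthesize the backscattered field matrix of a scenario
#'
#' Evaluates the monostatic CSAR point-scatterer model: at each frequency
#' `f` and antenna angle `phi`, the backscattered field is a superposition of
#' unit-modulus phasors over all scatter points,
#' `Es(f, phi) = A0 * sum_p exp(-i 4 pi f sqrt(eps_r mu_r) / c * R_p(phi))`,
#' with `R_p(phi)` the point-antenna distance and the two-way propagation
#' delay in the exponent. Tumor scatter points and skin circle points
#' contribute with unit weight.
#'
#' @param scen an `mwi_scenario`.
#' @param cfg an [acquisition_config()]; defaults to the scenario's.
#' @param include_skin include the skin ring points (default TRUE).
#' @return Object of class `mwi_field`: complex `n_freq x n_angles` matrix
#'   `values` with `freq_axis` (GHz) and `angle_axis` (degrees).
#' @export
backscattered_field <- function(scen, cfg = scen$cfg, include_skin = TRUE) {
  pts <- do.call(rbind, lapply(scen$tumors, function(t) t$points))
  if (include_skin) pts <- rbind(pts, scen$skin_points)
  if (is.null(pts) || nrow(pts) == 0L)
    stop("degenerate scenario: no scatter points")
  field_from_points(pts, cfg)
}

#' Backscattered field of an explicit point set
#'
#' @param points n x 2 matrix of scatter points (cm).
#' @param cfg an [acquisition_config()].
#' @param weights per-point weights (default 1).
#' @return An `mwi_field`.
#' @export
field_from_points <- function(points, cfg, weights = rep(1, nrow(points))) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, length(weights) == nrow(points))
  vals <- cs_field_cpp(points[, 1], points[, 2], weights,
                       cfg$freq_axis * 1e9, cfg$angle_axis * pi / 180,
                       cfg$antenna_radius, cfg$eps_r, cfg$mu_r, cfg$c0,
                       cfg$amplitude)
  structure(list(values = vals, freq_axis = cfg$freq_axis,
                 angle_axis = cfg$angle_axis),
            class = "mwi_field")
}

#' @export
print.mwi_field <- function(x, ...) {
  cat(sprintf("Backscattered field: %d frequencies x %d angles, |Es| in [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values),
              min(Mod(x$values)), max(Mod(x$values))))
  invisible(x)
}
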
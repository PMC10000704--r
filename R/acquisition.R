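#' Acquisition configuration for the monostatic CSAR setup
#'
#' Describes the stepped-frequency circular synthetic aperture radar (CSAR)
#' acquisition: a single transceiver antenna rotated on a ring around the
#' imaging domain, sweeping a uniform frequency grid at each stop. Defaults
#' reproduce the simulated setup: 1--10 GHz in 301 steps, a 7 cm skin circle,
#' a 2 cm skin-antenna gap, and 4 degree rotation increments (90 angles).
#'
#' Geometry is expressed in centimetres and frequency in gigahertz at the
#' interface; field synthesis converts to SI units internally.
#'
#' @param f_start,f_stop sweep limits in GHz.
#' @param n_freq number of frequency points (>= 2), uniformly spaced.
#' @param angle_step antenna rotation increment in degrees; must divide 360.
#' @param skin_radius radius of the skin circle in cm.
#' @param antenna_gap gap between skin and antenna ring in cm.
#' @param amplitude field amplitude A0 of each unit scatterer (default 1).
#' @param eps_r,mu_r relative permittivity and permeability of the
#'   (homogeneous) background medium.
#' @param c0 wave speed in m/s.
#' @return An object of class `mwi_config` with the frequency axis (GHz),
#'   angle axis (degrees) and derived `antenna_radius = skin_radius +
#'   antenna_gap`.
#' @examples
#' cfg <- acquisition_config()
#' cfg$antenna_radius  # 9 cm
#' @export
acquisition_config <- function(f_start = 1, f_stop = 10, n_freq = 301,
                               angle_step = 4, skin_radius = 7, antenna_gap = 2,
                               amplitude = 1, eps_r = 1, mu_r = 1,
                               c0 = 299792458) {
  stopifnot(f_start > 0, f_stop > f_start, n_freq >= 2,
            skin_radius > 0, antenna_gap >= 0, eps_r > 0, mu_r > 0, c0 > 0)
  if (abs(360 / angle_step - round(360 / angle_step)) > 1e-9)
    stop("angle_step must divide 360 degrees (full coverage)")
  n_angles <- as.integer(round(360 / angle_step))
  cfg <- list(
    f_start = f_start, f_stop = f_stop, n_freq = as.integer(n_freq),
    angle_step = angle_step, n_angles = n_angles,
    skin_radius = skin_radius, antenna_gap = antenna_gap,
    antenna_radius = skin_radius + antenna_gap,
    amplitude = amplitude, eps_r = eps_r, mu_r = mu_r, c0 = c0,
    freq_axis = seq(f_start, f_stop, length.out = n_freq),
    angle_axis = angle_step * (seq_len(n_angles) - 1)
  )
  structure(cfg, class = "mwi_config")
}

#' @export
print.mwi_config <- function(x, ...) {
  cat(sprintf("CSAR acquisition: %g-%g GHz x %d, %d angles (%g deg step)\n",
              x$f_start, x$f_stop, x$n_freq, x$n_angles, x$angle_step))
  cat(sprintf("  skin %g cm + gap %g cm -> antenna ring %g cm; A0=%g, eps_r=%g, mu_r=%g\n",
              x$skin_radius, x$antenna_gap, x$antenna_radius,
              x$amplitude, x$eps_r, x$mu_r))
  invisible(x)
}

#' Antenna position at a given angular stop
#'
#' @param cfg an [acquisition_config()].
#' @param j 0-based angle index, `0 <= j < cfg$n_angles`.
#' @return Numeric `(x, y)` in cm on the antenna ring.
#' @export
antenna_position <- function(cfg, j) {
  if (j < 0 || j >= cfg$n_angles || j != round(j))
    stop("angle index out of range")
  phi <- (j * cfg$angle_step) * pi / 180
  c(cfg$antenna_radius * cos(phi), cfg$antenna_radius * sin(phi))
}

#' Euclidean distance between a scatter point and the antenna
#'
#' @param point numeric `(x, y)` in cm.
#' @param phi antenna angle in degrees.
#' @param R0 antenna ring radius in cm.
#' @return Distance in cm.
#' @export
scatterer_distance <- function(point, phi, R0) {
  stopifnot(R0 > 0)
  a <- phi * pi / 180
  sqrt((point[1] - R0 * cos(a))^2 + (point[2] - R0 * sin(a))^2)
}

#' Range resolution and maximum range of the stepped-frequency sweep
#'
#' `delta_r = c / (2 N df)` with `df` the frequency step, and
#' `R_m = N * delta_r = c / (2 df)`, the standard stepped-frequency radar
#' relations.
#'
#' @param cfg an [acquisition_config()].
#' @return List with `delta_r` and `R_m` in metres, and the step `delta_f`
#'   in Hz.
#' @export
range_metrics <- function(cfg) {
  if (cfg$n_freq < 2) stop("need at least two frequencies")
  df <- (cfg$f_stop - cfg$f_start) * 1e9 / (cfg$n_freq - 1)
  dr <- cfg$c0 / (2 * cfg$n_freq * df)
  list(delta_r = dr, R_m = cfg$n_freq * dr, delta_f = df)
}
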
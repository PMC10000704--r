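# Shared fixtures and independent oracles used across the test files.

# small acquisition: 5 frequencies x 4 angles, exact speed of light 3e8
tiny_cfg <- function(...) {
  acquisition_config(f_start = 1, f_stop = 2, n_freq = 5, angle_step = 90,
                     c0 = 3e8, ...)
}

# naive R-loop evaluation of the point-scatterer field model
field_oracle <- function(points, cfg, weights = rep(1, nrow(points))) {
  out <- matrix(complex(real = 0), cfg$n_freq, cfg$n_angles)
  for (fi in seq_len(cfg$n_freq)) for (ai in seq_len(cfg$n_angles)) {
    f <- cfg$freq_axis[fi] * 1e9
    phi <- cfg$angle_axis[ai]
    s <- 0
    for (p in seq_len(nrow(points))) {
      R <- scatterer_distance(points[p, ], phi, cfg$antenna_radius) / 100
      s <- s + weights[p] *
        exp(-1i * 4 * pi * f * sqrt(cfg$eps_r * cfg$mu_r) / cfg$c0 * R)
    }
    out[fi, ai] <- cfg$amplitude * s
  }
  out
}

# quadruple-loop valid cross-correlation oracle
conv_oracle <- function(x, w) {
  x <- array(x, dim(x)[1:3])
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; F <- dim(w)[4]
  oH <- H - kh + 1; oW <- W - kw + 1
  y <- array(0, c(oH, oW, F))
  for (f in seq_len(F)) for (i in seq_len(oH)) for (j in seq_len(oW)) {
    s <- 0
    for (c in seq_len(C)) for (a in seq_len(kh)) for (b in seq_len(kw))
      s <- s + x[i + a - 1, j + b - 1, c] * w[a, b, c, f]
    y[i, j, f] <- s
  }
  y
}

# explicit-loop dense layer oracle
dense_oracle <- function(x, W, b) {
  n <- nrow(x); u <- ncol(W)
  y <- matrix(0, n, u)
  for (r in seq_len(n)) for (cix in seq_len(u))
    y[r, cix] <- sum(x[r, ] * W[, cix]) + b[cix]
  y
}

# centered finite differences
num_grad <- function(f, x, h = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + h; x2[i] <- x2[i] - h
    g[i] <- (f(x1) - f(x2)) / (2 * h)
  }
  g
}

# hand-written global UQI per the defining sums (independent of img_uqi)
uqi_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- sum((x - mx)^2) / (n - 1)
  vy <- sum((y - my)^2) / (n - 1)
  cxy <- sum((x - mx) * (y - my)) / (n - 1)
  (4 * cxy * mx * my) / ((vx + vy) * (mx^2 + my^2))
}

# simple angle unwrap
unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1], p[1] + cumsum(dp))
}
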
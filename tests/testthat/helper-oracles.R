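# Fixture builders and independent oracles used across the suite.

# Regular-polygon approximation of a circle (micrometre coordinates).
circle_ring <- function(radius_um, cx = 0, cy = 0, n = 360L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + radius_um * cos(th), cy + radius_um * sin(th))
}

# Random star-shaped (hence simple) polygon with n vertices.
star_polygon <- function(n = 12L, rmin_um = 800, rmax_um = 1500) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, rmin_um, rmax_um)
  cbind(r * cos(th), r * sin(th))
}

# Exact Euclidean distance from points to the closed polyline of a ring.
dist_to_ring_um <- function(pts, ring) {
  n <- nrow(ring)
  a <- ring; b <- ring[c(2:n, 1), , drop = FALSE]
  d2 <- rep(Inf, nrow(pts))
  for (e in seq_len(n)) {
    vx <- b[e, 1] - a[e, 1]; vy <- b[e, 2] - a[e, 2]
    L2 <- vx * vx + vy * vy
    t <- pmin(1, pmax(0, ((pts[, 1] - a[e, 1]) * vx + (pts[, 2] - a[e, 2]) * vy) / L2))
    d2e <- (pts[, 1] - (a[e, 1] + t * vx))^2 + (pts[, 2] - (a[e, 2] + t * vy))^2
    d2 <- pmin(d2, d2e)
  }
  sqrt(d2)
}

# Two-sample log-rank chi-square by direct O-E/V tabulation.
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  ts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Small synthetic configuration for fast geometry-level tests.
quick_config <- function(seed = 1L, ...) {
  sim_config(n_cases = 1L, seed = seed,
             radius_mm_mean = 1.0, radius_mm_sd = 0.2, radius_mm_min = 0.5,
             ...)
}
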
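# Shared fixtures for the test suite; everything is generated in code.

# A small, fixed cone array on a +/-10 deg crop for coverage oracles.
tiny_cone_array <- function(n = 40, domain = 10, seed = 101, rf = 0.38) {
  set.seed(seed)
  cone_array(runif(n, -domain, domain), runif(n, -domain, domain),
             rf_radius = rf, domain = domain)
}

# Exhaustive all-pairs coverage oracle: per-step counts by direct toroidal
# distance evaluation, one step at a time.
coverage_oracle <- function(traj, cones, target_radius) {
  dom <- attr(traj, "domain")
  w <- 2 * dom
  vapply(seq_len(nrow(traj)), function(s) {
    dx <- abs(cones$cones$azimuth - traj$azimuth[s]); dx <- pmin(dx, w - dx)
    dy <- abs(cones$cones$elevation - traj$elevation[s]); dy <- pmin(dy, w - dy)
    sum(sqrt(dx^2 + dy^2) < target_radius + cones$cones$rf_radius)
  }, 0L)
}

# Direct O(n*m) convolution oracle.
convolve_oracle <- function(series, ir) {
  n <- length(series)
  out <- numeric(n)
  for (t in seq_len(n)) {
    for (j in seq_along(ir)) {
      if (t - j + 1 >= 1) out[t] <- out[t] + series[t - j + 1] * ir[j]
    }
  }
  out
}

# Planted Hill curve evaluated exactly.
hill_curve <- function(I, a_max, i_half, h) a_max * I^h / (I^h + i_half^h)
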
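test_that("trajectory kinematics match the walk specification", {
  spec <- bright_target()
  expect_equal(spec$dt, 0.010)  # 1 deg steps at 100 deg/s
  traj <- generate_trajectory(spec, n_steps = 2000, domain = 60, seed = 4)
  expect_identical(traj, generate_trajectory(spec, 2000, 60, seed = 4))
  # heading changes bounded by the turn limit
  dh <- diff(traj$heading)
  expect_true(all(abs(dh) < spec$turn_limit))
  # step length conserved across toroidal wraparound
  w <- 120
  dx <- abs(diff(traj$azimuth)); dx <- pmin(dx, w - dx)
  dy <- abs(diff(traj$elevation)); dy <- pmin(dy, w - dy)
  expect_equal(sqrt(dx^2 + dy^2), rep(spec$step, 1999), tolerance = 1e-9)
  expect_error(target_spec(speed = 0), "positive")
})

test_that("coverage threshold arithmetic is exact", {
  # one cone, one step: covered iff distance < target_radius + rf_radius
  traj <- generate_trajectory(bright_target(), 1, domain = 10, seed = 1,
                              start = c(0, 0))
  traj$azimuth <- 0; traj$elevation <- 0
  near <- cone_array(1.30, 0, rf_radius = 0.38, domain = 10)
  far <- cone_array(1.50, 0, rf_radius = 0.38, domain = 10)
  expect_equal(coverage_series(traj, near, target_radius = 1)$counts, 1L)
  expect_equal(coverage_series(traj, far, target_radius = 1)$counts, 0L)
  # empty array: all-zero counts, not an error
  empty <- cone_array(numeric(0), numeric(0), domain = 10)
  expect_equal(coverage_series(traj, empty, target_radius = 1)$counts, 0L)
})

test_that("coverage counting matches the exhaustive all-pairs oracle", {
  cones <- tiny_cone_array(n = 80, domain = 10)
  traj <- generate_trajectory(bright_target(), 300, domain = 10, seed = 9)
  cov <- coverage_series(traj, cones, chunk = 64L)  # exercise chunking
  expect_equal(cov$counts, coverage_oracle(traj, cones, 1.0))
  # events agree with counts
  expect_equal(tabulate(factor(cov$events$step, levels = 1:300)),
               cov$counts)
})

test_that("uniform-density coverage approaches the Poisson prediction", {
  # lambda = rho * pi * (r_t + r_rf)^2 on a uniform array without spacing
  set.seed(77)
  dom <- 40; n <- 480  # rho = 0.075
  cones <- cone_array(runif(n, -dom, dom), runif(n, -dom, dom), domain = dom)
  traj <- generate_trajectory(bright_target(), 20000, domain = dom, seed = 78)
  cov <- coverage_series(traj, cones, events = FALSE)
  lambda <- n / (2 * dom)^2 * pi * 1.38^2
  st <- coverage_statistics(cov)
  expect_equal(unname(st["zero"]), exp(-lambda), tolerance = 0.05)
  expect_equal(unname(st["one"]), lambda * exp(-lambda), tolerance = 0.08)
  expect_equal(sum(st), 1)
})

test_that("zone weights interpolate dorsoventrally and blend the SZ", {
  # 75% toward the dorsal edge, outside the SZ radius
  w <- zone_weights(30, 45)
  expect_equal(unname(w), c(0.75, 0.25, 0, 0), tolerance = 1e-12)
  # on the horizon, outside SZ: all nasal
  w2 <- zone_weights(30, 0)
  expect_equal(unname(w2["nasal"]), 1)
  # at the SZ center: all SZ
  w3 <- zone_weights(-30, -30)
  expect_equal(unname(w3["sz"]), 1)
  # weights sum to 1 at random positions
  set.seed(5)
  for (k in 1:50) {
    w <- zone_weights(runif(1, -60, 60), runif(1, -60, 60))
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1)
  }
})

test_that("activation convolution is causal, linear, and matches the oracle", {
  ir <- impulse_response(-30, -30, polarity = "bright", dt = 0.01,
                         duration = 1)
  # single active step reproduces the impulse response
  s <- c(0, 0, 1, rep(0, 120))
  out <- convolve_activation(s, ir)
  expect_equal(out[3:(2 + length(ir))], as.numeric(ir))
  expect_equal(out[1:2], c(0, 0))
  # two disjoint activations superpose linearly
  s2 <- c(0, 0, 1, rep(0, 40), 1, rep(0, 79))
  o2 <- convolve_activation(s2, ir)
  o_shift <- convolve_activation(c(rep(0, 43), 1, rep(0, 79)), ir)
  expect_equal(o2, out + o_shift, tolerance = 1e-10)
  # random series vs direct-sum oracle
  set.seed(11)
  sr <- rbinom(200, 1, 0.1)
  expect_equal(convolve_activation(sr, ir), convolve_oracle(sr, ir),
               tolerance = 1e-8)
})

test_that("array normalization scales to unit peak and is idempotent", {
  m <- matrix(c(0, 1, 5, 2), 2)
  nm <- normalize_array(m)
  expect_equal(max(nm), 1)
  expect_equal(unclass(nm), m / 5, ignore_attr = TRUE)
  expect_equal(unclass(normalize_array(nm)), unclass(nm), ignore_attr = TRUE)
  expect_warning(z <- normalize_array(matrix(0, 2, 2)), "zero")
  expect_true(attr(z, "all_zero"))
})

test_that("BC placement and pooling respect spacing and sum membership", {
  for (s in 1:3) {
    bcs <- place_bcs(domain = 60, min_spacing = 10, seed = s)
    d <- as.matrix(stats::dist(bcs[, c("azimuth", "elevation")]))
    diag(d) <- Inf
    expect_gte(min(d), 10)
  }
  cones <- tiny_cone_array(n = 30, domain = 10)
  bcs <- place_bcs(domain = 10, min_spacing = 10, seed = 2)
  act <- matrix(runif(50 * 30), 50, 30)
  pooled <- pool_bc(bcs, cones, act)
  mem <- attr(pooled, "membership")
  for (b in seq_len(nrow(bcs))) {
    manual <- if (length(mem[[b]]))
      rowSums(act[, mem[[b]], drop = FALSE]) else rep(0, 50)
    expect_equal(pooled[, b], manual)
    # membership is exactly the cones within the pooling radius
    d2 <- (cones$cones$azimuth - bcs$azimuth[b])^2 +
      (cones$cones$elevation - bcs$elevation[b])^2
    expect_equal(sort(mem[[b]]), which(d2 <= 100))
  }
  # a BC with exactly one pooled cone carries that cone's trace
  one <- cone_array(0, 0, domain = 10)
  bc1 <- place_bcs(domain = 10, min_spacing = 10, seed = 5)
  a1 <- matrix(runif(20), 20, 1)
  p1 <- pool_bc(bc1, one, a1)
  hit <- which(vapply(attr(p1, "membership"), length, 0L) == 1)
  for (b in hit) expect_equal(p1[, b], a1[, 1])
})

test_that("dark-target BC activation is more spatially uniform than bright", {
  arr <- make_cone_array(mosaic_config(), seed = 21)
  bcs <- place_bcs(domain = 60, min_spacing = 10, seed = 22)
  simb <- simulate_detector(arr, bright_target(), n_steps = 4000, seed = 23,
                            bcs = bcs)
  simd <- simulate_detector(arr, dark_target(), n_steps = 4000, seed = 23,
                            bcs = bcs)
  cv <- function(x) stats::sd(x) / mean(x)
  peak_b <- apply(simb$bc, 2, max)
  peak_d <- apply(simd$bc, 2, max)
  expect_lt(cv(peak_d), cv(peak_b))
})
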
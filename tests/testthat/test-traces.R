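test_that("z-normalization standardizes on the baseline window", {
  set.seed(20)
  x <- rnorm(1000, mean = 7, sd = 3)
  dt <- 1 / 62.5
  z <- znorm(x, dt)
  w <- z[(floor(1 / dt) + 1):floor(6 / dt)]
  expect_equal(mean(w), 0, tolerance = 1e-12)
  expect_equal(stats::sd(w), 1, tolerance = 1e-12)
  # affine invariance
  expect_equal(znorm(5 * x + 2, dt), z, tolerance = 1e-9)
  # hand-computed example on a coarse trace (window covers samples 2-6)
  y <- c(10, 1, 2, 3, 4, 5, 99)
  zy <- znorm(y, dt = 1, window = c(1, 6))
  m <- mean(1:5); s <- stats::sd(1:5)
  expect_equal(zy, (y - m) / s)
  expect_error(znorm(rep(1, 700), 0.01), "variance")
  expect_error(znorm(x, dt, window = c(1, 60)), "window")
})

test_that("the dark-light index is bounded, signed, and antisymmetric", {
  expect_equal(dli(1, 0), 1)
  expect_equal(dli(0, 1), -1)
  expect_equal(dli(3, 1), 0.5)
  set.seed(21)
  L <- runif(100); D <- runif(100)
  expect_true(all(abs(dli(L, D)) <= 1))
  expect_equal(dli(L, D), -dli(D, L))
  expect_warning(nd <- dli(0, 0), "undefined")
  expect_true(is.na(nd))
})

test_that("the amplitude mode finds the dominant response peak", {
  expect_equal(amplitude_mode(rep(2.5, 10)), 2.5)
  # symmetric unimodal: mode ~ mean within KDE bandwidth
  set.seed(22)
  x <- rnorm(500, mean = 4, sd = 0.5)
  expect_equal(amplitude_mode(x), 4, tolerance = 0.2)
  # bimodal with more mass at 10: dense-grid argmax oracle
  x2 <- c(rnorm(40, 1, 0.1), rnorm(120, 10, 0.1))
  d <- stats::density(x2, bw = "nrd0", n = 4096)
  expect_equal(amplitude_mode(x2), d$x[which.max(d$y)], tolerance = 0.05)
  expect_equal(amplitude_mode(x2), 10, tolerance = 0.3)
  expect_warning(md <- amplitude_mode(c(1, 2)), "median")
  expect_equal(md, 1.5)
})

test_that("baseline fraction spans the dynamic range and clips", {
  expect_equal(as.numeric(baseline_fraction(2, 10, 2)), 0)
  expect_equal(as.numeric(baseline_fraction(10, 10, 2)), 1)
  expect_equal(as.numeric(baseline_fraction(6, 10, 2)), 0.5)
  # monotone in baseline
  b <- seq(2, 10, by = 0.5)
  expect_true(all(diff(as.numeric(baseline_fraction(b, 10, 2))) > 0))
  # out-of-range input clipped and flagged
  f <- baseline_fraction(12, 10, 2)
  expect_equal(as.numeric(f), 1)
  expect_true(attr(f, "clipped"))
  expect_error(baseline_fraction(5, 2, 10), "exceed")
})

test_that("hill fits recover planted dose-response parameters", {
  I <- c(50, 100, 200, 400, 800, 1600, 3200, 6400)
  A <- hill_curve(I, a_max = 2, i_half = 300, h = 1.5)
  fit <- hill_fit(I, A)
  expect_equal(fit$a_max, 2, tolerance = 1e-6)
  expect_equal(fit$i_half, 300, tolerance = 1e-6)
  expect_equal(fit$h, 1.5, tolerance = 1e-6)
  expect_error(hill_fit(I, rep(0, 8)), "zero")
  expect_error(hill_fit(c(1, 2, 3), c(1, 2, 3)), "4 intensity")
  # Monte-Carlo recovery: 5% noise, 8 levels x 20 repeats, i_half within 10%
  set.seed(23)
  i_hats <- replicate(20, {
    An <- pmax(0, rep(A, each = 20) +
                 rnorm(8 * 20, sd = 0.05 * max(A)))
    hill_fit(rep(I, each = 20), An)$i_half
  })
  expect_equal(median(i_hats), 300, tolerance = 0.1)
  expect_lt(mean(abs(i_hats - 300) / 300 > 0.10), 0.3)
})

test_that("sensitivity index inverts the Hill curves at a common criterion", {
  I <- c(50, 100, 200, 400, 800, 1600, 3200, 6400)
  ref <- hill_fit(I, hill_curve(I, 2, 300, 1.5))
  expect_equal(sensitivity_index(ref, ref), 1.0, tolerance = 1e-9)
  # test curve with i_half 10x lower, same max and slope
  shifted <- hill_fit(I, hill_curve(I, 2, 30, 1.5))
  expect_equal(sensitivity_index(ref, shifted), 10, tolerance = 1e-6)
  # invariant to a common rescaling of both intensity axes
  ref2 <- hill_fit(I * 7, hill_curve(I * 7, 2, 2100, 1.5))
  shifted2 <- hill_fit(I * 7, hill_curve(I * 7, 2, 210, 1.5))
  expect_equal(sensitivity_index(ref2, shifted2), 10, tolerance = 1e-6)
  # criterion unreachable by a weak test curve
  weak <- hill_fit(I, hill_curve(I, 0.4, 300, 1.5))
  expect_error(sensitivity_index(ref, weak), "non-comparable")
})

test_that("recovery taus are recovered from flash decays", {
  fr <- make_flash_response_set(1000, a_max = 2, i_half = 300, tau = 0.5,
                                noise_sd = 0)
  rt <- recovery_tau(fr$traces[[1]][, 1], dt = 1 / 62.5)
  expect_equal(rt$tau, 0.5, tolerance = 1e-6)
  # amplitude scaling leaves tau unchanged
  rt2 <- recovery_tau(10 * fr$traces[[1]][, 1], dt = 1 / 62.5)
  expect_equal(rt2$tau, rt$tau, tolerance = 1e-9)
  # Monte-Carlo: tau = 1 s, 10% noise, 62.5 Hz, 10 s record, within 10%
  set.seed(24)
  taus <- replicate(20, {
    fr <- make_flash_response_set(1000, tau = 1, duration = 10,
                                  noise_sd = 0.1 * 2, seed = sample.int(1e6, 1))
    recovery_tau(fr$traces[[1]][, 1], dt = 1 / 62.5)$tau
  })
  expect_equal(median(taus), 1, tolerance = 0.1)
  # a non-decaying trace is an error
  expect_error(recovery_tau(seq(0, 1, length.out = 100), dt = 0.01),
               "decay|post-peak")
})

test_that("planted baseline fractions predict computed DLi across a population", {
  # synthetic population: cones with higher calcium baseline respond
  # relatively more to light; DLi computed from planted L/D amplitudes
  set.seed(25)
  n <- 60
  baseline <- runif(n, 0.05, 0.95)
  idx <- vapply(seq_len(n), function(i) {
    # per-cone trial amplitudes around the planted light/dark preference
    l_trials <- pmax(0, rnorm(7, mean = baseline[i], sd = 0.08))
    d_trials <- pmax(0, rnorm(7, mean = 1 - baseline[i], sd = 0.08))
    dli(amplitude_mode(l_trials), amplitude_mode(d_trials))
  }, 0)
  expect_gt(stats::cor(baseline, idx, method = "spearman"), 0.8)
})
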
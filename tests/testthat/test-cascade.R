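test_that("dark steady state is a fixed point and matches a bisection oracle", {
  p <- cascade_params()
  st <- dark_steady_state(p)
  expect_true(all(st[c("g", "ca", "cab")] > 0))
  # simulation launched from the steady state stays constant
  tr <- simulate_response(p, function(t) 0, t_end = 10, dt = 0.01)
  drift <- max(abs(tr$current - attr(tr, "dark_current"))) /
    attr(tr, "dark_current")
  expect_lt(drift, 1e-6)
  # independent bisection on the synthesis/hydrolysis balance
  jmaxf <- function(g) p$j_max * g^p$n_cg / (g^p$n_cg + p$k_cg^p$n_cg)
  resid <- function(g) {
    ca <- p$ca_min + p$q_ca * jmaxf(g) / p$gamma_ca
    p$alpha_max / (1 + (ca / p$k_gc)^p$n_gc) - p$beta_dark * g
  }
  lo <- 1e-9; hi <- 100
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (resid(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(unname(st["g"]), (lo + hi) / 2, tolerance = 1e-8)
  # halving CNG density at fixed cGMP halves the dark current
  p_half <- cascade_params(j_max = cascade_params()$j_max / 2)
  g_fix <- st[["g"]]
  j1 <- p$j_max * g_fix^p$n_cg / (g_fix^p$n_cg + p$k_cg^p$n_cg)
  j2 <- p_half$j_max * g_fix^p_half$n_cg / (g_fix^p_half$n_cg + p_half$k_cg^p_half$n_cg)
  expect_equal(j2, j1 / 2)
})

test_that("cascade responses behave across the stimulus range", {
  p <- cascade_params()
  # zero stimulus: flat trace at dark current
  tr0 <- simulate_response(p, rep(0, 200), dt = 0.01)
  expect_lt(diff(range(tr0$current)), 1e-6 * attr(tr0, "dark_current"))
  # saturating bright step: current approaches zero
  trs <- simulate_response(p, function(t) 1e6, t_end = 1, dt = 1e-3)
  expect_lt(min(trs$current) / attr(trs, "dark_current"), 1e-3)
  # state variables stay non-negative along solutions
  expect_true(all(as.matrix(trs[, c("R", "E", "g", "ca", "cab")]) > -1e-9))
  # flash amplitude is non-decreasing over a 5-decade strength sweep
  amps <- vapply(10^seq(0, 5), function(s) flash_response(p, s), 0)
  expect_true(all(diff(amps) > 0))
  expect_gt(amps[length(amps)], 0.99)  # saturates
  # negative stimulus rejected
  expect_error(simulate_response(p, c(-1, 0, 0)), "non-negative")
})

test_that("steady current decreases with steady background light", {
  p <- cascade_params()
  bgs <- c(0, 50, 500, 5000)
  j_end <- vapply(bgs, function(b) {
    tr <- simulate_response(p, function(t) b, t_end = 5, dt = 0.01)
    tail(tr$current, 1)
  }, 0)
  expect_true(all(diff(j_end) < 0))
})

test_that("expression scaling targets exactly the four tuned parameters", {
  base <- cascade_params()
  # identity scaling leaves everything untouched
  same <- scale_params_from_expression(base, expression_scaling())
  expect_equal(unclass(same), unclass(base))
  # the transducin ratio takes the lowest subunit value
  sc <- expression_scaling(transducin_subunits = c(0.8, 0.9, 0.7),
                           gc3 = 2, rec2 = 0.5, cnga3 = 0.6)
  expect_equal(sc$transducin, 0.7)
  scaled <- scale_params_from_expression(base, sc)
  expect_equal(scaled$nu_re, base$nu_re * 0.7)
  expect_equal(scaled$alpha_max, base$alpha_max * 2)
  expect_equal(scaled$w_rec, base$w_rec * 0.5)
  expect_equal(scaled$j_max, base$j_max * 0.6)
  changed <- names(base)[unlist(base) != unlist(scaled)]
  expect_setequal(changed, c("nu_re", "alpha_max", "w_rec", "j_max"))
  # composition of scalings equals scaling by the product
  sc2 <- expression_scaling(transducin_subunits = 0.5, gc3 = 1.5,
                            rec2 = 2, cnga3 = 0.5)
  ab <- scale_params_from_expression(scale_params_from_expression(base, sc), sc2)
  prod_sc <- expression_scaling(transducin_subunits = 0.7 * 0.5,
                                gc3 = 2 * 1.5, rec2 = 0.5 * 2,
                                cnga3 = 0.6 * 0.5)
  expect_equal(unclass(ab),
               unclass(scale_params_from_expression(base, prod_sc)),
               tolerance = 1e-12)
  expect_error(expression_scaling(gc3 = -1), "positive")
})

test_that("flash gain analysis recovers known gain shifts", {
  p <- cascade_params()
  res <- flash_gain_analysis(p, p)
  expect_equal(res$gain_ratio, 1.0, tolerance = 1e-6)
  # 10x transducin gain in the linear regime shifts sensitivity ~10-fold
  p10 <- cascade_params(nu_re = cascade_params()$nu_re * 10)
  res10 <- flash_gain_analysis(p, p10)
  expect_equal(res10$gain_ratio, 10, tolerance = 0.15)
})

test_that("SZ-style scaling elevates baseline and light-biases the response", {
  p <- cascade_params()
  sz <- scale_params_from_expression(p, example_sz_scaling())
  # elevated dark/baseline current (higher constitutive calcium baseline)
  expect_gt(attr(dark_steady_state(sz), "dark_current"),
            attr(dark_steady_state(p), "dark_current"))
  # contrast steps from a 50%-contrast background
  step_resp <- function(pp, bg = 500) {
    stim <- function(t) ifelse(t < 2, bg,
                        ifelse(t < 3, 2 * bg,
                        ifelse(t < 4, bg, ifelse(t < 5, 0, bg))))
    tr <- simulate_response(pp, stim, t_end = 6, dt = 5e-3)
    j_bg <- tr$current[max(which(tr$time < 2))]
    j_dark <- attr(dark_steady_state(pp), "dark_current")
    # amplitudes expressed relative to each cone's own dark current
    c(light = (j_bg - min(tr$current[tr$time >= 2 & tr$time < 3])) / j_dark,
      dark = (max(tr$current[tr$time >= 4 & tr$time < 5]) - j_bg) / j_dark)
  }
  r0 <- step_resp(p)
  rz <- step_resp(sz)
  expect_gt(rz["light"], r0["light"])  # bright-step response grows
  expect_lt(rz["dark"], r0["dark"])    # dark-step response shrinks
})
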
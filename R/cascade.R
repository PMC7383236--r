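#' Phototransduction cascade parameters
#'
#' Rate constants and concentrations of a deterministic, well-stirred model
#' of the vertebrate ciliary-photoreceptor phototransduction cascade:
#' photoactivated opsin drives transducin/PDE activation, activated PDE
#' hydrolyzes cGMP, cGMP gates the CNG current, a fraction of which carries
#' calcium; calcium feeds back on cGMP synthesis (guanylate cyclase via
#' GCAPs) and on opsin shutoff (via recoverin inhibition of opsin kinase),
#' and is cleared by exchanger extrusion and cytoplasmic buffering.
#'
#' The state variables are activated opsin `R` (a.u.), activated effector
#' `E` (transducin-PDE, a.u.), cGMP `g` (uM), free calcium `ca` (uM) and
#' buffered calcium `cab` (uM); the output is the CNG current `J` (pA,
#' dark current positive).
#'
#' Defaults are self-consistent order-of-magnitude cone values (dark state
#' near cGMP 3 uM, Ca 0.4 uM, dark current ~27 pA); every parameter is
#' exposed and serializable to JSON.
#'
#' @param phi_gain Photoisomerization gain (R* per unit stimulus).
#' @param k_r0 Maximal opsin shutoff rate, 1/s (opsin kinase + arrestin).
#' @param w_rec Recoverin weight: shutoff is slowed by factor
#'   `1 + w_rec * ca/(ca + k_rec)`; scales with recoverin concentration.
#' @param k_rec Recoverin Ca half-point, uM.
#' @param nu_re Transducin/PDE activation gain, E* per R* per s; scales
#'   with transducin level.
#' @param k_e Effector shutoff rate, 1/s (transducin GTPase / PDE decay).
#' @param beta_dark Dark cGMP hydrolysis rate, 1/s.
#' @param beta_e Hydrolysis rate per unit activated effector, 1/s per E*.
#' @param alpha_max Maximal cGMP synthesis rate, uM/s (guanylate cyclase);
#'   scales with GC level.
#' @param k_gc GCAP calcium half-point, uM.
#' @param n_gc GCAP Hill coefficient.
#' @param j_max Maximal CNG current, pA; scales with channel density.
#' @param k_cg CNG cGMP half-point, uM.
#' @param n_cg CNG Hill coefficient (cooperativity).
#' @param q_ca Calcium influx per unit current, uM/s per pA (includes the
#'   fraction of CNG current carried by Ca).
#' @param gamma_ca Calcium extrusion rate, 1/s.
#' @param ca_min Extrusion floor (minimal free Ca), uM.
#' @param b_tot Cytoplasmic buffer capacity, uM.
#' @param k_on,k_off Buffer binding/unbinding rates (1/(uM s), 1/s).
#' @return A `cascade_params` object.
#' @export
cascade_params <- function(phi_gain = 1, k_r0 = 30, w_rec = 1, k_rec = 0.3,
                           nu_re = 300, k_e = 15, beta_dark = 10,
                           beta_e = 0.1, alpha_max = 60, k_gc = 0.4,
                           n_gc = 2, j_max = 8000, k_cg = 20, n_cg = 3,
                           q_ca = 0.72, gamma_ca = 50, ca_min = 0.01,
                           b_tot = 50, k_on = 20, k_off = 20) {
  p <- list(phi_gain = phi_gain, k_r0 = k_r0, w_rec = w_rec, k_rec = k_rec,
            nu_re = nu_re, k_e = k_e, beta_dark = beta_dark, beta_e = beta_e,
            alpha_max = alpha_max, k_gc = k_gc, n_gc = n_gc, j_max = j_max,
            k_cg = k_cg, n_cg = n_cg, q_ca = q_ca, gamma_ca = gamma_ca,
            ca_min = ca_min, b_tot = b_tot, k_on = k_on, k_off = k_off)
  bad <- names(p)[vapply(p, function(v) !is.numeric(v) || length(v) != 1 ||
                           !is.finite(v) || v <= 0, TRUE)]
  bad <- setdiff(bad, "ca_min")  # ca_min may be small but must be >= 0
  if (p$ca_min < 0) bad <- c(bad, "ca_min")
  if (length(bad))
    stop("cascade parameters must be positive numbers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(p, class = "cascade_params")
}

#' @export
print.cascade_params <- function(x, ...) {
  cat("<cascade_params>\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v)), " = ", signif(v, 4), collapse = "\n"),
      "\n")
  invisible(x)
}

## internal: CNG current and cyclase rate
cng_current <- function(g, p) p$j_max * g^p$n_cg / (g^p$n_cg + p$k_cg^p$n_cg)
gc_rate <- function(ca, p) p$alpha_max / (1 + (ca / p$k_gc)^p$n_gc)
opsin_shutoff <- function(ca, p) p$k_r0 / (1 + p$w_rec * ca / (ca + p$k_rec))

cascade_deriv <- function(t, y, p, stim_fun) {
  R <- y[1]; E <- y[2]; g <- y[3]; ca <- y[4]; cab <- y[5]
  phi <- stim_fun(t)
  J <- cng_current(g, p)
  buf <- p$k_on * ca * (p$b_tot - cab) - p$k_off * cab
  list(c(
    p$phi_gain * phi - opsin_shutoff(ca, p) * R,
    p$nu_re * R - p$k_e * E,
    gc_rate(ca, p) - (p$beta_dark + p$beta_e * E) * g,
    p$q_ca * J - p$gamma_ca * (ca - p$ca_min) - buf,
    buf))
}

#' Dark-adapted steady state of the cascade
#'
#' In darkness activated opsin and effector vanish exactly, which reduces
#' the fixed point to a one-dimensional balance in cGMP: synthesis
#' `alpha(ca(g))` equals hydrolysis `beta_dark * g`, with `ca(g)` given by
#' the calcium influx/extrusion balance at the corresponding CNG current.
#' The root is bracketed and solved with [stats::uniroot()]; the returned
#' state is a fixed point of the full ODE (a simulation launched from it
#' stays constant).
#'
#' @param params A [cascade_params()].
#' @param tol Root tolerance on cGMP, uM.
#' @return A named state vector `c(R, E, g, ca, cab)` with attribute
#'   `dark_current` (pA).
#' @export
dark_steady_state <- function(params, tol = 1e-10) {
  stopifnot(inherits(params, "cascade_params"))
  p <- params
  ca_of_g <- function(g) p$ca_min + p$q_ca * cng_current(g, p) / p$gamma_ca
  resid <- function(g) gc_rate(ca_of_g(g), p) - p$beta_dark * g
  upper <- p$alpha_max / p$beta_dark + p$k_cg  # synthesis can never exceed alpha_max
  if (resid(1e-9) <= 0 || resid(upper) >= 0)
    stop("no positive dark steady state for these parameters", call. = FALSE)
  g <- stats::uniroot(resid, c(1e-9, upper), tol = tol)$root
  ca <- ca_of_g(g)
  cab <- p$b_tot * ca / (ca + p$k_off / p$k_on)
  st <- c(R = 0, E = 0, g = g, ca = ca, cab = cab)
  attr(st, "dark_current") <- cng_current(g, p)
  st
}

#' Simulate the cascade current response to a light stimulus
#'
#' Integrates the cascade ODE from the dark (or a supplied) steady state
#' under a non-negative photon-rate time course, with stiff adaptive-step
#' integration (`deSolve::lsoda`, relative tolerance 1e-8). The output is
#' the CNG current over time (dark current positive).
#'
#' @param params A [cascade_params()].
#' @param stimulus Either a function of time (seconds) returning the photon
#'   rate, or a numeric vector sampled at `dt` (zero-order hold).
#' @param t_end Simulation end time, seconds (defaults to cover a vector
#'   stimulus).
#' @param dt Output sample interval, seconds.
#' @param state0 Initial state; defaults to [dark_steady_state()].
#' @param rtol,atol Solver tolerances.
#' @param hmax Maximal internal solver step, seconds; bound it below the
#'   duration of any brief stimulus feature so the solver cannot step over
#'   it.
#' @return A data.frame `time`, `current` (pA), plus the state variables;
#'   attribute `dark_current`.
#' @export
simulate_response <- function(params, stimulus, t_end = NULL, dt = 1e-3,
                              state0 = NULL, rtol = 1e-8, atol = 1e-10,
                              hmax = NULL) {
  stopifnot(inherits(params, "cascade_params"))
  if (is.numeric(stimulus)) {
    sv <- stimulus
    if (any(sv < 0)) stop("stimulus must be non-negative", call. = FALSE)
    if (is.null(t_end)) t_end <- length(sv) * dt
    stim_fun <- function(t) {
      i <- pmin(length(sv), pmax(1L, floor(t / dt) + 1L))
      sv[i]
    }
  } else if (is.function(stimulus)) {
    if (is.null(t_end)) stop("`t_end` required with a function stimulus",
                             call. = FALSE)
    stim_fun <- stimulus
  } else stop("`stimulus` must be a function or numeric vector", call. = FALSE)
  if (is.null(state0)) state0 <- dark_steady_state(params)
  times <- seq(0, t_end, by = dt)
  y0 <- as.numeric(state0)[1:5]
  names(y0) <- c("R", "E", "g", "ca", "cab")
  sol <- deSolve::lsoda(y = y0, times = times,
                        func = cascade_deriv, parms = params,
                        stim_fun = stim_fun, rtol = rtol, atol = atol,
                        hmax = if (is.null(hmax)) dt else hmax)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed to converge; istate = ",
         attr(sol, "istate")[1], call. = FALSE)
  out <- as.data.frame(sol)
  names(out) <- c("time", "R", "E", "g", "ca", "cab")
  out$current <- cng_current(out$g, params)
  attr(out, "dark_current") <- cng_current(dark_steady_state(params)[["g"]],
                                           params)
  out
}

#' Peak fractional response to a brief flash
#'
#' Runs a square flash of given duration and strength from darkness and
#' returns the peak fractional suppression of the dark current.
#'
#' @param params A [cascade_params()].
#' @param strength Photon rate during the flash (a.u. photons/s).
#' @param flash_dur Flash duration, seconds (default 5 ms).
#' @param t_end Simulated time, seconds.
#' @param dt Output step, seconds.
#' @return Peak suppression in `[0, 1]`.
#' @export
flash_response <- function(params, strength, flash_dur = 0.005, t_end = 1.5,
                           dt = 1e-3) {
  stim <- function(t) ifelse(t >= 0.02 & t < 0.02 + flash_dur, strength, 0)
  tr <- simulate_response(params, stim, t_end = t_end, dt = dt,
                          hmax = flash_dur / 2)
  j0 <- attr(tr, "dark_current")
  max(0, (j0 - min(tr$current)) / j0)
}

#' Flash-strength gain comparison between two parameter sets
#'
#' Runs a series of 5-ms flashes of increasing strength from darkness for
#' both parameter sets, fits a Hill curve to peak amplitude versus flash
#' strength, and reports the fold difference in the flash strength at which
#' each curve reaches a common criterion amplitude: half the maximal
#' response of the reference set `params_a` (see [sensitivity_index()]).
#' A ratio > 1 means `params_b` reaches the criterion at lower strengths,
#' i.e. has higher gain.
#'
#' @param params_a Reference [cascade_params()].
#' @param params_b Test [cascade_params()].
#' @param flash_strengths Increasing flash strengths (>= 6 values spanning
#'   threshold to saturation).
#' @param flash_dur Flash duration, seconds.
#' @return List: `gain_ratio`, `fit_a`, `fit_b` ([hill_fit()] objects),
#'   `amplitudes` (data.frame), `extrapolated` flag (TRUE when the sweep
#'   did not saturate; a warning is raised).
#' @export
flash_gain_analysis <- function(params_a, params_b,
                                flash_strengths = 10^seq(0, 5, length.out = 9),
                                flash_dur = 0.005) {
  if (length(flash_strengths) < 6)
    stop("need at least 6 flash strengths", call. = FALSE)
  amp_a <- vapply(flash_strengths, function(s)
    flash_response(params_a, s, flash_dur), 0)
  amp_b <- vapply(flash_strengths, function(s)
    flash_response(params_b, s, flash_dur), 0)
  extrapolated <- FALSE
  for (a in list(amp_a, amp_b)) {
    if (max(a) < 0.8 || a[length(a)] < 0.95 * max(a)) {
      extrapolated <- TRUE
    }
  }
  if (extrapolated)
    warning("flash sweep does not clearly saturate; criterion crossing may be extrapolated")
  fit_a <- hill_fit(flash_strengths, amp_a)
  fit_b <- hill_fit(flash_strengths, amp_b)
  list(gain_ratio = sensitivity_index(fit_a, fit_b),
       fit_a = fit_a, fit_b = fit_b,
       amplitudes = data.frame(strength = flash_strengths, a = amp_a,
                               b = amp_b),
       extrapolated = extrapolated)
}
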
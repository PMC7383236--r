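#' Moving-target specification
#'
#' Geometry and kinematics of the random-walk target used in the detector
#' simulation: a bright 2 deg-diameter spot mimicking a paramecium (radius
#' 1 deg) or a dark 5 deg spot mimicking a small/distant predator (radius
#' 2.5 deg), moving at constant 100 deg/s in 1 deg steps with heading
#' changes bounded by +/-15 deg per step.
#'
#' @param radius Target radius in degrees.
#' @param polarity `"bright"` or `"dark"`.
#' @param speed Speed in degrees per second.
#' @param step Step size in degrees; `dt = step / speed`.
#' @param turn_limit Per-step heading-change bound, degrees.
#' @return A `target_spec` list.
#' @export
target_spec <- function(radius = 1.0,
                        polarity = c("bright", "dark"),
                        speed = 100, step = 1, turn_limit = 15) {
  polarity <- match.arg(polarity)
  if (!is.numeric(radius) || radius <= 0)
    stop("`radius` must be positive", call. = FALSE)
  if (!is.numeric(speed) || speed <= 0)
    stop("`speed` must be positive", call. = FALSE)
  if (turn_limit <= 0 || turn_limit >= 180)
    stop("`turn_limit` must lie in (0, 180)", call. = FALSE)
  structure(list(radius = radius, polarity = polarity, speed = speed,
                 step = step, turn_limit = turn_limit, dt = step / speed),
            class = "target_spec")
}

#' Canonical bright (2 deg) and dark (5 deg) targets
#' @rdname target_spec
#' @export
bright_target <- function() target_spec(radius = 1.0, polarity = "bright")

#' @rdname target_spec
#' @export
dark_target <- function() target_spec(radius = 2.5, polarity = "dark")

#' Random-walk target trajectory on the toroidal crop
#'
#' Advances the target one `spec$step` per iteration (10 ms at the default
#' 100 deg/s and 1 deg steps) with a heading change drawn uniformly within
#' `+/- spec$turn_limit`; the square +/-`domain` crop wraps left/right and
#' top/bottom (canonical torus), so step length is conserved across
#' boundaries.
#'
#' @param spec A [target_spec()].
#' @param n_steps Number of steps (>= 1).
#' @param domain Crop half-width in degrees.
#' @param seed Integer seed.
#' @param start Optional c(azimuth, elevation) start; default random.
#' @return A `trajectory`: data.frame (`azimuth`, `elevation`, `heading`)
#'   with attributes `dt`, `domain`, `spec`.
#' @export
generate_trajectory <- function(spec = bright_target(), n_steps, domain = 60,
                                seed = 1, start = NULL) {
  stopifnot(inherits(spec, "target_spec"))
  if (n_steps < 1) stop("`n_steps` must be >= 1", call. = FALSE)
  set.seed(seed)
  if (is.null(start)) start <- runif(2, -domain, domain)
  heading <- runif(1, -180, 180) +
    cumsum(c(0, runif(n_steps - 1, -spec$turn_limit, spec$turn_limit)))
  dx <- spec$step * cos(heading * pi / 180)
  dy <- spec$step * sin(heading * pi / 180)
  wrap <- function(z) ((z + domain) %% (2 * domain)) - domain
  az <- wrap(start[1] + cumsum(dx))
  el <- wrap(start[2] + cumsum(dy))
  out <- data.frame(azimuth = az, elevation = el, heading = heading)
  attr(out, "dt") <- spec$dt
  attr(out, "domain") <- domain
  attr(out, "spec") <- spec
  class(out) <- c("trajectory", "data.frame")
  out
}

## internal: toroidal distance matrix (steps x cones), chunk-friendly
torus_dist2 <- function(tx, ty, cx, cy, domain) {
  w <- 2 * domain
  ddx <- abs(outer(tx, cx, "-")); ddx <- pmin(ddx, w - ddx)
  ddy <- abs(outer(ty, cy, "-")); ddy <- pmin(ddy, w - ddy)
  ddx^2 + ddy^2
}

#' Per-step cone coverage by a moving target
#'
#' A cone is covered at a time step when the distance between the target
#' center and the cone center is smaller than the target radius plus the
#' cone's receptive-field radius. Distances are toroidal, matching the
#' trajectory wraparound.
#'
#' @param traj A [generate_trajectory()] result.
#' @param cones A [cone_array()]; an empty array yields all-zero counts.
#' @param target_radius Target radius in degrees; defaults to the radius of
#'   the spec the trajectory was generated with.
#' @param events If `TRUE` (default) also return the (step, cone) coverage
#'   events, from which per-cone binary activation series are built.
#' @param chunk Steps per distance-matrix block (memory control).
#' @return A `coverage` object: list with `counts` (integer per step),
#'   `events` (data.frame step/cone or NULL), `n_cones`, `dt`.
#' @export
coverage_series <- function(traj, cones,
                            target_radius = attr(traj, "spec")$radius,
                            events = TRUE, chunk = 2000L) {
  stopifnot(inherits(traj, "trajectory"), inherits(cones, "cone_array"))
  n <- nrow(traj)
  nc <- nrow(cones$cones)
  counts <- integer(n)
  ev <- if (events) vector("list", ceiling(n / chunk)) else NULL
  if (nc > 0) {
    thr2 <- (target_radius + cones$cones$rf_radius)^2  # per-cone threshold
    dom <- attr(traj, "domain")
    bi <- 0L
    for (s0 in seq(1L, n, by = chunk)) {
      s1 <- min(n, s0 + chunk - 1L)
      d2 <- torus_dist2(traj$azimuth[s0:s1], traj$elevation[s0:s1],
                        cones$cones$azimuth, cones$cones$elevation, dom)
      hit <- sweep(d2, 2L, thr2, "<")
      counts[s0:s1] <- rowSums(hit)
      if (events) {
        bi <- bi + 1L
        w <- which(hit, arr.ind = TRUE)
        if (nrow(w))
          ev[[bi]] <- data.frame(step = w[, 1] + s0 - 1L, cone = w[, 2])
      }
    }
  }
  structure(list(counts = counts,
                 events = if (events) {
                   e <- do.call(rbind, ev)
                   if (is.null(e)) data.frame(step = integer(0), cone = integer(0)) else e
                 } else NULL,
                 n_cones = nc, dt = attr(traj, "dt")),
            class = "coverage")
}

#' Binary activation series for one cone
#'
#' @param cov A [coverage_series()] result (with events).
#' @param cone Cone index.
#' @return Integer 0/1 vector over steps.
#' @export
activation_series <- function(cov, cone) {
  stopifnot(inherits(cov, "coverage"), !is.null(cov$events))
  out <- integer(length(cov$counts))
  out[cov$events$step[cov$events$cone == cone]] <- 1L
  out
}

#' Coverage-count summary statistics
#'
#' Fraction of time steps on which the target covers zero, exactly one, or
#' two-or-more cones.
#'
#' @param counts Integer vector of per-step cone counts (or a `coverage`).
#' @return Named numeric vector `c(zero=, one=, two_plus=)`; sums to 1.
#' @export
coverage_statistics <- function(counts) {
  if (inherits(counts, "coverage")) counts <- counts$counts
  if (!length(counts)) stop("empty coverage series", call. = FALSE)
  c(zero = mean(counts == 0), one = mean(counts == 1),
    two_plus = mean(counts >= 2))
}

## ---- zone kinetics and impulse responses --------------------------------

#' Zone-resolved impulse-response kinetics
#'
#' Peak amplitudes and single-exponential recovery time constants of the
#' cone impulse response for the four reference regions (dorsal, nasal =
#' horizon, ventral, and strike zone), separately for responses to the
#' bright and dark target. The shipped defaults are order-of-magnitude
#' values consistent with the imaging phenotype (SZ strongly light-biased
#' with slow light recovery; dorsal/nasal dark-biased); they are
#' user-overridable since no numeric table is published.
#'
#' @param path Optional JSON file (as in
#'   `system.file("extdata/zone_kinetics_default.json", package = "strikezone")`).
#' @return A `zone_kinetics` object: named list of zones, each with
#'   `amplitude_light`, `amplitude_dark`, `tau_light`, `tau_dark`.
#' @export
zone_kinetics <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "zone_kinetics_default.json",
                        package = "strikezone")
  zk <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (z in names(zk)) {
    if (any(unlist(zk[[z]][c("tau_light", "tau_dark")]) <= 0))
      stop("zone taus must be positive", call. = FALSE)
    if (any(unlist(zk[[z]][c("amplitude_light", "amplitude_dark")]) < 0))
      stop("zone amplitudes must be >= 0", call. = FALSE)
  }
  structure(zk, class = "zone_kinetics")
}

#' Positional mixing weights over the four reference zones
#'
#' Along the dorsal-ventral axis a cone's kinetics are interpolated between
#' the horizon (nasal) measurement and the dorsal or ventral edge value in
#' proportion to its relative elevation; e.g. a cone 75% of the way from
#' horizon to the dorsal edge weights dorsal:nasal:ventral = 0.75:0.25:0.
#' Cones within `sz_radius` of the SZ center are additionally blended
#' toward the SZ values with weight `1 - d/sz_radius` (linear distance
#' weighting).
#'
#' @param azimuth,elevation Cone position, degrees.
#' @param sz_center SZ center, degrees.
#' @param sz_radius SZ influence radius, degrees.
#' @param domain Crop half-width (sets the dorsal/ventral edge), degrees.
#' @return Named weight vector over `c(dorsal, nasal, ventral, sz)`,
#'   non-negative, summing to 1.
#' @export
zone_weights <- function(azimuth, elevation, sz_center = c(-30, -30),
                         sz_radius = 30, domain = 60) {
  f <- pmin(1, abs(elevation) / domain)  # fraction toward the nearer edge
  if (elevation >= 0) w <- c(dorsal = f, nasal = 1 - f, ventral = 0)
  else w <- c(dorsal = 0, nasal = 1 - f, ventral = f)
  d <- sqrt(sum((c(azimuth, elevation) - sz_center)^2))
  wsz <- if (d < sz_radius) 1 - d / sz_radius else 0
  out <- c(w * (1 - wsz), sz = wsz)
  out / sum(out)
}

#' Impulse response assigned to a cone position
#'
#' Instantaneous rise to the position-weighted peak amplitude followed by a
#' single-exponential decay with the position-weighted time constant,
#' sampled at `dt`.
#'
#' @param azimuth,elevation Cone position, degrees.
#' @param kinetics A [zone_kinetics()] table.
#' @param polarity `"bright"` (light response) or `"dark"`.
#' @param dt Sample interval, seconds.
#' @param duration Kernel length, seconds.
#' @inheritParams zone_weights
#' @return Numeric impulse-response vector with attribute `dt`.
#' @export
impulse_response <- function(azimuth, elevation, kinetics = zone_kinetics(),
                             polarity = c("bright", "dark"), dt = 0.01,
                             duration = 3, sz_center = c(-30, -30),
                             sz_radius = 30, domain = 60) {
  polarity <- match.arg(polarity)
  w <- zone_weights(azimuth, elevation, sz_center, sz_radius, domain)
  fld <- if (polarity == "bright") c("amplitude_light", "tau_light")
         else c("amplitude_dark", "tau_dark")
  zn <- c(dorsal = "dorsal", nasal = "nasal", ventral = "ventral", sz = "sz")
  amp <- sum(vapply(names(zn), function(z) w[[z]] * kinetics[[zn[[z]]]][[fld[1]]], 0))
  tau <- sum(vapply(names(zn), function(z) w[[z]] * kinetics[[zn[[z]]]][[fld[2]]], 0))
  t <- seq(0, duration, by = dt)
  ir <- amp * exp(-t / tau)
  attr(ir, "dt") <- dt
  ir
}

#' Convolve a binary activation series with an impulse response
#'
#' Causal discrete linear convolution: a single active step reproduces the
#' impulse response; overlapping activations superpose linearly. Output has
#' the length of the input series.
#'
#' @param series Numeric/binary activation series.
#' @param ir Impulse response (from [impulse_response()] or any numeric
#'   vector); if both carry a `dt` attribute they must match.
#' @return Activation trace, same length as `series`.
#' @export
convolve_activation <- function(series, ir) {
  dts <- attr(series, "dt"); dti <- attr(ir, "dt")
  if (!is.null(dts) && !is.null(dti) && abs(dts - dti) > 1e-12)
    stop("sample intervals of series and impulse response differ",
         call. = FALSE)
  n <- length(series)
  full <- stats::convolve(as.numeric(series), rev(as.numeric(ir)),
                          type = "open")
  full[seq_len(n)]
}

#' Normalize activation traces to the array-wide peak
#'
#' Divides all traces by the maximum activation across the whole array and
#' all time points, so the array peak equals 1. An all-zero input is
#' returned unchanged with attribute `all_zero = TRUE` and a warning.
#'
#' @param activations Numeric matrix (time x cones) or vector.
#' @return Normalized activations (attribute `all_zero` flags degenerate
#'   input).
#' @export
normalize_array <- function(activations) {
  m <- max(activations)
  if (m == 0) {
    warning("all activations are zero; returned unchanged")
    attr(activations, "all_zero") <- TRUE
    return(activations)
  }
  out <- activations / m
  attr(out, "all_zero") <- FALSE
  out
}

## ---- bipolar cells -------------------------------------------------------

#' Place model bipolar cells by dart throwing
#'
#' Bipolar cells (BCs) are placed uniformly at random on the crop subject
#' to a hard minimum pairwise spacing (rejection / dart throwing), matching
#' "randomly spaced at a minimum radius". Each BC pools all cones within
#' `pool_radius` (same value as the spacing by default).
#'
#' @param domain Crop half-width, degrees.
#' @param min_spacing Minimum pairwise BC distance, degrees.
#' @param seed Integer seed.
#' @param max_attempts Dart-throwing attempts before giving up.
#' @return A `bc_array`: data.frame of positions with attributes
#'   `pool_radius`, `domain`. Zero rows (with a warning) if the domain
#'   cannot host a single BC.
#' @export
place_bcs <- function(domain = 60, min_spacing = 10, seed = 1,
                      max_attempts = 5000L) {
  if (min_spacing <= 0) stop("`min_spacing` must be positive", call. = FALSE)
  set.seed(seed)
  if (2 * domain <= 0) {
    warning("domain too small for any BC")
    pos <- data.frame(azimuth = numeric(0), elevation = numeric(0))
  } else {
    az <- el <- numeric(0)
    for (i in seq_len(max_attempts)) {
      p <- runif(2, -domain, domain)
      if (!length(az) || min((az - p[1])^2 + (el - p[2])^2) >= min_spacing^2) {
        az <- c(az, p[1]); el <- c(el, p[2])
      }
    }
    pos <- data.frame(azimuth = az, elevation = el)
  }
  structure(pos, pool_radius = min_spacing, domain = domain,
            class = c("bc_array", "data.frame"))
}

#' Pool cone activation traces into bipolar-cell traces
#'
#' Each BC trace is the plain sum of the activation traces of all cones
#' whose centers lie within the BC's pooling radius (planar distance on the
#' crop).
#'
#' @param bcs A [place_bcs()] array.
#' @param cones A [cone_array()].
#' @param activations Matrix (time x cones) of cone activation traces.
#' @return Matrix (time x BCs); attribute `membership` lists pooled cone
#'   indices per BC.
#' @export
pool_bc <- function(bcs, cones, activations) {
  stopifnot(inherits(bcs, "bc_array"), inherits(cones, "cone_array"))
  activations <- as.matrix(activations)
  if (ncol(activations) != nrow(cones$cones))
    stop("`activations` must have one column per cone", call. = FALSE)
  r2 <- attr(bcs, "pool_radius")^2
  out <- matrix(0, nrow(activations), nrow(bcs))
  membership <- vector("list", nrow(bcs))
  for (b in seq_len(nrow(bcs))) {
    d2 <- (cones$cones$azimuth - bcs$azimuth[b])^2 +
      (cones$cones$elevation - bcs$elevation[b])^2
    idx <- which(d2 <= r2)
    membership[[b]] <- idx
    if (length(idx))
      out[, b] <- rowSums(activations[, idx, drop = FALSE])
  }
  attr(out, "membership") <- membership
  out
}

#' Run the full detector-array simulation
#'
#' Convenience wrapper: random-walk trajectory, per-cone binary coverage,
#' convolution with position-dependent impulse responses, array-wide
#' normalization, and BC pooling.
#'
#' @param cones A [cone_array()].
#' @param spec A [target_spec()].
#' @param n_steps Number of trajectory steps.
#' @param kinetics A [zone_kinetics()] table.
#' @param seed Integer seed (trajectory and BC placement derive from it).
#' @param bcs Optional precomputed [place_bcs()] array.
#' @return List: `trajectory`, `coverage`, `activations` (time x cones,
#'   normalized), `bc` (time x BCs), `bcs`, `stats`
#'   (coverage fractions).
#' @export
simulate_detector <- function(cones, spec = bright_target(), n_steps = 5000,
                              kinetics = zone_kinetics(), seed = 1,
                              bcs = NULL) {
  traj <- generate_trajectory(spec, n_steps, domain = cones$domain, seed = seed)
  cov <- coverage_series(traj, cones)
  nc <- nrow(cones$cones)
  act <- matrix(0, n_steps, nc)
  active <- sort(unique(cov$events$cone))
  for (ci in active) {
    ir <- impulse_response(cones$cones$azimuth[ci], cones$cones$elevation[ci],
                           kinetics, polarity = spec$polarity, dt = spec$dt,
                           domain = cones$domain)
    act[, ci] <- convolve_activation(activation_series(cov, ci), ir)
  }
  act <- normalize_array(act)
  if (is.null(bcs)) bcs <- place_bcs(domain = cones$domain, seed = seed + 1L)
  bc <- pool_bc(bcs, cones, act)
  list(trajectory = traj, coverage = cov, activations = act, bc = bc,
       bcs = bcs, stats = coverage_statistics(cov))
}
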
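#' Cone detector array on the visual-field crop
#'
#' Positions of cone receptive-field centers in visual-field coordinates
#' (azimuth, elevation, degrees) within a square crop, together with the
#' receptive-field radius and a cone-type tag. This is the sampling lattice
#' for all detector simulations.
#'
#' @param azimuth,elevation Cone positions in degrees.
#' @param rf_radius Receptive-field radius in degrees (default 0.38, i.e.
#'   the ~0.76 deg UV-cone receptive-field diameter).
#' @param type Cone type tag, `"UV"` or other; recycled.
#' @param domain Half-width of the square crop in degrees.
#' @return A `cone_array` object (data.frame-backed).
#' @export
cone_array <- function(azimuth, elevation, rf_radius = 0.38, type = "UV",
                       domain = 60) {
  stopifnot(length(azimuth) == length(elevation))
  if (any(rf_radius <= 0)) stop("`rf_radius` must be positive", call. = FALSE)
  n <- length(azimuth)
  if (n > 0 && (any(abs(azimuth) > domain + 1e-9) ||
                any(abs(elevation) > domain + 1e-9)))
    stop("cone positions outside the +/-", domain, " deg domain", call. = FALSE)
  df <- data.frame(azimuth = as.numeric(azimuth),
                   elevation = as.numeric(elevation),
                   rf_radius = rep_len(rf_radius, n),
                   type = rep_len(type, n))
  structure(list(cones = df, domain = domain), class = "cone_array")
}

#' @export
print.cone_array <- function(x, ...) {
  cat(sprintf("<cone_array> %d cones on +/-%g deg, rf radius %s deg\n",
              nrow(x$cones), x$domain,
              paste(unique(signif(x$cones$rf_radius, 3)), collapse = "/")))
  invisible(x)
}

#' @export
length.cone_array <- function(x) nrow(x$cones)

#' Mosaic generator configuration
#'
#' Parameters of the synthetic UV-cone density field: a uniform background
#' plus a Gaussian acute-zone ("strike zone", SZ) elevation. Defaults follow
#' the study organism: peak density 0.19 cones per square degree at the SZ
#' center (-30, -30) with a 3-fold elevation over background, on a +/-60 deg
#' crop of the visual field. The whole eye carries roughly 2,400 UV cones
#' over its full ~169 deg monocular field; the crop therefore holds the
#' subset implied by integrating the density field (about 1,100 cones at the
#' defaults), unless `total_cones` is forced.
#'
#' @param total_cones Number of cones to draw; `NULL` (default) derives the
#'   count from the integral of the density field.
#' @param domain Half-width of the square crop, degrees.
#' @param peak_density Peak (SZ-center) density, cones per square degree.
#' @param elevation_factor Fold-elevation of the SZ peak over background.
#' @param sz_center SZ center, c(azimuth, elevation) degrees.
#' @param sz_sigma Gaussian width (s.d.) of the SZ elevation, degrees.
#' @param ventral_factor Optional ventral density elevation (1 = none).
#' @param min_spacing Hard-core minimum inter-cone distance, degrees
#'   (0 disables thinning).
#' @param rf_radius Receptive-field radius assigned to every cone, degrees.
#' @return A `mosaic_config` list.
#' @export
mosaic_config <- function(total_cones = NULL, domain = 60,
                          peak_density = 0.19, elevation_factor = 3,
                          sz_center = c(-30, -30), sz_sigma = 15,
                          ventral_factor = 1, min_spacing = 1.4,
                          rf_radius = 0.38) {
  stopifnot(peak_density > 0, elevation_factor >= 1, sz_sigma > 0,
            domain > 0, min_spacing >= 0, ventral_factor >= 1)
  structure(list(total_cones = total_cones, domain = domain,
                 peak_density = peak_density,
                 elevation_factor = elevation_factor,
                 sz_center = sz_center, sz_sigma = sz_sigma,
                 ventral_factor = ventral_factor,
                 min_spacing = min_spacing, rf_radius = rf_radius),
            class = "mosaic_config")
}

#' Evaluate the configured cone density field
#'
#' @param cfg A [mosaic_config()].
#' @param azimuth,elevation Positions (degrees) at which to evaluate.
#' @return Density in cones per square degree.
#' @export
mosaic_density <- function(cfg, azimuth, elevation) {
  bg <- cfg$peak_density / cfg$elevation_factor
  d2 <- (azimuth - cfg$sz_center[1])^2 + (elevation - cfg$sz_center[2])^2
  dens <- bg * (1 + (cfg$elevation_factor - 1) * exp(-d2 / (2 * cfg$sz_sigma^2)))
  if (cfg$ventral_factor > 1) {
    # optional smooth ventral elevation ramping in below the horizon
    ramp <- pmax(0, -elevation) / cfg$domain
    dens <- dens * (1 + (cfg$ventral_factor - 1) * ramp)
  }
  dens
}

#' Generate a synthetic UV-cone mosaic
#'
#' Draws an inhomogeneous point sample from the configured density field by
#' rejection sampling, followed by optional hard-core (minimum-spacing)
#' thinning via sequential dart throwing. The realized mosaic bundles its
#' ground truth (the config and expected counts) for closed-loop testing.
#'
#' @param cfg A [mosaic_config()].
#' @param seed Integer seed for reproducibility.
#' @return A `cone_array` with attribute `ground_truth` (list: `config`,
#'   `expected_n`, `seed`).
#' @examples
#' arr <- make_cone_array(mosaic_config(), seed = 1)
#' arr
#' @export
make_cone_array <- function(cfg = mosaic_config(), seed = 1) {
  stopifnot(inherits(cfg, "mosaic_config"))
  set.seed(seed)
  area <- (2 * cfg$domain)^2
  # expected count from the field integral (midpoint grid quadrature)
  gx <- seq(-cfg$domain, cfg$domain, length.out = 121)
  gx <- (gx[-1] + gx[-length(gx)]) / 2
  gg <- expand.grid(az = gx, el = gx)
  cell <- (2 * cfg$domain / 120)^2
  expected_n <- sum(mosaic_density(cfg, gg$az, gg$el)) * cell
  n_target <- if (is.null(cfg$total_cones)) round(expected_n) else cfg$total_cones
  if (n_target == 0)
    return(structure(cone_array(numeric(0), numeric(0),
                                rf_radius = cfg$rf_radius, domain = cfg$domain),
                     ground_truth = list(config = cfg, expected_n = expected_n,
                                         seed = seed)))
  if (cfg$min_spacing > 0) {
    # feasibility: sequential hard-core sampling jams near
    # 0.547 * 4 / (pi * s^2); refuse configs beyond ~90% of that limit
    jam <- 0.547 * 4 / (pi * cfg$min_spacing^2)
    if (cfg$peak_density > 0.9 * jam)
      stop("infeasible spacing/density combination: peak density ",
           signif(cfg$peak_density, 3), " exceeds 90% of the hard-core ",
           "jamming density ", signif(jam, 3), call. = FALSE)
  }
  dmax <- cfg$peak_density * cfg$ventral_factor
  az <- el <- numeric(n_target)
  kept <- 0L
  guard <- 0L
  while (kept < n_target) {
    guard <- guard + 1L
    if (guard > 2000L)
      stop("mosaic sampling failed to place all cones (infeasible config?)",
           call. = FALSE)
    m <- max(1000L, 4L * (n_target - kept))
    px <- runif(m, -cfg$domain, cfg$domain)
    py <- runif(m, -cfg$domain, cfg$domain)
    ok <- runif(m) < mosaic_density(cfg, px, py) / dmax
    px <- px[ok]; py <- py[ok]
    for (i in seq_along(px)) {
      if (kept >= n_target) break
      if (cfg$min_spacing > 0 && kept > 0) {
        d2 <- (az[seq_len(kept)] - px[i])^2 + (el[seq_len(kept)] - py[i])^2
        if (min(d2) < cfg$min_spacing^2) next
      }
      kept <- kept + 1L
      az[kept] <- px[i]; el[kept] <- py[i]
    }
  }
  out <- cone_array(az, el, rf_radius = cfg$rf_radius, domain = cfg$domain)
  attr(out, "ground_truth") <- list(config = cfg, expected_n = expected_n,
                                    seed = seed)
  out
}

#' Read / write cone arrays as CSV
#'
#' CSV columns: `azimuth_deg`, `elevation_deg`, `type`, `rf_radius_deg`.
#'
#' @param path File path.
#' @param domain Crop half-width for validation on read.
#' @return `read_cone_array` returns a `cone_array`.
#' @export
read_cone_array <- function(path, domain = 60) {
  df <- utils::read.csv(path)
  need <- c("azimuth_deg", "elevation_deg")
  if (!all(need %in% names(df)))
    stop("cone CSV must have columns azimuth_deg, elevation_deg", call. = FALSE)
  cone_array(df$azimuth_deg, df$elevation_deg,
             rf_radius = if ("rf_radius_deg" %in% names(df)) df$rf_radius_deg else 0.38,
             type = if ("type" %in% names(df)) df$type else "UV",
             domain = domain)
}

#' @param x A `cone_array`.
#' @rdname read_cone_array
#' @export
write_cone_array <- function(x, path) {
  stopifnot(inherits(x, "cone_array"))
  df <- data.frame(azimuth_deg = x$cones$azimuth,
                   elevation_deg = x$cones$elevation,
                   type = x$cones$type,
                   rf_radius_deg = x$cones$rf_radius)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Binned density map of a cone array
#'
#' Counts cones in square bins and converts to cones per square degree;
#' used to verify that realized mosaics match their configured density
#' field.
#'
#' @param arr A `cone_array`.
#' @param bin Bin side length, degrees.
#' @return A data.frame with bin centers and density.
#' @export
density_map <- function(arr, bin = 10) {
  stopifnot(inherits(arr, "cone_array"))
  br <- seq(-arr$domain, arr$domain, by = bin)
  cx <- cut(arr$cones$azimuth, br, include.lowest = TRUE)
  cy <- cut(arr$cones$elevation, br, include.lowest = TRUE)
  tab <- table(cx, cy)
  centers <- (br[-1] + br[-length(br)]) / 2
  data.frame(azimuth = rep(centers, times = length(centers)),
             elevation = rep(centers, each = length(centers)),
             density = as.vector(tab) / bin^2)
}
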
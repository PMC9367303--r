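#' Kilometres per nautical mile
#' @keywords internal
KM_PER_NM <- 1.852

## Separable Gaussian blur with replicated borders; used to turn white noise
## into fields with a controllable correlation length.
smooth_field <- function(m, sd_cells) {
  if (sd_cells <= 0) return(m)
  half <- max(1L, ceiling(3 * sd_cells))
  w <- stats::dnorm(-half:half, sd = sd_cells)
  w <- w / sum(w)
  pad_conv <- function(v) {
    vp <- c(rep(v[1], half), v, rep(v[length(v)], half))
    out <- stats::filter(vp, w, sides = 2)
    out[(half + 1):(half + length(v))]
  }
  m <- apply(m, 2, pad_conv)
  t(apply(m, 1, pad_conv))
}

## Standardized smooth Gaussian random field on an ny x nx grid.
random_field <- function(ny, nx, corr_cells) {
  f <- smooth_field(matrix(stats::rnorm(ny * nx), ny, nx), corr_cells)
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic coastal environment with known structure
#'
#' Builds the five eco-geographical variables (EGVs) used throughout the
#' package — bathymetry, slope, sea-surface temperature, chlorophyll-a and
#' ammonium — as smooth random fields on a 1 km grid, with a straight
#' coastline along the western (low-x) edge. Depth increases offshore,
#' chlorophyll is negatively coupled to SST by construction (coastal
#' upwelling-like pattern), and ammonium is highest near the coast. Land
#' cells are `NA` in every layer.
#'
#' @param grid A [grid_spec()]; at least 16 x 16 cells.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param corr_length_km Correlation length of the random texture (km).
#' @param land_width_km Width of the land strip on the low-x edge (km).
#' @param flat_bathymetry If `TRUE`, sea depth is constant (useful for
#'   testing slope derivation).
#' @return An object of class `env_truth`: list with `grid`, `layers` (named
#'   list of matrices: bathymetry (depth, m, >= 0 at sea), slope (degrees),
#'   sst (deg C), chla (mg m^-3), ammonium (mmol m^-3)), `sea` (logical
#'   mask), `seed`.
#' @export
make_environment <- function(grid, seed = 1L, corr_length_km = 15,
                             land_width_km = 2, flat_bathymetry = FALSE) {
  stopifnot(inherits(grid, "grid_spec"))
  if (grid$nx < 16 || grid$ny < 16)
    stop("grid too small: need at least 16 x 16 cells")
  set.seed(seed)
  nx <- grid$nx; ny <- grid$ny; cs <- grid$cell_size_km
  corr_cells <- corr_length_km / cs
  xk <- matrix(rep((seq_len(nx) - 0.5) * cs, each = ny), ny, nx)  # x of centres
  yk <- matrix(rep((ny - seq_len(ny) + 0.5) * cs, times = nx), ny, nx)
  land <- xk < land_width_km
  offshore <- pmax(0, xk - land_width_km)

  if (flat_bathymetry) {
    depth <- matrix(50, ny, nx)
  } else {
    depth <- 4 * offshore^1.1 + 12 * random_field(ny, nx, corr_cells)
    depth <- pmax(depth, 0.5)
  }
  sst <- 16 + 1.5 * (yk / (ny * cs)) + 1.8 * random_field(ny, nx, corr_cells)
  sst_z <- (sst - mean(sst)) / stats::sd(sst)
  chla <- exp(0.4 - 0.45 * sst_z + 0.55 * random_field(ny, nx, corr_cells))
  ammonium <- exp(-0.4 + 0.6 * random_field(ny, nx, corr_cells) -
                    0.008 * offshore)

  layers <- list(bathymetry = depth, sst = sst, chla = chla,
                 ammonium = ammonium)
  layers <- lapply(layers, function(m) { m[land] <- NA_real_; m })
  layers$slope <- slope_from_bathymetry(layers$bathymetry, cs)
  layers <- layers[c("bathymetry", "slope", "sst", "chla", "ammonium")]
  structure(
    list(grid = grid, layers = layers, sea = !land, seed = seed,
         land_width_km = land_width_km),
    class = "env_truth"
  )
}

#' Parameters of the true habitat-suitability surface
#'
#' Encodes the simulation truth used to place porpoise groups: suitability
#' rises with chlorophyll-a, falls with SST and depth, and responds mildly
#' to slope and ammonium, via a logistic link on the raw layer values.
#'
#' @param intercept Baseline on the logit scale.
#' @param chla,sst,depth,slope,ammonium Per-EGV linear coefficients on the
#'   logit scale (raw units of each layer).
#' @param intensity_scale Expected porpoise groups per km^2 where
#'   suitability = 1.
#' @return An object of class `suitability_truth`.
#' @export
suitability_truth <- function(intercept = 3.5, chla = 1.2, sst = -0.35,
                              depth = -0.03, slope = -0.05, ammonium = 0.4,
                              intensity_scale = 0.05) {
  structure(
    list(coef = c(intercept = intercept, chla = chla, sst = sst,
                  depth = depth, slope = slope, ammonium = ammonium),
         intensity_scale = intensity_scale),
    class = "suitability_truth"
  )
}

#' Evaluate the true suitability surface on an environment
#'
#' @param env An [make_environment()] result.
#' @param truth A [suitability_truth()].
#' @return Matrix of suitability values in \[0, 1\] (`NA` on land). Monotone
#'   increasing in chlorophyll-a and decreasing in SST and depth whenever the
#'   default coefficient signs are kept.
#' @export
true_suitability <- function(env, truth = suitability_truth()) {
  stopifnot(inherits(env, "env_truth"), inherits(truth, "suitability_truth"))
  b <- truth$coef
  l <- env$layers
  eta <- b[["intercept"]] + b[["chla"]] * l$chla + b[["sst"]] * l$sst +
    b[["depth"]] * l$bathymetry + b[["slope"]] * l$slope +
    b[["ammonium"]] * l$ammonium
  stats::plogis(eta)
}

#' Zero-truncated Poisson sampler
#'
#' Inverse-CDF draw conditioned on a positive outcome; mean is
#' `lambda / (1 - exp(-lambda))`, which is 1.390 at `lambda = 0.70`.
#'
#' @param n Number of draws.
#' @param lambda Poisson rate (> 0).
#' @return Integer vector of draws, all >= 1.
#' @export
rztpois <- function(n, lambda) {
  stopifnot(lambda > 0)
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  stats::qpois(u, lambda)
}

#' Place porpoise groups from a suitability surface
#'
#' Inhomogeneous Poisson point process: each sea cell receives a Poisson
#' count with mean `intensity_scale * suitability * cell_area`, positions are
#' uniform within the cell, and group sizes are i.i.d. zero-truncated
#' Poisson.
#'
#' @param suitability Matrix in \[0, 1\] (`NA` = land).
#' @param grid The matching [grid_spec()].
#' @param intensity_scale Expected groups per km^2 at suitability 1 (> 0
#'   unless exactly 0, which yields an empty population).
#' @param group_size_lambda Rate of the zero-truncated Poisson group-size law
#'   (default 0.70, giving mean group size 1.39).
#' @param seed Integer seed.
#' @return A data frame (class `population`) with columns `x`, `y` (km) and
#'   `size`.
#' @export
place_groups <- function(suitability, grid, intensity_scale,
                         group_size_lambda = 0.70, seed = 1L) {
  stopifnot(intensity_scale >= 0, group_size_lambda > 0)
  set.seed(seed)
  area <- grid$cell_size_km^2
  mu <- intensity_scale * suitability * area
  mu[is.na(mu)] <- 0
  counts <- stats::rpois(length(mu), as.vector(mu))
  idx <- rep(seq_along(counts), counts)
  n <- length(idx)
  if (n == 0) {
    out <- data.frame(x = numeric(0), y = numeric(0), size = integer(0))
  } else {
    row <- ((idx - 1) %% grid$ny) + 1
    col <- ((idx - 1) %/% grid$ny) + 1
    cs <- grid$cell_size_km
    x <- grid$x0 + (col - 1) * cs + stats::runif(n) * cs
    y <- grid$y0 + (grid$ny - row) * cs + stats::runif(n) * cs
    out <- data.frame(x = x, y = y,
                      size = rztpois(n, group_size_lambda))
  }
  class(out) <- c("population", "data.frame")
  attr(out, "seed") <- seed
  out
}

#' Aerial survey scenario parameters
#'
#' Defaults follow a systematic equal-coverage aerial design for coastal
#' porpoise surveys: parallel 20-nm transects perpendicular to the coast,
#' spaced 10 nm alongshore, flown at 500 ft, with half-normal detection and
#' an availability/perception correction g(0) = 0.364.
#'
#' @param spacing_km Alongshore spacing between transects (default 18.52 km
#'   = 10 nm).
#' @param length_km Design transect length (default 37.04 km = 20 nm).
#' @param altitude_m Flight altitude (default 150.4 m = 500 ft).
#' @param sigma_km Scale of the true detection function (km).
#' @param g0 Probability of detecting a group on the trackline (0 < g0 <= 1).
#' @param W_km Truncation distance (km).
#' @param key True detection key: `"half-normal"` or `"hazard-rate"`.
#' @param hr_shape Hazard-rate shape (only used for that key).
#' @return An object of class `survey_scenario`.
#' @export
survey_scenario <- function(spacing_km = 10 * KM_PER_NM,
                            length_km = 20 * KM_PER_NM,
                            altitude_m = 150.4, sigma_km = 0.12,
                            g0 = 0.364, W_km = 0.3,
                            key = c("half-normal", "hazard-rate"),
                            hr_shape = 2.5) {
  key <- match.arg(key)
  stopifnot(spacing_km > 0, length_km > 0, sigma_km > 0, W_km > 0,
            g0 > 0, g0 <= 1, altitude_m > 0)
  structure(
    list(spacing_km = spacing_km, length_km = length_km,
         altitude_m = altitude_m, sigma_km = sigma_km, g0 = g0,
         W_km = W_km, key = key, hr_shape = hr_shape),
    class = "survey_scenario"
  )
}

#' Lay out parallel transects perpendicular to the coast
#'
#' Transects run offshore (along x) from the coastline, spaced evenly
#' alongshore with the first line offset by half a spacing from the domain
#' edge (equal coverage probability). Lengths are clipped to the sea extent.
#' At least one transect is always returned.
#'
#' @param env An [make_environment()] result.
#' @param scenario A [survey_scenario()].
#' @return Data frame with `transect_id`, `y_km`, `x_start`, `x_end`,
#'   `length_km`.
#' @export
make_transects <- function(env, scenario = survey_scenario()) {
  grid <- env$grid
  extent_y <- grid$ny * grid$cell_size_km
  if (extent_y <= scenario$spacing_km / 2) {
    ys <- grid$y0 + extent_y / 2
  } else {
    ys <- grid$y0 + seq(scenario$spacing_km / 2, extent_y - 1e-9,
                        by = scenario$spacing_km)
  }
  x_start <- grid$x0 + env$land_width_km
  x_max <- grid$x0 + grid$nx * grid$cell_size_km
  x_end <- pmin(x_start + scenario$length_km, x_max)
  data.frame(
    transect_id = sprintf("T%02d", seq_along(ys)),
    y_km = ys, x_start = x_start, x_end = x_end,
    length_km = x_end - x_start
  )
}

## detection key of the simulator (truth), without the g0 factor
true_detect_prob <- function(y, scenario) {
  if (scenario$key == "half-normal") {
    exp(-y^2 / (2 * scenario$sigma_km^2))
  } else {
    1 - exp(-(y / scenario$sigma_km)^(-scenario$hr_shape))
  }
}

#' Simulate an aerial line-transect survey of a known population
#'
#' Each group at perpendicular distance `y <= W` from a transect (and within
#' the transect's alongshore span) is recorded with probability
#' `g0 * g(y)` where `g` is the scenario's detection key; groups beyond `W`
#' are never recorded. Availability bias is a single Bernoulli thinning with
#' probability `g0`, constant in distance.
#'
#' @param population A [place_groups()] result.
#' @param transects A [make_transects()] result.
#' @param scenario A [survey_scenario()].
#' @param seed Integer seed.
#' @param stratum,year Labels attached to every record.
#' @return List with `sightings` (transect_id, stratum, year,
#'   perp_distance_km, group_size) and `effort` (transect_id, stratum, year,
#'   length_km).
#' @export
simulate_survey <- function(population, transects,
                            scenario = survey_scenario(), seed = 1L,
                            stratum = "S1", year = NA_integer_) {
  set.seed(seed)
  recs <- vector("list", nrow(transects))
  for (i in seq_len(nrow(transects))) {
    tr <- transects[i, ]
    d <- abs(population$y - tr$y_km)
    in_strip <- d <= scenario$W_km & population$x >= tr$x_start &
      population$x <= tr$x_end
    if (!any(in_strip)) next
    dd <- d[in_strip]
    p <- scenario$g0 * true_detect_prob(dd, scenario)
    seen <- stats::runif(length(dd)) < p
    if (!any(seen)) next
    recs[[i]] <- data.frame(
      transect_id = tr$transect_id, stratum = stratum, year = year,
      perp_distance_km = dd[seen],
      group_size = population$size[in_strip][seen]
    )
  }
  sightings <- do.call(rbind, recs)
  if (is.null(sightings))
    sightings <- data.frame(transect_id = character(0),
                            stratum = character(0), year = integer(0),
                            perp_distance_km = numeric(0),
                            group_size = integer(0))
  effort <- data.frame(transect_id = transects$transect_id,
                       stratum = stratum, year = year,
                       length_km = transects$length_km)
  list(sightings = sightings, effort = effort)
}
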
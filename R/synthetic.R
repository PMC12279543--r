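#' Configuration for a synthetic lake population
#'
#' Captures the statistical structure the composite framework assumes of a
#' regional lake population: a truncated Pareto law of surface areas
#' (exceedance-count slope \code{-pareto_alpha} on log-log axes; 0.98 is
#' typical of glaciated and 0.92 of non-glaciated regions), an increasing
#' maximum-depth vs area power law with multiplicative lognormal noise
#' (\eqn{Z_{max} = c\,SA^b\,e^{\sigma\varepsilon}}), and a lognormal
#' basin-shape exponent. Mean depth follows as \eqn{Z_{max}/(q+1)}.
#'
#' @param n_lakes Number of lakes.
#' @param pareto_alpha Positive magnitude of the Pareto exceedance slope.
#' @param area_min,area_max Truncation bounds of surface area (m^2);
#'   default 1 ha to 1000 km^2.
#' @param depth_c,depth_b Coefficient and exponent of the depth-area
#'   scaling (m, with area in m^2).
#' @param depth_sigma Lognormal noise SD of the depth scaling (natural log).
#' @param q_median,q_sigma Median and lognormal SD of the shape exponent.
#' @param lat_range,lon_range Optional 2-vectors; when given, centroids are
#'   drawn uniformly so populations can be gridded.
#' @param seed Integer seed; identical configurations generate identical
#'   populations.
#' @return A list of class \code{"population_config"}.
#' @export
population_config <- function(n_lakes = 1000,
                              pareto_alpha = 0.98,
                              area_min = 1e4, area_max = 1e9,
                              depth_c = 0.2, depth_b = 0.25,
                              depth_sigma = 0.4,
                              q_median = 2, q_sigma = 0.5,
                              lat_range = NULL, lon_range = NULL,
                              seed = 1L) {
  if (area_min >= area_max) stop("config error: area_min must be < area_max")
  if (pareto_alpha <= 0) stop("config error: pareto_alpha must be positive")
  if (depth_b < 0 || n_lakes < 1) stop("config error")
  structure(list(n_lakes = n_lakes, pareto_alpha = pareto_alpha,
                 area_min = area_min, area_max = area_max,
                 depth_c = depth_c, depth_b = depth_b,
                 depth_sigma = depth_sigma,
                 q_median = q_median, q_sigma = q_sigma,
                 lat_range = lat_range, lon_range = lon_range,
                 seed = as.integer(seed)),
            class = "population_config")
}

#' Sample lake surface areas from a truncated Pareto law
#'
#' Inverse-CDF draws from the Pareto distribution with survival function
#' \eqn{S(a) \propto a^{-\alpha}} truncated to
#' \code{[area_min, area_max]}, so the exceedance count of a large sample
#' has slope \code{-alpha} on log10-log10 axes.
#'
#' @param config A \code{\link{population_config}}.
#' @param n Number of draws; defaults to \code{config$n_lakes}.
#' @return Areas (m^2) within the truncation bounds.
#' @export
sample_areas <- function(config, n = config$n_lakes) {
  set.seed(config$seed)
  a <- config$pareto_alpha
  lo <- config$area_min^(-a)
  hi <- config$area_max^(-a)
  u <- stats::runif(n)
  (lo - u * (lo - hi))^(-1 / a)
}

#' Generate a full synthetic lake population
#'
#' Draws areas from the truncated Pareto law, maximum depths from the
#' depth-area power law with lognormal noise, shape exponents from a
#' lognormal, and derives mean depth as \eqn{Z_{max}/(q+1)}; construction
#' guarantees every record satisfies the morphometry invariants. Optional
#' uniform centroids are attached when coordinate ranges are configured.
#'
#' @param config A \code{\link{population_config}}.
#' @return A \code{\link{as_lake_table}} lake table of \code{n_lakes} rows.
#' @examples
#' lakes <- synth_population(population_config(n_lakes = 100, seed = 7))
#' range(lakes$area_m2)
#' @export
synth_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  a <- config$pareto_alpha
  lo <- config$area_min^(-a)
  hi <- config$area_max^(-a)
  areas <- (lo - stats::runif(config$n_lakes) * (lo - hi))^(-1 / a)
  df <- sample_morphometry(areas, config, .reseed = FALSE)
  df
}

#' Attach depths and shape exponents to sampled areas
#'
#' @param areas Surface areas (m^2), positive.
#' @param config A \code{\link{population_config}}.
#' @param .reseed Internal; set \code{FALSE} to continue an existing RNG
#'   stream instead of reseeding from the config.
#' @return A lake table.
#' @export
sample_morphometry <- function(areas, config, .reseed = TRUE) {
  if (any(areas <= 0)) stop("areas must be positive")
  if (.reseed) set.seed(config$seed + 1L)
  n <- length(areas)
  z_max <- config$depth_c * areas^config$depth_b *
    exp(config$depth_sigma * stats::rnorm(n))
  q <- stats::rlnorm(n, meanlog = log(config$q_median), sdlog = config$q_sigma)
  df <- data.frame(
    lake_id = sprintf("syn%07d", seq_len(n)),
    area_m2 = areas,
    zmax_m = z_max,
    zmean_m = z_max / (q + 1),
    q = q
  )
  if (!is.null(config$lat_range))
    df$lat <- stats::runif(n, config$lat_range[1], config$lat_range[2])
  if (!is.null(config$lon_range))
    df$lon <- stats::runif(n, config$lon_range[1], config$lon_range[2])
  as_lake_table(df)
}

#' Fit the Pareto exceedance slope of a lake-size sample
#'
#' Regresses \eqn{\log_{10}(\#\{A \ge a\})} on \eqn{\log_{10} a} over a
#' central quantile range of the sample (default 5-95%, avoiding
#' truncation bias at both ends), the conventional exceedance-curve
#' estimate of the Pareto slope used in limnology. A bootstrap percentile
#' interval accompanies the point estimate.
#'
#' @param areas At least 50 positive areas.
#' @param quantile_range Two probabilities bounding the areas used.
#' @param n_boot Bootstrap replicates for the CI (0 skips the CI).
#' @param conf Confidence level. Default 0.95.
#' @return List with \code{slope} (negative, about \code{-alpha}),
#'   \code{ci} (2-vector or NULL) and \code{n_used}.
#' @export
fit_pareto_slope <- function(areas, quantile_range = c(0.05, 0.95),
                             n_boot = 100, conf = 0.95) {
  if (length(areas) < 50) stop("estimation error: need at least 50 areas")
  if (stats::sd(log10(areas)) == 0)
    stop("estimation error: areas are constant")
  est <- function(a) {
    a <- sort(a)
    qs <- stats::quantile(a, quantile_range)
    keep <- a >= qs[1] & a <= qs[2]
    x <- log10(a[keep])
    y <- log10(length(a) - which(keep) + 1)  # exceedance count at sorted a
    if (stats::sd(x) == 0) return(NA_real_)
    stats::cov(x, y) / stats::var(x)
  }
  slope <- est(areas)
  ci <- NULL
  if (n_boot > 0) {
    bs <- vapply(seq_len(n_boot), function(i)
      est(sample(areas, replace = TRUE)), numeric(1))
    ci <- unname(stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                                 na.rm = TRUE))
  }
  list(slope = slope, ci = ci, n_used = length(areas))
}

#' Configuration for a schematic annual thermal series
#'
#' A deliberately simple stand-in for a hydrodynamic model's output whose
#' only contract is producing valid daily temperature/ice inputs for the
#' stratification stage: a sinusoidal surface temperature, a two-layer
#' profile (warm epilimnion over a 4 degC hypolimnion) during a stratified
#' season centred on the warm peak, an isothermal column otherwise, and an
#' ice season of constant thickness centred on the cold trough.
#'
#' @param t_mean,t_amplitude Annual mean and half-range of surface
#'   temperature (degC).
#' @param peak_day Day of year of the surface temperature maximum.
#' @param strat_days Length of the stratified season (days, 0-365).
#' @param therm_frac Thermocline depth as a fraction of \code{z_max}
#'   (clipped to \code{z_max}); ignored when \code{therm_depth} is given.
#' @param therm_depth Optional fixed thermocline depth (m).
#' @param ice_days Length of the ice season (days, 0-365).
#' @param ice_thickness Ice thickness on ice days (m).
#' @param n_days Days in the year (365; leap days are dropped upstream).
#' @param hypo_temp Hypolimnion temperature during stratification (degC).
#' @return A list of class \code{"thermal_config"}.
#' @export
thermal_config <- function(t_mean = 12, t_amplitude = 10, peak_day = 200,
                           strat_days = 120, therm_frac = 0.3,
                           therm_depth = NULL,
                           ice_days = 0, ice_thickness = 0.3,
                           n_days = 365, hypo_temp = 4) {
  if (strat_days < 0 || strat_days > n_days ||
      ice_days < 0 || ice_days > n_days)
    stop("config error: season lengths must lie in [0, n_days]")
  structure(list(t_mean = t_mean, t_amplitude = t_amplitude,
                 peak_day = peak_day, strat_days = strat_days,
                 therm_frac = therm_frac, therm_depth = therm_depth,
                 ice_days = ice_days, ice_thickness = ice_thickness,
                 n_days = n_days, hypo_temp = hypo_temp),
            class = "thermal_config")
}

#' Generate a schematic daily thermal series for one lake
#'
#' @param z_max Maximum lake depth (m).
#' @param config A \code{\link{thermal_config}}.
#' @param dz Depth grid spacing (m) of the series.
#' @return A \code{\link{thermal_series}}.
#' @export
generate_thermal <- function(z_max, config = thermal_config(), dz = 0.5) {
  stopifnot(inherits(config, "thermal_config"))
  nd <- config$n_days
  zg <- depth_grid_for(z_max, dz)
  days <- seq_len(nd)
  t_surf <- config$t_mean +
    config$t_amplitude * cos(2 * pi * (days - config$peak_day) / nd)
  t_surf <- pmax(t_surf, 0.5)

  in_season <- function(centre, len) {
    # exactly len days, the circularly closest to the season centre
    if (len <= 0) return(rep(FALSE, nd))
    d <- abs(((days - centre + nd / 2) %% nd) - nd / 2)
    out <- rep(FALSE, nd)
    out[order(d, days)[seq_len(len)]] <- TRUE
    out
  }
  strat <- in_season(config$peak_day, config$strat_days)
  trough <- ((config$peak_day + nd / 2 - 1) %% nd) + 1
  ice_on <- in_season(trough, config$ice_days)

  z_therm <- if (!is.null(config$therm_depth)) config$therm_depth else
    config$therm_frac * z_max
  z_therm <- min(z_therm, z_max)

  temp <- matrix(rep(t_surf, length(zg)), nrow = nd)
  deep <- zg > z_therm
  if (any(strat) && any(deep))
    temp[strat, deep] <- config$hypo_temp
  temp[ice_on, ] <- 0.5
  ice <- ifelse(ice_on, config$ice_thickness, 0)
  thermal_series(zg, temp, ice)
}
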
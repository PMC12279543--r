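#' Fresh-water density from temperature
#'
#' Temperature-only density of fresh water (salinity 0) after the
#' Martin & McCutcheon formulation,
#' \deqn{\rho(T) = 1000\left(1 - \frac{T + 288.9414}{508929.2\,(T + 68.12963)}(T - 3.9863)^2\right),}
#' with the density maximum near 4 degrees C. Used by the thermocline rule;
#' an alternative polynomial can be passed to the functions that consume it.
#'
#' @param temperature Water temperature (degrees C), in [-0.5, 40].
#' @return Density (kg m^-3).
#' @export
water_density <- function(temperature) {
  if (any(!is.finite(temperature)) ||
      any(temperature < -0.5) || any(temperature > 40))
    stop("temperature out of supported range [-0.5, 40] degC")
  1000 * (1 - (temperature + 288.9414) /
            (508929.2 * (temperature + 68.12963)) *
            (temperature - 3.9863)^2)
}

#' Thermocline depth from a density-gradient threshold
#'
#' The thermocline is the shallowest depth at which the water density
#' gradient between adjacent measurement depths exceeds 0.1 kg m^-4
#' (kg m^-3 per metre of depth). Gradients are forward differences scaled
#' per metre, so the threshold is independent of the profile grid spacing.
#' If no gradient exceeds the threshold the water column is taken as fully
#' mixed and the maximum depth is returned.
#'
#' @param temperature Temperatures (degC) at the profile depths, surface first.
#' @param depth_grid Depths (m) of the profile, strictly increasing.
#' @param z_max Maximum lake depth (m), returned when no thermocline exists.
#' @param threshold Density gradient threshold (kg m^-4). Default 0.1.
#' @param density Function mapping temperature to density; default
#'   \code{\link{water_density}}.
#' @return Thermocline depth (m): the midpoint of the first interface whose
#'   gradient exceeds the threshold, or \code{z_max}.
#' @export
thermocline_depth <- function(temperature, depth_grid, z_max,
                              threshold = 0.1, density = water_density) {
  if (length(temperature) < 2L || length(depth_grid) < 2L)
    stop("insufficient profile: need at least 2 depths")
  if (length(temperature) != length(depth_grid))
    stop("temperature and depth_grid lengths differ")
  rho <- density(temperature)
  grad <- diff(rho) / diff(depth_grid)
  hit <- which(grad > threshold)
  if (length(hit) == 0L) return(z_max)
  i <- hit[1L]
  (depth_grid[i] + depth_grid[i + 1L]) / 2
}

#' Daily depth-resolved thermal series
#'
#' Container for one lake-year of daily temperature profiles and ice
#' thickness, the input to \code{\link{isolation_fraction}}.
#'
#' @param depth_grid Depths (m), strictly increasing.
#' @param temperature Matrix of temperatures (degC), days in rows, depths in
#'   columns.
#' @param ice_thickness Daily ice thickness (m), one value per day, >= 0.
#' @return An object of class \code{"thermal_series"}.
#' @export
thermal_series <- function(depth_grid, temperature, ice_thickness) {
  temperature <- as.matrix(temperature)
  if (ncol(temperature) != length(depth_grid))
    stop("temperature columns must match depth_grid")
  if (nrow(temperature) < 1L) stop("need at least one day")
  if (length(ice_thickness) != nrow(temperature))
    stop("ice_thickness must have one value per day")
  if (any(!is.finite(temperature))) stop("temperatures must be finite")
  if (any(ice_thickness < 0)) stop("ice_thickness must be >= 0")
  if (is.unsorted(depth_grid, strictly = TRUE))
    stop("depth_grid must be strictly increasing")
  structure(list(depth_grid = depth_grid, temperature = temperature,
                 ice_thickness = ice_thickness, n_days = nrow(temperature)),
            class = "thermal_series")
}

#' @export
print.thermal_series <- function(x, ...) {
  cat("Daily thermal series:", x$n_days, "days,",
      length(x$depth_grid), "depths,",
      sum(x$ice_thickness > 0), "ice days\n")
  invisible(x)
}

#' Atmosphere-isolation profile and annual mean temperature
#'
#' For every depth of the series grid, computes the fraction of the year
#' that depth is isolated from direct contact with the atmosphere: a depth
#' counts as isolated on a day when it lies below that day's thermocline or
#' when any ice is present (ice is taken to cap the whole air-water
#' interface, isolating all depths). The fraction ranges from 0 (never
#' isolated) to 1 (isolated all year). Also returns the annually integrated
#' mean temperature per depth and the daily thermocline series.
#'
#' @param series A \code{\link{thermal_series}}.
#' @param z_max Maximum lake depth (m) assigned on fully mixed days.
#' @param threshold,density Passed to \code{\link{thermocline_depth}}.
#' @return An object of class \code{"isolation_profile"}: list with
#'   \code{depth_grid}, \code{f_iso} (fraction per depth),
#'   \code{t_mean_z} (degC per depth), \code{thermocline_series} (m per
#'   day), \code{ice_days} and \code{n_days}.
#' @export
isolation_fraction <- function(series, z_max, threshold = 0.1,
                               density = water_density) {
  stopifnot(inherits(series, "thermal_series"))
  nd <- series$n_days
  zg <- series$depth_grid
  therm <- vapply(seq_len(nd), function(d) {
    thermocline_depth(series$temperature[d, ], zg, z_max,
                      threshold = threshold, density = density)
  }, numeric(1))
  ice <- series$ice_thickness > 0
  # days isolated per depth: below that day's thermocline, or under ice
  iso_count <- vapply(zg, function(z) sum(z > therm | ice), numeric(1))
  structure(
    list(depth_grid = zg,
         f_iso = iso_count / nd,
         t_mean_z = colMeans(series$temperature),
         thermocline_series = therm,
         ice_days = sum(ice),
         n_days = nd),
    class = "isolation_profile"
  )
}

#' @export
print.isolation_profile <- function(x, ...) {
  cat("Atmosphere-isolation profile:", length(x$depth_grid), "depths,",
      x$n_days, "days,", x$ice_days, "ice days\n")
  cat(sprintf("  f_iso surface: %.3f, f_iso bottom: %.3f\n",
              x$f_iso[1], x$f_iso[length(x$f_iso)]))
  invisible(x)
}
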
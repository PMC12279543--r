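#' Shape exponent of the Imboden hypsographic model
#'
#' Computes the dimensionless basin-shape exponent \eqn{q = Z_{max}/Z_{mean} - 1}
#' from maximum and mean depth. \code{q = 2} corresponds to a perfect cone;
#' values below 2 describe more convex basins, values above 2 more concave
#' (steep-sided with a flat deep tail). \code{q = 0} is a cylinder.
#'
#' @param z_max Maximum depth (m), positive.
#' @param z_mean Mean depth (m), positive and not exceeding \code{z_max}.
#' @return Numeric vector of shape exponents, \code{q >= 0}.
#' @examples
#' shape_exponent(30, 10)  # 2: a perfect cone
#' shape_exponent(10, 10)  # 0: a cylinder
#' @export
shape_exponent <- function(z_max, z_mean) {
  if (any(!is.finite(z_max)) || any(!is.finite(z_mean)))
    stop("invalid morphometry: depths must be finite")
  if (any(z_mean <= 0))
    stop("invalid morphometry: z_mean must be positive")
  if (any(z_mean > z_max * (1 + 1e-12)))
    stop("invalid morphometry: z_mean exceeds z_max")
  pmax(z_max / z_mean - 1, 0)
}

#' Single-lake hypsographic model
#'
#' Constructs the two-parameter depth-area model of a lake basin,
#' \deqn{A(z) = SA (1 - z/Z_{max})^q,}
#' from surface area, maximum depth and either mean depth or the shape
#' exponent \code{q} directly. The returned object supports
#' \code{\link[stats]{predict}} (area or cumulative volume at depth),
#' \code{print} and \code{plot}.
#'
#' When both \code{z_mean} and \code{q} are supplied they must be mutually
#' consistent with \eqn{q = Z_{max}/Z_{mean} - 1}; the constructor checks the
#' identity rather than silently recomputing one from the other.
#'
#' @param surface_area Lake surface area (m^2), positive.
#' @param z_max Maximum depth (m), positive.
#' @param z_mean Mean depth (m); optional if \code{q} is given.
#' @param q Shape exponent; optional if \code{z_mean} is given.
#' @param lake_id Optional identifier stored with the model.
#' @return An object of class \code{"lake_hypso"} with elements
#'   \code{surface_area}, \code{z_max}, \code{z_mean}, \code{q},
#'   \code{volume} (total volume, m^3) and \code{lake_id}.
#' @examples
#' lk <- lake_hypso(surface_area = 1e5, z_max = 20, z_mean = 5)
#' lk$q           # 3
#' predict(lk, depth = c(0, 10, 20))
#' @export
lake_hypso <- function(surface_area, z_max, z_mean = NULL, q = NULL,
                       lake_id = NA_character_) {
  stopifnot(length(surface_area) == 1L, length(z_max) == 1L)
  if (!is.finite(surface_area) || surface_area <= 0)
    stop("invalid morphometry: surface_area must be positive")
  if (!is.finite(z_max) || z_max <= 0)
    stop("invalid morphometry: z_max must be positive")
  if (is.null(z_mean) && is.null(q))
    stop("supply z_mean or q")
  if (!is.null(q)) {
    if (!is.finite(q) || q < 0) stop("invalid morphometry: q must be >= 0")
    if (!is.null(z_mean)) {
      if (abs(q - (z_max / z_mean - 1)) >= 1e-9)
        stop("inconsistent morphometry: q does not match z_max/z_mean - 1")
    } else {
      z_mean <- z_max / (q + 1)
    }
  } else {
    q <- shape_exponent(z_max, z_mean)
  }
  structure(
    list(surface_area = surface_area, z_max = z_max, z_mean = z_mean,
         q = q, volume = surface_area * z_max / (q + 1), lake_id = lake_id),
    class = "lake_hypso"
  )
}

#' Planar area at depth
#'
#' Evaluates \eqn{A(z) = SA (1 - z/Z_{max})^q}. Depths at or below the lake
#' bottom return 0 rather than erroring, so composite grids may extend past
#' any one lake's maximum depth.
#'
#' @param lake A \code{\link{lake_hypso}} object.
#' @param z Depths (m), non-negative, positive downward from the surface.
#' @return Areas (m^2) at each depth.
#' @export
area_at_depth <- function(lake, z) {
  stopifnot(inherits(lake, "lake_hypso"))
  if (any(z < 0)) stop("depth must be non-negative")
  ifelse(z >= lake$z_max, 0,
         lake$surface_area * (1 - z / lake$z_max)^lake$q)
}

#' Cumulative volume below depth
#'
#' Closed-form integral of the depth-area model from \code{z} to the bottom:
#' \deqn{V(z) = SA \frac{(Z_{max} - z)(1 - z/Z_{max})^q}{q + 1}.}
#' At \code{z = 0} this is the total volume \eqn{SA\,Z_{max}/(q+1) = SA\,Z_{mean}}.
#'
#' @inheritParams area_at_depth
#' @return Volumes (m^3) below each depth.
#' @export
volume_below <- function(lake, z) {
  stopifnot(inherits(lake, "lake_hypso"))
  if (any(z < 0)) stop("depth must be non-negative")
  ifelse(z >= lake$z_max, 0,
         lake$surface_area * (lake$z_max - z) *
           (1 - z / lake$z_max)^lake$q / (lake$q + 1))
}

#' Total lake volume
#'
#' @inheritParams area_at_depth
#' @return Total volume (m^3), \eqn{SA\,Z_{max}/(q+1)}.
#' @export
total_volume <- function(lake) {
  stopifnot(inherits(lake, "lake_hypso"))
  lake$volume
}

#' @export
print.lake_hypso <- function(x, ...) {
  cat("Lake hypsography (Imboden model)\n")
  if (!is.na(x$lake_id)) cat("  lake_id:     ", x$lake_id, "\n")
  cat(sprintf("  surface area: %.6g m2\n", x$surface_area))
  cat(sprintf("  z_max:        %.6g m\n", x$z_max))
  cat(sprintf("  z_mean:       %.6g m\n", x$z_mean))
  cat(sprintf("  q:            %.4g  (2 = cone, 0 = cylinder)\n", x$q))
  cat(sprintf("  volume:       %.6g m3\n", x$volume))
  invisible(x)
}

#' @rdname lake_hypso
#' @param object A \code{lake_hypso} object.
#' @param depth Depths (m) at which to evaluate.
#' @param what \code{"area"} for planar area at depth, \code{"volume"} for
#'   cumulative volume below depth.
#' @param ... Unused.
#' @export
predict.lake_hypso <- function(object, depth = 0, what = c("area", "volume"),
                               ...) {
  what <- match.arg(what)
  if (what == "area") area_at_depth(object, depth) else
    volume_below(object, depth)
}

#' @export
plot.lake_hypso <- function(x, dz = x$z_max / 200, ...) {
  z <- seq(0, x$z_max, by = dz)
  a <- area_at_depth(x, z)
  plot(a, -z, type = "l", xlab = "Area at depth (m2)", ylab = "Depth (m)",
       main = if (!is.na(x$lake_id)) x$lake_id else "Lake hypsography", ...)
  invisible(x)
}

# Depth grid spanning 0 to the smallest multiple of dz >= z_max.
depth_grid_for <- function(z_max, dz) {
  if (!is.finite(dz) || dz <= 0) stop("dz must be positive")
  n <- ceiling(z_max / dz - 1e-12)
  seq(0, n * dz, by = dz)
}

#' Discretize a lake hypsography onto a uniform depth grid
#'
#' Evaluates area at depth and cumulative volume below depth on a uniform
#' grid from the surface to the smallest multiple of \code{dz} at or beyond
#' \code{z_max}, and forms the layer (differential) area and volume between
#' consecutive depths, \eqn{dA_z = A_z - A_{z+dz}} and
#' \eqn{dV_z = V_z - V_{z+dz}}. Layers are half-open \code{[z, z+dz)} with
#' the final layer truncated at the lake bottom; the telescoping sums
#' guarantee that layer areas add up to the surface area and layer volumes
#' to the total volume exactly.
#'
#' @inheritParams area_at_depth
#' @param dz Grid spacing (m), positive. Default 0.5 m.
#' @return An object of class \code{"hypso_curve"}: a list with
#'   \code{depth_grid}, \code{area_at_depth}, \code{volume_below} (per grid
#'   depth), \code{layer_area}, \code{layer_volume} (per layer, one fewer
#'   than grid depths) and \code{dz}.
#' @export
discretize <- function(lake, dz = 0.5) {
  stopifnot(inherits(lake, "lake_hypso"))
  zg <- depth_grid_for(lake$z_max, dz)
  a <- area_at_depth(lake, zg)
  v <- volume_below(lake, zg)
  new_hypso_curve(zg, a, v, dz)
}

new_hypso_curve <- function(depth_grid, area, volume, dz) {
  structure(
    list(depth_grid = depth_grid,
         area_at_depth = area,
         volume_below = volume,
         layer_area = -diff(area),
         layer_volume = -diff(volume),
         dz = dz),
    class = "hypso_curve"
  )
}

#' @export
print.hypso_curve <- function(x, ...) {
  cat("Hypsographic curve:", length(x$depth_grid), "depths, dz =", x$dz, "m\n")
  cat(sprintf("  surface area: %.6g m2, total volume: %.6g m3, z span: 0-%g m\n",
              x$area_at_depth[1], x$volume_below[1], max(x$depth_grid)))
  invisible(x)
}

#' @export
plot.hypso_curve <- function(x, ...) {
  plot(x$area_at_depth, -x$depth_grid, type = "l",
       xlab = "Area at depth (m2)", ylab = "Depth (m)", ...)
  invisible(x)
}

#' Compare a modelled curve against a measured one
#'
#' Resamples the measured curve to the modelled depth grid by linear
#' interpolation and returns per-depth relative errors
#' \code{(measured - modelled)/measured} for area and cumulative volume,
#' at every grid depth where the measured value is positive.
#'
#' @param modelled,measured \code{hypso_curve} objects. The measured curve
#'   need not share the modelled grid.
#' @return A data.frame with columns \code{depth_m}, \code{rel_err_area},
#'   \code{rel_err_volume} (NA where the measured quantity is zero), plus a
#'   \code{"summary"} attribute holding the mean and quartiles of each error.
#' @export
validate_curve <- function(modelled, measured) {
  stopifnot(inherits(modelled, "hypso_curve"), inherits(measured, "hypso_curve"))
  zr <- range(measured$depth_grid)
  keep <- modelled$depth_grid >= zr[1] & modelled$depth_grid <= zr[2]
  if (!any(keep)) stop("validation error: depth grids do not overlap")
  z <- modelled$depth_grid[keep]
  ma <- stats::approx(measured$depth_grid, measured$area_at_depth, z)$y
  mv <- stats::approx(measured$depth_grid, measured$volume_below, z)$y
  ea <- ifelse(ma > 0, (ma - modelled$area_at_depth[keep]) / ma, NA_real_)
  ev <- ifelse(mv > 0, (mv - modelled$volume_below[keep]) / mv, NA_real_)
  out <- data.frame(depth_m = z, rel_err_area = ea, rel_err_volume = ev)
  summ <- function(e) {
    e <- e[is.finite(e)]
    c(mean = mean(e), stats::quantile(e, c(0.25, 0.5, 0.75)))
  }
  attr(out, "summary") <- list(area = summ(ea), volume = summ(ev))
  out
}
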
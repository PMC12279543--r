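#' Build a composite lake from a collection of lakes
#'
#' Aggregates a lake collection depth by depth into a single composite
#' ("uber") lake: each member's analytic depth-area model is evaluated on a
#' common uniform grid spanning the surface to the deepest member, and
#' areas, cumulative volumes and layer (differential) areas and volumes are
#' summed per depth. Because every member curve is evaluated in closed form
#' on the composite grid, no interpolation error enters the aggregation.
#'
#' With per-lake thermal/isolation profiles the composite also carries the
#' volume-weighted temperature profile
#' \eqn{T_{C,z} = \sum_i T_{z,i}\,dV_{z,i} / \sum_i dV_{z,i}}, its
#' volume-weighted vertical mean \eqn{wT_{meanC}}, the isolated layer area
#' and volume \eqn{dA_{IsoC,z} = \sum_i fIso_{z,i}\,dA_{z,i}} (and the
#' volume analogue), and the epilimnetic metrics
#' \eqn{fA_{EpiC}}, \eqn{fV_{EpiC}} and \eqn{V_{EpiC}/A_{EpiC}}.
#'
#' @param lakes A \code{\link{as_lake_table}} lake table (or a data.frame
#'   coercible to one).
#' @param dz Depth grid spacing (m). Default 0.5.
#' @param thermal Optional named list, one entry per \code{lake_id}, each an
#'   \code{\link{isolation_fraction}} profile or a data.frame with columns
#'   \code{depth_m}, \code{f_iso}, \code{t_mean_c}. Profiles are evaluated
#'   at composite layer midpoints by linear interpolation (constant beyond
#'   their grid ends).
#' @return An object of class \code{"composite_lake"}: depth grid and
#'   aggregated curves (\code{area_c}, \code{vol_below_c} per grid depth;
#'   \code{layer_area_c}, \code{layer_vol_c}, \code{iso_layer_area},
#'   \code{iso_layer_vol}, \code{temp_c_z} per layer) plus the metric block
#'   \code{sa_c}, \code{v_c}, \code{z_mean_c}, \code{z_max_c}, \code{dr_c},
#'   \code{fa_epi_c}, \code{fv_epi_c}, \code{epi_ratio}, \code{wt_mean_c},
#'   \code{n_lakes}.
#' @examples
#' lakes <- as_lake_table(data.frame(
#'   lake_id = c("a", "b"), area_m2 = c(100, 50),
#'   zmax_m = c(10, 4), zmean_m = c(10/3, 2)))
#' cl <- composite_lake(lakes, dz = 0.5)
#' cl$sa_c      # 150
#' cl$z_mean_c  # 2.888...
#' @export
composite_lake <- function(lakes, dz = 0.5, thermal = NULL) {
  if (!inherits(lakes, "lake_table")) lakes <- as_lake_table(lakes)
  n <- nrow(lakes)
  if (n == 0L) stop("aggregation error: empty lake collection")
  if (!is.finite(dz) || dz <= 0) stop("dz must be positive")

  z_max_c <- max(lakes$zmax_m)
  zg <- depth_grid_for(z_max_c, dz)
  nz <- length(zg)
  zm <- zg[-nz] + dz / 2  # layer midpoints

  has_thermal <- !is.null(thermal)
  if (has_thermal) {
    missing_ids <- setdiff(as.character(lakes$lake_id), names(thermal))
    if (length(missing_ids))
      stop("thermal profiles missing for lakes: ",
           paste(utils::head(missing_ids, 5), collapse = ", "))
  }

  area_c <- numeric(nz)
  vol_c <- numeric(nz)
  iso_a <- numeric(nz - 1L)
  iso_v <- numeric(nz - 1L)
  t_dv <- numeric(nz - 1L)   # sum T_i * dV_i
  w_dv <- numeric(nz - 1L)   # sum dV_i (temperature weights)

  chunk <- 2000L
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    sa <- lakes$area_m2[idx]
    zx <- lakes$zmax_m[idx]
    qq <- lakes$q[idx]
    # lakes in rows, depths in columns
    rel <- 1 - outer(1 / zx, zg)          # 1 - z/zmax
    dry <- rel <= 0                        # at/below each lake's bottom
    rel[dry] <- 0
    a <- sa * rel^qq                       # 0^0 = 1, so mask dry cells below
    v <- sa * (outer(zx, zg, "-") * rel^qq) / (qq + 1)
    a[dry] <- 0
    v[dry] <- 0
    area_c <- area_c + colSums(a)
    vol_c <- vol_c + colSums(v)
    if (has_thermal) {
      da <- a[, -nz, drop = FALSE] - a[, -1L, drop = FALSE]
      dv <- v[, -nz, drop = FALSE] - v[, -1L, drop = FALSE]
      for (k in seq_along(idx)) {
        pr <- profile_at(thermal[[as.character(lakes$lake_id[idx[k]])]], zm)
        if (any(pr$f_iso < -1e-12 | pr$f_iso > 1 + 1e-12))
          stop("validation error: f_iso outside [0, 1]")
        iso_a <- iso_a + pr$f_iso * da[k, ]
        iso_v <- iso_v + pr$f_iso * dv[k, ]
        t_dv <- t_dv + pr$t_mean * dv[k, ]
        w_dv <- w_dv + dv[k, ]
      }
    }
  }

  layer_area_c <- -diff(area_c)
  layer_vol_c <- -diff(vol_c)
  sa_c <- sum(lakes$area_m2)
  v_c <- sum(lakes$area_m2 * lakes$zmax_m / (lakes$q + 1))
  z_mean_c <- v_c / sa_c

  out <- list(
    depth_grid = zg, dz = dz,
    area_c = area_c, vol_below_c = vol_c,
    layer_area_c = layer_area_c, layer_vol_c = layer_vol_c,
    sa_c = sa_c, v_c = v_c,
    z_mean_c = z_mean_c, z_max_c = z_max_c,
    dr_c = sqrt(sa_c / 1e6) / z_mean_c,
    n_lakes = n,
    iso_layer_area = NULL, iso_layer_vol = NULL, temp_c_z = NULL,
    fa_epi_c = NA_real_, fv_epi_c = NA_real_, epi_ratio = NA_real_,
    wt_mean_c = NA_real_
  )
  if (has_thermal) {
    temp_c_z <- ifelse(w_dv > 0, t_dv / w_dv, NA_real_)
    out$iso_layer_area <- iso_a
    out$iso_layer_vol <- iso_v
    out$temp_c_z <- temp_c_z
    ok <- is.finite(temp_c_z)
    out$wt_mean_c <- sum(temp_c_z[ok] * layer_vol_c[ok]) / v_c
    out[c("fa_epi_c", "fv_epi_c", "epi_ratio")] <-
      epilimnetic_metrics(out)
  }
  class(out) <- "composite_lake"
  out
}

# Evaluate a per-lake thermal profile at given depths.
profile_at <- function(p, depths) {
  if (inherits(p, "isolation_profile")) {
    zg <- p$depth_grid; fi <- p$f_iso; tm <- p$t_mean_z
  } else {
    zg <- p$depth_m; fi <- p$f_iso; tm <- p$t_mean_c
  }
  if (length(zg) == 1L) {
    list(f_iso = rep(fi, length(depths)), t_mean = rep(tm, length(depths)))
  } else {
    list(f_iso = stats::approx(zg, fi, depths, rule = 2)$y,
         t_mean = stats::approx(zg, tm, depths, rule = 2)$y)
  }
}

#' Epilimnetic fractions and mean epilimnion thickness of a composite lake
#'
#' From the isolated layer sums: the fraction of sediment surface area in
#' contact with the atmosphere through the mixed layer
#' \eqn{fA_{EpiC} = 1 - \sum dA_{IsoC,z}/SA_C}, the fraction of epilimnetic
#' volume \eqn{fV_{EpiC} = 1 - \sum dV_{IsoC,z}/V_C}, and the composite
#' epilimnetic volume to sediment surface area ratio
#' \eqn{V_{EpiC}/A_{EpiC} = (V_C - \sum dV_{IsoC,z})/(SA_C - \sum dA_{IsoC,z})}
#' (m^3 m^-2), the mean thickness of the composite epilimnion. A fully
#' isolated composite has an undefined ratio, reported as NA.
#'
#' @param composite A \code{\link{composite_lake}} with isolated layers
#'   populated (built with \code{thermal}), or a list with elements
#'   \code{iso_layer_area}, \code{iso_layer_vol}, \code{sa_c}, \code{v_c}.
#' @return Named list: \code{fa_epi_c}, \code{fv_epi_c}, \code{epi_ratio}.
#' @export
epilimnetic_metrics <- function(composite) {
  if (is.null(composite$iso_layer_area))
    stop("isolated layers not populated; build the composite with thermal profiles")
  a_iso <- sum(composite$iso_layer_area)
  v_iso <- sum(composite$iso_layer_vol)
  a_epi <- composite$sa_c - a_iso
  list(fa_epi_c = 1 - a_iso / composite$sa_c,
       fv_epi_c = 1 - v_iso / composite$v_c,
       epi_ratio = if (abs(a_epi) <= 1e-9 * composite$sa_c) NA_real_
                   else (composite$v_c - v_iso) / a_epi)
}

#' Composite mean depth
#'
#' \eqn{Z_{meanC} = V_C / SA_C} (m): the ratio of composite volume to
#' composite surface area, a first-order index of the relative importance
#' of sediment vs water-column processes.
#'
#' @param v_c Composite volume. Either m^3 with \code{sa_c} in m^2, or any
#'   consistent unit pair; with km^3 and km^2 multiply the result by 1000
#'   to obtain metres. Alternatively pass a \code{composite_lake} object.
#' @param sa_c Composite surface area (same length unit as \code{v_c}).
#' @return Mean depth in the length unit implied by the inputs.
#' @export
composite_mean_depth <- function(v_c, sa_c) {
  if (inherits(v_c, "composite_lake")) return(v_c$z_mean_c)
  v_c / sa_c
}

#' Composite dynamic ratio
#'
#' \eqn{DR_C = \sqrt{SA_C\,[\mathrm{km^2}]} / Z_{meanC}\,[\mathrm{m}]}:
#' high values indicate dominance of aggregated shallow areas.
#'
#' @param sa_c_km2 Composite surface area in km^2, or a
#'   \code{composite_lake} object (then \code{z_mean_c_m} is ignored).
#' @param z_mean_c_m Composite mean depth in m.
#' @return Dimensionless dynamic ratio.
#' @export
dynamic_ratio <- function(sa_c_km2, z_mean_c_m) {
  if (inherits(sa_c_km2, "composite_lake")) return(sa_c_km2$dr_c)
  sqrt(sa_c_km2) / z_mean_c_m
}

#' @export
print.composite_lake <- function(x, ...) {
  cat("Composite lake of", x$n_lakes, "lakes\n")
  cat(sprintf("  SA_C:    %.6g m2 (%.6g km2)\n", x$sa_c, x$sa_c / 1e6))
  cat(sprintf("  V_C:     %.6g m3 (%.6g km3)\n", x$v_c, x$v_c / 1e9))
  cat(sprintf("  Z_meanC: %.4g m   Z_maxC: %.4g m   DR_C: %.3g\n",
              x$z_mean_c, x$z_max_c, x$dr_c))
  if (!is.na(x$fa_epi_c))
    cat(sprintf("  fA_EpiC: %.3f  fV_EpiC: %.3f  V_Epi/A_Epi: %.4g m3 m-2  wT_meanC: %.3g degC\n",
                x$fa_epi_c, x$fv_epi_c, x$epi_ratio, x$wt_mean_c))
  invisible(x)
}

#' @export
summary.composite_lake <- function(object, ...) {
  m <- composite_metrics(object)
  cat("Composite lake metric block:\n")
  print(m, row.names = FALSE)
  invisible(m)
}

#' One-row metric block of a composite lake
#'
#' Reporting-unit view of a composite: areas in km^2, volumes in km^3,
#' depths in m, fractions dimensionless.
#'
#' @param composite A \code{composite_lake}.
#' @param label Optional group label stored in the first column.
#' @return A one-row data.frame.
#' @export
composite_metrics <- function(composite, label = NA_character_) {
  data.frame(
    label = label,
    n_lakes = composite$n_lakes,
    sa_c_km2 = composite$sa_c / 1e6,
    v_c_km3 = composite$v_c / 1e9,
    z_mean_c_m = composite$z_mean_c,
    z_max_c_m = composite$z_max_c,
    dr_c = composite$dr_c,
    fa_epi_c = composite$fa_epi_c,
    fv_epi_c = composite$fv_epi_c,
    epi_ratio_m = composite$epi_ratio,
    wt_mean_c = composite$wt_mean_c
  )
}

#' @export
plot.composite_lake <- function(x, relative = FALSE, ...) {
  a <- if (relative) x$area_c / x$sa_c else x$area_c
  plot(a, -x$depth_grid, type = "l",
       xlab = if (relative) "Relative area at depth" else "Area at depth (m2)",
       ylab = "Depth (m)", main = "Composite lake hypsography", ...)
  invisible(x)
}

#' Export composite curves as a data.frame
#'
#' Layer-resolved curve table for writing: depth at the top of each layer,
#' area and cumulative volume at that depth, layer area/volume and, when
#' present, isolated layer area/volume and the layer temperature.
#'
#' @param x A \code{composite_lake}.
#' @param ... Unused.
#' @return A data.frame with one row per grid depth.
#' @export
as.data.frame.composite_lake <- function(x, ...) {
  nz <- length(x$depth_grid)
  pad <- function(v) if (is.null(v)) rep(NA_real_, nz) else c(v, NA_real_)
  data.frame(
    depth_m = x$depth_grid,
    area_m2 = x$area_c,
    vol_below_m3 = x$vol_below_c,
    layer_area_m2 = pad(x$layer_area_c),
    layer_vol_m3 = pad(x$layer_vol_c),
    iso_area_m2 = pad(x$iso_layer_area),
    iso_vol_m3 = pad(x$iso_layer_vol),
    temp_c = pad(x$temp_c_z)
  )
}
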
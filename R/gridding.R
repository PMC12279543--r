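#' Assign centroids to 1-by-1 degree grid cells
#'
#' Maps lake centroid coordinates to the unit graticule cell containing
#' them, with the floor convention (south and west edges inclusive): cell
#' id is \code{(floor(lat), floor(lon))}. Latitude 90 maps to cell 89 and
#' longitude 180 to cell 179 so every valid coordinate has a cell.
#'
#' @param lat,lon Decimal degrees; \code{|lat| <= 90}, \code{|lon| <= 180}.
#' @return A data.frame with columns \code{cell_lat}, \code{cell_lon}
#'   (integers) and \code{cell_id} (string \code{"lat_lon"}).
#' @export
assign_cell <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(abs(lat) > 90) || any(abs(lon) > 180))
    stop("coordinate error: need |lat| <= 90 and |lon| <= 180")
  cl <- pmin(floor(lat), 89)
  cn <- pmin(floor(lon), 179)
  data.frame(cell_lat = as.integer(cl), cell_lon = as.integer(cn),
             cell_id = paste(as.integer(cl), as.integer(cn), sep = "_"))
}

#' One composite lake per group label
#'
#' Splits a lake table by a label column (a climate zone, glaciation class,
#' grid cell id, ...) and aggregates each group into its own composite
#' lake. Groups are exactly additive: the surface areas and volumes of the
#' per-group composites sum to those of the whole-collection composite.
#' Lakes with a missing label are excluded with a warning carrying the
#' count.
#'
#' @param lakes A lake table.
#' @param key Name of the label column.
#' @param dz Depth grid spacing (m).
#' @param thermal Optional per-lake thermal profiles (see
#'   \code{\link{composite_lake}}).
#' @return Named list of \code{composite_lake} objects, one per label value.
#' @export
group_composites <- function(lakes, key, dz = 0.5, thermal = NULL) {
  if (!inherits(lakes, "lake_table")) lakes <- as_lake_table(lakes)
  if (!(key %in% names(lakes))) stop("missing label column: ", key)
  lab <- lakes[[key]]
  miss <- is.na(lab) | lab == ""
  if (any(miss)) {
    warning(sum(miss), " lake(s) without '", key, "' label excluded")
    lakes <- lakes[!miss, , drop = FALSE]
    lab <- lab[!miss]
  }
  if (nrow(lakes) == 0L) stop("aggregation error: no labelled lakes")
  groups <- split(seq_len(nrow(lakes)), lab)
  lapply(groups, function(idx) {
    g <- lakes[idx, , drop = FALSE]
    class(g) <- c("lake_table", "data.frame")
    th <- if (is.null(thermal)) NULL else
      thermal[as.character(g$lake_id)]
    composite_lake(g, dz = dz, thermal = th)
  })
}

#' One composite lake per 1-by-1 degree grid cell
#'
#' Convenience wrapper: assigns every lake to its graticule cell from the
#' \code{lat}/\code{lon} columns and builds one composite per occupied
#' cell.
#'
#' @inheritParams group_composites
#' @return Named list of \code{composite_lake} objects keyed by cell id.
#' @export
grid_composites <- function(lakes, dz = 0.5, thermal = NULL) {
  if (!inherits(lakes, "lake_table")) lakes <- as_lake_table(lakes)
  if (!all(c("lat", "lon") %in% names(lakes)))
    stop("lake table needs lat and lon columns for gridding")
  lakes$cell_id <- assign_cell(lakes$lat, lakes$lon)$cell_id
  group_composites(lakes, "cell_id", dz = dz, thermal = thermal)
}
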
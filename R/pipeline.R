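#' Read a measured hypsographic curve CSV
#'
#' Columns \code{depth_m}, \code{area_m2}, \code{vol_below_m3}; depths must
#' be increasing from 0. Used for validating modelled curves.
#'
#' @param path CSV path.
#' @return A \code{hypso_curve} (layer fields from differences of the
#'   supplied grid; \code{dz} is the median spacing).
#' @export
read_curve <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("depth_m", "area_m2", "vol_below_m3")
  if (!all(need %in% names(df)))
    stop("format error: curve CSV needs columns ", paste(need, collapse = ", "))
  if (is.unsorted(df$depth_m, strictly = TRUE))
    stop("format error: depths must be strictly increasing")
  new_hypso_curve(df$depth_m, df$area_m2, df$vol_below_m3,
                  stats::median(diff(df$depth_m)))
}

#' Write a hypsographic or composite curve CSV
#'
#' @param x A \code{hypso_curve} or \code{composite_lake}.
#' @param path Output path.
#' @param header_comment Optional \code{#}-prefixed header lines.
#' @return \code{path}, invisibly.
#' @export
write_curve <- function(x, path, header_comment = NULL) {
  df <- if (inherits(x, "composite_lake")) as.data.frame(x) else
    data.frame(depth_m = x$depth_grid, area_m2 = x$area_at_depth,
               vol_below_m3 = x$volume_below)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read daily thermal series from a long-format CSV
#'
#' Columns \code{day}, \code{depth_m}, \code{temp_c}, \code{ice_m}, plus an
#' optional \code{lake_id} column when one file carries several lakes.
#' Day 366 (a leap day) is dropped.
#'
#' @param path CSV path.
#' @return A \code{\link{thermal_series}}, or a named list of them when a
#'   \code{lake_id} column is present.
#' @export
read_thermal_series <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("day", "depth_m", "temp_c", "ice_m")
  if (!all(need %in% names(df)))
    stop("format error: thermal CSV needs columns ", paste(need, collapse = ", "))
  df <- df[df$day <= 365, , drop = FALSE]
  build <- function(d) {
    zg <- sort(unique(d$depth_m))
    days <- sort(unique(d$day))
    tm <- matrix(NA_real_, length(days), length(zg))
    tm[cbind(match(d$day, days), match(d$depth_m, zg))] <- d$temp_c
    if (any(is.na(tm))) stop("format error: incomplete day x depth grid")
    ice <- vapply(days, function(dd) d$ice_m[d$day == dd][1], numeric(1))
    thermal_series(zg, tm, ice)
  }
  if ("lake_id" %in% names(df))
    lapply(split(df, df$lake_id), build)
  else
    build(df)
}

# Polynomial rolling hash of a deparsed object: a short reproducible
# config fingerprint (not cryptographic).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the composite-lake pipeline end to end
#'
#' Reads (or synthesizes) a lake population, optionally attaches schematic
#' thermal series run through the stratification stage, builds one
#' composite per group label (or one overall), and writes a metrics CSV, a
#' curve CSV per composite and a JSON manifest recording the seed and a
#' config fingerprint. Deterministic: rerunning the same configuration
#' reproduces the outputs byte for byte.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{lakes}{path to a lake CSV, or NULL to synthesize;}
#'     \item{population}{a \code{\link{population_config}} when synthesizing;}
#'     \item{thermal}{optional \code{\link{thermal_config}} to generate and
#'       apply schematic thermal series;}
#'     \item{dz}{grid spacing (m), default 0.5;}
#'     \item{group_key}{optional label column for per-group composites;}
#'     \item{out_dir}{output directory (created);}
#'     \item{seed}{integer seed, default 1.}
#'   }
#' @return Invisibly, a list with the metrics data.frame, the composites
#'   and the manifest.
#' @export
run_pipeline <- function(config) {
  dz <- config$dz %||% 0.5
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config error: out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  lakes <- if (!is.null(config$lakes)) {
    read_lake_table(config$lakes)
  } else {
    pc <- config$population %||% population_config(seed = seed)
    synth_population(pc)
  }

  thermal <- NULL
  if (!is.null(config$thermal)) {
    thermal <- lapply(seq_len(nrow(lakes)), function(i) {
      isolation_fraction(
        generate_thermal(lakes$zmax_m[i], config$thermal, dz = dz),
        z_max = lakes$zmax_m[i])
    })
    names(thermal) <- as.character(lakes$lake_id)
  }

  composites <- if (!is.null(config$group_key))
    group_composites(lakes, config$group_key, dz = dz, thermal = thermal)
  else
    list(all = composite_lake(lakes, dz = dz, thermal = thermal))

  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  hdr <- sprintf("seed=%d config=%s", seed, hash)
  metrics <- do.call(rbind, Map(composite_metrics, composites,
                                names(composites)))
  mpath <- file.path(out_dir, "metrics.csv")
  con <- file(mpath, "w"); writeLines(paste0("# ", hdr), con)
  utils::write.csv(metrics, con, row.names = FALSE); close(con)
  for (nm in names(composites))
    write_curve(composites[[nm]],
                file.path(out_dir, paste0("curve_", gsub("[^A-Za-z0-9_.-]", "_", nm), ".csv")),
                header_comment = hdr)
  manifest <- list(package = "lakecomposer",
                   version = as.character(utils::packageVersion("lakecomposer")),
                   seed = seed, config_hash = hash,
                   n_lakes = nrow(lakes), n_groups = length(composites))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(metrics = metrics, composites = composites,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
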
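#' Validate and complete a lake morphometry table
#'
#' A lake table is the atom collection of every aggregation: one row per
#' lake with columns \code{lake_id}, \code{area_m2}, \code{zmax_m}, and at
#' least one of \code{zmean_m} or \code{q}; optional \code{lat}, \code{lon}
#' and free label columns (region, climate zone, glaciation class, ...).
#' Missing \code{q} is filled from \eqn{q = Z_{max}/Z_{mean} - 1}; missing
#' \code{zmean_m} from \eqn{Z_{mean} = Z_{max}/(q+1)}. Rows violating the
#' invariants (non-positive area or depths, \code{zmean_m > zmax_m},
#' negative \code{q}, inconsistent \code{q} vs depths) are dropped and
#' reported via the \code{"rejected"} attribute.
#'
#' @param df A data.frame of lake records.
#' @return The validated data.frame with class \code{"lake_table"}, columns
#'   \code{lake_id}, \code{area_m2}, \code{zmax_m}, \code{zmean_m},
#'   \code{q} plus any extra input columns, and attribute \code{"rejected"}:
#'   a data.frame of dropped row numbers and reasons (empty if none).
#' @export
as_lake_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("lake_id", "area_m2", "zmax_m")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing required columns: ", paste(miss, collapse = ", "))
  if (!("zmean_m" %in% names(df)) && !("q" %in% names(df)))
    stop("format error: need zmean_m or q")
  if (!("q" %in% names(df))) df$q <- NA_real_
  if (!("zmean_m" %in% names(df))) df$zmean_m <- NA_real_

  reason <- character(nrow(df))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[cond & reason == ""] <<- why
  }
  bad(!is.finite(df$area_m2) | df$area_m2 <= 0, "non-positive area")
  bad(!is.finite(df$zmax_m) | df$zmax_m <= 0, "non-positive zmax")
  no_depth <- is.na(df$zmean_m) & is.na(df$q)
  bad(no_depth, "neither zmean nor q")
  bad(!is.na(df$zmean_m) & (df$zmean_m <= 0 | df$zmean_m > df$zmax_m * (1 + 1e-12)),
      "zmean out of (0, zmax]")
  bad(!is.na(df$q) & df$q < 0, "negative q")
  both <- !is.na(df$zmean_m) & !is.na(df$q) & reason == ""
  bad(both & abs(df$q - (df$zmax_m / df$zmean_m - 1)) >= 1e-9,
      "q inconsistent with zmax/zmean - 1")

  rejected <- data.frame(row = which(reason != ""),
                         lake_id = df$lake_id[reason != ""],
                         reason = reason[reason != ""])
  ok <- df[reason == "", , drop = FALSE]
  fill_q <- is.na(ok$q)
  ok$q[fill_q] <- pmax(ok$zmax_m[fill_q] / ok$zmean_m[fill_q] - 1, 0)
  fill_zm <- is.na(ok$zmean_m)
  ok$zmean_m[fill_zm] <- ok$zmax_m[fill_zm] / (ok$q[fill_zm] + 1)
  rownames(ok) <- NULL
  attr(ok, "rejected") <- rejected
  class(ok) <- c("lake_table", "data.frame")
  ok
}

#' Read a lake morphometry CSV
#'
#' Expects a header with at least \code{lake_id}, \code{area_m2},
#' \code{zmax_m} and one of \code{zmean_m} or \code{q}; extra columns
#' (\code{lat}, \code{lon}, labels) pass through. Invalid rows are dropped
#' with a warning carrying the rejection count; details are in the
#' \code{"rejected"} attribute of the result.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A \code{\link{as_lake_table}}-validated lake table.
#' @export
read_lake_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  out <- as_lake_table(df)
  rej <- attr(out, "rejected")
  if (nrow(rej) > 0)
    warning(sprintf("%d row(s) rejected: rows %s", nrow(rej),
                    paste(rej$row, collapse = ", ")))
  out
}

#' Write a lake table to CSV
#'
#' @param lakes A lake table.
#' @param path Output path.
#' @param header_comment Optional comment lines (e.g. seed, config hash)
#'   written as \code{#}-prefixed header lines.
#' @return \code{path}, invisibly.
#' @export
write_lake_table <- function(lakes, path, header_comment = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.csv(as.data.frame(lakes), con, row.names = FALSE)
  invisible(path)
}

# Internal: one lake_hypso per row (used where per-lake objects are handy).
lake_table_models <- function(lakes) {
  lapply(seq_len(nrow(lakes)), function(i)
    lake_hypso(lakes$area_m2[i], lakes$zmax_m[i], q = lakes$q[i],
               lake_id = as.character(lakes$lake_id[i])))
}
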
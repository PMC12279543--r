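#' Standardize a feature matrix
#'
#' Centres and scales each column to mean 0 and (sample) SD 1, keeping the
#' transformation parameters for the inverse transform. Constant columns
#' are degenerate for distance-based clustering and raise an error.
#'
#' @param x Numeric matrix or data.frame of composite features (rows:
#'   composites; columns: features such as \code{z_mean_c_m}, \code{dr_c},
#'   \code{fa_epi_c}).
#' @return Matrix with attributes \code{"center"} and \code{"scale"}.
#' @export
standardize_features <- function(x) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("feature matrix contains missing values")
  s <- apply(x, 2, stats::sd)
  if (any(s == 0)) stop("degenerate feature: zero-variance column")
  scale(x, center = TRUE, scale = s)
}

#' Ward (ward.D2) hierarchical clustering cut at k
#'
#' Agglomerative clustering of standardized features under the Ward
#' variance-minimization criterion on Euclidean distances (the ward.D2
#' variant squares pairwise distances at each merge), cut into \code{k}
#' groups.
#'
#' @param x Numeric matrix (rows clustered).
#' @param k Number of clusters, \code{1 <= k <= nrow(x)}.
#' @return Integer vector of cluster labels in \code{1..k}.
#' @export
ward_cluster <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1 || k > n) stop("parameter error: need 1 <= k <= n")
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' Select the number of clusters by mean silhouette
#'
#' Runs Ward (ward.D2) clustering over a range of candidate cluster counts
#' and keeps the one with the highest mean silhouette width (Euclidean
#' distances in the standardized feature space); ties go to the smallest
#' k. A maximum mean silhouette below \code{weak_threshold} flags the
#' clustering as weak (no real group structure).
#'
#' @param x Numeric matrix of (already standardized) features.
#' @param k_range Candidate cluster counts, each within \code{[2, n-1]}.
#'   Default \code{2:10}.
#' @param weak_threshold Mean-silhouette level below which the selected
#'   clustering is flagged weak. Default 0.25.
#' @return An object of class \code{"lake_clusters"}: list with
#'   \code{labels}, \code{k}, \code{silhouette} (data.frame of k vs mean
#'   silhouette), \code{weak} flag and the \code{hclust} merge history.
#' @export
silhouette_select <- function(x, k_range = 2:10, weak_threshold = 0.25) {
  x <- as.matrix(x)
  n <- nrow(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L) stop("parameter error: empty k_range")
  if (any(k_range < 2 | k_range > n - 1))
    stop("parameter error: k_range must lie within [2, n-1]")
  d <- stats::dist(x)
  hc <- stats::hclust(d, method = "ward.D2")
  sil <- vapply(k_range, function(k) {
    lab <- stats::cutree(hc, k = k)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, numeric(1))
  best <- k_range[which.max(sil)]  # which.max takes the first maximum: smallest k wins ties
  structure(
    list(labels = stats::cutree(hc, k = best),
         k = best,
         silhouette = data.frame(k = k_range, mean_silhouette = sil),
         weak = max(sil) < weak_threshold,
         hclust = hc),
    class = "lake_clusters"
  )
}

#' @export
print.lake_clusters <- function(x, ...) {
  cat("Ward (ward.D2) clustering:", length(x$labels), "composites, k =",
      x$k, if (x$weak) "(weak structure)" else "", "\n")
  print(x$silhouette, row.names = FALSE)
  invisible(x)
}

#' Cluster grid-cell composites on the standard feature triplet
#'
#' End-to-end helper: extracts \code{z_mean_c_m}, \code{dr_c} and
#' \code{fa_epi_c} from a list of composites, standardizes them and selects
#' the cluster count by silhouette.
#'
#' @param composites Named list of \code{composite_lake} objects (with
#'   epilimnetic metrics populated).
#' @param k_range Candidate cluster counts.
#' @return A \code{\link{silhouette_select}} result with a \code{features}
#'   element (the unstandardized feature data.frame, rownames = composite
#'   names).
#' @export
cluster_composites <- function(composites, k_range = 2:10) {
  feats <- do.call(rbind, lapply(composites, function(cl)
    data.frame(z_mean_c_m = cl$z_mean_c, dr_c = cl$dr_c,
               fa_epi_c = cl$fa_epi_c)))
  rownames(feats) <- names(composites)
  keep <- stats::complete.cases(feats)
  res <- silhouette_select(standardize_features(feats[keep, ]), k_range)
  res$features <- feats[keep, ]
  res
}
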
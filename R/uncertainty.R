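#' Morphometric error model for Monte Carlo propagation
#'
#' Perturbations are additive Gaussian noise applied in cube-root space
#' (the transform that makes morphometric prediction errors close to
#' normal): \eqn{Z_{max}' = (Z_{max}^{1/3} + \varepsilon_1)^3} and
#' \eqn{q' = \max(0, (q^{1/3} + \varepsilon_2)^3)}, with mean depth
#' recomputed as \eqn{Z_{max}'/(q'+1)}. Draws for the two parameters are
#' independent by default; \code{correlation} couples them.
#'
#' @param sd_zmax_cuberoot SD of the noise on \code{z_max^(1/3)}.
#' @param sd_q_cuberoot SD of the noise on \code{q^(1/3)}.
#' @param n_iter Monte Carlo iterations.
#' @param seed Integer base seed.
#' @param correlation Correlation between the two error draws, in [-1, 1].
#' @return A list of class \code{"error_model"}.
#' @export
error_model <- function(sd_zmax_cuberoot = 0.1, sd_q_cuberoot = 0.1,
                        n_iter = 100, seed = 1L, correlation = 0) {
  if (sd_zmax_cuberoot < 0 || sd_q_cuberoot < 0)
    stop("error SDs must be >= 0")
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (abs(correlation) > 1) stop("correlation must be in [-1, 1]")
  structure(list(sd_zmax_cuberoot = sd_zmax_cuberoot,
                 sd_q_cuberoot = sd_q_cuberoot,
                 n_iter = as.integer(n_iter), seed = as.integer(seed),
                 correlation = correlation),
            class = "error_model")
}

# One deterministic sub-seed per (seed, iteration), kept within 32-bit range.
seed_for_iteration <- function(seed, iteration) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(iteration) * 16807) %%
               2147483629)
}

#' Perturb a lake collection under the error model
#'
#' Applies one Monte Carlo draw of the cube-root-space error model to every
#' lake. The random stream is fixed by \code{(model$seed, iteration)} and
#' draws are made in lake-id order, so the same lake receives the same
#' perturbation regardless of row order. Draws pushing \code{z_max} to zero
#' or below are rejected and redrawn (preserving the distribution shape
#' near zero); \code{q} is clamped at zero.
#'
#' @param lakes A lake table.
#' @param model An \code{\link{error_model}}.
#' @param iteration Iteration index (changes the stream).
#' @return The perturbed lake table, with attribute \code{"rejections"}
#'   counting redraws.
#' @export
perturb <- function(lakes, model, iteration = 1L) {
  if (!inherits(lakes, "lake_table")) lakes <- as_lake_table(lakes)
  stopifnot(inherits(model, "error_model"))
  n <- nrow(lakes)
  ord <- order(as.character(lakes$lake_id))
  set.seed(seed_for_iteration(model$seed, iteration))
  e1 <- stats::rnorm(n)
  e2 <- model$correlation * e1 +
    sqrt(1 - model$correlation^2) * stats::rnorm(n)
  zc <- lakes$zmax_m[ord]^(1 / 3) + model$sd_zmax_cuberoot * e1
  rejections <- 0L
  bad <- which(zc <= 0)
  while (length(bad)) {
    rejections <- rejections + length(bad)
    zc[bad] <- lakes$zmax_m[ord][bad]^(1 / 3) +
      model$sd_zmax_cuberoot * stats::rnorm(length(bad))
    bad <- bad[zc[bad] <= 0]
  }
  qc <- lakes$q[ord]^(1 / 3) + model$sd_q_cuberoot * e2
  out <- lakes
  out$zmax_m[ord] <- zc^3
  out$q[ord] <- pmax(qc, 0)^3
  out$zmean_m <- out$zmax_m / (out$q + 1)
  attr(out, "rejections") <- rejections
  out
}

# Composite area at given depths without building the full curve object.
composite_area_at <- function(lakes, depths) {
  rel <- 1 - outer(1 / lakes$zmax_m, depths)
  dry <- rel <= 0
  rel[dry] <- 0
  a <- lakes$area_m2 * rel^lakes$q
  a[dry] <- 0
  colSums(a)
}

#' Monte Carlo propagation of morphometric uncertainty
#'
#' Re-perturbs the collection \code{model$n_iter} times, rebuilds the
#' composite each time, and summarizes the spread: 2.5/50/97.5% quantiles
#' of the composite volume, mean depth and dynamic ratio, and the
#' per-depth relative error of the composite area at depth, defined as
#' SD across draws divided by the mean across draws.
#'
#' @param lakes A lake table.
#' @param model An \code{\link{error_model}}.
#' @param dz Depth grid spacing (m) for the area-at-depth profile.
#' @return An object of class \code{"lake_uncertainty"}: list with
#'   \code{quantiles} (data.frame metric x 2.5/50/97.5%), \code{depth_error}
#'   (data.frame depth_m, rel_error), \code{point} (unperturbed metrics),
#'   \code{n_iter} and \code{rejections}.
#' @export
propagate <- function(lakes, model, dz = 0.5) {
  if (!inherits(lakes, "lake_table")) lakes <- as_lake_table(lakes)
  if (model$n_iter < 2) stop("n_iter must be >= 2 for quantiles")
  point <- composite_lake(lakes, dz = dz)
  # grid generous enough to hold perturbed maximum depths
  zg <- depth_grid_for(point$z_max_c *
                         (1 + 6 * model$sd_zmax_cuberoot)^3, dz)
  nit <- model$n_iter
  v_c <- z_mean <- dr <- numeric(nit)
  areas <- matrix(0, nit, length(zg))
  rejections <- 0L
  for (it in seq_len(nit)) {
    p <- perturb(lakes, model, iteration = it)
    rejections <- rejections + attr(p, "rejections")
    v_c[it] <- sum(p$area_m2 * p$zmax_m / (p$q + 1))
    z_mean[it] <- v_c[it] / point$sa_c
    dr[it] <- sqrt(point$sa_c / 1e6) / z_mean[it]
    areas[it, ] <- composite_area_at(p, zg)
  }
  qs <- function(x) stats::quantile(x, c(0.025, 0.5, 0.975))
  quantiles <- rbind(v_c_m3 = qs(v_c), z_mean_c_m = qs(z_mean), dr_c = qs(dr))
  mu <- colMeans(areas)
  rel <- ifelse(mu > 0, apply(areas, 2, stats::sd) / mu, NA_real_)
  structure(
    list(quantiles = as.data.frame(quantiles),
         depth_error = data.frame(depth_m = zg, rel_error = rel),
         point = composite_metrics(point),
         n_iter = nit, rejections = rejections),
    class = "lake_uncertainty"
  )
}

#' @export
print.lake_uncertainty <- function(x, ...) {
  cat("Monte Carlo uncertainty propagation,", x$n_iter, "iterations",
      sprintf("(%d rejected draws)\n", x$rejections))
  print(round(x$quantiles, 4))
  invisible(x)
}

#' Relative error of composite area vs aggregation size
#'
#' Demonstrates the aggregation behaviour of morphometric errors: for each
#' collection size \code{n}, the first \code{n} lakes of the population are
#' aggregated under repeated Monte Carlo perturbation and the relative
#' error (SD/mean across draws) of the composite area is evaluated at a
#' near-surface reference depth and near the deepest depth of the subset.
#' Aggregated area grows faster than its error, so the surface-layer
#' relative error declines with \code{n}, while the deep reference depth -
#' fed by fewer lakes under the Pareto size law - carries a larger error.
#'
#' @param population A lake table (ordering defines the nested subsets).
#' @param model An \code{\link{error_model}}.
#' @param sizes Aggregation sizes, each at most \code{nrow(population)}.
#' @param dz Grid spacing used for the near-surface reference depth (m).
#' @param deep_frac Deep reference depth as a fraction of the subset's
#'   maximum depth. Default 0.9.
#' @return A data.frame with one row per (size, reference depth):
#'   columns \code{n}, \code{layer} ("surface"/"deep"), \code{depth_m},
#'   \code{rel_error}.
#' @export
error_vs_aggregation <- function(population, model, sizes = c(1, 10, 100, 1000),
                                 dz = 0.5, deep_frac = 0.9) {
  if (!inherits(population, "lake_table"))
    population <- as_lake_table(population)
  if (any(sizes > nrow(population)))
    stop("sizes exceed the population size")
  out <- do.call(rbind, lapply(sizes, function(n) {
    sub <- population[seq_len(n), , drop = FALSE]
    class(sub) <- c("lake_table", "data.frame")
    depths <- c(surface = dz, deep = deep_frac * max(sub$zmax_m))
    draws <- matrix(0, model$n_iter, 2L)
    for (it in seq_len(model$n_iter))
      draws[it, ] <- composite_area_at(perturb(sub, model, iteration = it),
                                       depths)
    mu <- colMeans(draws)
    rel <- ifelse(mu > 0, apply(draws, 2, stats::sd) / mu, NA_real_)
    data.frame(n = n, layer = c("surface", "deep"),
               depth_m = unname(depths), rel_error = rel)
  }))
  rownames(out) <- NULL
  out
}
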
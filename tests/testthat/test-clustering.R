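# Independent Lance-Williams agglomerator for the ward.D2 criterion:
# squared Euclidean distances, merge the closest pair, update
# d2(k, i+j) = ((n_i+n_k) d2_ki + (n_j+n_k) d2_kj - n_k d2_ij) / (n_i+n_j+n_k).
lw_ward2 <- function(x, stop_at = 1) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  diag(d2) <- Inf
  sizes <- rep(1, n)
  active <- rep(TRUE, n)
  heights <- numeric(n - stop_at)
  members <- as.list(seq_len(n))
  for (s in seq_len(n - stop_at)) {
    idx <- which(active)
    sub <- d2[idx, idx, drop = FALSE]
    pos <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- idx[min(pos)]; j <- idx[max(pos)]
    heights[s] <- sqrt(d2[i, j])
    for (k in idx) {
      if (k == i || k == j) next
      d2[i, k] <- d2[k, i] <-
        ((sizes[i] + sizes[k]) * d2[k, i] + (sizes[j] + sizes[k]) * d2[k, j] -
           sizes[k] * d2[i, j]) / (sizes[i] + sizes[j] + sizes[k])
    }
    sizes[i] <- sizes[i] + sizes[j]
    members[[i]] <- c(members[[i]], members[[j]])
    active[j] <- FALSE
    d2[j, ] <- d2[, j] <- Inf
  }
  labels <- integer(n)
  for (g in seq_along(which(active)))
    labels[members[[which(active)[g]]]] <- g
  list(heights = sort(heights), labels = labels)
}

blobs <- function(centers, n_per, sd, seed) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
  list(x = x, truth = rep(seq_len(nrow(centers)), each = n_per))
}

# label-permutation-free comparison of two partitions
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

test_that("standardization centres and scales, keeping parameters", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 30, 50))
  s <- standardize_features(m)
  expect_equal(unname(s[, "a"]), c(-1, 0, 1))
  expect_equal(unname(colMeans(s)), c(0, 0))
  expect_equal(unname(apply(s, 2, sd)), c(1, 1))
  # location invariance: shifting a column leaves standardized values alone
  expect_equal(standardize_features(m + 100)[, "a"], s[, "a"],
               ignore_attr = TRUE)
  expect_error(standardize_features(cbind(c(1, 1, 1), c(1, 2, 3))),
               "degenerate feature")
  set.seed(4)
  r <- standardize_features(matrix(rnorm(60), 20))
  expect_true(all(abs(colMeans(r)) < 1e-9))
  expect_true(all(abs(apply(r, 2, sd) - 1) < 1e-9))
})

test_that("ward.D2 merge heights match the Lance-Williams hand computation", {
  set.seed(31)
  x <- matrix(rnorm(16), 8, 2)
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  oracle <- lw_ward2(x)
  expect_equal(sort(hc$height), oracle$heights, tolerance = 1e-9)
  # partitions at k = 2 agree up to label permutation
  expect_true(same_partition(ward_cluster(x, 2), lw_ward2(x, stop_at = 2)$labels))
})

test_that("ward cluster boundary cases", {
  set.seed(32)
  x <- matrix(rnorm(20), 10, 2)
  expect_equal(sort(unique(ward_cluster(x, 10))), 1:10)  # k = n: singletons
  expect_error(ward_cluster(x, 11), "parameter error")
  b <- blobs(rbind(c(0, 0), c(10, 10)), 10, 0.2, seed = 33)
  expect_true(same_partition(ward_cluster(b$x, 2), b$truth))
})

test_that("silhouette selection recovers the planted number of blobs", {
  b3 <- blobs(rbind(c(0, 0), c(6, 0), c(0, 6)), 25, 0.4, seed = 34)
  res3 <- silhouette_select(standardize_features(b3$x), 2:8)
  expect_equal(res3$k, 3)
  expect_false(res3$weak)
  expect_true(same_partition(res3$labels, b3$truth))

  b2 <- blobs(rbind(c(0, 0), c(7, 3)), 30, 0.5, seed = 35)
  res2 <- silhouette_select(standardize_features(b2$x), 2:8)
  expect_equal(res2$k, 2)

  # a single blob has no real structure: silhouettes stay in the weak band
  # (well below the ~0.7+ of genuinely separated groups) at every k
  set.seed(36)
  one <- matrix(rnorm(120), 60, 2)
  res1 <- silhouette_select(standardize_features(one), 2:5)
  expect_lt(max(res1$silhouette$mean_silhouette), 0.5)
  expect_lt(max(res1$silhouette$mean_silhouette),
            max(res3$silhouette$mean_silhouette) / 1.5)
  expect_true(silhouette_select(standardize_features(one), 2:5,
                                weak_threshold = 0.5)$weak)
  expect_error(silhouette_select(one, integer(0)), "parameter error")
})

test_that("composite feature clustering runs end to end", {
  # two synthetic regions with very different morphometry
  shallow <- synth_population(population_config(n_lakes = 80, depth_c = 0.05,
                                                seed = 41))
  deep <- synth_population(population_config(n_lakes = 80, depth_c = 2,
                                             seed = 42))
  comps <- list()
  th_cfg <- thermal_config(strat_days = 150, therm_frac = 0.3)
  for (nm in paste0("cell", 1:6)) {
    src <- if (nm %in% paste0("cell", 1:3)) shallow else deep
    idx <- ((match(nm, paste0("cell", 1:6)) - 1) %% 3) * 25 + 1:25
    sub <- src[idx, ]
    class(sub) <- c("lake_table", "data.frame")
    th <- lapply(seq_len(nrow(sub)), function(i)
      isolation_fraction(generate_thermal(sub$zmax_m[i], th_cfg),
                         z_max = sub$zmax_m[i]))
    names(th) <- as.character(sub$lake_id)
    comps[[nm]] <- composite_lake(sub, dz = 0.5, thermal = th)
  }
  res <- cluster_composites(comps, k_range = 2:4)
  expect_equal(res$k, 2)
  expect_true(same_partition(res$labels, rep(1:2, each = 3)))
})
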
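test_that("single-lake composite reproduces the lake's own curve", {
  lk <- cone_lake()
  tab <- as_lake_table(data.frame(lake_id = "cone", area_m2 = 100,
                                  zmax_m = 10, q = 2))
  cl <- composite_lake(tab, dz = 0.5)
  cv <- discretize(lk, dz = 0.5)
  expect_equal(cl$area_c, cv$area_at_depth)
  expect_equal(cl$vol_below_c, cv$volume_below)
  expect_equal(cl$layer_vol_c, cv$layer_volume)
  expect_equal(cl$z_mean_c, lk$z_mean)
})

test_that("two-lake closed-form sums and metric block", {
  cl <- composite_lake(two_lake_table(), dz = 0.5)
  expect_equal(cl$sa_c, 150)
  expect_equal(cl$v_c, 433 + 1 / 3, tolerance = 1e-12)
  expect_equal(cl$z_mean_c, 433.3333 / 150, tolerance = 1e-6)
  expect_equal(cl$z_max_c, 10)
  expect_equal(cl$n_lakes, 2)
  expect_equal(cl$dr_c, sqrt(150 / 1e6) / cl$z_mean_c)
  expect_error(composite_lake(two_lake_table()[0, ]), "empty")
})

test_that("aggregation equals brute-force per-lake summation", {
  lakes <- random_lake_table(1000, seed = 7)
  cl <- composite_lake(lakes, dz = 0.5)
  models <- lakecomposer:::lake_table_models(lakes)
  brute <- Reduce(`+`, lapply(models, function(m)
    area_at_depth(m, cl$depth_grid)))
  expect_equal(cl$area_c, brute, tolerance = 1e-9)
  brute_v <- Reduce(`+`, lapply(models, function(m)
    volume_below(m, cl$depth_grid)))
  expect_equal(cl$vol_below_c, brute_v, tolerance = 1e-9)
  expect_equal(cl$v_c, sum(vapply(models, total_volume, numeric(1))),
               tolerance = 1e-9)
})

test_that("aggregation is associative over sub-collections", {
  lakes <- random_lake_table(60, seed = 9)
  whole <- composite_lake(lakes, dz = 0.5)
  split1 <- lakes[1:25, ]; split2 <- lakes[26:60, ]
  class(split1) <- class(split2) <- c("lake_table", "data.frame")
  c1 <- composite_lake(split1, dz = 0.5)
  c2 <- composite_lake(split2, dz = 0.5)
  expect_equal(whole$sa_c, c1$sa_c + c2$sa_c)
  expect_equal(whole$v_c, c1$v_c + c2$v_c)
  # shared grid: pad the shallower composite's curve with zeros
  pad <- function(x, n) c(x, rep(0, n - length(x)))
  n <- length(whole$depth_grid)
  expect_equal(whole$area_c, pad(c1$area_c, n) + pad(c2$area_c, n))
})

test_that("composite mean depth differs from the mean of member depths", {
  lakes <- random_lake_table(50, seed = 3)
  cl <- composite_lake(lakes)
  expect_gt(abs(cl$z_mean_c - mean(lakes$zmean_m)), 0.5)
  # but equals the area-weighted mean by the volume identity
  expect_equal(cl$z_mean_c,
               sum(lakes$area_m2 * lakes$zmean_m) / sum(lakes$area_m2))
})

make_thermal <- function(lakes, f_iso_fun, t_fun) {
  th <- lapply(seq_len(nrow(lakes)), function(i) {
    zg <- seq(0, lakes$zmax_m[i] + 1, by = 0.5)
    data.frame(depth_m = zg, f_iso = f_iso_fun(zg, i), t_mean_c = t_fun(zg, i))
  })
  names(th) <- as.character(lakes$lake_id)
  th
}

test_that("volume-weighted temperature: invariance and brute force", {
  lakes <- random_lake_table(50, seed = 5)
  # all lakes isothermal at 11 degC: weighting cannot change the mean
  th <- make_thermal(lakes, function(z, i) rep(0, length(z)),
                     function(z, i) rep(11, length(z)))
  cl <- composite_lake(lakes, dz = 0.5, thermal = th)
  expect_equal(cl$wt_mean_c, 11)
  expect_true(all(abs(cl$temp_c_z[is.finite(cl$temp_c_z)] - 11) < 1e-9))

  # heterogeneous per-lake constant temperatures: brute-force double sum
  set.seed(5); temps <- runif(nrow(lakes), 2, 25)
  th2 <- make_thermal(lakes, function(z, i) rep(0, length(z)),
                      function(z, i) rep(temps[i], length(z)))
  cl2 <- composite_lake(lakes, dz = 0.5, thermal = th2)
  models <- lakecomposer:::lake_table_models(lakes)
  dv <- sapply(models, function(m) {
    v <- volume_below(m, cl2$depth_grid); -diff(v)
  })
  t_c_oracle <- as.vector(dv %*% temps) / rowSums(dv)
  ok <- rowSums(dv) > 0
  expect_equal(cl2$temp_c_z[ok], t_c_oracle[ok], tolerance = 1e-9)
  wt_oracle <- sum(t_c_oracle[ok] * rowSums(dv)[ok]) / cl2$v_c
  expect_equal(cl2$wt_mean_c, wt_oracle, tolerance = 1e-9)
})

test_that("two equal volumes at 10 and 20 degC average to 15", {
  # two cylinders of equal volume, one fully 10 degC, one fully 20 degC
  lakes <- as_lake_table(data.frame(lake_id = c("x", "y"),
                                    area_m2 = c(100, 100),
                                    zmax_m = c(8, 8), q = c(0, 0)))
  th <- make_thermal(lakes, function(z, i) rep(0, length(z)),
                     function(z, i) rep(c(10, 20)[i], length(z)))
  cl <- composite_lake(lakes, dz = 0.5, thermal = th)
  expect_equal(cl$wt_mean_c, 15)
})

test_that("isolated layers: limits and brute-force weighted sums", {
  lakes <- random_lake_table(30, seed = 8)
  th0 <- make_thermal(lakes, function(z, i) rep(0, length(z)),
                      function(z, i) rep(10, length(z)))
  cl0 <- composite_lake(lakes, dz = 0.5, thermal = th0)
  expect_equal(sum(cl0$iso_layer_area), 0)
  expect_equal(cl0$fa_epi_c, 1)
  expect_equal(cl0$fv_epi_c, 1)
  # never isolated: mean epilimnion thickness reduces to Z_meanC
  expect_equal(cl0$epi_ratio, cl0$z_mean_c)

  th1 <- make_thermal(lakes, function(z, i) rep(1, length(z)),
                      function(z, i) rep(10, length(z)))
  cl1 <- composite_lake(lakes, dz = 0.5, thermal = th1)
  expect_equal(cl1$iso_layer_area, cl1$layer_area_c, tolerance = 1e-12)
  expect_equal(cl1$fa_epi_c, 0)
  expect_equal(cl1$fv_epi_c, 0)
  expect_true(is.na(cl1$epi_ratio))

  # mixed depth-dependent profiles vs brute force
  set.seed(8); depths_iso <- runif(nrow(lakes), 0, 30)
  thm <- make_thermal(lakes,
                      function(z, i) as.numeric(z > depths_iso[i]) * 0.8,
                      function(z, i) rep(10, length(z)))
  clm <- composite_lake(lakes, dz = 0.5, thermal = thm)
  models <- lakecomposer:::lake_table_models(lakes)
  zm <- clm$depth_grid[-length(clm$depth_grid)] + 0.25
  iso_a_oracle <- Reduce(`+`, lapply(seq_along(models), function(i) {
    a <- area_at_depth(models[[i]], clm$depth_grid)
    fi <- approx(thm[[i]]$depth_m, thm[[i]]$f_iso, zm, rule = 2)$y
    fi * (-diff(a))
  }))
  expect_equal(clm$iso_layer_area, iso_a_oracle, tolerance = 1e-9)
  expect_error(
    composite_lake(lakes, dz = 0.5,
                   thermal = make_thermal(lakes,
                                          function(z, i) rep(1.5, length(z)),
                                          function(z, i) rep(10, length(z)))),
    "f_iso")
})

test_that("epilimnetic fractions are dA/dV-weighted means of member values", {
  lakes <- random_lake_table(20, seed = 13)
  set.seed(13); fvals <- runif(nrow(lakes))
  th <- make_thermal(lakes, function(z, i) rep(fvals[i], length(z)),
                     function(z, i) rep(10, length(z)))
  cl <- composite_lake(lakes, dz = 0.5, thermal = th)
  # per-lake fA_Epi = 1 - f_iso (depth-constant profile); composite value
  # is the surface-area-weighted mean, volume fraction the volume-weighted
  expect_equal(cl$fa_epi_c,
               sum((1 - fvals) * lakes$area_m2) / sum(lakes$area_m2),
               tolerance = 1e-9)
  vols <- lakes$area_m2 * lakes$zmax_m / (lakes$q + 1)
  expect_equal(cl$fv_epi_c, sum((1 - fvals) * vols) / sum(vols),
               tolerance = 1e-9)
})

test_that("printed-value identities for the composite metric helpers", {
  # global composite: V_C / SA_C in m
  expect_equal(composite_mean_depth(163117 * 1e9, 2408550 * 1e6), 67.7,
               tolerance = 0.01)
  expect_equal(dynamic_ratio(1154794, 24.0), 44.8, tolerance = 0.01)
  expect_equal(dynamic_ratio(1, 1), 1)
})
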
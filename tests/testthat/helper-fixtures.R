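# Shared fixtures: small deterministic lake sets and quadrature oracles.

cone_lake <- function() lake_hypso(100, 10, q = 2, lake_id = "cone")

two_lake_table <- function() {
  as_lake_table(data.frame(
    lake_id = c("a", "b"),
    area_m2 = c(100, 50),
    zmax_m = c(10, 4),
    zmean_m = c(10 / 3, 2)))
}

# Trapezoidal integration of the depth-area model, the independent oracle
# for the closed-form volume expressions.
trapz_volume <- function(sa, z_max, q, from = 0, to = z_max, dz = 0.001) {
  z <- seq(from, to, by = dz)
  # left limit at the bottom (0^0 = 1 keeps the cylinder integrand exact)
  a <- sa * pmax(1 - z / z_max, 0)^q
  sum((a[-1] + a[-length(a)]) / 2) * dz
}

random_lake_table <- function(n, seed = 42) {
  set.seed(seed)
  as_lake_table(data.frame(
    lake_id = sprintf("lk%04d", seq_len(n)),
    area_m2 = exp(runif(n, log(1e3), log(1e7))),
    zmax_m = runif(n, 1, 60),
    q = rlnorm(n, log(2), 0.5)))
}
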
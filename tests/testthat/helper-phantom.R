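# Shared fixtures: small, fast configurations used across test files.

default_sat <- function(...) saturation_params(...)

two_pool <- function(fraction = 0.002) {
  pool_system(pool_water(), pool_amine(proton_fraction = fraction))
}

three_pool <- function() {
  pool_system(pool_water(t1 = 1.4, t2 = 0.075),
              pool_amine(0.002),
              pool("mt", 0.05, -2.4, 40, 1.0, 1e-5))
}

small_config <- function(seed = 101L, ...) {
  phantom_config(matrix_size = c(32, 16), n_control = 2, n_fatigue = 2,
                 snr = Inf, seed = seed, ...)
}

# Rician-corrupted magnitude signals for Monte-Carlo fitting tests
rician_stack <- function(clean, n_voxels, sigma, seed) {
  set.seed(seed)
  t(replicate(n_voxels,
              sqrt((clean + rnorm(length(clean), 0, sigma))^2 +
                     rnorm(length(clean), 0, sigma)^2)))
}

ti7 <- round(exp(seq(log(100), log(7500), length.out = 7)))
te5 <- seq(40, 400, length.out = 5)
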
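test_that("unsaturated or water-only systems behave as physics demands", {
  sat0 <- saturation_params(b1_amplitude = 0)
  z0 <- simulate_zspectrum(pool_system(pool_water()), sat0)
  expect_lt(max(abs(z0 - 1)), 1e-9)

  # single on-resonance pool: spectrum is an even function of offset
  sat <- default_sat()
  zw <- simulate_zspectrum(pool_system(pool_water()), sat)
  expect_lt(max(abs(zw - rev(zw))), 1e-9)

  glu <- unname(zw[abs(sat$offsets + 3) < 1e-6] -
                  zw[abs(sat$offsets - 3) < 1e-6])
  expect_equal(glu, 0, tolerance = 1e-9)
})

test_that("Z stays in [0, 1] for physical pool systems", {
  sat <- default_sat()
  for (ps in list(pool_system(pool_water()), two_pool(), three_pool(),
                  two_pool(0.01))) {
    z <- simulate_zspectrum(ps, sat)
    expect_gte(min(z), -1e-9)
    expect_lte(max(z), 1 + 1e-9)
  }
})

test_that("amine pool produces a downfield dip deepening with concentration", {
  sat <- default_sat()
  z <- simulate_zspectrum(two_pool(), sat, offsets = c(-3, 3))
  expect_lt(z[2], z[1])  # Z(+3) < Z(-3)

  fracs <- c(0, 0.0005, 0.002, 0.005, 0.01)
  dips <- vapply(fracs, function(f) {
    z <- simulate_zspectrum(two_pool(f), sat, offsets = c(-3, 3))
    unname(z[1] - z[2])
  }, numeric(1))
  expect_true(all(diff(dips) >= -1e-12))
  expect_equal(dips[1], 0, tolerance = 1e-9)
})

test_that("matrix-exponential and fine-step RK4 integrators agree", {
  sat <- default_sat()
  off <- seq(-5, 5, by = 1)  # coarse grid for speed; full grid in acceptance
  z1 <- simulate_zspectrum(three_pool(), sat, offsets = off)
  z2 <- simulate_zspectrum(three_pool(), sat, offsets = off, method = "rk4")
  expect_lt(max(abs(z1 - z2)), 1e-6)
})

test_that("a B0 shift is equivalent to translating the offset grid", {
  sat <- default_sat()
  delta <- 0.4
  za <- simulate_zspectrum(two_pool(), sat, b0_shift = delta)
  zb <- simulate_zspectrum(two_pool(), sat,
                           offsets = round(sat$offsets - delta, 10))
  expect_equal(unname(za), unname(zb), tolerance = 1e-10)
})

test_that("invalid pools and offsets are rejected", {
  expect_error(pool("w", 1, 0, 0, t1 = -1, t2 = 0.1), "positive")
  expect_error(pool("w", 1, 0, 0, t1 = 0.5, t2 = 0.8), "t2")
  expect_error(pool("a", -0.1, 3, 100, 1, 0.01), "proton_fraction")
  expect_error(pool_system(pool_amine()), "water")
  expect_error(simulate_zspectrum(two_pool(), default_sat(),
                                  offsets = c(1, 0.5, 2)),
               "increasing")
  expect_error(saturation_params(offsets = c(1, 1, 2)), "increasing")
  expect_error(saturation_params(duration = 0), "duration")
})

test_that("phantom study is reproducible and recovers noiseless ground truth", {
  cfg <- small_config()
  st1 <- build_phantom_study(cfg)
  st2 <- build_phantom_study(cfg)
  expect_identical(st1, st2)

  # different seed changes the noise fields
  st3 <- build_phantom_study(small_config(seed = 102L))
  expect_false(identical(st1$subjects[[1]]$b0_ppm_truth,
                         st3$subjects[[1]]$b0_ppm_truth))

  # noiseless T1 recovery to <= 0.1% inside the brain
  s <- st1$subjects[[1]]
  wh <- st1$rois$labels > 0
  ft1 <- fit_t1_inversion_recovery(s$ir, cfg$ti_ms, mask = wh)
  truth <- st1$truth$t1_ms
  err <- abs(ft1$map$data[ft1$map$mask] / truth[ft1$map$mask] - 1)
  expect_lt(max(err), 0.001)
})

test_that("designed group contrast difference survives noise across seeds", {
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    cfg <- phantom_config(matrix_size = c(24, 12), n_control = 1,
                          n_fatigue = 1, snr = 50, seed = 200L + r)
    st <- build_phantom_study(cfg)
    wh <- st$rois$labels > 0
    means <- vapply(st$subjects, function(s) {
      z <- assemble_zspectrum(s$cest, cfg$sat$offsets, s$i0, mask = wh)
      b0 <- b0_map_dual_echo(s$phase1, s$phase2, cfg$delta_te_s)
      glu <- compute_glucest(correct_b0(z, b0))
      mean(glu$data[glu$mask])
    }, numeric(1))
    grp <- vapply(st$subjects, `[[`, character(1), "group")
    if (mean(means[grp == "FATIGUE"]) > mean(means[grp == "CTL"]))
      hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * n_rep))
})

test_that("phantom config validation rejects bad inputs", {
  expect_error(phantom_config(n_control = 0), "counts")
  expect_error(phantom_config(snr = -2), "snr")
})

test_that("activity generator is seeded and respects the dip model", {
  a1 <- generate_activity_series(seed = 33L)
  a2 <- generate_activity_series(seed = 33L)
  expect_identical(a1, a2)
  expect_setequal(unique(a1$night_index), c(-3:-1, 1:4))

  # null model: no dip leaves the normalized post-night-1 mean near 1
  null <- normalize_activity(generate_activity_series(
    n_animals = 200, dip = 1, seed = 5L))
  m1 <- mean(null$normalized[null$night_index == 1])
  expect_equal(m1, 1, tolerance = 0.05)

  # designed dip: normalized post-night-1 mean near the dip factor
  dipped <- normalize_activity(generate_activity_series(
    n_animals = 200, dip = 0.5, seed = 6L))
  expect_equal(mean(dipped$normalized[dipped$night_index == 1]), 0.5,
               tolerance = 0.05)

  expect_error(generate_activity_series(dip = 0), "dip")
  expect_error(generate_activity_series(n_nights = 5), "nights")
})
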
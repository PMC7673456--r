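make_disc_i0 <- function(nr = 24, nc = 20, r = 7) {
  x <- matrix(seq_len(nr), nr, nc)
  y <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  disc <- (x - nr / 2)^2 + (y - nc / 2)^2 <= r^2
  i0 <- matrix(0.02, nr, nc)
  i0[disc] <- 1
  list(i0 = i0, disc = disc)
}

test_that("brain masking finds a bright disc and rejects empty images", {
  d <- make_disc_i0()
  m <- mask_brain(d$i0)
  expect_true(all(m[d$disc]))
  expect_false(any(m[!d$disc]))
  expect_error(mask_brain(matrix(0, 8, 8)), "empty mask")
})

test_that("phantom brain mask covers the ground-truth region under noise", {
  cfg <- phantom_config(matrix_size = c(48, 24), n_control = 1,
                        n_fatigue = 1, snr = 50, seed = 77L)
  st <- build_phantom_study(cfg)
  m <- mask_brain(st$subjects[[1]]$i0)
  wh <- st$rois$labels > 0
  expect_gte(sum(m & wh) / sum(wh), 0.99)
})

test_that("Z-spectrum assembly normalizes and orders frames", {
  d <- make_disc_i0()
  off_desc <- seq(5, -5, by = -0.2)  # acquisition order
  frames <- array(rep(d$i0, length(off_desc)), c(dim(d$i0), length(off_desc)))
  z <- assemble_zspectrum(frames, off_desc, d$i0)
  expect_equal(z$offsets, round(seq(-5, 5, by = 0.2), 10))
  expect_length(z$offsets, 51)
  v <- z$z[rep(z$mask, 51)]
  expect_equal(max(abs(v - 1)), 0, tolerance = 1e-12)

  # ascending supply gives the identical volume
  za <- assemble_zspectrum(frames[, , 51:1], rev(off_desc), d$i0)
  expect_identical(za$z, z$z)

  expect_error(assemble_zspectrum(frames[, , 1:50], off_desc, d$i0),
               "number of frames")
  off_dup <- off_desc
  off_dup[2] <- off_dup[1]
  expect_error(assemble_zspectrum(frames, off_dup, d$i0), "duplicate")
})

test_that("B0 correction is the identity at zero shift and undoes real shifts", {
  sat <- default_sat()
  ps <- two_pool()
  d <- make_disc_i0(10, 8, 3)
  nvox <- prod(dim(d$i0))

  spectrum <- function(shift) simulate_zspectrum(ps, sat, b0_shift = shift)
  stack_from <- function(zvec) {
    array(rep(as.vector(d$i0), length(zvec)) *
            rep(zvec, each = nvox), c(dim(d$i0), length(zvec)))
  }

  z0 <- assemble_zspectrum(stack_from(spectrum(0)), sat$offsets, d$i0,
                           mask = d$disc)
  zc <- correct_b0(z0, matrix(0, 10, 8))
  expect_equal(zc$z, z0$z, tolerance = 1e-12)

  # round trip: simulate at +0.3 ppm, correct with the true map
  zs <- assemble_zspectrum(stack_from(spectrum(0.3)), sat$offsets, d$i0,
                           mask = d$disc)
  zcorr <- correct_b0(zs, matrix(0.3, 10, 8))
  interior <- which(abs(sat$offsets) <= 4.6)
  v <- which(d$disc)[1]
  zm <- matrix(zcorr$z, nvox, 51)[v, interior]
  z0m <- matrix(z0$z, nvox, 51)[v, interior]
  expect_lt(max(abs(zm - z0m)), 1e-4)
  expect_true(zcorr$edge[v])  # grid end needed extrapolation

  # oversized shifts invalidate rather than extrapolate
  zbig <- correct_b0(z0, matrix(1.5, 10, 8))
  expect_false(any(zbig$mask))
})

test_that("contrast arithmetic, antisymmetry and scaling invariance hold", {
  sat <- default_sat()
  d <- make_disc_i0(8, 6, 2)
  nvox <- prod(dim(d$i0))
  zvec <- simulate_zspectrum(two_pool(), sat)

  stack <- array(rep(as.vector(d$i0), 51) * rep(zvec, each = nvox),
                 c(8, 6, 51))
  z <- assemble_zspectrum(stack, sat$offsets, d$i0, mask = d$disc)
  glu <- compute_glucest(z)
  want <- unname(zvec[abs(sat$offsets + 3) < 1e-6] -
                   zvec[abs(sat$offsets - 3) < 1e-6])
  expect_equal(glu$data[d$disc][1], want, tolerance = 1e-12)

  # symmetric spectrum -> zero contrast
  sym <- (zvec + rev(zvec)) / 2
  zsym <- assemble_zspectrum(
    array(rep(as.vector(d$i0), 51) * rep(sym, each = nvox), c(8, 6, 51)),
    sat$offsets, d$i0, mask = d$disc)
  expect_equal(compute_glucest(zsym)$data[d$disc][1], 0, tolerance = 1e-12)

  # reflecting the spectrum about 0 ppm negates the contrast
  zrev <- assemble_zspectrum(
    array(rep(as.vector(d$i0), 51) * rep(rev(zvec), each = nvox),
          c(8, 6, 51)),
    sat$offsets, d$i0, mask = d$disc)
  expect_equal(compute_glucest(zrev)$data[d$disc][1], -want,
               tolerance = 1e-12)

  # global intensity scaling cancels in Z and in the contrast
  zscaled <- assemble_zspectrum(stack * 3.7, sat$offsets, d$i0 * 3.7,
                                mask = d$disc)
  expect_equal(compute_glucest(zscaled)$data[d$disc][1], want,
               tolerance = 1e-12)

  # direct formula example
  zz <- z
  i3 <- which(abs(sat$offsets + 3) < 1e-6); i3p <- which(abs(sat$offsets - 3) < 1e-6)
  zm <- matrix(zz$z, nvox, 51)
  zm[, i3] <- 0.700; zm[, i3p] <- 0.668
  zz$z <- array(zm, c(8, 6, 51))
  expect_equal(compute_glucest(zz)$data[d$disc][1], 0.032,
               tolerance = 1e-12)

  # grid not covering +/-3 ppm is rejected
  znarrow <- assemble_zspectrum(stack[, , 16:36],
                                sat$offsets[16:36], d$i0, mask = d$disc)
  expect_error(compute_glucest(znarrow), "cover")
})

test_that("contrast is monotone in amine concentration on noiseless spectra", {
  sat <- default_sat()
  fr <- c(0, 0.002, 0.005, 0.01)
  con <- vapply(fr, function(f) {
    z <- simulate_zspectrum(two_pool(f), sat, offsets = c(-3, 3))
    unname(z[1] - z[2])
  }, numeric(1))
  expect_true(all(diff(con) > 0))
})

test_that("per-ROI Z-spectrum summaries have the expected layout", {
  cfg <- small_config()
  st <- build_phantom_study(cfg)
  s <- st$subjects[[1]]
  z <- assemble_zspectrum(s$cest, cfg$sat$offsets, s$i0,
                          mask = st$rois$labels > 0)
  tab <- roi_zspectrum(z, st$rois)
  expect_setequal(unique(tab$roi), c("WH", "PFC", "HP", "Str"))
  expect_equal(nrow(tab), 4 * 51)
  expect_true(all(is.finite(tab$mean_Z)))
})
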
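#' Brain mask from the reference image
#'
#' Otsu threshold on the unsaturated reference image, keep the largest
#' connected component, fill holes. A conservative automatic stand-in for
#' manual brain outlining.
#'
#' @param i0 non-negative reference image (matrix)
#' @return logical matrix
#' @export
mask_brain <- function(i0) {
  i0 <- as.matrix(i0)
  if (any(i0 < 0, na.rm = TRUE)) stop("reference image must be non-negative")
  rng <- range(i0, finite = TRUE)
  if (!is.finite(rng[2]) || rng[2] <= rng[1])
    stop("empty mask: reference image has no contrast")
  norm <- (i0 - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bw <- norm > thr
  if (!any(bw)) stop("empty mask")
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  keep <- which.max(tab)
  comp <- EBImage::imageData(lab) == keep
  filled <- EBImage::fillHull(EBImage::Image(comp * 1))
  out <- EBImage::imageData(filled) > 0
  dim(out) <- dim(i0)
  if (!any(out)) stop("empty mask")
  out
}

#' Assemble a Z-spectrum volume from a saturation stack
#'
#' Normalizes each saturation frame by the reference image I0 voxel-wise
#' (Z = I/I0) and orders frames by ascending offset; offsets may arrive in
#' acquisition (descending) order.
#'
#' @param frames 3-D array (rows x cols x offsets) of saturation images
#' @param offsets saturation offsets in ppm, one per frame, no duplicates
#' @param i0 reference image acquired far off-resonance
#' @param mask logical validity mask; default [mask_brain()] on `i0`
#' @return an object of class `zspec_volume`: normalized spectra `$z`
#'   (rows x cols x offsets, NA outside the mask), `$offsets`, `$mask`,
#'   `$i0`
#' @export
assemble_zspectrum <- function(frames, offsets, i0, mask = NULL) {
  stopifnot(length(dim(frames)) == 3)
  if (dim(frames)[3] != length(offsets))
    stop("number of frames must equal number of offsets")
  if (anyDuplicated(offsets)) stop("duplicate offsets")
  i0 <- as.matrix(i0)
  if (is.null(mask)) mask <- mask_brain(i0)
  mask <- mask & is.finite(i0) & i0 > 0
  ord <- order(offsets)
  offsets <- round(offsets[ord], 10)
  z <- frames[, , ord, drop = FALSE] / as.vector(i0)
  z[!rep(mask, times = length(offsets))] <- NA_real_
  structure(list(z = z, offsets = offsets, mask = mask, i0 = i0,
                 edge = matrix(FALSE, nrow(i0), ncol(i0))),
            class = "zspec_volume")
}

#' @export
print.zspec_volume <- function(x, ...) {
  cat(sprintf("<zspec_volume> %d x %d voxels, %d offsets [%g, %g] ppm, %d valid\n",
              dim(x$z)[1], dim(x$z)[2], length(x$offsets),
              min(x$offsets), max(x$offsets), sum(x$mask)))
  invisible(x)
}

#' Voxel-by-voxel B0 realignment of a Z-spectrum volume
#'
#' Each voxel's spectrum is re-centred on its true water frequency: the
#' spectrum is interpolated (natural cubic spline by default) and
#' resampled at `grid + delta`, where `delta` is the voxel's B0 offset in
#' ppm. A positive B0 value (water resonating above nominal) shifts the
#' apparent Z-minimum to +delta, so resampling at `grid + delta` restores
#' a spectrum centred at zero; `sign_flip` accommodates the opposite
#' vendor phase convention. Voxels with |delta| > `max_shift_ppm` are
#' invalidated (beyond that, the +/-3 ppm evaluation would lean on
#' extrapolation). Resample points outside the sampled range use
#' clamped-end values and raise the voxel's edge flag.
#'
#' @param z a `zspec_volume`
#' @param b0 a B0 `param_map` in Hz (converted through its
#'   reference_frequency), or a numeric matrix of ppm shifts
#' @param interp `"spline"` (natural cubic) or `"linear"`
#' @param sign_flip flip the B0 sign convention
#' @param max_shift_ppm invalidation threshold in ppm
#' @return a corrected `zspec_volume`
#' @export
correct_b0 <- function(z, b0, interp = c("spline", "linear"),
                       sign_flip = FALSE, max_shift_ppm = 1) {
  interp <- match.arg(interp)
  stopifnot(inherits(z, "zspec_volume"))
  delta <- if (inherits(b0, "param_map")) b0_ppm(b0) else as.matrix(b0)
  if (!identical(dim(delta), dim(z$mask)))
    stop("B0 map grid does not match the Z-spectrum volume")
  if (sign_flip) delta <- -delta
  grid <- z$offsets
  nvox <- prod(dim(z$mask))
  zm <- matrix(z$z, nvox, length(grid))
  out <- zm
  mask <- as.vector(z$mask)
  edge <- as.vector(z$edge)
  dvec <- as.vector(delta)
  for (v in which(mask)) {
    d <- dvec[v]
    if (!is.finite(d) || abs(d) > max_shift_ppm) { mask[v] <- FALSE; next }
    if (d == 0) next
    at <- grid + d
    zi <- zm[v, ]
    if (any(!is.finite(zi))) { mask[v] <- FALSE; next }
    outside <- at < grid[1] | at > grid[length(grid)]
    at_cl <- pmin(pmax(at, grid[1]), grid[length(grid)])
    out[v, ] <- if (interp == "spline")
      splinefun(grid, zi, method = "natural")(at_cl)
    else approx(grid, zi, xout = at_cl)$y
    if (any(outside)) edge[v] <- TRUE
  }
  out[!mask, ] <- NA_real_
  z$z <- array(out, dim(z$z))
  z$mask <- matrix(mask, nrow(z$mask), ncol(z$mask))
  z$edge <- matrix(edge, nrow(z$mask), ncol(z$mask))
  z
}

#' Glutamate-weighted CEST contrast map
#'
#' The asymmetry contrast at the glutamate amine resonance:
#' \deqn{\mathrm{GluCEST} = (I(-3\,\mathrm{ppm}) - I(+3\,\mathrm{ppm}))/I_0
#'       = Z(-3) - Z(+3).}
#' With the standard 0.2-ppm grid the +/-3 ppm points are exact nodes and
#' are read directly; on other grids covering +/-3 ppm the spectrum is
#' spline-evaluated.
#'
#' @param z a (B0-corrected) `zspec_volume`
#' @param at_ppm evaluation offset (default 3 ppm, glutamate amine)
#' @return a `param_map` of dimensionless contrast fractions
#' @export
compute_glucest <- function(z, at_ppm = 3) {
  stopifnot(inherits(z, "zspec_volume"))
  grid <- z$offsets
  if (min(grid) > -at_ppm || max(grid) < at_ppm)
    stop(sprintf("offset grid does not cover +/-%g ppm", at_ppm))
  ineg <- which(abs(grid + at_ppm) < 1e-6)
  ipos <- which(abs(grid - at_ppm) < 1e-6)
  nvox <- prod(dim(z$mask))
  zm <- matrix(z$z, nvox, length(grid))
  if (length(ineg) == 1 && length(ipos) == 1) {
    contrast <- zm[, ineg] - zm[, ipos]
  } else {
    contrast <- apply(zm, 1, function(zi) {
      if (any(!is.finite(zi))) return(NA_real_)
      f <- splinefun(grid, zi, method = "natural")
      f(-at_ppm) - f(at_ppm)
    })
  }
  contrast <- matrix(contrast, nrow(z$mask), ncol(z$mask))
  contrast[!z$mask] <- NA_real_
  big <- sum(abs(contrast) >= 0.5, na.rm = TRUE)
  if (big > 0)
    warning(sprintf("%d voxel(s) with |contrast| >= 0.5; check B0/masking", big))
  param_map(contrast, "fraction", "GluCEST", mask = z$mask & is.finite(contrast))
}

#' Per-ROI mean Z-spectrum
#'
#' Summarizes a Z-spectrum volume over ROI labels, for spectrum plots of
#' the CEST effect at 3 ppm.
#'
#' @param z a `zspec_volume`
#' @param rois an `roi_labels` object or integer label matrix
#' @return data frame: roi, offset_ppm, mean_Z, sem_Z
#' @export
roi_zspectrum <- function(z, rois) {
  rl <- as_roi_labels(rois)
  nvox <- prod(dim(z$mask))
  zm <- matrix(z$z, nvox, length(z$offsets))
  res <- lapply(names(rl$legend), function(nm) {
    sel <- as.vector(roi_mask(rl, nm) & z$mask)
    if (!any(sel)) return(NULL)
    zz <- zm[sel, , drop = FALSE]
    data.frame(roi = nm, offset_ppm = z$offsets,
               mean_Z = colMeans(zz),
               sem_Z = apply(zz, 2, sd) / sqrt(nrow(zz)))
  })
  do.call(rbind, res)
}

#' @importFrom stats approx
NULL
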
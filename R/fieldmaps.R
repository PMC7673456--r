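#' B0 field map from dual-echo phase data
#'
#' The off-resonance frequency per voxel is the phase accrued between two
#' echoes separated by `delta_te`:
#' \deqn{\Delta f = \mathrm{wrap}(\varphi_2 - \varphi_1) / (2\pi\,\Delta TE)}
#' with the phase difference wrapped to \eqn{(-\pi, \pi]}. With
#' \eqn{\Delta TE} = 2 ms the unaliased range is +/-250 Hz; no spatial
#' unwrapping is applied — a well-shimmed rodent brain at 7 T stays well
#' inside that range, and out-of-range field would alias rather than be
#' silently "fixed".
#'
#' @param phase_e1,phase_e2 phase maps in radians at the first and second
#'   echo, same grid
#' @param delta_te echo spacing in seconds
#' @param reference_frequency proton frequency in MHz, kept in the map
#'   metadata for ppm views
#' @param mask optional logical validity mask
#' @return a `param_map` in Hz with `meta$reference_frequency`
#' @examples
#' p1 <- matrix(0, 4, 4); p2 <- matrix(pi / 2, 4, 4)
#' b0 <- b0_map_dual_echo(p1, p2, delta_te = 0.002)  # 125 Hz everywhere
#' @export
b0_map_dual_echo <- function(phase_e1, phase_e2, delta_te = 0.002,
                             reference_frequency = 300, mask = NULL) {
  phase_e1 <- as.matrix(phase_e1); phase_e2 <- as.matrix(phase_e2)
  if (!identical(dim(phase_e1), dim(phase_e2)))
    stop("phase maps must share the same grid")
  if (!is.finite(delta_te) || delta_te <= 0) stop("delta_te must be > 0")
  d <- wrap_phase(phase_e2 - phase_e1)
  df <- d / (2 * pi * delta_te)
  if (is.null(mask)) mask <- is.finite(df)
  param_map(df, "Hz", "B0", mask = mask & is.finite(df),
            meta = list(reference_frequency = reference_frequency,
                        delta_te_s = delta_te))
}

# wrap to (-pi, pi]; the +pi boundary maps to +pi by convention
wrap_phase <- function(x) {
  w <- atan2(sin(x), cos(x))
  w[w == -pi] <- pi
  w
}

#' ppm view of a B0 map
#'
#' @param b0 a B0 `param_map` in Hz
#' @return numeric matrix of ppm offsets
#' @export
b0_ppm <- function(b0) {
  stopifnot(inherits(b0, "param_map"), b0$units == "Hz")
  rf <- b0$meta$reference_frequency
  if (is.null(rf)) stop("B0 map carries no reference_frequency")
  hz_to_ppm(b0$data, rf)
}

#' Relative B1 map by the double-angle method
#'
#' From magnitude images at nominal flip angles \eqn{\alpha} and
#' \eqn{2\alpha}, the actual angle satisfies
#' \eqn{\cos\hat\alpha = S(2\alpha) / (2 S(\alpha))}; the map reports
#' \eqn{\hat\alpha / \alpha} (1 = nominal excitation). Voxels whose
#' single-angle signal falls below the mask threshold are invalid rather
#' than extrapolated.
#'
#' @param img_alpha,img_2alpha magnitude images at \eqn{\alpha} and
#'   \eqn{2\alpha}, same grid
#' @param nominal_alpha nominal flip angle in degrees, in (0, 90)
#' @param mask_threshold voxels with `img_alpha` below this fraction of
#'   its 99th percentile are invalid
#' @return a `param_map` of dimensionless flip-angle factors
#' @export
b1_map_double_angle <- function(img_alpha, img_2alpha, nominal_alpha = 60,
                                mask_threshold = 0.05) {
  img_alpha <- as.matrix(img_alpha); img_2alpha <- as.matrix(img_2alpha)
  if (!identical(dim(img_alpha), dim(img_2alpha)))
    stop("magnitude maps must share the same grid")
  if (any(img_alpha < 0, na.rm = TRUE) || any(img_2alpha < 0, na.rm = TRUE))
    stop("magnitude maps must be non-negative")
  if (!is.finite(nominal_alpha) || nominal_alpha <= 0 || nominal_alpha >= 90)
    stop("nominal_alpha must be in (0, 90) degrees")
  thr <- mask_threshold * quantile(img_alpha[is.finite(img_alpha)], 0.99)
  valid <- is.finite(img_alpha) & is.finite(img_2alpha) & img_alpha > thr
  ratio <- pmin(pmax(img_2alpha / (2 * img_alpha), -1), 1)
  factor <- acos(ratio) * 180 / pi / nominal_alpha
  factor[!valid] <- NA_real_
  param_map(factor, "factor", "B1", mask = valid,
            meta = list(nominal_alpha_deg = nominal_alpha))
}
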
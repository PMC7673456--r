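#' Voxel-wise T1 mapping from inversion-recovery magnitude data
#'
#' Fits the 3-parameter magnitude model
#' \deqn{S(TI) = |a + b\,e^{-TI/T_1}|}
#' per voxel. Magnitude data lose the sign of the recovering
#' magnetization, so the fit restores polarity first: samples before the
#' minimum-signal TI are negated, both polarities of the boundary sample
#' are tried, and the lower-residual fit is kept. The signed model is then
#' refined by bounded nonlinear least squares
#' (\code{minpack.lm::nlsLM}, T1 in (0, 10000] ms). The 3-parameter form
#' is robust to imperfect inversion (ideal inversion gives b = -2a).
#'
#' @param stack magnitude data: a voxels-by-TI matrix, or a 3-D array with
#'   TI along the last dimension
#' @param ti_ms inversion times in ms (>= 4 distinct values)
#' @param mask optional logical mask of voxels to fit
#' @return a `relax_fit` with `$map` (T1 `param_map` in ms), amplitude and
#'   residual-norm maps, and a validity mask; voxels failing bounds or
#'   convergence are invalid, never clamped
#' @examples
#' ti <- round(exp(seq(log(100), log(7500), length.out = 7)))
#' s <- abs(1 - 2 * exp(-rep(ti, each = 2) / 1400))
#' fit <- fit_t1_inversion_recovery(matrix(s, 2, 7), ti)
#' @export
fit_t1_inversion_recovery <- function(stack, ti_ms, mask = NULL) {
  d <- as_voxel_matrix(stack)
  if (length(unique(ti_ms)) < 4) stop("need at least 4 distinct TIs")
  if (ncol(d$m) != length(ti_ms)) stop("stack/TI length mismatch")
  fit_relax_stack(d, ti_ms, mask, fit_t1_voxel, upper = 10000,
                  metric = "T1")
}

#' Voxel-wise T2 mapping from multi-echo magnitude data
#'
#' Fits \eqn{S(TE) = S_0 e^{-TE/T_2}} per voxel: a variance-weighted
#' log-linear fit (weights \eqn{S^2}, the correct first-order weighting
#' for log-transformed additive noise) provides the initializer, refined
#' by bounded nonlinear least squares (T2 in (0, 2000] ms).
#'
#' @param stack magnitude data, as in [fit_t1_inversion_recovery()]
#' @param te_ms echo times in ms (>= 3 distinct values)
#' @param mask optional logical mask
#' @return a `relax_fit` (T2 map in ms)
#' @export
fit_t2_monoexp <- function(stack, te_ms, mask = NULL) {
  d <- as_voxel_matrix(stack)
  if (length(unique(te_ms)) < 3) stop("need at least 3 distinct TEs")
  if (ncol(d$m) != length(te_ms)) stop("stack/TE length mismatch")
  fit_relax_stack(d, te_ms, mask, fit_t2_voxel, upper = 2000,
                  metric = "T2")
}

# accept voxels x time matrix or r x c x time array
as_voxel_matrix <- function(stack) {
  if (is.matrix(stack)) return(list(m = stack, dim = NULL))
  if (length(dim(stack)) == 3) {
    dm <- dim(stack)
    return(list(m = matrix(stack, dm[1] * dm[2], dm[3]), dim = dm[1:2]))
  }
  stop("stack must be a voxels-by-time matrix or a 3-D array")
}

fit_relax_stack <- function(d, t_ms, mask, voxel_fn, upper, metric) {
  nv <- nrow(d$m)
  if (is.null(mask)) mask <- rep(TRUE, nv) else mask <- as.vector(mask)
  par <- amp <- rss <- rep(NA_real_, nv)
  ok <- rep(FALSE, nv)
  for (v in seq_len(nv)) {
    if (!mask[v]) next
    s <- d$m[v, ]
    if (any(!is.finite(s))) next
    r <- voxel_fn(s, t_ms, upper)
    if (!is.null(r)) {
      par[v] <- r$par; amp[v] <- r$amp; rss[v] <- r$rss; ok[v] <- TRUE
    }
  }
  shape <- function(x) if (is.null(d$dim)) matrix(x, ncol = 1) else
    matrix(x, d$dim[1], d$dim[2])
  structure(list(
    map = param_map(shape(par), "ms", metric, mask = shape(ok)),
    amplitude = shape(amp), residual = shape(rss), valid = shape(ok),
    n_valid = sum(ok), n_failed = sum(mask) - sum(ok)),
    class = "relax_fit")
}

#' @export
print.relax_fit <- function(x, ...) {
  cat(sprintf("<relax_fit> %s: %d fitted, %d failed\n",
              x$map$metric, x$n_valid, x$n_failed))
  print(x$map)
  invisible(x)
}

#' Per-map fit report
#'
#' @param fit a `relax_fit`
#' @return one-row data frame: n_valid, n_failed, median, q25, q75
#' @export
relax_fit_report <- function(fit) {
  v <- fit$map$data[fit$map$mask]
  data.frame(metric = fit$map$metric, n_valid = fit$n_valid,
             n_failed = fit$n_failed,
             median = if (length(v)) median(v) else NA_real_,
             q25 = if (length(v)) unname(quantile(v, 0.25)) else NA_real_,
             q75 = if (length(v)) unname(quantile(v, 0.75)) else NA_real_)
}

fit_t1_voxel <- function(s, ti, upper) {
  if (sd(s) < 1e-12 * (abs(mean(s)) + 1e-300)) return(NULL)  # no decay info
  ord <- order(ti)
  s <- s[ord]; ti_s <- ti[ord]
  imin <- which.min(s)
  best <- NULL
  for (flip_min in c(TRUE, FALSE)) {      # both polarities of the boundary TI
    sgn <- rep(1, length(s))
    if (imin > 1) sgn[seq_len(imin - 1)] <- -1
    sgn[imin] <- if (flip_min) -1 else 1
    ss <- sgn * s
    a0 <- ss[length(ss)]
    b0 <- ss[1] - a0
    if (a0 <= 0) next
    t10 <- max(min(ti_s[imin] / log(2), upper * 0.9), ti_s[1] * 0.1)
    fit <- tryCatch(
      minpack.lm::nlsLM(ss ~ a + b * exp(-ti_s / t1),
                        start = list(a = a0, b = b0, t1 = t10),
                        lower = c(0, -Inf, 1e-3), upper = c(Inf, Inf, upper),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- coef(fit)
    # residual judged on magnitude, as acquired
    rss <- sum((abs(cf["a"] + cf["b"] * exp(-ti_s / cf["t1"])) - s)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = unname(cf["t1"]), amp = unname(cf["a"]), rss = rss)
  }
  if (is.null(best) || best$par <= 0 || best$par > upper ||
      best$par >= upper * 0.999) return(NULL)  # at bound: unconverged
  best
}

fit_t2_voxel <- function(s, te, upper) {
  pos <- s > 0
  if (sum(pos) < 2) return(NULL)       # underdetermined
  if (sd(s) < 1e-12 * (abs(mean(s)) + 1e-300)) return(NULL)
  w <- s[pos]^2
  lf <- lm(log(s[pos]) ~ te[pos], weights = w)
  slope <- unname(coef(lf)[2])
  t20 <- if (is.finite(slope) && slope < 0) min(-1 / slope, upper * 0.9)
         else median(te)
  s00 <- exp(unname(coef(lf)[1]))
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ s0 * exp(-te / t2),
                      start = list(s0 = s00, t2 = max(t20, 1e-2)),
                      lower = c(0, 1e-3), upper = c(Inf, upper),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  if (cf["t2"] <= 0 || cf["t2"] >= upper * 0.999) return(NULL)
  list(par = unname(cf["t2"]), amp = unname(cf["s0"]),
       rss = sum(residuals(fit)^2))
}

#' @importFrom stats residuals
NULL
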
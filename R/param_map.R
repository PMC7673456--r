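#' Scalar parametric voxel map
#'
#' Light container for a 2-D parametric map (T1, T2, B0, B1 factor,
#' GluCEST fraction) with units, a validity mask and free-form metadata
#' (e.g. the reference frequency needed for Hz <-> ppm views of a B0 map).
#'
#' @param data numeric matrix of voxel values
#' @param units unit string ("ms", "Hz", "factor", "fraction")
#' @param metric short name of the mapped quantity
#' @param mask logical matrix of valid voxels (default: finite values)
#' @param meta named list of extra metadata
#' @return an object of class `param_map`
#' @export
param_map <- function(data, units, metric, mask = NULL, meta = list()) {
  data <- as.matrix(data)
  if (is.null(mask)) mask <- is.finite(data)
  stopifnot(identical(dim(mask), dim(data)))
  structure(list(data = data, units = units, metric = metric,
                 mask = mask, meta = meta),
            class = "param_map")
}

#' @export
print.param_map <- function(x, ...) {
  v <- x$data[x$mask]
  cat(sprintf("<param_map> %s [%s], %d x %d, %d valid voxels\n",
              x$metric, x$units, nrow(x$data), ncol(x$data), sum(x$mask)))
  if (length(v))
    cat(sprintf("  median %.4g  IQR [%.4g, %.4g]\n", median(v),
                quantile(v, 0.25), quantile(v, 0.75)))
  invisible(x)
}

#' @export
summary.param_map <- function(object, ...) {
  v <- object$data[object$mask]
  c(n_valid = sum(object$mask), n_invalid = sum(!object$mask),
    median = if (length(v)) median(v) else NA_real_,
    mean = if (length(v)) mean(v) else NA_real_,
    sd = if (length(v)) sd(v) else NA_real_)
}

#' @importFrom stats quantile
#' @export
as.matrix.param_map <- function(x, ...) {
  out <- x$data
  out[!x$mask] <- NA_real_
  out
}
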
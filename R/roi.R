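#' ROI label map
#'
#' Integer label map with a legend. By convention label 1 ("WH") marks
#' whole-brain tissue not in any sub-region; the whole-brain ROI is the
#' union of all labels, matching how a manually drawn whole-brain outline
#' contains the sub-region outlines.
#'
#' @param labels integer matrix, 0 = background
#' @param legend named integer vector mapping ROI names to label codes
#' @return an object of class `roi_labels`
#' @export
roi_labels <- function(labels,
                       legend = c(WH = 1L, PFC = 2L, HP = 3L, Str = 4L)) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, legend = legend), class = "roi_labels")
}

as_roi_labels <- function(x) {
  if (inherits(x, "roi_labels")) x else roi_labels(x)
}

#' @rdname roi_labels
#' @param x an `roi_labels`
#' @param roi ROI name from the legend, or "WH" for the union
#' @export
roi_mask <- function(x, roi) {
  x <- as_roi_labels(x)
  if (roi == "WH") return(x$labels > 0L)
  code <- x$legend[[roi]]
  if (is.null(code)) stop("unknown ROI: ", roi)
  x$labels == code
}

#' Per-subject ROI means of a parametric map
#'
#' Arithmetic mean of the map over valid voxels of each ROI.
#'
#' @param map a `param_map` (or numeric matrix)
#' @param rois an `roi_labels` or integer label matrix
#' @param subject_id,group identifiers copied into the output rows
#' @param metric metric name; defaults to the map's own
#' @return data frame rows (subject_id, group, roi, metric, value); an
#'   ROI with no valid voxel yields an NA value with a warning
#' @export
extract_roi_means <- function(map, rois, subject_id = "s1", group = "CTL",
                              metric = NULL) {
  if (!inherits(map, "param_map"))
    map <- param_map(map, units = "", metric = metric %||% "value")
  metric <- metric %||% map$metric
  rl <- as_roi_labels(rois)
  if (!identical(dim(rl$labels), dim(map$data)))
    stop("map and ROI labels are not co-registered")
  vals <- vapply(names(rl$legend), function(nm) {
    sel <- roi_mask(rl, nm) & map$mask
    if (!any(sel)) {
      warning("ROI ", nm, " has no valid voxels; emitting NA")
      return(NA_real_)
    }
    mean(map$data[sel])
  }, numeric(1))
  data.frame(subject_id = subject_id, group = group,
             roi = names(rl$legend), metric = metric,
             value = unname(vals), row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
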
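#' Write a synthetic study to disk as NIfTI + JSON sidecars
#'
#' Lays the study out one directory per subject, each stack as a NIfTI-1
#' volume with a JSON sidecar carrying the acquisition metadata
#' (offsets_ppm, reference_offset_ppm, ti_ms, te_ms, flip_deg,
#' delta_te_ms, field_T, ref_freq_MHz), plus the ROI label map with its
#' legend and a top-level manifest listing every file with its
#' ground-truth parameters.
#'
#' @param study a `cest_study`
#' @param dir output directory (created if needed)
#' @return the manifest, invisibly
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "cest_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- study$config
  sat <- cfg$sat
  side_common <- list(field_T = sat$field_strength,
                      ref_freq_MHz = sat$reference_frequency)
  wr <- function(data, path, sidecar = NULL) {
    RNifti::writeNifti(data, path)
    if (!is.null(sidecar))
      jsonlite::write_json(c(sidecar, side_common),
                           sub("\\.nii(\\.gz)?$", ".json", path),
                           auto_unbox = TRUE, digits = NA)
    basename(path)
  }
  files <- list()
  lab <- study$rois$labels
  files$roi_labels <- wr(lab, file.path(dir, "roi_labels.nii.gz"))
  jsonlite::write_json(as.list(setNames(names(study$rois$legend),
                                        study$rois$legend)),
                       file.path(dir, "roi_legend.json"), auto_unbox = TRUE)
  files$wh_mask <- wr((lab > 0) * 1L, file.path(dir, "wh_mask.nii.gz"))

  for (s in study$subjects) {
    sd <- file.path(dir, s$id)
    dir.create(sd, showWarnings = FALSE)
    wr(s$cest, file.path(sd, "cest.nii.gz"),
       list(offsets_ppm = sat$offsets,
            reference_offset_ppm = sat$reference_offset))
    wr(s$i0, file.path(sd, "i0.nii.gz"),
       list(reference_offset_ppm = sat$reference_offset))
    wr(s$ir, file.path(sd, "ir.nii.gz"), list(ti_ms = cfg$ti_ms))
    wr(s$se, file.path(sd, "se.nii.gz"), list(te_ms = cfg$te_ms))
    wr(s$phase1, file.path(sd, "phase_e1.nii.gz"),
       list(delta_te_ms = cfg$delta_te_s * 1000, echo = 1))
    wr(s$phase2, file.path(sd, "phase_e2.nii.gz"),
       list(delta_te_ms = cfg$delta_te_s * 1000, echo = 2))
    wr(s$da_low, file.path(sd, "da_low.nii.gz"),
       list(flip_deg = cfg$flip_deg[1]))
    wr(s$da_high, file.path(sd, "da_high.nii.gz"),
       list(flip_deg = cfg$flip_deg[2]))
    wr(s$b0_ppm_truth, file.path(sd, "truth_b0_ppm.nii.gz"))
    wr(s$b1_truth, file.path(sd, "truth_b1.nii.gz"))
  }
  manifest <- list(
    matrix_size = cfg$matrix_size,
    snr = if (is.infinite(cfg$snr)) "Inf" else cfg$snr,
    seed = cfg$seed,
    subjects = lapply(study$subjects, function(s)
      list(id = s$id, group = s$group)),
    truth = list(t1_ms = as.list(cfg$t1_ms), t2_ms = as.list(cfg$t2_ms),
                 amine_ctl = as.list(cfg$amine_ctl),
                 amine_fat = as.list(cfg$amine_fat)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a study laid out by [write_study()]
#'
#' @param dir study directory containing manifest.json
#' @return a list with `$rois`, `$subjects` (stacks as arrays) and the
#'   parsed sidecar metadata
#' @export
read_study <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  legend <- jsonlite::read_json(file.path(dir, "roi_legend.json"),
                                simplifyVector = TRUE)
  lab <- drop(as.array(RNifti::readNifti(file.path(dir,
                                                   "roi_labels.nii.gz"))))
  lab <- matrix(as.integer(round(lab)), nrow(lab), ncol(lab))
  rois <- roi_labels(lab, setNames(as.integer(names(legend)),
                                   unlist(legend)))
  rd <- function(sd, nm) {
    a <- RNifti::readNifti(file.path(sd, paste0(nm, ".nii.gz")))
    a <- drop(as.array(a))
    array(as.numeric(a), dim(a))  # shed NIfTI header attributes
  }
  side <- function(sd, nm) jsonlite::read_json(
    file.path(sd, paste0(nm, ".json")), simplifyVector = TRUE)
  subjects <- lapply(manifest$subjects, function(m) {
    sd <- file.path(dir, m$id)
    list(id = m$id, group = m$group,
         cest = rd(sd, "cest"), i0 = rd(sd, "i0"),
         ir = rd(sd, "ir"), se = rd(sd, "se"),
         phase1 = rd(sd, "phase_e1"), phase2 = rd(sd, "phase_e2"),
         da_low = rd(sd, "da_low"), da_high = rd(sd, "da_high"),
         meta = list(cest = side(sd, "cest"), ir = side(sd, "ir"),
                     se = side(sd, "se"), phase = side(sd, "phase_e1"),
                     da_low = side(sd, "da_low"),
                     da_high = side(sd, "da_high")))
  })
  names(subjects) <- vapply(subjects, `[[`, character(1), "id")
  list(manifest = manifest, rois = rois, subjects = subjects)
}

#' Write a `param_map` as NIfTI with a JSON sidecar
#'
#' @param map a `param_map`
#' @param path output path (.nii or .nii.gz)
#' @export
write_param_map <- function(map, path) {
  data <- map$data
  data[!map$mask] <- NA_real_
  RNifti::writeNifti(data, path)
  jsonlite::write_json(c(list(metric = map$metric, units = map$units),
                         map$meta),
                       sub("\\.nii(\\.gz)?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
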
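#' Configuration for a synthetic two-group CEST study
#'
#' Describes a digital brain phantom emulating a 7 T rat fatigue study:
#' an elliptical whole-brain (WH) section containing prefrontal-cortex
#' (PFC), hippocampus (HP) and striatum (Str) sub-regions, per-group
#' glutamate amine proton fractions, ground-truth T1/T2, smooth B0 (ppm)
#' and B1 (multiplicative) field surfaces, and Rician noise at a given
#' SNR. The default 64 x 32 matrix is half the acquired 128 x 64 for
#' speed; group sizes default to the study's 10 control / 6 fatigue.
#'
#' @param matrix_size c(rows, cols) of the image grid
#' @param n_control,n_fatigue subjects per group
#' @param amine_fraction_ctl glutamate amine proton fraction in the
#'   control group; a single value or named per-ROI vector
#'   (WH, PFC, HP, Str). The default is calibrated (see
#'   [calibrate_amine_fraction()]) so the noiseless whole-brain contrast
#'   is 0.021, a typical healthy-brain GluCEST level under this protocol
#' @param amine_ratio_fatigue fatigue-group fraction as a multiple of
#'   control (1.5 gives the ~50% contrast increase seen after fatigue
#'   loading)
#' @param t1_ms,t2_ms ground-truth water relaxation times, single value
#'   or named per-ROI
#' @param b0_amp_ppm peak amplitude of the smooth B0 surface
#' @param b1_amp peak deviation of the B1 factor from 1
#' @param snr signal-to-noise ratio of the magnitude data relative to I0
#'   (Inf = noiseless)
#' @param sat a `saturation_params`
#' @param ti_ms inversion times (default 7, log-spaced 100-7500 ms)
#' @param te_ms echo times (default 5, linear 40-400 ms)
#' @param flip_deg double-angle flip pair
#' @param delta_te_s dual-echo spacing in seconds
#' @param seed master seed; per-subject, per-acquisition streams are
#'   drawn from it
#' @return a `phantom_config`
#' @export
phantom_config <- function(matrix_size = c(64, 32),
                           n_control = 10, n_fatigue = 6,
                           amine_fraction_ctl = 0.00026,
                           amine_ratio_fatigue = 1.5,
                           t1_ms = 1425.3, t2_ms = 74.8,
                           b0_amp_ppm = 0.3, b1_amp = 0.1,
                           snr = 50,
                           sat = saturation_params(),
                           ti_ms = round(exp(seq(log(100), log(7500),
                                                 length.out = 7))),
                           te_ms = seq(40, 400, length.out = 5),
                           flip_deg = c(60, 120),
                           delta_te_s = 0.002,
                           seed = 1L) {
  stopifnot(length(matrix_size) == 2, all(matrix_size >= 8))
  if (!is.finite(n_control) || !is.finite(n_fatigue) ||
      n_control < 1 || n_fatigue < 1) stop("subject counts must be >= 1")
  if (!(is.infinite(snr) || (is.finite(snr) && snr > 0)))
    stop("snr must be positive (or Inf)")
  rois <- c("WH", "PFC", "HP", "Str")
  expand <- function(x) {
    if (length(x) == 1) return(setNames(rep(as.numeric(x), 4), rois))
    stopifnot(all(rois %in% names(x)))
    x[rois]
  }
  structure(list(
    matrix_size = as.integer(matrix_size),
    n_control = as.integer(n_control), n_fatigue = as.integer(n_fatigue),
    amine_ctl = expand(amine_fraction_ctl),
    amine_fat = expand(amine_fraction_ctl) * amine_ratio_fatigue,
    t1_ms = expand(t1_ms), t2_ms = expand(t2_ms),
    b0_amp_ppm = b0_amp_ppm, b1_amp = b1_amp, snr = snr,
    sat = sat, ti_ms = as.numeric(ti_ms), te_ms = as.numeric(te_ms),
    flip_deg = flip_deg, delta_te_s = delta_te_s,
    seed = as.integer(seed)), class = "phantom_config")
}

#' Calibrate the amine proton fraction to a target contrast
#'
#' Finds, by root bisection, the amine proton fraction whose noiseless
#' Bloch-McConnell Z-spectrum yields a given asymmetry contrast
#' Z(-3) - Z(+3) under the stated saturation protocol and water
#' relaxation times.
#'
#' @param target desired contrast (fraction)
#' @param sat a `saturation_params`
#' @param t1_ms,t2_ms water relaxation times in ms
#' @param interval search interval for the proton fraction
#' @return the calibrated proton fraction
#' @export
calibrate_amine_fraction <- function(target, sat = saturation_params(),
                                     t1_ms = 1425.3, t2_ms = 74.8,
                                     interval = c(1e-7, 0.02)) {
  f <- function(fr) {
    ps <- pool_system(pool_water(t1 = t1_ms / 1000, t2 = t2_ms / 1000),
                      pool_amine(proton_fraction = fr))
    z <- simulate_zspectrum(ps, sat, offsets = c(-3, 3))
    unname(z[1] - z[2]) - target
  }
  stats::uniroot(f, interval, tol = 1e-10)$root
}

# elliptical WH with three disjoint sub-region discs, all inside WH
phantom_roi_layout <- function(matrix_size) {
  nr <- matrix_size[1]; nc <- matrix_size[2]
  x <- matrix(seq_len(nr), nr, nc)
  y <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  cx <- (nr + 1) / 2; cy <- (nc + 1) / 2
  rx <- 0.42 * nr; ry <- 0.40 * nc
  wh <- ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
  disc <- function(fx, fy, fr) {
    (x - (cx + fx * rx))^2 + (y - (cy + fy * ry))^2 <= (fr * min(rx, ry))^2
  }
  pfc <- disc(-0.55, 0, 0.30)
  hp  <- disc(0.35, -0.45, 0.30)
  str_ <- disc(0.35, 0.45, 0.30)
  labels <- matrix(0L, nr, nc)
  labels[wh] <- 1L
  labels[pfc & wh] <- 2L
  labels[hp & wh] <- 3L
  labels[str_ & wh] <- 4L
  if (any(pfc & hp) || any(pfc & str_) || any(hp & str_))
    stop("ROI layout overlap")
  roi_labels(labels)
}

# smooth low-order polynomial surface rescaled to a given peak amplitude
smooth_surface <- function(matrix_size, amp, coefs) {
  nr <- matrix_size[1]; nc <- matrix_size[2]
  x <- matrix(seq(-1, 1, length.out = nr), nr, nc)
  y <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
  s <- coefs[1] * x + coefs[2] * y + coefs[3] * x * y +
    coefs[4] * (x^2 - y^2) + coefs[5] * (x^2 + y^2 - 1)
  if (amp == 0 || max(abs(s)) == 0) return(matrix(0, nr, nc))
  s / max(abs(s)) * amp
}

rician <- function(x, sigma) {
  if (sigma == 0) return(x)
  sqrt((x + rnorm(length(x), 0, sigma))^2 + rnorm(length(x), 0, sigma)^2)
}

#' Build a complete synthetic two-group study
#'
#' For every subject, simulates the full multi-parametric session through
#' the Bloch-McConnell model and closed-form relaxation signals: the
#' 51-offset CEST stack plus I0 reference, the 7-TI inversion-recovery
#' stack, the 5-TE spin-echo stack, a dual-echo phase pair consistent
#' with the subject's B0 field, and a 60/120-degree magnitude pair
#' consistent with its B1 field. Magnitude data are corrupted by Rician
#' noise at `config$snr`; phase data receive matched Gaussian phase
#' noise. Ground truth (T1, T2, B0, B1, GluCEST contrast, ROI labels) is
#' returned alongside. Bit-reproducible for a fixed seed: the master seed
#' deterministically spawns one RNG stream per subject, and acquisitions
#' within a subject draw from that stream in a fixed order.
#'
#' @param config a `phantom_config`
#' @return a `cest_study` list: `$config`, `$rois`, `$subjects` (named
#'   list; each has group, b0/b1 truth, all stacks) and `$truth`
#'   (per-group ground-truth maps, incl. the noiseless GluCEST contrast)
#' @export
build_phantom_study <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  rois <- phantom_roi_layout(config$matrix_size)
  lab <- rois$labels
  sat <- config$sat
  nr <- config$matrix_size[1]; nc <- config$matrix_size[2]
  inside <- lab > 0L

  groups <- c(rep("CTL", config$n_control), rep("FATIGUE", config$n_fatigue))
  ids <- sprintf("%s%02d", ifelse(groups == "CTL", "c", "f"),
                 stats::ave(seq_along(groups), groups, FUN = seq_along))

  # pool systems per (group, roi-tissue); tissue 0 = background (unused)
  tissue_pools <- function(amine) {
    lapply(1:4, function(code) {
      roi_nm <- c("WH", "PFC", "HP", "Str")[code]
      pool_system(
        pool_water(t1 = config$t1_ms[[roi_nm]] / 1000,
                   t2 = config$t2_ms[[roi_nm]] / 1000),
        pool_amine(proton_fraction = amine[[roi_nm]]))
    })
  }
  pools_by_group <- list(CTL = tissue_pools(config$amine_ctl),
                         FATIGUE = tissue_pools(config$amine_fat))

  # noiseless ground-truth contrast per tissue and group
  truth_contrast <- function(grp) {
    out <- matrix(NA_real_, nr, nc)
    for (code in 1:4) {
      z <- simulate_zspectrum(pools_by_group[[grp]][[code]], sat,
                              offsets = c(-3, 3))
      out[lab == code] <- z[1] - z[2]
    }
    out
  }
  truth <- list(
    t1_ms = ground_truth_map(lab, config$t1_ms),
    t2_ms = ground_truth_map(lab, config$t2_ms),
    glucest = list(CTL = truth_contrast("CTL"),
                   FATIGUE = truth_contrast("FATIGUE")))

  set.seed(config$seed)
  subject_seeds <- sample.int(2^31 - 2, length(ids))

  w1 <- 2 * pi * sat$b1_hz
  all_off <- c(sat$offsets, sat$reference_offset)
  sigma <- if (is.infinite(config$snr)) 0 else 1 / config$snr

  subjects <- vector("list", length(ids))
  names(subjects) <- ids
  for (s in seq_along(ids)) {
    set.seed(subject_seeds[s])
    grp <- groups[s]
    b0 <- smooth_surface(config$matrix_size, config$b0_amp_ppm,
                         runif(5, -1, 1))
    b1 <- 1 + smooth_surface(config$matrix_size, config$b1_amp,
                             runif(5, -1, 1))

    # CEST stack + I0 via the Bloch-McConnell propagator
    vox <- which(inside)
    zmat <- bm_zspectrum_batch(
      lapply(pools_by_group[[grp]], pool_matrix,
             reference_frequency = sat$reference_frequency),
      tissue_idx = lab[vox] - 1L,
      b0_hz = ppm_to_hz(b0[vox], sat$reference_frequency),
      b1_scale = b1[vox], w1 = w1, t_sat = sat$duration,
      offsets_hz = ppm_to_hz(all_off, sat$reference_frequency))
    cest <- array(0, c(nr, nc, length(sat$offsets)))
    i0 <- matrix(0, nr, nc)
    for (j in seq_along(sat$offsets)) {
      fr <- matrix(0, nr, nc); fr[vox] <- zmat[, j]
      cest[, , j] <- rician(fr, sigma)
    }
    i0[vox] <- zmat[, length(all_off)]
    i0 <- rician(i0, sigma)

    # relaxometry stacks (closed-form, ideal inversion a = 1, b = -2)
    t1map <- ground_truth_map(lab, config$t1_ms)
    t2map <- ground_truth_map(lab, config$t2_ms)
    ir <- array(0, c(nr, nc, length(config$ti_ms)))
    for (j in seq_along(config$ti_ms)) {
      fr <- matrix(0, nr, nc)
      fr[vox] <- abs(1 - 2 * exp(-config$ti_ms[j] / t1map[vox]))
      ir[, , j] <- rician(fr, sigma)
    }
    se <- array(0, c(nr, nc, length(config$te_ms)))
    for (j in seq_along(config$te_ms)) {
      fr <- matrix(0, nr, nc)
      fr[vox] <- exp(-config$te_ms[j] / t2map[vox])
      se[, , j] <- rician(fr, sigma)
    }

    # dual-echo phase pair: phase accrual 2*pi*f*TE (TE1 = 5 ms)
    f_hz <- ppm_to_hz(b0, sat$reference_frequency)
    te1 <- 0.005
    ph_sigma <- if (sigma == 0) 0 else sigma  # small-angle phase noise
    phase1 <- wrap_phase(2 * pi * f_hz * te1 +
                           rnorm(nr * nc, 0, ph_sigma))
    phase2 <- wrap_phase(2 * pi * f_hz * (te1 + config$delta_te_s) +
                           rnorm(nr * nc, 0, ph_sigma))

    # double-angle magnitude pair
    a1 <- config$flip_deg[1] * pi / 180
    da1 <- matrix(0, nr, nc); da2 <- matrix(0, nr, nc)
    da1[vox] <- sin(b1[vox] * a1)
    da2[vox] <- sin(b1[vox] * 2 * a1)
    da1 <- rician(da1, sigma); da2 <- rician(da2, sigma)

    subjects[[s]] <- list(
      id = ids[s], group = grp,
      b0_ppm_truth = b0, b1_truth = b1,
      cest = cest, i0 = i0,
      ir = ir, se = se,
      phase1 = phase1, phase2 = phase2,
      da_low = da1, da_high = da2)
  }

  structure(list(config = config, rois = rois, subjects = subjects,
                 truth = truth), class = "cest_study")
}

ground_truth_map <- function(lab, per_roi) {
  out <- matrix(NA_real_, nrow(lab), ncol(lab))
  for (code in 1:4)
    out[lab == code] <- per_roi[[c("WH", "PFC", "HP", "Str")[code]]]
  out
}

#' @export
print.cest_study <- function(x, ...) {
  g <- vapply(x$subjects, `[[`, character(1), "group")
  cat(sprintf("<cest_study> %d x %d, %d CTL + %d FATIGUE subjects, SNR %s\n",
              x$config$matrix_size[1], x$config$matrix_size[2],
              sum(g == "CTL"), sum(g == "FATIGUE"),
              format(x$config$snr)))
  invisible(x)
}

#' Simulate nightly home-cage activity with a post-fatigue dip
#'
#' Nightly counts follow a log-normal model. Baseline nights (-3..-1)
#' have unit multiplicative level; post night k carries a factor
#' \eqn{d^{g^{k-1}}} (d = `dip`, g = `relax`), i.e. the full dip on the
#' first post night relaxing geometrically back to ~1 by night 4.
#'
#' @param n_animals number of animals
#' @param n_nights total nights, >= 7 (3 baseline + >= 4 post)
#' @param dip multiplicative activity level on post night 1 (> 0;
#'   1 = no effect)
#' @param relax geometric relaxation rate of the log-dip
#' @param sigma_log log-scale night-to-night variability
#' @param base_mean baseline mean counts
#' @param seed RNG seed
#' @return data frame: animal_id, night_index (-3..-1 baseline, 1..
#'   post), counts
#' @export
generate_activity_series <- function(n_animals = 5, n_nights = 7,
                                     dip = 0.5, relax = 1 / 3,
                                     sigma_log = 0.2, base_mean = 1000,
                                     seed = 1L) {
  if (!is.finite(dip) || dip <= 0) stop("dip factor must be > 0")
  if (n_nights < 7) stop("need >= 7 nights (3 baseline + >= 4 post)")
  set.seed(seed)
  nights <- c(-3:-1, seq_len(n_nights - 3))
  fac <- ifelse(nights < 0, 1, dip^(relax^(pmax(nights, 1) - 1)))
  out <- do.call(rbind, lapply(seq_len(n_animals), function(a) {
    data.frame(animal_id = sprintf("r%02d", a), night_index = nights,
               counts = rlnorm(length(nights),
                               meanlog = log(base_mean) + log(fac),
                               sdlog = sigma_log))
  }))
  rownames(out) <- NULL
  out
}
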
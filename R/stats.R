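#' Two-sample Student's t-test (pooled variance)
#'
#' The classical equal-variance two-tailed test, df = n_a + n_b - 2.
#' Welch's unequal-variance form is available for sensitivity analysis.
#' With zero pooled variance the test is degenerate: equal means give
#' p = 1 by convention, unequal means are an error.
#'
#' @param a,b numeric samples, each of length >= 2
#' @param var_equal pooled (Student) if TRUE, Welch if FALSE
#' @return a `cest_test` list: statistic, df, p (two-tailed), group means,
#'   SEMs and sizes
#' @examples
#' two_sample_ttest(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, p = 0.0213
#' @export
two_sample_ttest <- function(a, b, var_equal = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 values")
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) {
    if (mean(a) == mean(b)) {
      res <- list(statistic = 0, df = length(a) + length(b) - 2, p = 1)
    } else stop("degenerate samples: zero variance, unequal means")
  } else {
    tt <- t.test(a, b, var.equal = var_equal)
    res <- list(statistic = unname(tt$statistic),
                df = unname(tt$parameter), p = tt$p.value)
  }
  structure(c(res, list(
    mean_a = mean(a), mean_b = mean(b),
    sem_a = sd(a) / sqrt(length(a)), sem_b = sd(b) / sqrt(length(b)),
    n_a = length(a), n_b = length(b))), class = "cest_test")
}

#' @export
print.cest_test <- function(x, ...) {
  cat(sprintf("t = %.4f, df = %.4g, p = %.4g\n", x$statistic, x$df, x$p))
  cat(sprintf("  a: %.4g +/- %.4g (n=%d)   b: %.4g +/- %.4g (n=%d)\n",
              x$mean_a, x$sem_a, x$n_a, x$mean_b, x$sem_b, x$n_b))
  invisible(x)
}

#' Per-ROI group summary table
#'
#' For each ROI (and metric): group means with SEM, percent change of the
#' fatigue group relative to control, and the pooled two-tailed t-test.
#' Percent change = 100 (mean_F - mean_C) / mean_C; undefined (NA) when
#' the control mean is zero.
#'
#' @param table ROI table as produced by [extract_roi_means()], with
#'   groups "CTL" and "FATIGUE"
#' @param var_equal passed to [two_sample_ttest()]
#' @return data frame: roi, metric, ctl_mean, ctl_sem, ctl_n, fat_mean,
#'   fat_sem, fat_n, pct_change, t, df, p
#' @export
group_summary <- function(table, var_equal = TRUE) {
  stopifnot(all(c("group", "roi", "metric", "value") %in% names(table)))
  groups <- unique(table$group)
  if (!all(c("CTL", "FATIGUE") %in% groups))
    stop("both CTL and FATIGUE groups must be present")
  out <- list()
  for (m in unique(table$metric)) for (r in unique(table$roi)) {
    sub <- table[table$metric == m & table$roi == r, ]
    a <- sub$value[sub$group == "CTL"]
    b <- sub$value[sub$group == "FATIGUE"]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2)
      stop("SEM undefined: group with fewer than 2 subjects in ROI ", r)
    tt <- two_sample_ttest(a, b, var_equal = var_equal)
    pct <- if (mean(a) == 0) NA_real_ else 100 * (mean(b) - mean(a)) / mean(a)
    out[[paste(m, r)]] <- data.frame(
      roi = r, metric = m,
      ctl_mean = tt$mean_a, ctl_sem = tt$sem_a, ctl_n = tt$n_a,
      fat_mean = tt$mean_b, fat_sem = tt$sem_b, fat_n = tt$n_b,
      pct_change = pct, t = tt$statistic, df = tt$df, p = tt$p)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Normalize nightly activity to the pre-fatigue baseline
#'
#' Each animal's counts are divided by its own mean over the 3 baseline
#' nights (indices -3, -2, -1), so the baseline mean of the normalized
#' values is exactly 1 per animal. Animals with a zero baseline mean are
#' excluded with a warning.
#'
#' @param raw data frame: animal_id, night_index (negative = baseline),
#'   counts
#' @return the table with a `normalized` column added
#' @export
normalize_activity <- function(raw) {
  stopifnot(all(c("animal_id", "night_index", "counts") %in% names(raw)))
  out <- list()
  for (id in unique(raw$animal_id)) {
    sub <- raw[raw$animal_id == id, ]
    base <- sub$counts[sub$night_index %in% c(-3L, -2L, -1L)]
    if (length(base) < 3)
      stop("animal ", id, " is missing baseline nights")
    bm <- mean(base)
    if (bm == 0) {
      warning("animal ", id, " has zero baseline mean; excluded")
      next
    }
    sub$normalized <- sub$counts / bm
    out[[as.character(id)]] <- sub
  }
  if (!length(out)) stop("no animals with usable baselines")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-way ANOVA across nights with Bonferroni post-hoc
#'
#' Compares activity across time points, with the pooled pre-fatigue
#' baseline (each animal's mean over the 3 baseline nights) as one level
#' and each post-fatigue night as a further level. If the omnibus test
#' rejects at `alpha`, each post night is compared to baseline and the
#' raw p-values are Bonferroni-adjusted (p_adj = min(1, m p), m = number
#' of post nights). The default treats time point as a between-level
#' factor; `repeated_measures = TRUE` blocks on animal instead, which
#' respects the paired design.
#'
#' @param table normalized activity table ([normalize_activity()] output;
#'   run automatically when the `normalized` column is absent)
#' @param alpha omnibus significance threshold
#' @param repeated_measures block on animal in the ANOVA and use paired
#'   post-hoc comparisons
#' @return list with `omnibus` (F, df, p) and `posthoc` data frame
#'   (night, mean, sem, t, df, p, p_adj; empty when the omnibus fails)
#' @export
anova_bonferroni <- function(table, alpha = 0.05, repeated_measures = FALSE) {
  if (!"normalized" %in% names(table)) table <- normalize_activity(table)
  post_nights <- sort(unique(table$night_index[table$night_index > 0]))
  if (length(post_nights) < 1) stop("no post-fatigue nights in table")
  ids <- unique(table$animal_id)
  # baseline level: one pooled pre-fatigue mean per animal
  rows <- lapply(ids, function(id) {
    sub <- table[table$animal_id == id, ]
    if (!all(post_nights %in% sub$night_index)) {
      warning("animal ", id, " is missing nights; excluded listwise")
      return(NULL)
    }
    base <- mean(sub$normalized[sub$night_index < 0])
    data.frame(animal_id = id,
               timepoint = c("baseline", paste0("post", post_nights)),
               value = c(base, sub$normalized[match(post_nights,
                                                    sub$night_index)]))
  })
  long <- do.call(rbind, rows)
  if (length(unique(long$animal_id)) < 2) stop("need at least 2 animals")
  long$timepoint <- factor(long$timepoint,
                           levels = c("baseline", paste0("post", post_nights)))
  fml <- if (repeated_measures) value ~ timepoint + factor(animal_id)
         else value ~ timepoint
  if (var(long$value) <= 1e-20 * mean(long$value)^2) {
    # all time points identical: no variance to test
    omnibus <- list(F = 0, df1 = length(post_nights),
                    df2 = nrow(long) - length(post_nights) - 1, p = 1)
  } else {
    av <- summary(aov(fml, data = long))[[1]]
    omnibus <- list(F = av["timepoint", "F value"],
                    df1 = av["timepoint", "Df"],
                    df2 = av["Residuals", "Df"],
                    p = av["timepoint", "Pr(>F)"])
    if (!is.finite(omnibus$F)) { omnibus$F <- 0; omnibus$p <- 1 }
  }
  posthoc <- data.frame(night = integer(), mean = numeric(),
                        sem = numeric(), t = numeric(), df = numeric(),
                        p = numeric(), p_adj = numeric())
  m <- length(post_nights)
  if (is.finite(omnibus$p) && omnibus$p < alpha) {
    base_vals <- long$value[long$timepoint == "baseline"]
    posthoc <- do.call(rbind, lapply(post_nights, function(k) {
      v <- long$value[long$timepoint == paste0("post", k)]
      tt <- if (repeated_measures) {
        pt <- t.test(v, base_vals, paired = TRUE)
        list(statistic = unname(pt$statistic), df = unname(pt$parameter),
             p = pt$p.value)
      } else two_sample_ttest(v, base_vals)
      data.frame(night = k, mean = mean(v), sem = sd(v) / sqrt(length(v)),
                 t = tt$statistic, df = tt$df, p = tt$p,
                 p_adj = min(1, m * tt$p))
    }))
  }
  list(omnibus = omnibus, posthoc = posthoc, n_comparisons = m,
       data = long)
}

#' @importFrom stats var
NULL
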
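test_that("pooled t-test matches the closed form and its invariances", {
  tt <- two_sample_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.02131164, tolerance = 1e-6)

  same <- two_sample_ttest(c(2, 4, 9), c(2, 4, 9))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # affine transform x -> cx + d of both samples: |t| and p unchanged
  a <- c(1.2, 3.4, 2.2, 5.1); b <- c(2.0, 4.4, 6.1)
  base <- two_sample_ttest(a, b)
  for (cd in list(c(2, 1), c(-3, 10), c(0.01, -4))) {
    tr <- two_sample_ttest(cd[1] * a + cd[2], cd[1] * b + cd[2])
    expect_equal(abs(tr$statistic), abs(base$statistic), tolerance = 1e-10)
    expect_equal(tr$p, base$p, tolerance = 1e-10)
  }

  expect_equal(two_sample_ttest(c(1, 1, 1), c(1, 1))$p, 1)
  expect_error(two_sample_ttest(c(1, 1), c(2, 2)), "degenerate")
  expect_error(two_sample_ttest(1, c(2, 3)), "at least 2")
})

test_that("ROI extraction averages valid voxels and flags empty ROIs", {
  lab <- matrix(0L, 4, 4)
  lab[1:2, 1:2] <- 1L; lab[3, 3] <- 2L; lab[4, 3] <- 3L; lab[4, 4] <- 4L
  rl <- roi_labels(lab)

  const <- param_map(matrix(0.42, 4, 4), "fraction", "GluCEST")
  rows <- extract_roi_means(const, rl, "s", "CTL")
  expect_true(all(rows$value == 0.42))

  two <- matrix(NA_real_, 4, 4)
  two[1, 1] <- 0.02; two[1, 2] <- 0.04
  pm <- param_map(two, "fraction", "GluCEST")
  r2 <- suppressWarnings(extract_roi_means(pm, rl, "s", "CTL"))
  expect_equal(r2$value[r2$roi == "WH"], 0.03)

  w <- capture_warnings(r4 <- extract_roi_means(pm, rl, "s", "CTL"))
  expect_true(any(grepl("PFC", w)))
  expect_true(is.na(r4$value[r4$roi == "PFC"]))
})

test_that("group summary reproduces the whole-brain percent increase", {
  # samples whose means are the printed group values 0.021 and 0.032
  ctl <- 0.021 + c(-0.002, 0, 0.002)
  fat <- 0.032 + c(-0.001, 0, 0.001)
  tab <- data.frame(
    subject_id = paste0("s", 1:6),
    group = rep(c("CTL", "FATIGUE"), each = 3),
    roi = "WH", metric = "glucest", value = c(ctl, fat))
  gs <- group_summary(tab)
  expect_equal(gs$ctl_mean, 0.021)
  expect_equal(gs$fat_mean, 0.032)
  expect_equal(gs$pct_change, 100 * (0.032 - 0.021) / 0.021,
               tolerance = 1e-10)
  expect_equal(gs$df, 4)

  # equal group means -> zero percent change
  tab0 <- tab; tab0$value <- rep(c(1, 2, 3), 2)
  expect_equal(group_summary(tab0)$pct_change, 0)

  # single-subject group: SEM undefined
  tab1 <- tab[-(1:2), ]
  expect_error(group_summary(tab1), "SEM undefined")

  # percent change is self-consistent with its own reported means
  expect_equal(gs$pct_change,
               100 * (gs$fat_mean - gs$ctl_mean) / gs$ctl_mean)
})

test_that("activity normalization divides by each animal's baseline mean", {
  raw <- data.frame(animal_id = "a1",
                    night_index = c(-3, -2, -1, 1),
                    counts = c(100, 100, 100, 50))
  norm <- normalize_activity(raw)
  expect_equal(norm$normalized, c(1, 1, 1, 0.5))

  flat <- data.frame(animal_id = "a2", night_index = c(-3:-1, 1:4),
                     counts = rep(77, 7))
  expect_true(all(normalize_activity(flat)$normalized == 1))

  zero <- rbind(raw,
                data.frame(animal_id = "a3", night_index = c(-3, -2, -1, 1),
                           counts = 0))
  expect_warning(nz <- normalize_activity(zero), "zero baseline")
  expect_false("a3" %in% nz$animal_id)

  missing_base <- data.frame(animal_id = "a4", night_index = c(-2, -1, 1),
                             counts = 1:3)
  expect_error(normalize_activity(missing_base), "baseline")
})

test_that("activity ANOVA handles nulls, identities and the Bonferroni cap", {
  # all nights identical: omnibus degenerates to F = 0, p = 1, no post-hoc
  flat <- do.call(rbind, lapply(1:4, function(a)
    data.frame(animal_id = a, night_index = c(-3:-1, 1:4), counts = 100)))
  res <- anova_bonferroni(flat)
  expect_equal(res$omnibus$F, 0)
  expect_equal(res$omnibus$p, 1)
  expect_equal(nrow(res$posthoc), 0)

  # two time points: ANOVA F equals t^2 of the corresponding t-test
  set.seed(9)
  two <- do.call(rbind, lapply(1:6, function(a)
    data.frame(animal_id = a, night_index = c(-3:-1, 1),
               counts = rlnorm(4, log(100) + c(0, 0, 0, log(0.5)), 0.2))))
  res2 <- anova_bonferroni(two, alpha = 1)  # force post-hoc
  base <- res2$data$value[res2$data$timepoint == "baseline"]
  post <- res2$data$value[res2$data$timepoint == "post1"]
  tt <- two_sample_ttest(post, base)
  expect_equal(res2$omnibus$F, tt$statistic^2, tolerance = 1e-10)

  # Bonferroni: p_adj = min(1, m p); m = 4 post nights caps 0.3 at 1
  expect_equal(min(1, 4 * 0.3), 1.0)
  act <- normalize_activity(generate_activity_series(n_animals = 6,
                                                     dip = 0.5, seed = 12))
  res3 <- anova_bonferroni(act)
  expect_true(all(res3$posthoc$p_adj >= res3$posthoc$p))
  expect_true(all(res3$posthoc$p_adj <=
                    pmin(1, res3$n_comparisons * res3$posthoc$p) + 1e-12))
  expect_true(all(res3$posthoc$p_adj <= 1))

  # repeated-measures variant runs and respects pairing
  res4 <- anova_bonferroni(act, repeated_measures = TRUE)
  expect_true(is.finite(res4$omnibus$F))
})

test_that("designed activity dip is detected with high power", {
  rejections <- 0L
  n_rep <- 50L
  for (r in seq_len(n_rep)) {
    act <- generate_activity_series(n_animals = 5, dip = 0.5,
                                    seed = 1000L + r)
    res <- anova_bonferroni(normalize_activity(act))
    if (res$omnibus$p < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / n_rep, 0.8)
})
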
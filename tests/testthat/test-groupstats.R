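test_that("roi_summary averages valid voxels only", {
  d <- array(7, dim = c(4, 4, 2))
  m <- parametric_map(d, c(1, 1, 1), "MTR", "%")
  whole <- roi_mask(array(TRUE, dim(d)), c(1, 1, 1), "brain")
  s <- roi_summary(m, whole)
  expect_equal(s$mean, 7)
  expect_equal(s$sem, 0)
  expect_equal(s$n, 32)

  chk <- array(rep(c(10, 20), 16), dim = c(4, 4, 2))
  s2 <- roi_summary(parametric_map(chk, c(1, 1, 1), "MTR", "%"), whole)
  expect_equal(s2$mean, 15)

  valid <- array(TRUE, dim(d))
  valid[1, , ] <- FALSE
  mv <- parametric_map(d, c(1, 1, 1), "MTR", "%", valid = valid)
  s3 <- roi_summary(mv, whole)
  expect_equal(s3$n, 24)
  expect_equal(s3$n_excluded, 8)
  none <- parametric_map(d, c(1, 1, 1), "MTR", "%",
    valid = array(FALSE, dim(d))
  )
  expect_error(roi_summary(none, whole), "no valid voxels")
})

test_that("mask_volume is count times voxel volume", {
  d <- array(FALSE, dim = c(10, 10, 1))
  d[1:10, 1:10, 1] <- TRUE
  m <- roi_mask(d, c(0.136, 0.136, 1.5), "core")
  expect_equal(mask_volume(m), 100 * 0.136 * 0.136 * 1.5)
  expect_equal(mask_volume(roi_mask(array(FALSE, c(2, 2, 1)), c(1, 1, 1), "core")), 0)
})

test_that("percent change follows the relative-change definition", {
  gl <- group_summary(mean = 22.00, sem = 0.16, n = 8, label = "male/tumour")
  sh <- group_summary(mean = 20.10, sem = 0.20, n = 8, label = "male/sham")
  pc <- percent_change(gl, sh)
  expect_equal(pc$pct, (22.00 - 20.10) / 20.10 * 100)
  expect_equal(pc$pct, 9.4527, tolerance = 1e-4)

  gl2 <- group_summary(mean = 13.02, sem = 0.07, n = 8)
  sh2 <- group_summary(mean = 18.57, sem = 0.22, n = 8)
  expect_equal(percent_change(gl2, sh2)$pct, -29.8869, tolerance = 1e-4)

  same <- percent_change(gl, gl)
  expect_equal(same$pct, 0)
  expect_error(
    percent_change(gl, group_summary(mean = 0, sem = 1, n = 8)),
    "nonzero"
  )
  # sign convention: glioma above sham is a positive change
  expect_gt(percent_change(gl, sh)$pct, 0)
  expect_lt(percent_change(sh, gl)$pct, 0)
})

test_that("per-subject percent-change mode averages subject ratios", {
  sh <- group_summary(mean = 10, sem = 0.5, n = 4)
  gl <- group_summary(label = "g", values = c(11, 12, 13, 14))
  pc <- percent_change(gl, sh, mode = "per-subject")
  expect_equal(pc$pct, mean(c(10, 20, 30, 40)))
  expect_equal(pc$sem, sd(c(10, 20, 30, 40)) / 2)
  expect_error(percent_change(sh, sh, mode = "per-subject"), "raw")
})

test_that("Welch test reproduces the closed-form arithmetic", {
  a <- group_summary(mean = 9.44, sem = 0.42, n = 8)
  b <- group_summary(mean = 8.09, sem = 0.41, n = 8)
  w <- welch_test(a, b)
  expect_equal(w$t, (9.44 - 8.09) / sqrt(0.42^2 + 0.41^2), tolerance = 1e-12)
  expect_equal(w$t, 2.30, tolerance = 0.005)
  expect_equal(w$df, 13.99, tolerance = 0.01)
  expect_lt(w$p, 0.05)
  expect_equal(w$stars, "*")

  same <- welch_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  z <- group_summary(mean = 1, sem = 0, n = 8)
  expect_error(welch_test(z, z), "SEMs are zero")
})

test_that("raw-mode Welch coincides with summary mode and stats::t.test", {
  set.seed(8)
  x <- rnorm(8, 1, 1)
  y <- rnorm(8, 0, 2)
  raw <- welch_test(
    group_summary(label = "a", values = x),
    group_summary(label = "b", values = y)
  )
  summ <- welch_test(
    group_summary(mean = mean(x), sem = sd(x) / sqrt(8), n = 8),
    group_summary(mean = mean(y), sem = sd(y) / sqrt(8), n = 8)
  )
  expect_equal(raw$t, summ$t)
  expect_equal(raw$p, summ$p)
  tt <- t.test(x, y) # independent reference implementation
  expect_equal(raw$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(raw$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(raw$p, tt$p.value, tolerance = 1e-12)
})

test_that("significance stars follow the figure-legend convention", {
  expect_equal(significance_stars(0.04), "*")
  expect_equal(significance_stars(0.0005), "***")
  expect_equal(significance_stars(0.004), "**")
  expect_equal(significance_stars(5e-5), "****")
  expect_equal(significance_stars(0.2), "ns")
})

test_that("day/night RER aggregation recovers configured group offsets", {
  # constant RER: zero change in both cycles
  cfg <- default_rer_config()
  cfg$pct_change <- lapply(cfg$pct_change, function(x) c(day = 0, night = 0))
  cfg$subject_sd <- 0
  cfg$bin_sd <- 0
  rec <- simulate_rer_cohort(n_per_group = 3, hours = 48, seed = 2, config = cfg)
  out <- rer_day_night(rec)
  expect_equal(out$comparison$pct_change, rep(0, 4), tolerance = 1e-10)

  # configured day offsets are recovered within Monte-Carlo error
  rec2 <- simulate_rer_cohort(n_per_group = 40, hours = 60, seed = 3)
  out2 <- rer_day_night(rec2)
  day <- out2$comparison[out2$comparison$cycle == "day", ]
  # 4-sigma Monte-Carlo band: subject day-mean SD ~0.004 RER at n = 40
  # per group gives a difference SEM of ~0.1 percentage points
  expect_lt(abs(day$pct_change[day$sex == "male"] - (-4.85)), 0.4)
  expect_lt(abs(day$pct_change[day$sex == "female"] - (-1.22)), 0.4)
  night <- out2$comparison[out2$comparison$cycle == "night", ]
  expect_lt(abs(night$pct_change[night$sex == "male"] - (-4.11)), 0.4)
  expect_lt(abs(night$pct_change[night$sex == "female"] - (-1.99)), 0.4)

  # shifting the light schedule by 12 h swaps the day and night aggregates
  rec3 <- rec
  rec3$light <- !rec3$light
  out3 <- rer_day_night(rec3)
  m <- out$subject_means
  m3 <- out3$subject_means
  expect_equal(
    m3$rer[m3$cycle == "day"][order(m3$subject[m3$cycle == "day"])],
    m$rer[m$cycle == "night"][order(m$subject[m$cycle == "night"])]
  )
  expect_error(
    rer_day_night(rec[rec$time_h < 20, ]),
    "full 24-h cycle"
  )
})

test_that("report tables reproduce a noiseless cohort's generating values", {
  co <- simulate_cohort(n_per_group = 3, seed = 1, sd = 0)
  rep_ <- build_report(co$values)
  eff <- default_group_effects()
  for (i in seq_len(nrow(rep_$absolute))) {
    r <- rep_$absolute[i, ]
    expect_equal(
      r$mean_male_tumour,
      effect_value(eff, "male/tumour", r$region, r$quantity)
    )
    expect_equal(
      r$mean_female_sham,
      effect_value(eff, "female/sham", r$region, r$quantity)
    )
  }
  expect_true(all(grepl("±", rep_$absolute$male_tumour)))
  # degenerate zero-SD comparisons are flagged, not starred
  expect_true(all(rep_$change$stars == ""))
  # a noisy cohort carries star annotations
  con <- simulate_cohort(n_per_group = 4, seed = 6)
  repn <- build_report(con$values)
  expect_true(all(repn$change$stars %in% c("ns", "*", "**", "***", "****")))

  broken <- co$values[co$values$group != "female/sham", ]
  expect_error(build_report(broken), "female/sham")
  expect_error(build_report(co$values[0, ]), "missing group")
})
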
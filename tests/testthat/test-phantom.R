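test_that("phantom masks partition the lesion and stay inside the brain", {
  for (grid in c("map", "dsc")) {
    mk <- phantom_masks(small_geometry(), grid)
    expect_false(any(mk$core & mk$periphery))
    expect_true(all(vol_data(mk$tumour) == (vol_data(mk$core) | vol_data(mk$periphery))))
    expect_true(all(!vol_data(mk$tumour) | vol_data(mk$brain)))
    expect_true(all(!vol_data(mk$reference) | vol_data(mk$brain)))
    expect_false(any(mk$reference & mk$tumour))
    expect_gt(sum(mk$core), 0)
    expect_gt(sum(mk$periphery), 0)
  }
})

test_that("the default tumour matches the scan-trigger volume", {
  mk <- phantom_masks(phantom_geometry(), "map")
  v <- mask_volume(mk$tumour)
  expect_gte(v, 75)
  expect_lte(v, 100)
})

test_that("geometry rejects regions that leave the brain or collide", {
  expect_error(
    phantom_geometry(reference_centre = c(-1, 1, 0)),
    "overlaps"
  )
  expect_error(
    phantom_geometry(tumour_centre = c(7, 0, 0)),
    "outside the brain"
  )
})

test_that("truth maps carry the group-effect values and are deterministic", {
  g <- small_geometry()
  tr <- make_truth(g, group = "female/tumour", seed = 1)
  core <- vol_data(tr$masks_map$core)
  expect_equal(mean(tr$maps$md[core]), 1120)
  expect_equal(mean(tr$maps$mtr[core]), 13.02)
  peri <- vol_data(tr$masks_map$periphery)
  expect_equal(mean(tr$maps$md[peri]), 955)

  tr2 <- make_truth(g, group = "female/tumour", seed = 1)
  expect_identical(tr$maps, tr2$maps)
  expect_identical(tr$perf, tr2$perf)

  expect_error(make_truth(g, group = "male/glioma"), "valid groups")
})

test_that("sham truth shows no lesion contrast beyond regional baselines", {
  tr <- make_truth(small_geometry(), group = "male/sham", seed = 7)
  core <- mean(tr$maps$mtr[vol_data(tr$masks_map$core)])
  peri <- mean(tr$maps$mtr[vol_data(tr$masks_map$periphery)])
  # sham regional values differ only by the small baseline difference of
  # analogous healthy areas, not by a lesion effect
  expect_lt(abs(core - peri) / core, 0.02)
  md_core <- mean(tr$maps$md[vol_data(tr$masks_map$core)])
  md_peri <- mean(tr$maps$md[vol_data(tr$masks_map$periphery)])
  expect_lt(abs(md_core - md_peri) / md_core, 0.02)
})

test_that("truth tensor field reproduces the MD/FA maps", {
  tr <- make_truth(small_geometry(), group = "male/tumour", orientation = "random")
  idx <- sample(which(vol_data(tr$masks_map$brain)), 50)
  for (i in idx) {
    lam <- mpmri:::eigen_spectrum6(c(
      tr$tensor$xx[i], tr$tensor$yy[i], tr$tensor$zz[i],
      tr$tensor$xy[i], tr$tensor$xz[i], tr$tensor$yz[i]
    ))
    expect_equal(md_from_eigenvalues(lam), tr$maps$md[i], tolerance = 1e-9)
    expect_equal(fa_from_eigenvalues(lam), tr$maps$fa[i], tolerance = 1e-9)
    expect_true(all(lam >= -1e-6))
  }
})

test_that("MT pair inverts the MTR definition and validates snr", {
  tr <- make_truth(small_geometry(), group = "male/tumour")
  pair <- simulate_mt_pair(tr)
  brain <- vol_data(tr$masks_map$brain)
  ratio <- vol_data(pair$smt)[brain] / vol_data(pair$s0)[brain]
  expect_equal(ratio, 1 - tr$maps$mtr[brain] / 100)
  expect_error(simulate_mt_pair(tr, snr = 0), "positive")
  expect_error(simulate_mt_pair(tr, snr = -3), "positive")
  n1 <- simulate_mt_pair(tr, snr = 40, seed = 3)
  n2 <- simulate_mt_pair(tr, snr = 40, seed = 3)
  expect_identical(vol_data(n1$s0), vol_data(n2$s0))
  expect_false(identical(vol_data(n1$s0), vol_data(pair$s0)))
})

test_that("noisy MTR matches a Rician Monte-Carlo oracle", {
  tr <- make_truth(small_geometry(), group = "male/tumour")
  snr <- 40
  pair <- simulate_mt_pair(tr, snr = snr, seed = 3)
  m <- compute_mtr(pair, tr$masks_map$brain)
  core <- tr$masks_map$core
  obs <- roi_summary(m, core)

  # oracle: expected value of the ratio estimator under Rician noise,
  # from 10,000 independent draws at the core's true signal levels
  s0_ref <- 1000
  sigma <- s0_ref / snr
  mtr_true <- 14.29
  set.seed(999)
  nmc <- 10000
  s0d <- sqrt((s0_ref + rnorm(nmc, 0, sigma))^2 + rnorm(nmc, 0, sigma)^2)
  smtd <- sqrt((s0_ref * (1 - mtr_true / 100) + rnorm(nmc, 0, sigma))^2 +
    rnorm(nmc, 0, sigma)^2)
  est <- (s0d - smtd) / s0d * 100
  tol <- 4 * sd(est) / sqrt(obs$n)
  expect_lt(abs(obs$mean - mean(est)), tol)
})

test_that("diffusion simulation honours isotropy and the b = 0 volume", {
  g <- small_geometry()
  eff <- default_group_effects()
  eff$mean[eff$quantity == "fa"] <- 0 # isotropic everywhere
  tr <- make_truth(g, eff, group = "male/tumour")
  scheme <- default_dti_scheme()
  dwi <- simulate_dwi(tr, scheme)
  sig <- vol_data(dwi)
  brain <- which(vol_data(tr$masks_map$brain))
  i300 <- which(scheme$table$b == 300)
  # identical signal in all directions at fixed b for isotropic tensors
  flat <- matrix(aperm(sig, c(4, 1, 2, 3)), nrow = dim(sig)[4])
  expect_equal(
    apply(flat[i300, brain[1:50]], 2, function(x) diff(range(x))),
    rep(0, 50)
  )
  # b = 0 equals S0 exactly
  expect_equal(flat[1, brain], rep(1000, length(brain)))
})

test_that("simulate_dwi rejects non-unit directions", {
  expect_error(
    dti_scheme(c(0, 300), rbind(c(0, 0, 0), c(1, 1, 0))),
    "unit-norm"
  )
})

test_that("DSC simulation matches the gamma-variate closed forms", {
  g <- small_geometry()
  tr <- make_truth(g, group = "male/tumour")
  acq <- dsc_acquisition()
  dsc <- simulate_dsc(tr, acq, conc_scale = 1)
  times <- dsc_times(acq)
  # a tumour voxel: recover concentration, compare with analytic area
  vox <- which(vol_data(tr$masks_dsc$tumour))[1]
  idx <- arrayInd(vox, dim(vol_data(tr$masks_dsc$tumour)))
  s <- vol_data(dsc)[idx[1], idx[2], idx[3], ]
  cc <- signal_to_concentration(s, acq)
  K <- tr$perf$K[vox]
  alpha <- tr$perf$alpha
  beta <- tr$perf$beta[vox]
  analytic_cbv <- K * beta^(alpha + 1) * gamma(alpha + 1)
  num_cbv <- sum(diff(times) * (head(cc$conc, -1) + tail(cc$conc, -1)) / 2)
  expect_equal(num_cbv, analytic_cbv, tolerance = 5e-3)
  # first moment about the origin = t0 + beta (alpha + 1)
  num_m1 <- sum(diff(times) * (head(cc$conc * times, -1) + tail(cc$conc * times, -1)) / 2)
  expect_equal(num_m1 / num_cbv, tr$perf$t0 + beta * (alpha + 1),
    tolerance = 5e-3
  )

  # K = 0 voxel -> flat signal at baseline
  bg <- which(vol_data(tr$masks_dsc$brain) & tr$perf$K == 0)
  expect_length(bg, 0) # every brain voxel perfused in this phantom
  eff0 <- default_group_effects()
  eff0$mean[eff0$quantity == "cbv"] <- 1 # same as reference
  tr0 <- make_truth(g, eff0, group = "male/sham", reference_cbv = 0)
  d0 <- simulate_dsc(tr0, acq)
  v0 <- which(vol_data(tr0$masks_dsc$brain))[1]
  i0 <- arrayInd(v0, dim(vol_data(tr0$masks_dsc$brain)))
  expect_equal(
    vol_data(d0)[i0[1], i0[2], i0[3], ],
    rep(1000, acq$n_rep)
  )
})

test_that("DSC simulation validates the bolus arrival window", {
  tr <- make_truth(small_geometry(), group = "male/tumour", arrival_time = 50)
  expect_error(simulate_dsc(tr, dsc_acquisition()), "window")
})

test_that("cohort simulation is seeded, bounded and errors on tiny n", {
  expect_error(simulate_cohort(n_per_group = 1), ">= 2")
  c0 <- simulate_cohort(n_per_group = 4, seed = 5, sd = 0)
  # zero SD: all subjects identical to the group mean
  v <- c0$values[c0$values$group == "male/tumour" &
    c0$values$region == "core" & c0$values$quantity == "mtr", ]
  expect_equal(v$value, rep(14.29, 4))
  c1 <- simulate_cohort(n_per_group = 4, seed = 5)
  c2 <- simulate_cohort(n_per_group = 4, seed = 5)
  expect_identical(c1$values, c2$values)

  # group mean converges to the generating value as n grows
  cbig <- simulate_cohort(n_per_group = 400, seed = 9)
  vb <- cbig$values[cbig$values$group == "male/tumour" &
    cbig$values$region == "core" & cbig$values$quantity == "mtr", "value"]
  # SEM at n = 400 is 0.35*sqrt(8)/20 = 0.0495; 4 SEM band
  expect_lt(abs(mean(vb) - 14.29), 4 * 0.35 * sqrt(8) / sqrt(400))
})

test_that("simulated percent-change recovers the generating effect", {
  # 500 seeded replicates at the study's n = 8: the simulated core-MD
  # percent change for males lies within 3 SEM of its generating value in
  # at least 95% of replicates
  gen <- (1200 - 1028) / 1028 * 100
  hit <- 0L
  reps <- 500L
  for (r in seq_len(reps)) {
    co <- simulate_cohort(n_per_group = 8, seed = 1000 + r)
    v <- co$values[co$values$region == "core" & co$values$quantity == "md", ]
    gl <- group_summary(label = "mt", values = v$value[v$group == "male/tumour"])
    sh <- group_summary(label = "ms", values = v$value[v$group == "male/sham"])
    pc <- percent_change(gl, sh)
    if (abs(pc$pct - gen) <= 3 * pc$sem) hit <- hit + 1L
  }
  expect_gte(hit / reps, 0.95)
})

test_that("RER series has the right binning and configurable means", {
  r <- simulate_rer("male/sham", hours = 60, seed = 1)
  expect_equal(nrow(r), 120)
  expect_equal(diff(r$time_h)[1], 0.5)
  # 60 h from lights-on covers [0,12), [24,36) and [48,60) in the light
  expect_equal(sum(r$light), 72)

  cfg <- default_rer_config()
  cfg$night_mean <- cfg$day_mean # constant configuration
  cfg$ripple_amplitude <- 0
  cfg$subject_sd <- 0
  cfg$bin_sd <- 0
  rc <- simulate_rer("male/sham", hours = 48, seed = 2, config = cfg)
  expect_equal(mean(rc$rer[rc$light]), mean(rc$rer[!rc$light]))

  expect_identical(
    simulate_rer("female/tumour", 60, seed = 4),
    simulate_rer("female/tumour", 60, seed = 4)
  )
  expect_error(simulate_rer("male/sham", hours = 0), "> 0")
})
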
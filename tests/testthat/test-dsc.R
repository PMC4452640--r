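test_that("acquisition parameters are validated", {
  acq <- dsc_acquisition()
  expect_equal(length(dsc_times(acq)), 150)
  expect_equal(max(dsc_times(acq)), 37.25)
  expect_error(dsc_acquisition(n_rep = 20, injection_time = 10), "before the bolus")
})

test_that("signal-to-concentration inverts the exponential model", {
  acq <- dsc_acquisition()
  times <- dsc_times(acq)
  # flat signal -> zero concentration
  cc <- signal_to_concentration(rep(500, acq$n_rep), acq)
  expect_equal(cc$conc, rep(0, acq$n_rep))
  # exact inversion of a known concentration curve
  conc <- mpmri:::gamma_variate(times, K = 3, alpha = 2, beta = 2, t0 = 10)
  s <- 800 * exp(-acq$te * conc)
  back <- signal_to_concentration(s, acq)
  expect_equal(back$conc, conc, tolerance = 1e-10)
  expect_equal(back$s_base, 800)
  # non-positive frames flagged
  s2 <- s
  s2[80] <- 0
  b2 <- signal_to_concentration(s2, acq)
  expect_equal(b2$flagged, 80L)
  expect_true(is.na(b2$conc[80]))
  expect_error(
    signal_to_concentration(s, acq, baseline_frames = integer(0)),
    "empty baseline"
  )
})

test_that("gamma-variate fit recovers noiseless parameters", {
  acq <- dsc_acquisition()
  times <- dsc_times(acq)
  truth <- list(K = 1, alpha = 2, beta = 2, t0 = 10)
  curve <- mpmri:::gamma_variate(times, truth$K, truth$alpha, truth$beta, truth$t0)
  fit <- fit_gamma_variate(curve, times)
  expect_true(fit$converged)
  expect_equal(fit$K, truth$K, tolerance = 1e-6)
  expect_equal(fit$alpha, truth$alpha, tolerance = 1e-6)
  expect_equal(fit$beta, truth$beta, tolerance = 1e-6)
  expect_equal(fit$t0, truth$t0, tolerance = 1e-6)
})

test_that("flat or empty curves are flagged, not fitted", {
  times <- dsc_times(dsc_acquisition())
  f0 <- fit_gamma_variate(rep(0, length(times)), times)
  expect_false(f0$converged)
  expect_true(is.na(f0$K))
  fna <- fit_gamma_variate(rep(NA_real_, length(times)), times)
  expect_false(fna$converged)
})

test_that("noisy gamma fits stay within a Monte-Carlo RMSE bound", {
  acq <- dsc_acquisition()
  times <- dsc_times(acq)
  truth <- list(K = 1, alpha = 2, beta = 2, t0 = 10)
  curve <- mpmri:::gamma_variate(times, truth$K, truth$alpha, truth$beta, truth$t0)
  sigma <- 0.02 * max(curve)
  # oracle: distribution of the CBV estimate over independent replicates
  set.seed(11)
  nmc <- 300
  cbv_true <- truth$K * truth$beta^(truth$alpha + 1) * gamma(truth$alpha + 1)
  cbv_mc <- replicate(nmc, {
    f <- fit_gamma_variate(curve + rnorm(length(curve), 0, sigma), times)
    if (f$converged) perfusion_summaries(f)$cbv else NA_real_
  })
  conv_rate <- mean(!is.na(cbv_mc))
  expect_gte(conv_rate, 0.95)
  rmse <- sqrt(mean((cbv_mc[!is.na(cbv_mc)] - cbv_true)^2))
  # the estimator's RMSE at 2% peak noise is small relative to CBV
  expect_lt(rmse / cbv_true, 0.05)
  # a fresh seeded fit lands inside the oracle's 4-sigma band
  set.seed(12)
  f1 <- fit_gamma_variate(curve + rnorm(length(curve), 0, sigma), times)
  expect_lt(
    abs(perfusion_summaries(f1)$cbv - mean(cbv_mc, na.rm = TRUE)),
    4 * sd(cbv_mc, na.rm = TRUE)
  )
})

test_that("perfusion summaries match the closed-form gamma integrals", {
  fit <- structure(
    list(
      K = 1, alpha = 2, beta = 2, t0 = 10, residual_norm = 0,
      converged = TRUE, n_used = 150L
    ),
    class = "gamma_fit"
  )
  ps <- perfusion_summaries(fit)
  expect_equal(ps$cbv, 16) # K beta^(a+1) Gamma(a+1) = 1*8*2
  expect_equal(ps$mtt, 6) # beta (alpha+1)
  expect_equal(ps$cbf, 16 / 6)
  # doubling K doubles CBV and CBF, leaves MTT unchanged
  fit2 <- fit
  fit2$K <- 2
  ps2 <- perfusion_summaries(fit2)
  expect_equal(ps2$cbv, 2 * ps$cbv)
  expect_equal(ps2$cbf, 2 * ps$cbf)
  expect_equal(ps2$mtt, ps$mtt)
})

test_that("trapezoid and analytic CBV/MTT agree at the study's sampling", {
  acq <- dsc_acquisition()
  times <- dsc_times(acq)
  curve <- mpmri:::gamma_variate(times, 1, 2, 2, 10)
  num <- perfusion_summaries(curve = curve, times = times, t0 = 10)
  expect_equal(num$cbv, 16, tolerance = 5e-3)
  expect_equal(num$mtt, 6, tolerance = 5e-3)
})

test_that("MTT of zero invalidates CBF", {
  fit <- structure(
    list(
      K = 1, alpha = 2, beta = 0, t0 = 10, residual_norm = 0,
      converged = TRUE, n_used = 150L
    ),
    class = "gamma_fit"
  )
  ps <- perfusion_summaries(fit)
  expect_false(ps$valid)
  expect_true(is.na(ps$cbf))
})

test_that("reference normalization is exact and scale invariant", {
  set.seed(4)
  d <- array(runif(4 * 4 * 2, 1, 2), dim = c(4, 4, 2))
  m <- parametric_map(d, c(1, 1, 1), "CBV", "a.u.")
  whole <- roi_mask(array(TRUE, dim(d)), c(1, 1, 1), "brain")
  rel <- normalize_to_reference(m, whole)
  expect_equal(roi_summary(rel, whole)$mean, 1)
  m10 <- parametric_map(10 * d, c(1, 1, 1), "CBV", "a.u.")
  rel10 <- normalize_to_reference(m10, whole)
  expect_equal(vol_data(rel10), vol_data(rel))
  z <- parametric_map(array(0, dim(d)), c(1, 1, 1), "CBV", "a.u.")
  expect_error(normalize_to_reference(z, whole), "zero")
})

test_that("noiseless phantom perfusion recovers the relative truth", {
  tr <- make_truth(small_geometry(), group = "male/tumour")
  acq <- dsc_acquisition()
  dsc <- simulate_dsc(tr, acq)
  md_ <- tr$masks_dsc
  fitmask <- roi_mask(
    vol_data(md_$tumour) | vol_data(md_$reference),
    attr(md_$tumour, "pixdim"), "brain"
  )
  perf <- quantify_dsc(dsc, acq, fitmask)
  expect_equal(perf$n_flagged, 0)
  rel <- lapply(perf[c("cbv", "cbf", "mtt")], normalize_to_reference,
    reference = md_$reference
  )
  expect_equal(roi_summary(rel$cbv, md_$tumour)$mean, 1.44, tolerance = 1e-3)
  expect_equal(roi_summary(rel$mtt, md_$tumour)$mean, 1.077, tolerance = 1e-3)
  # central-volume relation ties relative CBF to CBV/MTT
  expect_equal(roi_summary(rel$cbf, md_$tumour)$mean, 1.44 / 1.077,
    tolerance = 1e-3
  )
  # maps are non-negative wherever valid
  expect_true(all(vol_data(perf$cbv)[map_valid(perf$cbv)] >= 0))
  expect_true(all(vol_data(perf$mtt)[map_valid(perf$mtt)] >= 0))
})
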
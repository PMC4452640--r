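#' DSC acquisition parameters
#'
#' Bolus-tracking timing: the study used TR = 250 ms, TE = 7.1 ms, 150
#' repetitions (about 38 s total) with the contrast bolus injected 10 s
#' after the acquisition start, flip angle 30 degrees (metadata only).
#'
#' @param tr repetition time in s.
#' @param te echo time in s.
#' @param n_rep number of repetitions.
#' @param injection_time bolus injection time in s after start.
#' @param flip_angle_deg flip angle metadata.
#' @return a `dsc_acquisition` object.
#' @export
dsc_acquisition <- function(tr = 0.25, te = 0.0071, n_rep = 150L,
                            injection_time = 10, flip_angle_deg = 30) {
  stopifnot(tr > 0, te > 0, n_rep >= 2)
  if (tr * n_rep < injection_time) {
    stop("acquisition ends before the bolus injection", call. = FALSE)
  }
  structure(
    list(
      tr = tr, te = te, n_rep = as.integer(n_rep),
      injection_time = injection_time, flip_angle_deg = flip_angle_deg
    ),
    class = "dsc_acquisition"
  )
}

#' @rdname dsc_acquisition
#' @param acq a `dsc_acquisition`.
#' @return `dsc_times`: frame times in s (first frame at t = 0).
#' @export
dsc_times <- function(acq) (seq_len(acq$n_rep) - 1) * acq$tr

#' Convert a DSC signal time course to contrast concentration
#'
#' First-pass susceptibility model with unit proportionality:
#' `C(t) = -log(S(t)/S_base) / TE` with `S_base` the mean over the
#' baseline frames. The default baseline is every frame ending one frame
#' before the injection time (1-frame guard). Frames with non-positive
#' signal are flagged and set `NA`.
#'
#' @param signal numeric vector (one voxel's time course) or a matrix
#'   with one column per voxel.
#' @param acq a [dsc_acquisition()].
#' @param baseline_frames integer frame indices, or `NULL` for the
#'   default pre-injection window.
#' @return for a vector input, a list with `conc`, `s_base` and
#'   `flagged` (indices of non-positive frames); for a matrix, a list
#'   with matrix `conc` and vector `s_base`.
#' @export
signal_to_concentration <- function(signal, acq, baseline_frames = NULL) {
  times <- dsc_times(acq)
  if (is.null(baseline_frames)) {
    baseline_frames <- which(times < acq$injection_time - acq$tr)
  }
  if (length(baseline_frames) == 0) {
    stop("empty baseline window", call. = FALSE)
  }
  to_conc <- function(s) {
    sb <- mean(s[baseline_frames])
    if (!is.finite(sb) || sb <= 0) {
      stop("baseline mean must be positive", call. = FALSE)
    }
    bad <- which(s <= 0)
    cc <- rep(NA_real_, length(s))
    okv <- s > 0
    cc[okv] <- -log(s[okv] / sb) / acq$te
    list(conc = cc, s_base = sb, flagged = bad)
  }
  if (is.matrix(signal)) {
    out <- apply(signal, 2, to_conc, simplify = FALSE)
    list(
      conc = vapply(out, `[[`, numeric(nrow(signal)), "conc"),
      s_base = vapply(out, `[[`, numeric(1), "s_base")
    )
  } else {
    to_conc(as.numeric(signal))
  }
}

# Gamma-variate evaluated with the convention C = 0 at and before t0.
gamma_variate <- function(t, K, alpha, beta, t0) {
  dt <- pmax(t - t0, 0)
  out <- K * dt^alpha * exp(-dt / beta)
  out[dt == 0] <- 0
  out
}

#' Fit a gamma-variate bolus model to a concentration time course
#'
#' Nonlinear least squares of `C(t) = K (t-t0)^alpha exp(-(t-t0)/beta)`.
#' Initialization: t0 from the last sub-5%-of-peak sample before the
#' peak, then a log-linearized pre-fit (`log C` linear in `log(t-t0)` and
#' `(t-t0)`) seeds K, alpha and beta; Levenberg-Marquardt (bounded
#' iterations) refines all four parameters. To avoid recirculation
#' contamination the fitted window ends at 1.5 times the
#' first-rise-to-return-below-20%-of-peak span (configurable).
#' Non-convergent or flat/peakless curves return a flagged result
#' (`converged = FALSE`), never an exception.
#'
#' @param curve numeric concentration time course (a.u.).
#' @param times frame times in s.
#' @param peak_floor minimum peak value to attempt a fit.
#' @param window_factor recirculation-trim factor (Inf = use all frames).
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @return a `gamma_fit` list: `K`, `alpha`, `beta`, `t0`,
#'   `residual_norm`, `converged`, `n_used`.
#' @export
fit_gamma_variate <- function(curve, times, peak_floor = 1e-8,
                              window_factor = 1.5, max_iter = 100L) {
  stopifnot(length(curve) == length(times))
  flagged <- list(
    K = NA_real_, alpha = NA_real_, beta = NA_real_, t0 = NA_real_,
    residual_norm = NA_real_, converged = FALSE, n_used = 0L
  )
  class(flagged) <- "gamma_fit"
  use <- is.finite(curve)
  y <- curve[use]
  tt <- times[use]
  if (length(y) < 6) {
    return(flagged)
  }
  pk <- which.max(y)
  peak <- y[pk]
  if (!is.finite(peak) || peak <= peak_floor) {
    return(flagged)
  }

  # bolus arrival guess: last sample below 5% of peak before the peak
  pre <- which(y[seq_len(pk)] <= 0.05 * peak)
  t0_init <- if (length(pre)) tt[max(pre)] else max(tt[1], tt[pk] - 1)

  # recirculation trim: window from first rise to 1.5x the return point
  rise <- which(y > 0.05 * peak)
  first_rise <- if (length(rise)) min(rise) else 1L
  post <- which(seq_along(y) > pk & y < 0.2 * peak)
  if (is.finite(window_factor) && length(post)) {
    ret <- min(post)
    span <- tt[ret] - tt[first_rise]
    t_end <- tt[first_rise] + window_factor * span
    win <- tt <= t_end
  } else {
    win <- rep(TRUE, length(y))
  }
  yw <- y[win]
  tw <- tt[win]

  # log-linearized pre-fit on strictly positive samples past t0
  sel <- yw > 0.02 * peak & tw > t0_init
  init <- c(K = peak, alpha = 2, beta = max((tt[pk] - t0_init) / 2, 0.25))
  if (sum(sel) >= 4) {
    lt <- log(tw[sel] - t0_init)
    co <- tryCatch(
      stats::lm.fit(cbind(1, lt, tw[sel] - t0_init), log(yw[sel]))$coefficients,
      error = function(e) NULL
    )
    if (!is.null(co) && all(is.finite(co)) && co[2] > 0 && co[3] < 0) {
      init <- c(K = unname(exp(co[1])), alpha = unname(co[2]), beta = unname(-1 / co[3]))
    }
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      yv ~ gamma_variate(tv, K, alpha, beta, t0),
      data = list(yv = yw, tv = tw),
      start = list(
        K = init[["K"]], alpha = init[["alpha"]],
        beta = init[["beta"]], t0 = t0_init
      ),
      lower = c(K = 0, alpha = 1e-3, beta = 1e-3, t0 = min(tt)),
      upper = c(K = Inf, alpha = 25, beta = Inf, t0 = max(tt)),
      control = minpack.lm::nls.lm.control(maxiter = max_iter)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(flagged)
  }
  p <- stats::coef(fit)
  res <- sqrt(sum(stats::residuals(fit)^2))
  conv <- isTRUE(fit$convInfo$isConv) && all(is.finite(p)) &&
    p[["beta"]] > 0 && p[["alpha"]] > 0
  structure(
    list(
      K = unname(p[["K"]]), alpha = unname(p[["alpha"]]),
      beta = unname(p[["beta"]]), t0 = unname(p[["t0"]]),
      residual_norm = res, converged = conv, n_used = length(yw)
    ),
    class = "gamma_fit"
  )
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(
    "<gamma_fit> K=", signif(x$K, 4), " alpha=", signif(x$alpha, 4),
    " beta=", signif(x$beta, 4), " t0=", signif(x$t0, 4),
    if (x$converged) " (converged)\n" else " (NOT converged)\n",
    sep = ""
  )
  invisible(x)
}

#' Haemodynamic summaries of a bolus passage
#'
#' From a gamma-variate fit the closed forms are used:
#' CBV = integral of C = `K beta^(alpha+1) Gamma(alpha+1)`; MTT = first
#' moment of C relative to t0 = `beta (alpha+1)` (tissue transit, not
#' arrival delay); and, with no arterial input function available,
#' CBF = CBV / MTT by the central-volume relation. From a raw curve the
#' same quantities are computed by trapezoidal quadrature (the first
#' moment taken about the estimated t0).
#'
#' @param fit a [fit_gamma_variate()] result, or `NULL` to integrate the
#'   curve numerically.
#' @param curve,times concentration curve and times, needed when `fit` is
#'   `NULL` (or for the numeric route).
#' @param t0 arrival time for the numeric first moment (defaults to the
#'   fit's t0, or 0).
#' @return list `cbv`, `cbf`, `mtt`, and `valid` (FALSE when MTT = 0 or
#'   the fit is flagged).
#' @export
perfusion_summaries <- function(fit = NULL, curve = NULL, times = NULL,
                                t0 = NULL) {
  if (!is.null(fit)) {
    if (!isTRUE(fit$converged)) {
      return(list(cbv = NA_real_, cbf = NA_real_, mtt = NA_real_, valid = FALSE))
    }
    cbv <- fit$K * fit$beta^(fit$alpha + 1) * gamma(fit$alpha + 1)
    mtt <- fit$beta * (fit$alpha + 1)
  } else {
    if (is.null(curve) || is.null(times)) {
      stop("need either a fit or a curve with times", call. = FALSE)
    }
    ok <- is.finite(curve)
    y <- curve[ok]
    tt <- times[ok]
    if (is.null(t0)) t0 <- 0
    cbv <- trapz(tt, y)
    m1 <- trapz(tt, y * (tt - t0))
    mtt <- if (cbv > 0) m1 / cbv else 0
  }
  valid <- is.finite(cbv) && is.finite(mtt) && mtt > 0
  list(
    cbv = cbv,
    cbf = if (valid) cbv / mtt else NA_real_,
    mtt = mtt, valid = valid
  )
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Quantify a DSC series into CBV, CBF and MTT maps
#'
#' Converts every masked voxel's signal to concentration, fits the
#' gamma-variate bolus model, and evaluates the analytic perfusion
#' summaries. Voxels with flagged fits are invalid in the output maps.
#'
#' @param series 4D [image_volume()] of the DSC acquisition.
#' @param acq the [dsc_acquisition()].
#' @param mask [roi_mask()] of voxels to quantify (fitting every brain
#'   voxel is supported but slow; masks restricted to the ROIs of
#'   interest are typical).
#' @param ... passed to [fit_gamma_variate()].
#' @return list of [parametric_map()]s `cbv`, `cbf`, `mtt` (a.u.) plus
#'   `n_flagged`.
#' @export
quantify_dsc <- function(series, acq, mask, ...) {
  sd4 <- if (inherits(series, "image_volume")) vol_data(series) else as.array(series)
  dims <- dim(sd4)
  if (length(dims) != 4L || dims[4] != acq$n_rep) {
    stop("series must be 4D with one volume per repetition", call. = FALSE)
  }
  m <- vol_data(mask) & TRUE
  if (!any(m)) stop("mask is empty", call. = FALSE)
  times <- dsc_times(acq)
  sig <- aperm(sd4, c(4, 1, 2, 3))
  dim(sig) <- c(dims[4], prod(dims[1:3]))
  sig <- sig[, as.vector(m), drop = FALSE]

  blank <- array(NA_real_, dims[1:3])
  cbv <- blank
  cbf <- blank
  mtt <- blank
  valid <- array(FALSE, dims[1:3])
  idx <- which(m)
  n_flagged <- 0L
  for (j in seq_along(idx)) {
    cc <- signal_to_concentration(sig[, j], acq)
    fit <- fit_gamma_variate(cc$conc, times, ...)
    ps <- perfusion_summaries(fit)
    if (ps$valid) {
      cbv[idx[j]] <- ps$cbv
      cbf[idx[j]] <- ps$cbf
      mtt[idx[j]] <- ps$mtt
      valid[idx[j]] <- TRUE
    } else {
      n_flagged <- n_flagged + 1L
    }
  }
  pd <- if (inherits(series, "image_volume")) vol_pixdim(series) else c(1, 1, 1)
  list(
    cbv = parametric_map(cbv, pd, "CBV", "a.u.", valid = valid),
    cbf = parametric_map(cbf, pd, "CBF", "a.u.", valid = valid),
    mtt = parametric_map(mtt, pd, "MTT", "s", valid = valid),
    n_flagged = n_flagged
  )
}

#' Normalize a parametric map to a reference region
#'
#' Divides the map by the mean over the valid voxels of the reference ROI
#' (an apparently healthy region distant from the lesion), yielding a
#' dimensionless relative map - the form in which the study reports CBV,
#' CBF and MTT, since no arterial input function is available for
#' absolute calibration.
#'
#' @param map a [parametric_map()].
#' @param reference [roi_mask()] of the reference region.
#' @return relative [parametric_map()] (unit `"relative (a.u.)"`).
#' @export
normalize_to_reference <- function(map, reference) {
  v <- map_valid(map)
  r <- vol_data(reference) & v
  if (!any(r)) stop("reference region has no valid voxels", call. = FALSE)
  ref_mean <- mean(vol_data(map)[r])
  if (!is.finite(ref_mean) || ref_mean == 0) {
    stop("reference-region mean is zero or invalid", call. = FALSE)
  }
  parametric_map(vol_data(map) / ref_mean, vol_pixdim(map),
    map_quantity(map), "relative (a.u.)",
    valid = v
  )
}
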
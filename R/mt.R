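#' Magnetization transfer ratio map
#'
#' Pixel-wise MTR from an MT-off / MT-on image pair:
#' \deqn{\%MTR = (S_0 - S_{MT}) / S_0 \times 100.}
#' Voxels whose MT-off signal falls below a floor (division guard:
#' `max(eps, 1e-3 * median S0)` over the mask, the robust brain median)
#' are marked invalid in the map's validity mask rather than silently
#' zeroed. Under noise the MTR can be negative; values are kept unclipped
#' so ROI means stay unbiased.
#'
#' @param pair list with `s0` and `smt` [image_volume()]s sharing shape
#'   and voxel dimensions (as from [simulate_mt_pair()]).
#' @param mask optional [roi_mask()] restricting the computation (voxels
#'   outside are invalid); typically the brain mask.
#' @param s0_floor optional explicit signal floor overriding the robust
#'   default.
#' @return [parametric_map()] of MTR in %.
#' @export
compute_mtr <- function(pair, mask = NULL, s0_floor = NULL) {
  s0 <- pair$s0
  smt <- pair$smt
  if (!identical(dim(s0), dim(smt))) {
    stop("S0 and SMT shapes differ", call. = FALSE)
  }
  if (any(abs(vol_pixdim(s0) - vol_pixdim(smt)) > 1e-9)) {
    stop("S0 and SMT voxel dimensions differ", call. = FALSE)
  }
  s0d <- vol_data(s0)
  smtd <- vol_data(smt)
  inside <- if (is.null(mask)) {
    array(TRUE, dim = dim(s0d))
  } else {
    if (!identical(dim(vol_data(mask)), dim(s0d))) {
      stop("mask shape does not match the image pair", call. = FALSE)
    }
    vol_data(mask) & TRUE
  }
  if (is.null(s0_floor)) {
    ref <- stats::median(s0d[inside & s0d > 0])
    if (!is.finite(ref)) ref <- 0
    s0_floor <- max(.Machine$double.eps, 1e-3 * ref)
  }
  valid <- inside & s0d >= s0_floor
  if (!any(valid)) {
    stop("no valid voxels: all S0 signals below the floor", call. = FALSE)
  }
  mtr <- array(NA_real_, dim = dim(s0d))
  mtr[valid] <- (s0d[valid] - smtd[valid]) / s0d[valid] * 100
  parametric_map(mtr, vol_pixdim(s0), "MTR", "%", valid = valid)
}
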
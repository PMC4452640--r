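#' Mean diffusivity from tensor eigenvalues
#'
#' MD = (lambda1 + lambda2 + lambda3) / 3, in the eigenvalues' units
#' (um^2/s throughout the package).
#'
#' @param lambda numeric length-3 eigenvalues.
#' @return mean diffusivity.
#' @export
md_from_eigenvalues <- function(lambda) {
  stopifnot(length(lambda) == 3L, all(is.finite(lambda)))
  mean(lambda)
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' Standard normalized form
#' \deqn{FA = \sqrt{3/2}\,\sqrt{\sum_i(\lambda_i - MD)^2} \big/
#'   \sqrt{\sum_i \lambda_i^2},}
#' which maps an isotropic spectrum to 0 and the stick limit (a, 0, 0)
#' to 1. An all-zero spectrum has no defined anisotropy and returns `NA`
#' (callers flag the voxel invalid rather than raise).
#'
#' `printed_form = TRUE` evaluates the unnormalized variant
#' `sqrt(sum((lambda - MD)^2)) / (2 * sum(lambda^2))` that appears in some
#' write-ups of this analysis; it is provided for comparison only and is
#' not bounded by 1 (nor dimensionless).
#'
#' @param lambda numeric length-3 eigenvalues.
#' @param printed_form logical; evaluate the unnormalized variant.
#' @return FA in `[0, 1]` (standard form), or `NA` for a zero spectrum.
#' @export
fa_from_eigenvalues <- function(lambda, printed_form = FALSE) {
  stopifnot(length(lambda) == 3L, all(is.finite(lambda)))
  ss <- sum(lambda^2)
  if (ss == 0) {
    return(NA_real_)
  }
  md <- mean(lambda)
  dev <- sum((lambda - md)^2)
  if (printed_form) {
    return(sqrt(dev) / (2 * ss))
  }
  min(1, sqrt(1.5 * dev / ss))
}

#' Build an axially symmetric tensor with prescribed MD and FA
#'
#' Inverts the MD/FA closed forms for a cylindrically symmetric (prolate)
#' spectrum lambda_parallel >= lambda_perp = lambda_perp aligned with
#' `orientation`. With d = MD * FA / sqrt(3 - 2 FA^2) the spectrum is
#' (MD + 2d, MD - d, MD - d), which reproduces the requested MD and FA
#' exactly and is non-negative for all FA in [0, 1).
#'
#' @param md mean diffusivity, um^2/s, > 0.
#' @param fa fractional anisotropy in `[0, 1)`.
#' @param orientation principal-axis direction (need not be unit length).
#' @return symmetric positive semi-definite 3x3 matrix (um^2/s).
#' @export
tensor_from_md_fa <- function(md, fa, orientation = c(0, 0, 1)) {
  if (!is.finite(md) || md <= 0) stop("md must be positive", call. = FALSE)
  if (!is.finite(fa) || fa < 0 || fa >= 1) {
    stop("fa must lie in [0, 1); no admissible axially symmetric spectrum",
      call. = FALSE
    )
  }
  n <- as.numeric(orientation)
  nn <- sqrt(sum(n^2))
  if (length(n) != 3L || nn == 0) {
    stop("orientation must be a nonzero 3-vector", call. = FALSE)
  }
  n <- n / nn
  d <- md * fa / sqrt(3 - 2 * fa^2)
  l_par <- md + 2 * d
  l_perp <- md - d
  l_perp * diag(3) + (l_par - l_perp) * tcrossprod(n)
}

# Eigenvalues of a symmetric 3x3 given its 6 unique elements
# (xx, yy, zz, xy, xz, yz), sorted descending.
eigen_spectrum6 <- function(d6) {
  m <- matrix(
    c(
      d6[1], d6[4], d6[5],
      d6[4], d6[2], d6[6],
      d6[5], d6[6], d6[3]
    ),
    3, 3
  )
  sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
    decreasing = TRUE
  )
}
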
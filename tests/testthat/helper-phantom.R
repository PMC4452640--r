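# Reduced geometry for fast unit tests: same physics, smaller grids and a
# smaller lesion. Acceptance tests use the full default geometry.
small_geometry <- function() {
  phantom_geometry(
    matrix_size = c(48L, 48L),
    dsc_matrix_size = c(24L, 20L),
    tumour_centre = c(2.6, 0.8, 0),
    tumour_radius = 2.0,
    brain_semiaxes = c(6, 6),
    reference_centre = c(-3.6, 0.8, 0),
    reference_radius = 1.2
  )
}

# Random symmetric positive semi-definite 3x3 tensor with MD on the
# physiological scale (um^2/s).
rand_psd_tensor <- function() {
  a <- matrix(stats::rnorm(9), 3, 3)
  m <- crossprod(a)
  m / mean(diag(m)) * stats::runif(1, 300, 2500)
}

# Random 3D rotation matrix (QR of a Gaussian matrix, det fixed to +1).
rand_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

tensor6 <- function(m) c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
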
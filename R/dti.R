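#' Diffusion acquisition scheme
#'
#' Per-volume b-values (s/mm^2) and unit gradient directions, plus the
#' pulse timing metadata (gradient separation Delta = 16 ms, duration
#' delta = 4 ms). At least one b = 0 volume is required; weighted
#' directions must be unit-norm within 1e-6.
#'
#' @param b numeric b-values, s/mm^2.
#' @param directions matrix with one row per volume and columns
#'   `(gx, gy, gz)`; rows for b = 0 volumes may be zero.
#' @param delta_sep_ms,delta_dur_ms gradient timing metadata.
#' @return a `dti_scheme` object.
#' @export
dti_scheme <- function(b, directions, delta_sep_ms = 16, delta_dur_ms = 4) {
  directions <- as.matrix(directions)
  if (length(b) != nrow(directions) || ncol(directions) != 3L) {
    stop("need one 3-vector direction per b-value", call. = FALSE)
  }
  tab <- data.frame(
    b = as.numeric(b),
    gx = directions[, 1], gy = directions[, 2], gz = directions[, 3]
  )
  s <- structure(
    list(table = tab, delta_sep_ms = delta_sep_ms, delta_dur_ms = delta_dur_ms),
    class = "dti_scheme"
  )
  validate_dti_scheme(s)
  s
}

validate_dti_scheme <- function(scheme) {
  tab <- scheme$table
  if (any(tab$b < 0)) stop("b-values must be non-negative", call. = FALSE)
  if (!any(tab$b == 0)) {
    stop("scheme needs at least one b = 0 volume", call. = FALSE)
  }
  w <- tab$b > 0
  norms <- sqrt(tab$gx[w]^2 + tab$gy[w]^2 + tab$gz[w]^2)
  if (any(abs(norms - 1) > 1e-6)) {
    stop("weighted gradient directions must be unit-norm (tol 1e-6)",
      call. = FALSE
    )
  }
  invisible(scheme)
}

#' @export
print.dti_scheme <- function(x, ...) {
  cat("<dti_scheme> ", nrow(x$table), " volumes, b = {",
    paste(sort(unique(x$table$b)), collapse = ", "), "} s/mm^2\n",
    sep = ""
  )
  invisible(x)
}

#' Default 7-direction scheme
#'
#' One b = 0 volume plus seven directions (the six (1,1,0)/sqrt(2)-family
#' axes-pair directions and (1,1,1)/sqrt(3)) at b = 300 and 1400 s/mm^2 -
#' 15 volumes total. The study acquired one basal image and two b factors
#' in seven directions but does not list its vendor direction set; this
#' documented set is full-rank for the tensor fit and any user scheme is
#' accepted in its place.
#'
#' @param b_values weighted b-values, default `c(300, 1400)`.
#' @return a [dti_scheme()].
#' @export
default_dti_scheme <- function(b_values = c(300, 1400)) {
  dirs <- rbind(
    c(1, 1, 0), c(1, -1, 0),
    c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1)
  )
  dirs <- dirs / sqrt(rowSums(dirs^2))
  b <- c(0, rep(b_values, each = nrow(dirs)))
  g <- rbind(c(0, 0, 0), dirs[rep(seq_len(nrow(dirs)), times = length(b_values)), ])
  dti_scheme(b, g)
}

#' Design matrix of the log-linear tensor model
#'
#' Row i maps the six unique tensor elements plus log S0 to the
#' log-signal of volume i:
#' `[-b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz, 1]`.
#' The matrix must have full column rank (7); rank-deficient schemes
#' (e.g. too few non-collinear directions) raise an error naming the
#' deficiency.
#'
#' @param scheme a [dti_scheme()].
#' @return numeric matrix, one row per volume, 7 columns.
#' @export
build_design_matrix <- function(scheme) {
  validate_dti_scheme(scheme)
  tab <- scheme$table
  X <- cbind(
    -tab$b * tab$gx^2,
    -tab$b * tab$gy^2,
    -tab$b * tab$gz^2,
    -2 * tab$b * tab$gx * tab$gy,
    -2 * tab$b * tab$gx * tab$gz,
    -2 * tab$b * tab$gy * tab$gz,
    1
  )
  colnames(X) <- c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz", "logS0")
  r <- qr(X)$rank
  if (r < 7L) {
    stop(
      "diffusion scheme is rank-deficient (design rank ", r,
      " < 7); need >= 6 non-collinear weighted directions plus b = 0",
      call. = FALSE
    )
  }
  X
}

#' Fit the diffusion tensor voxel-wise
#'
#' Ordinary least squares on the log-signals (plain log-linear fit, no
#' weighting) per voxel inside the mask. Voxels containing any
#' non-positive signal are flagged invalid - the log is undefined there
#' and silent epsilon substitution would bias the tensor. Tensors are
#' returned in um^2/s.
#'
#' @param series 4D [image_volume()] (or array), volumes in scheme order.
#' @param scheme the [dti_scheme()] used for the acquisition.
#' @param mask [roi_mask()] of voxels to fit (non-empty).
#' @return a `tensor_field`: list of six component arrays
#'   (`xx, yy, zz, xy, xz, yz`, um^2/s), `s0`, and `valid`.
#' @export
fit_tensor <- function(series, scheme, mask) {
  X <- build_design_matrix(scheme)
  sd4 <- if (inherits(series, "image_volume")) vol_data(series) else as.array(series)
  dims <- dim(sd4)
  if (length(dims) != 4L || dims[4] != nrow(X)) {
    stop("series must be 4D with one volume per scheme entry", call. = FALSE)
  }
  m <- vol_data(mask) & TRUE
  if (!identical(dim(m), dims[1:3])) {
    stop("mask shape does not match series", call. = FALSE)
  }
  if (!any(m)) stop("mask is empty", call. = FALSE)

  nvox <- sum(m)
  sig <- aperm(sd4, c(4, 1, 2, 3))
  dim(sig) <- c(dims[4], prod(dims[1:3]))
  sig <- sig[, as.vector(m), drop = FALSE]
  ok <- colSums(sig <= 0) == 0
  coef <- matrix(NA_real_, nrow = 7, ncol = nvox)
  if (any(ok)) {
    coef[, ok] <- qr.solve(X, log(sig[, ok, drop = FALSE]))
  }

  blank <- array(NA_real_, dim = dims[1:3])
  comp <- list(xx = blank, yy = blank, zz = blank, xy = blank, xz = blank, yz = blank)
  # b is in s/mm^2 so the fitted elements are mm^2/s -> um^2/s
  for (i in seq_along(comp)) comp[[i]][m] <- coef[i, ] * 1e6
  s0 <- blank
  s0[m] <- exp(coef[7, ])
  valid <- array(FALSE, dim = dims[1:3])
  valid[m] <- ok

  structure(
    list(
      xx = comp$xx, yy = comp$yy, zz = comp$zz,
      xy = comp$xy, xz = comp$xz, yz = comp$yz,
      s0 = s0, valid = valid,
      pixdim = if (inherits(series, "image_volume")) vol_pixdim(series) else c(1, 1, 1)
    ),
    class = "tensor_field"
  )
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("<tensor_field> ", paste(dim(x$xx), collapse = " x "), " voxels, ",
    sum(x$valid), " valid\n",
    sep = ""
  )
  invisible(x)
}

#' MD and FA maps from a fitted tensor field
#'
#' Eigendecomposes every valid voxel's tensor and applies
#' [md_from_eigenvalues()] and [fa_from_eigenvalues()]. Negative
#' eigenvalues (possible under noise) are clamped to zero before the FA
#' evaluation and the voxel is flagged in the returned `clamped` count;
#' all-zero spectra are marked invalid.
#'
#' @param tensor a `tensor_field` from [fit_tensor()].
#' @param mask optional [roi_mask()] further restricting the output.
#' @param printed_form evaluate the unnormalized FA variant instead of
#'   the standard one (see [fa_from_eigenvalues()]).
#' @return list with `md` and `fa` [parametric_map()]s and `clamped`, the
#'   number of voxels whose spectrum needed clamping.
#' @export
md_fa_maps <- function(tensor, mask = NULL, printed_form = FALSE) {
  stopifnot(inherits(tensor, "tensor_field"))
  dims <- dim(tensor$xx)
  sel <- tensor$valid
  if (!is.null(mask)) sel <- sel & (vol_data(mask) & TRUE)
  idx <- which(sel)
  md <- array(NA_real_, dims)
  fa <- array(NA_real_, dims)
  valid <- array(FALSE, dims)
  clamped <- 0L
  for (i in idx) {
    lam <- eigen_spectrum6(c(
      tensor$xx[i], tensor$yy[i], tensor$zz[i],
      tensor$xy[i], tensor$xz[i], tensor$yz[i]
    ))
    if (any(lam < 0)) {
      clamped <- clamped + sum(lam < 0)
      lam <- pmax(lam, 0)
    }
    md[i] <- md_from_eigenvalues(lam)
    f <- fa_from_eigenvalues(lam, printed_form = printed_form)
    fa[i] <- f
    valid[i] <- is.finite(f)
  }
  list(
    md = parametric_map(md, tensor$pixdim, "MD", "um^2/s", valid = valid),
    fa = parametric_map(fa, tensor$pixdim, "FA", "unitless", valid = valid),
    clamped = clamped
  )
}
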
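#' Image volume container
#'
#' A thin S3 wrapper around a 3D (or 4D) numeric array carrying the voxel
#' dimensions in mm and an intensity unit tag. All quantification functions
#' in the package consume and produce these.
#'
#' @param data numeric array, 3D `(x, y, z)` or 4D `(x, y, z, volume)`.
#' @param pixdim numeric length-3 voxel dimensions in mm `(dx, dy, dz)`.
#' @param unit character unit tag (e.g. `"a.u."`, `"%"`, `"um^2/s"`).
#' @return an `image_volume` object.
#' @export
image_volume <- function(data, pixdim, unit = "a.u.") {
  data <- as.array(data)
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) {
    stop("image_volume expects a 3D or 4D array, got ", nd, "D", call. = FALSE)
  }
  pixdim <- as.numeric(pixdim)
  if (length(pixdim) != 3L || any(!is.finite(pixdim)) || any(pixdim <= 0)) {
    stop("pixdim must be three positive voxel dimensions in mm", call. = FALSE)
  }
  structure(data,
    pixdim = pixdim, unit = unit,
    class = c("image_volume", "array")
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(
    "<image_volume> ", paste(dim(x), collapse = " x "),
    " voxels, ", paste(signif(vol_pixdim(x), 4), collapse = " x "),
    " mm, unit: ", attr(x, "unit"), "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname image_volume
#' @param x an `image_volume` or `parametric_map`.
#' @export
vol_pixdim <- function(x) attr(x, "pixdim")

#' @rdname image_volume
#' @export
vol_unit <- function(x) attr(x, "unit")

#' @rdname image_volume
#' @export
voxel_volume <- function(x) prod(attr(x, "pixdim"))

#' @rdname image_volume
#' @export
vol_data <- function(x) {
  a <- unclass(x)
  attributes(a) <- list(dim = dim(x))
  a
}

#' Parametric map
#'
#' An [image_volume()] tagged with the quantity it encodes (MTR, MD, FA,
#' CBV, CBF or MTT) and a per-voxel validity mask. Voxels that could not be
#' quantified (e.g. non-positive signals, failed fits) are flagged invalid
#' rather than silently zeroed, and excluded from ROI summaries.
#'
#' @param data 3D numeric array of voxel values.
#' @param pixdim voxel dimensions in mm.
#' @param quantity character, e.g. `"MTR"`.
#' @param unit character unit tag.
#' @param valid logical array of the same shape; `TRUE` where quantified.
#' @return a `parametric_map` object.
#' @export
parametric_map <- function(data, pixdim, quantity, unit,
                           valid = NULL) {
  v <- image_volume(data, pixdim, unit)
  if (is.null(valid)) valid <- array(TRUE, dim = dim(v))
  valid <- as.array(valid)
  if (!identical(dim(valid), dim(v))) {
    stop("validity mask shape does not match map shape", call. = FALSE)
  }
  storage.mode(valid) <- "logical"
  structure(unclass(v),
    pixdim = vol_pixdim(v), unit = unit, quantity = quantity, valid = valid,
    class = c("parametric_map", "image_volume", "array")
  )
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(
    "<parametric_map> ", attr(x, "quantity"), " [", attr(x, "unit"), "], ",
    paste(dim(x), collapse = " x "), " voxels, ",
    sum(attr(x, "valid")), " valid\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname parametric_map
#' @param x a `parametric_map`.
#' @export
map_valid <- function(x) {
  v <- attr(x, "valid")
  if (is.null(v)) array(TRUE, dim = dim(x)) else v
}

#' @rdname parametric_map
#' @export
map_quantity <- function(x) attr(x, "quantity")

#' Region-of-interest mask
#'
#' A binary volume on the same grid as the maps it summarizes, labelled by
#' its role (tumour core, periphery ring, whole tumour, reference region or
#' brain).
#'
#' @param data logical (or 0/1) 3D array.
#' @param pixdim voxel dimensions in mm.
#' @param label one of `"core"`, `"periphery"`, `"tumour"`, `"reference"`,
#'   `"brain"`.
#' @return an `roi_mask` object.
#' @export
roi_mask <- function(data, pixdim, label = "brain") {
  data <- as.array(data)
  storage.mode(data) <- "logical"
  if (length(dim(data)) != 3L) stop("roi_mask must be 3D", call. = FALSE)
  label <- match.arg(label, c("core", "periphery", "tumour", "reference", "brain"))
  v <- image_volume(data * 1, pixdim, unit = "binary")
  structure(data,
    pixdim = vol_pixdim(v), label = label,
    class = c("roi_mask", "array")
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(
    "<roi_mask> ", attr(x, "label"), ", ", sum(x), " voxels (",
    signif(mask_volume(x), 4), " mm^3)\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname roi_mask
#' @param x an `roi_mask`.
#' @export
mask_label <- function(x) attr(x, "label")

#' Volume of a binary mask in mm^3
#'
#' Voxel count times voxel volume; the bookkeeping used to check that the
#' phantom tumour matches the study's scan-trigger volume (tumours were
#' imaged at roughly 75 to 100 mm^3).
#'
#' @param roi an [roi_mask()].
#' @return volume in mm^3 (0 for an empty mask).
#' @export
mask_volume <- function(roi) {
  sum(roi) * prod(attr(roi, "pixdim"))
}

# Run expr with a fixed RNG state, restoring the caller's stream after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}
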
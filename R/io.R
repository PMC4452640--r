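#' Read / write image volumes as NIfTI-1
#'
#' `read_volume()` loads a 3D or 4D NIfTI file into an [image_volume()]
#' (2D files are rejected); the unit tag is recovered from the header
#' description field when present. `write_volume()` writes one, storing
#' voxel dimensions in the header and the unit tag in the description
#' field, so a write/read round trip preserves data, pixdim and unit.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume`: an [image_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop("no such NIfTI file: ", path, call. = FALSE)
  }
  img <- tryCatch(RNifti::readNifti(path),
    error = function(e) stop("malformed NIfTI file ", path, ": ",
      conditionMessage(e),
      call. = FALSE
    )
  )
  nd <- length(dim(img))
  if (nd < 3L) {
    stop(path, " is ", nd, "D; a 3D or 4D volume is expected", call. = FALSE)
  }
  unit <- RNifti::niftiHeader(img)$descrip
  if (is.null(unit) || !nzchar(unit)) unit <- "a.u."
  image_volume(as.array(img), RNifti::pixdim(img)[1:3], unit)
}

#' @rdname read_volume
#' @param vol an [image_volume()] or [parametric_map()].
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path))) {
    stop("output directory does not exist: ", dirname(path), call. = FALSE)
  }
  pd <- vol_pixdim(vol)
  nd <- length(dim(vol))
  pixdim8 <- c(-1, pd, rep(0, 4))
  if (nd == 4L) pixdim8[5] <- 1 # nominal volume spacing
  img <- RNifti::asNifti(vol_data(vol),
    reference = list(pixdim = pixdim8, descrip = substr(vol_unit(vol), 1, 79))
  )
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a diffusion scheme file
#'
#' Plain whitespace-delimited text, one `b gx gy gz` line per volume.
#'
#' @param path scheme file path.
#' @return `read_scheme`: a [dti_scheme()].
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop("no such scheme file: ", path, call. = FALSE)
  tab <- utils::read.table(path,
    col.names = c("b", "gx", "gy", "gz"),
    comment.char = "#"
  )
  dti_scheme(tab$b, as.matrix(tab[, c("gx", "gy", "gz")]))
}

#' @rdname read_scheme
#' @param scheme a [dti_scheme()].
#' @export
write_scheme <- function(scheme, path) {
  tab <- scheme$table
  lines <- c(
    "# b(s/mm^2) gx gy gz",
    sprintf("%g %.10f %.10f %.10f", tab$b, tab$gx, tab$gy, tab$gz)
  )
  writeLines(lines, path)
  invisible(path)
}
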
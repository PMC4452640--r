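#' Phantom geometry
#'
#' Continuous description of the digital phantom: the acquisition grids and
#' the physical placement (mm) of brain, tumour and reference regions. The
#' map grid matches the MTR/DTI acquisitions (128 x 128, 273 um in-plane,
#' five 1.5-mm slices); the perfusion grid matches the lower-resolution DSC
#' readout (80 x 64, 437 x 547 um). Masks are rasterized from the same
#' continuous shapes onto either grid, so the tumour occupies the same
#' physical location in every modality.
#'
#' The tumour is a sphere sized to the study's scan-trigger volume
#' (approximately 75-100 mm^3), implanted off-centre in the right
#' hemisphere; its outer shell of `periphery_width` mm is the "enhanced
#' outer ring" periphery ROI and the remainder is the core. The reference
#' region is a contralateral sphere distant from the lesion, used to
#' normalize perfusion maps.
#'
#' @param matrix_size map-grid in-plane size, default `c(128, 128)`.
#' @param n_slices number of axial slices, default 5.
#' @param inplane_res map-grid in-plane resolution in mm, default 0.273.
#' @param slice_thickness slice thickness in mm, default 1.5.
#' @param dsc_matrix_size DSC grid size, default `c(80, 64)`.
#' @param dsc_inplane_res DSC in-plane resolution in mm `(dx, dy)`,
#'   default `c(0.437, 0.547)`.
#' @param tumour_centre tumour centre in mm from grid centre.
#' @param tumour_radius tumour radius in mm (2.78 mm gives ~90 mm^3).
#' @param periphery_width periphery ring width in mm (two map voxels).
#' @param brain_semiaxes in-plane semi-axes (mm) of the elliptic-cylinder
#'   brain mask spanning all slices.
#' @param reference_centre,reference_radius contralateral reference sphere.
#' @return a `phantom_geometry` object.
#' @export
phantom_geometry <- function(matrix_size = c(128L, 128L),
                             n_slices = 5L,
                             inplane_res = 0.273,
                             slice_thickness = 1.5,
                             dsc_matrix_size = c(80L, 64L),
                             dsc_inplane_res = c(0.437, 0.547),
                             tumour_centre = c(3.2, 1.0, 0),
                             tumour_radius = 2.78,
                             periphery_width = 2 * 0.273,
                             brain_semiaxes = c(8.0, 11.0),
                             reference_centre = c(-4.2, 1.0, 0),
                             reference_radius = 1.6) {
  stopifnot(
    length(matrix_size) == 2L, all(matrix_size > 0),
    n_slices >= 1, inplane_res > 0, slice_thickness > 0,
    tumour_radius > 0, periphery_width > 0, reference_radius > 0
  )
  g <- structure(
    list(
      matrix_size = as.integer(matrix_size),
      n_slices = as.integer(n_slices),
      inplane_res = inplane_res,
      slice_thickness = slice_thickness,
      dsc_matrix_size = as.integer(dsc_matrix_size),
      dsc_inplane_res = dsc_inplane_res,
      tumour_centre = tumour_centre,
      tumour_radius = tumour_radius,
      periphery_width = periphery_width,
      brain_semiaxes = brain_semiaxes,
      reference_centre = reference_centre,
      reference_radius = reference_radius
    ),
    class = "phantom_geometry"
  )
  # reference must not touch the tumour and both must fit in the brain
  d <- sqrt(sum((g$tumour_centre - g$reference_centre)^2))
  if (d <= g$tumour_radius + g$reference_radius) {
    stop("reference region overlaps the tumour", call. = FALSE)
  }
  half_slab <- g$n_slices * g$slice_thickness / 2
  for (nm in c("tumour", "reference")) {
    ctr <- g[[paste0(nm, "_centre")]]
    r <- g[[paste0(nm, "_radius")]]
    shrunk <- g$brain_semiaxes - r # conservative: ellipse eroded by r
    inside_xy <- all(shrunk > 0) && sum((ctr[1:2] / shrunk)^2) <= 1
    inside_z <- abs(ctr[3]) + r <= half_slab
    if (!inside_xy || !inside_z) {
      stop(nm, " region extends outside the brain mask", call. = FALSE)
    }
  }
  g
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat("<phantom_geometry> map grid ", paste(c(x$matrix_size, x$n_slices), collapse = " x "),
    " @ ", x$inplane_res, " mm; tumour r = ", x$tumour_radius, " mm\n",
    sep = ""
  )
  invisible(x)
}

# Voxel-centre coordinates (mm, grid-centred) for a grid spec.
grid_coords <- function(n, d) (seq_len(n) - (n + 1) / 2) * d

geometry_grid <- function(geometry, grid = c("map", "dsc")) {
  grid <- match.arg(grid)
  if (grid == "map") {
    list(
      dims = c(geometry$matrix_size, geometry$n_slices),
      pixdim = c(
        geometry$inplane_res, geometry$inplane_res,
        geometry$slice_thickness
      )
    )
  } else {
    list(
      dims = c(geometry$dsc_matrix_size, geometry$n_slices),
      pixdim = c(geometry$dsc_inplane_res, geometry$slice_thickness)
    )
  }
}

# Distance of every voxel centre from a point (mm); returns a 3D array.
voxel_distance <- function(dims, pixdim, centre) {
  x <- grid_coords(dims[1], pixdim[1]) - centre[1]
  y <- grid_coords(dims[2], pixdim[2]) - centre[2]
  z <- grid_coords(dims[3], pixdim[3]) - centre[3]
  dx2 <- array(rep(x^2, times = dims[2] * dims[3]), dim = dims)
  dy2 <- aperm(array(rep(y^2, times = dims[1] * dims[3]),
    dim = dims[c(2, 1, 3)]
  ), c(2, 1, 3))
  dz2 <- aperm(array(rep(z^2, times = dims[1] * dims[2]),
    dim = dims[c(3, 1, 2)]
  ), c(2, 3, 1))
  sqrt(dx2 + dy2 + dz2)
}

#' Rasterize the phantom ROI masks onto an acquisition grid
#'
#' @param geometry a [phantom_geometry()].
#' @param grid `"map"` (MTR/DTI grid) or `"dsc"` (perfusion grid).
#' @return named list of [roi_mask()]: `brain`, `tumour`, `core`,
#'   `periphery`, `reference`. Core and periphery partition the tumour and
#'   all regions lie inside the brain.
#' @export
phantom_masks <- function(geometry, grid = c("map", "dsc")) {
  grid <- match.arg(grid)
  gg <- geometry_grid(geometry, grid)
  dims <- gg$dims
  pixdim <- gg$pixdim

  xs <- grid_coords(dims[1], pixdim[1])
  ys <- grid_coords(dims[2], pixdim[2])
  ex <- outer((xs / geometry$brain_semiaxes[1])^2,
    (ys / geometry$brain_semiaxes[2])^2, `+`) <= 1
  brain <- array(rep(ex, times = dims[3]), dim = dims)

  dt <- voxel_distance(dims, pixdim, geometry$tumour_centre)
  tumour <- dt <= geometry$tumour_radius
  periphery <- tumour & dt > (geometry$tumour_radius - geometry$periphery_width)
  core <- tumour & !periphery

  dr <- voxel_distance(dims, pixdim, geometry$reference_centre)
  reference <- dr <= geometry$reference_radius

  list(
    brain = roi_mask(brain, pixdim, "brain"),
    tumour = roi_mask(tumour & brain, pixdim, "tumour"),
    core = roi_mask(core & brain, pixdim, "core"),
    periphery = roi_mask(periphery & brain, pixdim, "periphery"),
    reference = roi_mask(reference & brain, pixdim, "reference")
  )
}
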
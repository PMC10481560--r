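#' Axis-aligned 3D scalar volume
#'
#' A `voxel_grid` holds a 3D scalar field (relative electron density, or dose
#' in Gy) on a regular axis-aligned grid. The array axes follow the patient
#' axes in the fixed order RL, AP, CC:
#'
#' * axis 1 (RL): increasing index points to the patient's **left**;
#' * axis 2 (AP): increasing index points **posterior**;
#' * axis 3 (CC): increasing index points **cranial**.
#'
#' `origin` is the world coordinate (mm) of the centre of voxel `[1, 1, 1]`;
#' voxel centres along axis `k` are `origin[k] + (0:(dim - 1)) * spacing[k]`.
#' This is the single place the coordinate convention is defined; every other
#' function in the package inherits it through the grid metadata.
#'
#' @param values numeric 3D array.
#' @param spacing positive numeric length-3, voxel size in mm.
#' @param origin numeric length-3, world position (mm) of the first voxel
#'   centre.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (mm)")
  structure(
    list(values = values, spacing = spacing, origin = origin,
         axes = c("RL", "AP", "CC")),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels (RL x AP x CC), spacing %s mm\n",
    d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  origin (%s) mm, value range [%g, %g]\n",
              paste(format(x$origin), collapse = ", "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

grid_geometry <- function(x) {
  list(dims = grid_dims(x), spacing = x$spacing, origin = x$origin)
}

grid_dims <- function(x) {
  if (inherits(x, "voxel_grid")) dim(x$values)
  else if (inherits(x, "roi_mask")) dim(x$voxels)
  else if (inherits(x, "structure_set")) x$dims
  else stop("no grid geometry on object of class ", paste(class(x), collapse = "/"))
}

#' Test whether two gridded objects share the same geometry
#'
#' @param a,b voxel grids, ROI masks or structure sets.
#' @param tol tolerance (mm) on spacing and origin.
#' @return Logical scalar.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  ga <- list(dims = grid_dims(a), spacing = a$spacing, origin = a$origin)
  gb <- list(dims = grid_dims(b), spacing = b$spacing, origin = b$origin)
  identical(ga$dims, gb$dims) &&
    all(abs(ga$spacing - gb$spacing) < tol) &&
    all(abs(ga$origin - gb$origin) < tol)
}

stop_if_geometry_differs <- function(a, b) {
  if (!same_geometry(a, b))
    stop("grid geometry mismatch between operands")
  invisible(TRUE)
}

#' Voxel-centre world coordinates
#'
#' @param x a gridded object.
#' @param idx optional integer matrix (n x 3) of 1-based voxel indices; by
#'   default all voxels.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
voxel_centers_mm <- function(x, idx = NULL) {
  d <- grid_dims(x)
  if (is.null(idx)) {
    idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  }
  sweep(sweep(idx - 1, 2, x$spacing, "*"), 2, x$origin, "+")
}

#' Volume of one voxel in cubic centimetres
#' @param x a gridded object.
#' @return Numeric scalar (cc).
#' @export
voxel_volume_cc <- function(x) prod(x$spacing) / 1000

linear_index <- function(dims, idx) {
  (idx[, 1] - 1) + dims[1] * ((idx[, 2] - 1) + dims[2] * (idx[, 3] - 1)) + 1
}

#' Resample a grid onto another geometry by trilinear interpolation
#'
#' Values outside the source grid are taken as zero.
#'
#' @param x source `voxel_grid`.
#' @param target a gridded object carrying the destination geometry.
#' @return A `voxel_grid` on the target geometry.
#' @export
resample_to <- function(x, target) {
  stopifnot(inherits(x, "voxel_grid"))
  pts <- voxel_centers_mm(target)
  vals <- cpp_resample(as.numeric(x$values), dim(x$values), x$spacing,
                       x$origin, pts)
  voxel_grid(array(vals, grid_dims(target)), target$spacing, target$origin)
}
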
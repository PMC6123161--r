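#' Volumetric containers with grid geometry
#'
#' Light S3 containers for the three kinds of gridded objects the package
#' works with: scalar intensity volumes (`vol3d`), binary organ masks
#' (`mask3d`) and per-voxel displacement fields in millimetres (`dvf3d`).
#' All three share the same geometry model: a regular voxel grid with
#' per-axis spacing in mm and an origin at the centre of voxel `(1,1,1)`.
#' Axis 3 of the array is the superior-inferior (SI) axis, with +z pointing
#' superior.
#'
#' @param data 3D numeric array (`vol3d`) or array coercible to logical
#'   (`mask3d`).
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin numeric length-3, mm position of the first voxel centre.
#' @param phase optional respiratory phase index (0 = full exhalation).
#' @param organ,source,series optional provenance tags carried by masks
#'   (organ name; `"manual"`/`"auto"`/`"truth"`; `"navigator"`/`"bellows"`).
#' @return An object of class `"vol3d"` or `"mask3d"`.
#' @examples
#' v <- vol3d(array(0, c(4, 4, 4)), spacing = c(2, 2, 5))
#' voxel_volume(v)
#' @export
vol3d <- function(data, spacing = c(2, 2, 5), origin = c(0, 0, 0), phase = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive finite values", call. = FALSE)
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), phase = phase),
            class = "vol3d")
}

#' @rdname vol3d
#' @export
mask3d <- function(data, spacing = c(2, 2, 5), origin = c(0, 0, 0),
                   organ = NULL, phase = NULL, source = NULL, series = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  storage.mode(data) <- "logical"
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), organ = organ, phase = phase,
                 source = source, series = series),
            class = "mask3d")
}

#' Displacement field container
#'
#' Stores a dense 3-component displacement field on a fixed-image grid.
#' Components are in mm and map a fixed-grid point `x` to the moving-image
#' point `x + u(x)`.
#'
#' @param ux,uy,uz 3D arrays of identical dimension: displacement components
#'   (mm) along the grid axes.
#' @inheritParams vol3d
#' @return Object of class `"dvf3d"`.
#' @export
dvf3d <- function(ux, uy, uz, spacing = c(2, 2, 5), origin = c(0, 0, 0)) {
  stopifnot(identical(dim(ux), dim(uy)), identical(dim(ux), dim(uz)))
  if (!all(is.finite(ux)) || !all(is.finite(uy)) || !all(is.finite(uz)))
    stop("displacement components must be finite", call. = FALSE)
  structure(list(ux = ux, uy = uy, uz = uz, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "dvf3d")
}

#' @export
print.vol3d <- function(x, ...) {
  cat(sprintf("<vol3d> %s voxels, spacing %s mm%s\n",
              paste(dim(x$data), collapse = "x"),
              paste(x$spacing, collapse = "x"),
              if (!is.null(x$phase)) sprintf(", phase %d", x$phase) else ""))
  invisible(x)
}

#' @export
print.mask3d <- function(x, ...) {
  cat(sprintf("<mask3d> %s voxels, %d foreground, spacing %s mm%s\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              paste(x$spacing, collapse = "x"),
              if (!is.null(x$organ)) paste0(", organ ", x$organ) else ""))
  invisible(x)
}

#' @export
print.dvf3d <- function(x, ...) {
  mag <- sqrt(x$ux^2 + x$uy^2 + x$uz^2)
  cat(sprintf("<dvf3d> %s voxels, |u| max %.2f mm, mean %.2f mm\n",
              paste(dim(x$ux), collapse = "x"), max(mag), mean(mag)))
  invisible(x)
}

grid_dim <- function(x) {
  if (inherits(x, "dvf3d")) dim(x$ux) else dim(x$data)
}

#' Voxel volume in mm^3
#' @param x a `vol3d`, `mask3d` or `dvf3d` object.
#' @export
voxel_volume <- function(x) prod(x$spacing)

#' Check that two gridded objects share a grid
#' @param a,b gridded objects.
#' @param tol geometric tolerance in mm.
#' @return `TRUE` invisibly, or an error.
#' @export
assert_same_grid <- function(a, b, tol = 1e-6) {
  if (!identical(grid_dim(a), grid_dim(b)))
    stop("grid mismatch: dimensions differ (",
         paste(grid_dim(a), collapse = "x"), " vs ",
         paste(grid_dim(b), collapse = "x"), ")", call. = FALSE)
  if (max(abs(a$spacing - b$spacing)) > tol || max(abs(a$origin - b$origin)) > tol)
    stop("grid mismatch: spacing or origin differ", call. = FALSE)
  invisible(TRUE)
}

# mm coordinate of voxel centres along one axis (1-based indices)
axis_coords_mm <- function(x, axis) {
  n <- grid_dim(x)[axis]
  x$origin[axis] + (seq_len(n) - 1) * x$spacing[axis]
}

# full coordinate arrays (list of three 3D arrays, mm)
coord_arrays_mm <- function(dim, spacing, origin = c(0, 0, 0)) {
  cx <- origin[1] + (seq_len(dim[1]) - 1) * spacing[1]
  cy <- origin[2] + (seq_len(dim[2]) - 1) * spacing[2]
  cz <- origin[3] + (seq_len(dim[3]) - 1) * spacing[3]
  list(x = array(cx, dim),
       y = array(rep(cy, each = dim[1]), dim),
       z = array(rep(cz, each = dim[1] * dim[2]), dim))
}

#' Total mask volume in mm^3
#' @param mask a `mask3d`.
#' @export
mask_volume <- function(mask) sum(mask$data) * voxel_volume(mask)

#' Centre of mass of a mask in mm
#' @param mask a `mask3d` with at least one foreground voxel.
#' @return numeric length 3 (mm).
#' @export
mask_com <- function(mask) {
  if (!any(mask$data)) stop("empty mask has no centre of mass", call. = FALSE)
  idx <- which(mask$data, arr.ind = TRUE)
  unname(colMeans((idx - 1) * rep(mask$spacing, each = nrow(idx)))) + mask$origin
}

# Gaussian kernel (normalized) with sigma in axis units; radius 3 sigma
gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  k / sum(k)
}

#' Separable Gaussian smoothing of a 3D array
#'
#' @param a 3D numeric array.
#' @param sigma_mm smoothing scale in mm (scalar or length 3).
#' @param spacing voxel spacing in mm.
#' @return smoothed array of the same dimension.
#' @export
gaussian_smooth3 <- function(a, sigma_mm, spacing = c(1, 1, 1)) {
  d <- dim(a)
  sigma_mm <- rep(sigma_mm, length.out = 3)
  v <- as.numeric(a)
  for (ax in 1:3) {
    sv <- sigma_mm[ax] / spacing[ax]
    if (sv > 1e-8 && d[ax] > 1)
      v <- cpp_convolve_axis(v, as.integer(d), gauss_kernel(sv), ax)
  }
  array(v, d)
}

# random smooth field: white noise smoothed and rescaled to unit sd
smooth_noise_field <- function(dim, spacing, corr_mm) {
  n <- array(rnorm(prod(dim)), dim)
  s <- gaussian_smooth3(n, corr_mm, spacing)
  sdv <- sd(as.numeric(s))
  if (sdv < 1e-12) return(array(0, dim))
  s / sdv
}

# bounding box (list lo, hi of integer index vectors) of TRUE voxels
mask_bbox <- function(data) {
  idx <- which(data, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  list(lo = apply(idx, 2, min), hi = apply(idx, 2, max))
}

dilate_bbox <- function(box, dil, dim) {
  list(lo = pmax(box$lo - dil, 1L), hi = pmin(box$hi + dil, dim))
}

bbox_to_mask <- function(box, dim) {
  m <- array(FALSE, dim)
  m[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]] <- TRUE
  m
}
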